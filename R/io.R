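## File I/O: GTF annotation, BED alignments, FASTA sequences, TSV count
## matrices, GMT gene sets. All text formats; coordinates in files follow
## each format's convention (GTF/FASTA/TSV 1-based closed, BED 0-based
## half-open) and are converted to the package's 1-based closed convention
## on read.

#' Write a transcript annotation as GTF
#'
#' Emits one `transcript` feature and one `exon` feature per exon, with
#' `transcript_id` and `biotype` attributes.
#'
#' @param ann A [transcript_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  tx <- ann$transcripts
  attr_str <- function(id, biotype) {
    sprintf('transcript_id "%s"; biotype "%s";', id, biotype)
  }
  tx_lines <- sprintf("%s\tsahnet\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      tx$chrom, tx$start, tx$end, tx$strand,
                      attr_str(tx$transcript_id, tx$biotype))
  ex <- ann$exons
  m <- match(ex$transcript_id, tx$transcript_id)
  ex_lines <- sprintf("%s\tsahnet\texon\t%d\t%d\t.\t%s\t.\t%s",
                      tx$chrom[m], ex$start, ex$end, tx$strand[m],
                      attr_str(ex$transcript_id, tx$biotype[m]))
  ## interleave in transcript order: transcript line then its exons
  ord <- order(c(match(tx$transcript_id, tx$transcript_id) - 0.5, m))
  writeLines(c(tx_lines, ex_lines)[ord], path)
  invisible(path)
}

#' Read a GTF annotation written by [write_gtf()] (or compatible)
#'
#' Uses `rtracklayer` for parsing; requires `transcript_id` attributes and
#' exon features. A missing `biotype` attribute yields `"unclassified"`.
#'
#' @param path GTF file path.
#' @return A [transcript_annotation()].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!"transcript_id" %in% names(df)) {
    stop_domain("GTF lacks transcript_id attributes: ", path)
  }
  if (!"biotype" %in% names(df)) df$biotype <- "unclassified"
  extx <- df[df$type == "exon", , drop = FALSE]
  if (nrow(extx) == 0L) stop_domain("GTF has no exon features: ", path)
  sp <- split(extx, extx$transcript_id)
  tx <- do.call(rbind, lapply(sp, function(e) {
    data.frame(transcript_id = e$transcript_id[1],
               chrom = as.character(e$seqnames[1]),
               start = min(e$start), end = max(e$end),
               strand = as.character(e$strand[1]),
               biotype = e$biotype[1])
  }))
  ## preserve file order of first appearance
  tx <- tx[order(match(tx$transcript_id, unique(extx$transcript_id))), ]
  exons <- data.frame(transcript_id = extx$transcript_id,
                      start = extx$start, end = extx$end)
  transcript_annotation(tx, exons)
}

#' Write read alignments as BED
#'
#' Single-block reads are written as BED6; if any read has multiple blocks
#' (e.g. exon-exon junction reads) BED12 is used for all rows.
#'
#' @param aln A `read_alignments` data.frame (see [simulate_alignments()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(aln, path) {
  n_blocks <- vapply(strsplit(aln$block_sizes, ","), length, integer(1))
  if (any(n_blocks > 1L)) {
    sizes <- aln$block_sizes
    rel_starts <- mapply(function(bs, s) {
      paste(as.integer(strsplit(bs, ",")[[1]]) - s, collapse = ",")
    }, aln$block_starts, aln$start)
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                     aln$chrom, aln$start - 1L, aln$end, aln$name,
                     aln$strand, aln$start - 1L, aln$end, n_blocks,
                     sizes, rel_starts)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     aln$chrom, aln$start - 1L, aln$end, aln$name, aln$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read BED6/BED12 alignments
#'
#' @param path BED file path.
#' @return A `read_alignments` data.frame with 1-based closed coordinates
#'   and comma-string `block_sizes` / `block_starts` (absolute, 1-based).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop_domain("expected BED6 or BED12: ", path)
  out <- data.frame(name = as.character(df[[4]]),
                    chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    strand = as.character(df[[6]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 12L) {
    sizes <- sub(",$", "", as.character(df[[11]]))
    rel <- sub(",$", "", as.character(df[[12]]))
    out$block_sizes <- sizes
    out$block_starts <- mapply(function(r, s) {
      paste(as.integer(strsplit(r, ",")[[1]]) + s, collapse = ",")
    }, rel, out$start)
  } else {
    out$block_sizes <- as.character(out$end - out$start + 1L)
    out$block_starts <- as.character(out$start)
  }
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Write transcript sequences as FASTA
#' @param seqs A named `Biostrings::DNAStringSet` (or named character vector).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA file path.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a count matrix (counts TSV + sample table TSV)
#'
#' `counts.tsv` has a header row, first column `transcript_id`, one column
#' per sample. The companion sample table stores per-sample library sizes
#' (total mapped reads, the RPKM denominator N) and group labels.
#'
#' @param cm A [count_matrix()].
#' @param counts_path Path for the counts TSV.
#' @param samples_path Path for the sample table TSV.
#' @return `counts_path`, invisibly.
#' @export
write_counts_tsv <- function(cm, counts_path,
                             samples_path = sub("\\.tsv$", "_samples.tsv",
                                                counts_path)) {
  df <- data.frame(transcript_id = rownames(cm$counts),
                   cm$counts, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sdf <- data.frame(sample_id = colnames(cm$counts),
                    library_size = cm$library_sizes,
                    group = as.character(cm$group))
  write.table(sdf, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Read a count matrix written by [write_counts_tsv()]
#' @param counts_path Counts TSV path.
#' @param samples_path Sample table TSV path.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(counts_path,
                            samples_path = sub("\\.tsv$", "_samples.tsv",
                                               counts_path)) {
  df <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "transcript_id") {
    stop_domain("counts TSV must have first column transcript_id: ",
                counts_path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$transcript_id
  sdf <- read.delim(samples_path, stringsAsFactors = FALSE)
  sdf <- sdf[match(colnames(m), sdf$sample_id), ]
  count_matrix(m, library_sizes = setNames(sdf$library_size, sdf$sample_id),
               group = sdf$group)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (unique members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop_domain("GMT line with fewer than 3 fields in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, d, members) {
    paste(c(nm, d, members), collapse = "\t")
  }, names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}
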