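## Mapping-summary percentages, read-region classification and GC-content
## distribution: the QC stage of the pipeline.

#' Mapping summary container
#'
#' Per-sample alignment bookkeeping: effective (input) reads, total /
#' multiple / unique mapping, mate and strand breakdowns, proper pairs.
#' Enforces `total_mapped = multiple_mapped + uniquely_mapped` and that no
#' count exceeds `effective_reads`.
#'
#' @param effective_reads,total_mapped,multiple_mapped,uniquely_mapped
#'   Read counts.
#' @param read1_mapped,read2_mapped,plus_strand,minus_strand,proper_pairs
#'   Optional breakdown counts (default `NA`).
#' @return An object of class `mapping_summary` (named list).
#' @export
mapping_summary <- function(effective_reads, total_mapped, multiple_mapped,
                            uniquely_mapped, read1_mapped = NA,
                            read2_mapped = NA, plus_strand = NA,
                            minus_strand = NA, proper_pairs = NA) {
  s <- list(effective_reads = effective_reads, total_mapped = total_mapped,
            multiple_mapped = multiple_mapped,
            uniquely_mapped = uniquely_mapped, read1_mapped = read1_mapped,
            read2_mapped = read2_mapped, plus_strand = plus_strand,
            minus_strand = minus_strand, proper_pairs = proper_pairs)
  if (total_mapped != multiple_mapped + uniquely_mapped) {
    stop_domain("total_mapped must equal multiple_mapped + uniquely_mapped")
  }
  cnt <- unlist(s)
  if (any(cnt > effective_reads, na.rm = TRUE)) {
    stop_domain("no count may exceed effective_reads")
  }
  structure(s, class = "mapping_summary")
}

#' Mapping percentages relative to effective reads
#'
#' Each field is reported as `100 * count / effective_reads`, rounded
#' half-up to 2 decimals (`effective_reads` itself reports 100.00).
#'
#' @param summary A [mapping_summary()].
#' @return Named numeric vector of percentages.
#' @export
mapping_percentages <- function(summary) {
  stopifnot(inherits(summary, "mapping_summary"))
  if (summary$effective_reads <= 0) {
    stop_domain("effective_reads must be > 0")
  }
  cnt <- unlist(summary)
  round_half_up(100 * cnt / summary$effective_reads, 2)
}

#' Write mapping summaries as a table of counts and percentages
#'
#' One row per field, one `count(percent%)` column per sample, mirroring
#' the usual mapping-statistics table layout.
#'
#' @param summaries Named list of [mapping_summary()] objects (one per
#'   sample).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mapping_summary_tsv <- function(summaries, path) {
  fields <- c("effective_reads", "total_mapped", "multiple_mapped",
              "uniquely_mapped", "read1_mapped", "read2_mapped",
              "plus_strand", "minus_strand", "proper_pairs")
  cols <- lapply(summaries, function(s) {
    pct <- mapping_percentages(s)
    sprintf("%s(%.2f%%)", format(unlist(s)[fields], big.mark = ","),
            pct[fields])
  })
  df <- data.frame(field = fields, cols, check.names = FALSE)
  names(df) <- c("field", names(summaries))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify reads into genomic regions
#'
#' Each read receives exactly one label with precedence
#' splicing > exonic > intronic > intergenic:
#' * splicing: the read's aligned blocks hit two or more distinct exons of
#'   one transcript (an exon-exon junction read);
#' * exonic: at least half of the read's bases fall in annotated exons;
#' * intronic: overlaps a transcript but fails the exonic majority rule;
#' * intergenic: overlaps no transcript (reads on unknown chromosomes are
#'   counted intergenic with a warning).
#'
#' @param reads A `read_alignments` data.frame ([read_bed()] /
#'   [simulate_alignments()]).
#' @param annotation A [transcript_annotation()].
#' @return List with `fractions` (named: exonic, intronic, intergenic,
#'   splicing; sums to 1) and `labels` (per-read character vector).
#' @export
classify_read_regions <- function(reads, annotation) {
  n <- nrow(reads)
  if (n == 0L) {
    return(list(fractions = c(exonic = NaN, intronic = NaN,
                              intergenic = NaN, splicing = NaN),
                labels = character(0)))
  }
  known_chroms <- unique(annotation$transcripts$chrom)
  unknown <- !reads$chrom %in% known_chroms
  if (any(unknown)) {
    warning(sum(unknown), " read(s) on unknown chromosome counted intergenic",
            call. = FALSE)
  }
  labels <- rep("intergenic", n)

  rg <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start, reads$end))
  ex <- exon_granges(annotation)
  ex_red <- GenomicRanges::reduce(ex, ignore.strand = TRUE)
  tx <- tx_granges(annotation)

  ## transcript overlap (strand-blind: library prep here is unstranded)
  in_tx <- IRanges::overlapsAny(rg, tx, ignore.strand = TRUE)

  ## exonic base coverage per read
  hits <- GenomicRanges::findOverlaps(rg, ex_red, ignore.strand = TRUE)
  exonic_bp <- rep(0L, n)
  if (length(hits)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      rg[S4Vectors::queryHits(hits)], ex_red[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    exonic_bp[as.integer(names(agg))] <- as.integer(agg)
  }
  read_len <- reads$end - reads$start + 1L
  labels[in_tx] <- ifelse(exonic_bp[in_tx] * 2L >= read_len[in_tx],
                          "exonic", "intronic")

  ## splicing: multi-block reads whose blocks hit >= 2 exons of a transcript
  nb <- vapply(strsplit(reads$block_sizes, ","), length, integer(1))
  multi <- which(nb > 1L)
  if (length(multi)) {
    bs <- strsplit(reads$block_starts[multi], ",")
    sz <- strsplit(reads$block_sizes[multi], ",")
    starts <- as.integer(unlist(bs))
    sizes <- as.integer(unlist(sz))
    ridx <- rep(multi, lengths(bs))
    bg <- GenomicRanges::GRanges(reads$chrom[ridx],
                                 IRanges::IRanges(starts,
                                                  starts + sizes - 1L))
    bh <- GenomicRanges::findOverlaps(bg, ex, ignore.strand = TRUE)
    if (length(bh)) {
      df <- unique(data.frame(
        read = ridx[S4Vectors::queryHits(bh)],
        tx = ex$transcript_id[S4Vectors::subjectHits(bh)],
        exon = S4Vectors::subjectHits(bh)))
      tab <- aggregate(exon ~ read + tx, df, function(e) length(unique(e)))
      spliced <- unique(tab$read[tab$exon >= 2L])
      labels[spliced] <- "splicing"
    }
  }
  labels[unknown] <- "intergenic"

  fr <- table(factor(labels, levels = c("exonic", "intronic",
                                        "intergenic", "splicing"))) / n
  list(fractions = setNames(as.numeric(fr), names(fr)), labels = labels)
}

#' GC-content distribution of sequence records
#'
#' Per-record GC fraction is `(G + C) / (A + C + G + T)`; ambiguous bases
#' are excluded from the denominator, and records with zero unambiguous
#' bases are skipped with a warning. Returns the empirical histogram and
#' the matched normal reference curve used to judge whether the GC profile
#' looks Gaussian.
#'
#' @param sequences Named `DNAStringSet` or character vector.
#' @param n_bins Number of histogram bins over \[0, 1\] (default 50).
#' @return List: `gc` (per-record fractions), `mean`, `sd`, `breaks`,
#'   `density` (empirical bin densities), `normal_density` (matched normal
#'   evaluated at bin midpoints).
#' @export
gc_distribution <- function(sequences, n_bins = 50) {
  if (length(sequences) == 0L) stop_domain("sequences must be non-empty")
  if (!methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
    names(sequences) <- nm
  }
  freq <- Biostrings::letterFrequency(sequences, c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  bad <- denom == 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with zero unambiguous bases skipped",
            call. = FALSE)
  }
  gc <- (freq[, "G"] + freq[, "C"])[!bad] / denom[!bad]
  names(gc) <- names(sequences)[!bad]
  mu <- mean(gc)
  s <- sd(gc)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  h <- graphics::hist(gc, breaks = breaks, plot = FALSE)
  mids <- h$mids
  list(gc = gc, mean = mu, sd = s, breaks = breaks,
       density = h$density,
       normal_density = if (is.na(s) || s == 0) rep(NA_real_, length(mids))
                        else stats::dnorm(mids, mu, s))
}
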