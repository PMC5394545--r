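#' Transcript annotation container
#'
#' Holds the genomic identity of a transcript catalogue: one row per
#' transcript (id, chromosome, 1-based fully-closed span, strand, exonic
#' length, biotype) plus a separate exon table. Coordinates are 1-based and
#' inclusive throughout, so a single-exon transcript satisfies
#' `length == end - start + 1`. `length` is the sum of exon widths (exonic
#' length), not the genomic span: multi-exon transcripts can span far more
#' than their length.
#'
#' @param transcripts data.frame with columns `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` (`"+"`/`"-"`), `biotype` (one of `"mRNA"`,
#'   `"known-lncRNA"`, `"novel-lncRNA"`, `"unclassified"`).
#' @param exons data.frame with columns `transcript_id`, `start`, `end`;
#'   exons of one transcript must be disjoint and sorted.
#' @return An object of class `transcript_annotation` with elements
#'   `transcripts` (with derived `length` and `n_exons` columns) and `exons`.
#' @export
transcript_annotation <- function(transcripts, exons) {
  req <- c("transcript_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(req %in% names(transcripts))) {
    stop_domain("transcripts must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(c("transcript_id", "start", "end") %in% names(exons))) {
    stop_domain("exons must have columns transcript_id, start, end")
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    stop_domain("duplicate transcript_id in annotation")
  }
  if (any(transcripts$end < transcripts$start)) {
    stop_domain("transcript end < start")
  }
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  sp <- split(exons, factor(exons$transcript_id,
                            levels = transcripts$transcript_id))
  widths <- vapply(sp, function(e) {
    if (nrow(e) == 0L) return(NA_real_)
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)])) {
      stop_domain("overlapping exons in transcript ", e$transcript_id[1])
    }
    sum(e$end - e$start + 1)
  }, numeric(1))
  if (anyNA(widths)) {
    stop_domain("transcript without exons: ",
                transcripts$transcript_id[which(is.na(widths))[1]])
  }
  # exons must lie within the transcript span
  first <- vapply(sp, function(e) min(e$start), numeric(1))
  last <- vapply(sp, function(e) max(e$end), numeric(1))
  if (any(first < transcripts$start | last > transcripts$end)) {
    stop_domain("exon outside transcript span")
  }
  transcripts$length <- as.integer(widths)
  transcripts$n_exons <- as.integer(vapply(sp, nrow, integer(1)))
  rownames(transcripts) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_annotation")
}

#' @export
print.transcript_annotation <- function(x, ...) {
  tab <- table(x$transcripts$biotype)
  cat("transcript_annotation:", nrow(x$transcripts), "transcripts on",
      length(unique(x$transcripts$chrom)), "chromosome(s)\n")
  cat(" ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

## GRanges of transcript spans, names = transcript_id.
tx_granges <- function(ann) {
  tx <- ann$transcripts
  GenomicRanges::GRanges(tx$chrom,
                         IRanges::IRanges(tx$start, tx$end),
                         strand = tx$strand,
                         transcript_id = tx$transcript_id)
}

## GRanges of exons with transcript_id metadata (strand from parent).
exon_granges <- function(ann) {
  ex <- ann$exons
  tx <- ann$transcripts
  str <- tx$strand[match(ex$transcript_id, tx$transcript_id)]
  chrom <- tx$chrom[match(ex$transcript_id, tx$transcript_id)]
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(ex$start, ex$end),
                         strand = str,
                         transcript_id = ex$transcript_id)
}

## Intron GRanges (gaps between consecutive exons within a transcript).
intron_granges <- function(ann) {
  sp <- split(ann$exons, ann$exons$transcript_id)
  rows <- lapply(sp, function(e) {
    if (nrow(e) < 2L) return(NULL)
    data.frame(transcript_id = e$transcript_id[1],
               start = e$end[-nrow(e)] + 1L,
               end = e$start[-1] - 1L)
  })
  intr <- do.call(rbind, rows)
  if (is.null(intr) || nrow(intr) == 0L) {
    return(GenomicRanges::GRanges())
  }
  tx <- ann$transcripts
  m <- match(intr$transcript_id, tx$transcript_id)
  GenomicRanges::GRanges(tx$chrom[m],
                         IRanges::IRanges(intr$start, intr$end),
                         strand = tx$strand[m],
                         transcript_id = intr$transcript_id)
}
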