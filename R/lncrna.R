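## Novel lncRNA identification: candidate transcripts that do not match any
## known mRNA or lncRNA are kept as novel lncRNAs when they are longer than
## 200 bp and lack coding potential, operationalized as longest open
## reading frame < 100 aa (configurable). Cis-proximal protein-coding
## neighbours are reported within a genomic window.

#' Match candidate transcripts against a reference annotation
#'
#' A candidate matches a reference transcript iff they are on the same
#' chromosome and strand and their exonic overlap covers at least
#' `min_overlap_fraction` of the shorter transcript's exonic length.
#'
#' @param candidates,reference [transcript_annotation()] objects on the
#'   same genome naming.
#' @param min_overlap_fraction Overlap threshold in (0, 1\] (default 0.5).
#' @return data.frame: `transcript_id`, `matched` (logical), `best_match`
#'   (reference id or `NA`), `overlap_fraction` (best fraction, 0 if none).
#' @export
match_known <- function(candidates, reference, min_overlap_fraction = 0.5) {
  ce <- exon_granges(candidates)
  re <- exon_granges(reference)
  hits <- GenomicRanges::findOverlaps(ce, re, ignore.strand = FALSE)
  out <- data.frame(transcript_id = candidates$transcripts$transcript_id,
                    matched = FALSE, best_match = NA_character_,
                    overlap_fraction = 0)
  if (length(hits) > 0) {
    ov <- IRanges::pintersect(ce[S4Vectors::queryHits(hits)],
                              re[S4Vectors::subjectHits(hits)])
    df <- data.frame(
      cand = ce$transcript_id[S4Vectors::queryHits(hits)],
      ref = re$transcript_id[S4Vectors::subjectHits(hits)],
      w = GenomicRanges::width(ov))
    agg <- aggregate(w ~ cand + ref, df, sum)
    clen <- setNames(candidates$transcripts$length,
                     candidates$transcripts$transcript_id)
    rlen <- setNames(reference$transcripts$length,
                     reference$transcripts$transcript_id)
    agg$frac <- agg$w / pmin(clen[agg$cand], rlen[agg$ref])
    agg <- agg[order(-agg$frac, agg$ref), ]
    best <- agg[!duplicated(agg$cand), ]
    m <- match(out$transcript_id, best$cand)
    found <- !is.na(m)
    out$overlap_fraction[found] <- best$frac[m[found]]
    out$best_match[found] <- best$ref[m[found]]
    out$matched <- out$overlap_fraction >= min_overlap_fraction
    out$best_match[!out$matched] <- NA_character_
  }
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame
#'
#' Scans the three forward reading frames (and, optionally, the reverse
#' complement) for the longest ATG-initiated, stop-terminated open reading
#' frame. The returned nucleotide length includes the stop codon; the amino
#' acid count excludes it (`aa = nt/3 - 1`). ORFs lacking an in-frame stop
#' are not counted.
#'
#' @param sequence Nucleotide string over A/C/G/T/N (case-insensitive).
#' @param both_strands Also scan the reverse complement (default `FALSE`).
#' @return List with `nt` and `aa` (both 0 when no ORF exists).
#' @export
longest_orf <- function(sequence, both_strands = FALSE) {
  seq <- toupper(as.character(sequence))
  if (!grepl("^[ACGTN]*$", seq)) {
    stop_domain("sequence must be over A/C/G/T/N")
  }
  scan1 <- function(s) {
    n <- nchar(s)
    best <- 0L
    for (off in 0:2) {
      len <- (n - off) %/% 3
      if (len < 2L) next
      codons <- substring(s, off + seq(1, by = 3, length.out = len),
                          off + seq(3, by = 3, length.out = len))
      starts <- which(codons == "ATG")
      stops <- which(codons %in% STOP_CODONS)
      if (!length(starts) || !length(stops)) next
      for (st in starts) {
        nx <- stops[stops > st]
        if (!length(nx)) next
        best <- max(best, (nx[1] - st + 1L) * 3L)
      }
    }
    best
  }
  nt <- scan1(seq)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    nt <- max(nt, scan1(rc))
  }
  list(nt = as.integer(nt), aa = as.integer(if (nt > 0) nt / 3 - 1 else 0))
}

#' Classify novel lncRNAs
#'
#' A candidate is a novel lncRNA iff it is unmatched against the known
#' reference, its exonic length is strictly greater than `min_length` bp,
#' and its longest ORF is shorter than `max_orf_aa` amino acids (the
#' coding-potential proxy). All other candidates are left unclassified;
#' unmatched candidates without a sequence are reported unclassifiable
#' with a warning.
#'
#' @param candidates A [transcript_annotation()].
#' @param sequences Named `DNAStringSet` (or character vector) of candidate
#'   transcript sequences.
#' @param match_status Result of [match_known()] for `candidates`.
#' @param min_length Minimum exonic length, exclusive (default 200 bp).
#' @param max_orf_aa ORF-length ceiling in aa, exclusive (default 100).
#' @return data.frame: `transcript_id`, `length`, `matched`, `orf_aa`,
#'   `class` (`"novel-lncRNA"`, `"unclassified"`, `"unclassifiable"`).
#' @export
classify_novel_lncrna <- function(candidates, sequences, match_status,
                                  min_length = 200, max_orf_aa = 100) {
  tx <- candidates$transcripts
  m <- match(tx$transcript_id, match_status$transcript_id)
  if (anyNA(m)) stop_domain("match_status does not cover all candidates")
  matched <- match_status$matched[m]
  seqs <- setNames(as.character(sequences), names(sequences))
  out <- data.frame(transcript_id = tx$transcript_id,
                    length = tx$length,
                    matched = matched,
                    orf_aa = NA_integer_,
                    class = "unclassified")
  for (i in which(!matched)) {
    id <- tx$transcript_id[i]
    if (!id %in% names(seqs)) {
      warning("no sequence for unmatched candidate ", id,
              ": unclassifiable", call. = FALSE)
      out$class[i] <- "unclassifiable"
      next
    }
    orf <- longest_orf(seqs[[id]])
    out$orf_aa[i] <- orf$aa
    if (tx$length[i] > min_length && orf$aa < max_orf_aa) {
      out$class[i] <- "novel-lncRNA"
    }
  }
  out
}

#' Cis-proximal genes of a lncRNA
#'
#' Returns genes whose genomic span lies within `window_bp` of the lncRNA
#' span (closed window: a gene exactly `window_bp` away is included;
#' overlapping or adjacent genes have distance 0), sorted by distance then
#' id. Strand is ignored (cis-regulation acts on neighbourhood, not
#' orientation).
#'
#' @param lncrna A single-row subset of a [transcript_annotation()]
#'   `transcripts` data.frame, or a transcript id present in `genes`.
#' @param genes A [transcript_annotation()] of candidate target genes.
#' @param window_bp Window size in bp (default 100000).
#' @return data.frame: `transcript_id`, `distance_bp`, ordered.
#' @export
cis_targets <- function(lncrna, genes, window_bp = 100000) {
  if (is.character(lncrna) && length(lncrna) == 1L) {
    stop_domain("pass the lncRNA as a one-row annotation data.frame")
  }
  if (is.data.frame(lncrna)) {
    stopifnot(nrow(lncrna) == 1L)
    q <- GenomicRanges::GRanges(lncrna$chrom,
                                IRanges::IRanges(lncrna$start, lncrna$end))
  } else stop_domain("unsupported lncrna argument")
  g <- tx_granges(genes)
  d <- suppressWarnings(GenomicRanges::distance(q, g, ignore.strand = TRUE))
  keep <- !is.na(d) & d <= window_bp
  out <- data.frame(transcript_id = g$transcript_id[keep],
                    distance_bp = d[keep])
  out <- out[order(out$distance_bp, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
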