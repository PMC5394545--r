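# Shared in-code fixtures.

# A small fixed annotation: two transcripts on chr1 (one spliced), one on
# chr2, known biotypes.
toy_annotation <- function() {
  transcript_annotation(
    transcripts = data.frame(
      transcript_id = c("txA", "txB", "txC"),
      chrom = c("chr1", "chr1", "chr2"),
      start = c(101L, 2001L, 501L),
      end = c(700L, 2400L, 900L),
      strand = c("+", "-", "+"),
      biotype = c("mRNA", "known-lncRNA", "mRNA")),
    exons = data.frame(
      transcript_id = c("txA", "txA", "txB", "txC"),
      start = c(101L, 501L, 2001L, 501L),
      end = c(300L, 700L, 2400L, 900L)))
}

# Small, fast simulation config for tests.
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_mrna = 60L, n_lncrna_known = 30L,
             n_lncrna_novel = 10L, ...)
}

# Deterministic count_matrix from explicit numbers.
toy_counts <- function(counts, lib = NULL,
                       group = rep(c("control", "SAH"),
                                   each = ncol(counts) / 2)) {
  if (is.null(lib)) lib <- rep(1e6, ncol(counts))
  count_matrix(counts, library_sizes = lib, group = group)
}
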