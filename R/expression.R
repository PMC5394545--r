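#' Count matrix container
#'
#' Raw read counts per transcript and sample, with per-sample library sizes
#' (total mapped reads, the `N` of the RPKM formula) and group labels.
#' Library sizes may exceed the column sums: `N` is total mapped reads, not
#' reads assigned to the catalogue.
#'
#' @param counts Numeric matrix, transcripts x samples, non-negative;
#'   rownames = transcript ids, colnames = sample ids.
#' @param library_sizes Named numeric vector of per-sample totals (> 0).
#' @param group Per-sample group labels (e.g. `"control"` / `"SAH"`).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, library_sizes, group) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_domain("counts must have row and column names")
  }
  if (any(counts < 0)) stop_domain("negative counts")
  if (length(library_sizes) != ncol(counts)) {
    stop_domain("library_sizes length must match sample count")
  }
  if (!is.null(names(library_sizes))) {
    library_sizes <- library_sizes[colnames(counts)]
  } else {
    names(library_sizes) <- colnames(counts)
  }
  if (length(group) != ncol(counts)) {
    stop_domain("group length must match sample count")
  }
  structure(list(counts = counts,
                 library_sizes = library_sizes,
                 group = factor(group)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x", ncol(x$counts),
      "samples; groups:",
      paste(levels(x$group), table(x$group), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Expression matrix container
#'
#' Same axes as the count matrix; `transform` records whether values are raw
#' RPKM or log10(RPKM + 1), so the log transform cannot be applied twice
#' silently.
#'
#' @param values Numeric matrix of expression values (>= 0).
#' @param transform `"rpkm"` or `"log10p1"`.
#' @param group Optional per-sample group labels.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, transform = c("rpkm", "log10p1"),
                              group = NULL) {
  transform <- match.arg(transform)
  structure(list(values = values, transform = transform,
                 group = if (is.null(group)) NULL else factor(group)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (", x$transform, "): ", nrow(x$values),
      " transcripts x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' RPKM quantification
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM = C * 1e9 / (N * L)` where `C` is the read count of a transcript in
#' a sample, `N` the sample's total mapped reads (library size) and `L` the
#' transcript's exonic length in bp.
#'
#' @param cm A [count_matrix()].
#' @param lengths Named numeric vector of transcript lengths in bp (> 0),
#'   covering all transcripts of `cm`.
#' @return An [expression_matrix()] with `transform = "rpkm"`.
#' @export
rpkm <- function(cm, lengths) {
  stopifnot(inherits(cm, "count_matrix"))
  ids <- rownames(cm$counts)
  if (!all(ids %in% names(lengths))) {
    stop_domain("missing length for transcript(s): ",
                paste(head(setdiff(ids, names(lengths))), collapse = ", "))
  }
  L <- lengths[ids]
  if (any(L <= 0)) {
    stop_domain("non-positive length for transcript ", ids[which(L <= 0)[1]])
  }
  N <- cm$library_sizes
  if (any(N <= 0)) {
    stop_domain("non-positive library size for sample ",
                names(N)[which(N <= 0)[1]])
  }
  vals <- sweep(cm$counts * 1e9, 2, N, "/") / L
  expression_matrix(vals, "rpkm", group = cm$group)
}

#' log10(RPKM + 1) transformation
#'
#' @param expr An [expression_matrix()] in raw-RPKM state.
#' @return An [expression_matrix()] with `transform = "log10p1"`.
#' @export
log_transform <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$transform != "rpkm") {
    stop_domain("log_transform requires raw-RPKM input; got state '",
                expr$transform, "' (double application?)")
  }
  expression_matrix(log10(expr$values + 1), "log10p1", group = expr$group)
}

#' GC-stratified count normalization
#'
#' A documented, simplified stand-in for within-lane GC-content
#' normalization: within each sample, transcripts are stratified into GC
#' quantile bins and each bin's counts are rescaled so the bin median
#' matches the median of bin medians, then the sample is rescaled to
#' preserve its total count. Values are integerized with largest-remainder
#' rounding per bin, so each sample total is preserved within +/- `n_bins`.
#'
#' @param cm A [count_matrix()].
#' @param gc Named numeric vector in \[0, 1\], per-transcript GC fraction.
#' @param n_bins Number of GC quantile bins (>= 2); bins with fewer than 2
#'   transcripts are merged into their neighbour with a warning.
#' @return A [count_matrix()] with normalized counts.
#' @export
gc_normalize <- function(cm, gc, n_bins = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  if (n_bins < 2) stop_domain("n_bins must be >= 2")
  ids <- rownames(cm$counts)
  if (!all(ids %in% names(gc))) stop_domain("missing GC for some transcripts")
  gc <- gc[ids]
  if (any(gc < 0 | gc > 1)) stop_domain("GC fractions must be in [0, 1]")

  br <- unique(quantile(gc, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3L) {
    ## effectively a single stratum (e.g. all-identical GC): no-op
    return(cm)
  }
  bin <- cut(gc, breaks = br, include.lowest = TRUE, labels = FALSE)
  ## merge undersized bins into the left neighbour
  n_merged <- 0L
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < 2L]
    if (length(small) == 0L || length(tab) <= 1L) break
    n_merged <- n_merged + 1L
    b <- as.integer(small[1])
    lev <- sort(unique(bin))
    tgt <- if (b == min(lev)) lev[lev > b][1] else max(lev[lev < b])
    bin[bin == b] <- tgt
  }
  if (n_merged > 0L) {
    warning("merging ", n_merged, " GC bin(s) with <2 transcripts",
            call. = FALSE)
  }

  out <- cm$counts
  for (s in seq_len(ncol(out))) {
    x <- cm$counts[, s]
    med <- tapply(x, bin, median)
    target <- median(med)
    fac <- ifelse(med > 0, target / med, 1)
    scaled <- x * fac[as.character(bin)]
    tot <- sum(x)
    if (sum(scaled) > 0) scaled <- scaled * tot / sum(scaled)
    ## integerize per bin, preserving each bin's (rounded) mass
    for (b in unique(bin)) {
      idx <- bin == b
      scaled[idx] <- round_preserve_sum(scaled[idx])
    }
    out[, s] <- scaled
  }
  count_matrix(out, cm$library_sizes, cm$group)
}
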