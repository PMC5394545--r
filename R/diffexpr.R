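#' Conditional binomial (random-sampling) differential expression test
#'
#' Two-group test on pooled counts. Under the null hypothesis of equal
#' relative expression, the count in group A conditional on the pooled total
#' is binomial: `k1 | (k1 + k2) ~ Binomial(k1 + k2, N1 / (N1 + N2))`. The
#' two-sided p-value sums the probabilities of all outcomes no more likely
#' than the observed one. Exact enumeration is used for pooled totals up to
#' `exact_max`; above that a normal approximation with continuity
#' correction is applied.
#'
#' @param k1,k2 Pooled counts in group A and group B (vectors allowed).
#' @param n1,n2 Library sizes (total mapped reads) for the two groups.
#' @param exact_max Largest `k1 + k2` for exact enumeration (default 1e4).
#' @return Numeric vector of p-values; `NA` (with a warning) where
#'   `k1 + k2 == 0` (untestable).
#' @export
de_test <- function(k1, k2, n1, n2, exact_max = 1e4) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop_domain("library sizes must be > 0")
  ln <- max(length(k1), length(k2))
  k1 <- rep_len(k1, ln); k2 <- rep_len(k2, ln)
  n1 <- rep_len(n1, ln); n2 <- rep_len(n2, ln)
  pi0 <- n1 / (n1 + n2)
  n <- k1 + k2
  p <- rep(NA_real_, ln)
  zero <- n == 0
  if (any(zero)) warning(sum(zero), " record(s) with zero pooled count are untestable",
                         call. = FALSE)
  exact <- !zero & n <= exact_max
  for (i in which(exact)) {
    d <- dbinom(0:n[i], n[i], pi0[i])
    p[i] <- min(1, sum(d[d <= d[k1[i] + 1] * (1 + 1e-7)]))
  }
  approx <- !zero & n > exact_max
  if (any(approx)) {
    mu <- n[approx] * pi0[approx]
    sig <- sqrt(n[approx] * pi0[approx] * (1 - pi0[approx]))
    z <- (abs(k1[approx] - mu) - 0.5) / sig
    p[approx] <- pmin(1, 2 * pnorm(-pmax(z, 0)))
  }
  p
}

#' Fold change and log2 fold change
#'
#' `FC = (mean_b + pseudocount) / (mean_a + pseudocount)`; the pseudocount
#' guards against zero group means (default 0.5 on the normalized-count
#' scale).
#'
#' @param mean_a,mean_b Group mean normalized expression (>= 0); group B is
#'   the condition of interest (SAH), group A the control.
#' @param pseudocount Non-negative stabilizer added to both means.
#' @return data.frame with columns `fold_change` and `log2fc`.
#' @export
fold_change <- function(mean_a, mean_b, pseudocount = 0.5) {
  if (any(mean_a < 0) || any(mean_b < 0)) stop_domain("means must be >= 0")
  if (pseudocount < 0) stop_domain("pseudocount must be >= 0")
  if (any(mean_a + pseudocount == 0 & mean_b + pseudocount == 0)) {
    stop_domain("fold change undefined: both means and pseudocount are zero")
  }
  fc <- (mean_b + pseudocount) / (mean_a + pseudocount)
  data.frame(fold_change = fc, log2fc = log2(fc))
}

#' Multiple-testing adjustment (q-values)
#'
#' Benjamini-Hochberg step-up by default, implemented directly: with sorted
#' p-values `p_(i)`, `q_(i) = min_{j >= i} ( m * p_(j) / j )`. The optional
#' Storey variant multiplies BH q-values by an estimate of the null
#' proportion `pi0 = min(1, 2 * mean(p > 0.5))`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @param method `"BH"` (default) or `"storey"`.
#' @return q-values in the input order.
#' @export
adjust_q <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_domain("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv)
    qs <- rev(cummin(rev(m * pv[o] / seq_len(m))))
    qs <- pmin(qs, 1)
    qv <- numeric(m)
    qv[o] <- qs
    if (method == "storey") {
      pi0 <- min(1, 2 * mean(pv > 0.5))
      qv <- pmin(qv * pi0, 1)
    }
    q[ok] <- qv
  }
  q
}

#' Two-group differential expression on a count matrix
#'
#' Pools counts across the samples of each group (sums), applies the
#' conditional binomial test per transcript, computes fold changes on group
#' mean CPM (counts per million mapped reads), and adjusts p-values.
#'
#' @param cm A [count_matrix()] whose `group` has exactly two levels;
#'   the first level is treated as control (group A).
#' @param biotypes Optional named character vector of per-transcript
#'   biotypes carried into the result.
#' @param pseudocount Passed to [fold_change()].
#' @param q_method Passed to [adjust_q()].
#' @return data.frame of class `de_table`: `transcript_id`, `biotype`,
#'   `mean_a`, `mean_b`, `fold_change`, `log2fc`, `p_value`, `q_value`.
#' @export
run_de <- function(cm, biotypes = NULL, pseudocount = 0.5,
                   q_method = "BH") {
  stopifnot(inherits(cm, "count_matrix"))
  if (nlevels(cm$group) != 2L) stop_domain("run_de needs exactly two groups")
  ga <- cm$group == levels(cm$group)[1]
  k1 <- rowSums(cm$counts[, ga, drop = FALSE])
  k2 <- rowSums(cm$counts[, !ga, drop = FALSE])
  n1 <- sum(cm$library_sizes[ga])
  n2 <- sum(cm$library_sizes[!ga])
  cpm <- sweep(cm$counts * 1e6, 2, cm$library_sizes, "/")
  mean_a <- rowMeans(cpm[, ga, drop = FALSE])
  mean_b <- rowMeans(cpm[, !ga, drop = FALSE])
  fc <- fold_change(mean_a, mean_b, pseudocount)
  p <- suppressWarnings(de_test(k1, k2, n1, n2))
  ids <- rownames(cm$counts)
  res <- data.frame(transcript_id = ids,
                    biotype = if (is.null(biotypes)) NA_character_
                              else unname(biotypes[ids]),
                    mean_a = mean_a, mean_b = mean_b,
                    fold_change = fc$fold_change, log2fc = fc$log2fc,
                    p_value = p,
                    q_value = adjust_q(p, q_method),
                    row.names = NULL)
  class(res) <- c("de_table", "data.frame")
  res
}

#' Significance filtering at fold-change and q-value thresholds
#'
#' A transcript is called up-regulated iff `log2fc > log2fc_threshold` and
#' `q < alpha`; down-regulated iff `log2fc < -log2fc_threshold` and
#' `q < alpha`; all others are non-significant.
#'
#' @param records A `de_table` from [run_de()] (or compatible data.frame
#'   with `log2fc` and `q_value`).
#' @param log2fc_threshold Absolute log2 fold-change threshold (default 1).
#' @param alpha q-value threshold (default 0.05).
#' @return List with `records` (input plus `direction` and `significant`
#'   columns), `up`, `down`, `nonsignificant` (partitions) and `summary`
#'   (counts per class and biotype).
#' @export
significance_filter <- function(records, log2fc_threshold = 1, alpha = 0.05) {
  stopifnot(all(c("log2fc", "q_value") %in% names(records)))
  up <- !is.na(records$q_value) & records$log2fc > log2fc_threshold &
    records$q_value < alpha
  down <- !is.na(records$q_value) & records$log2fc < -log2fc_threshold &
    records$q_value < alpha
  records$direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  records$significant <- up | down
  bt <- if ("biotype" %in% names(records)) records$biotype else
    rep(NA_character_, nrow(records))
  summary <- as.data.frame(table(direction = records$direction,
                                 biotype = factor(bt)),
                           stringsAsFactors = FALSE)
  list(records = records,
       up = records[up, , drop = FALSE],
       down = records[down, , drop = FALSE],
       nonsignificant = records[!up & !down, , drop = FALSE],
       summary = summary)
}

#' Volcano and heat-map table construction
#'
#' The volcano table carries `(log2fc, -log10 q, class)` for every record.
#' The heat-map table selects, per biotype, up to `top_n` transcripts with
#' `|log2fc| > log2fc_threshold` and `q < alpha`, ranked by q ascending then
#' `|log2fc|` descending then id; their log10(RPKM+1) values are
#' standardized per row (constant rows flagged and emitted as zeros) and
#' row-ordered by average-linkage hierarchical clustering on Euclidean
#' distance (rows pre-sorted by id for a deterministic tie-break).
#'
#' @param records A `de_table` (with `q_value`, `log2fc`, optionally
#'   `biotype`).
#' @param expr An [expression_matrix()] in `log10p1` state covering the
#'   records' transcripts.
#' @param log2fc_threshold,alpha Heat-map selection thresholds (defaults
#'   1.5 and 0.05).
#' @param top_n Per-biotype cap (default 100).
#' @return List with `volcano` (data.frame) and `heatmap` (named list per
#'   biotype of standardized matrices in clustered row order, or `NULL`
#'   with a notice when fewer than 2 transcripts pass).
#' @export
plot_selections <- function(records, expr, log2fc_threshold = 1.5,
                            alpha = 0.05, top_n = 100) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$transform != "log10p1") {
    stop_domain("plot_selections expects log10(RPKM+1) expression")
  }
  volcano <- data.frame(
    transcript_id = records$transcript_id,
    log2fc = records$log2fc,
    neg_log10_q = -log10(records$q_value),
    class = ifelse(!is.na(records$q_value) & records$q_value < alpha &
                     abs(records$log2fc) > log2fc_threshold,
                   ifelse(records$log2fc > 0, "up", "down"), "ns"))
  bt <- if ("biotype" %in% names(records) && !all(is.na(records$biotype))) {
    records$biotype
  } else rep("all", nrow(records))
  heat <- list()
  for (b in sort(unique(bt))) {
    sub <- records[bt == b & !is.na(records$q_value) &
                     records$q_value < alpha &
                     abs(records$log2fc) > log2fc_threshold, , drop = FALSE]
    if (nrow(sub) < 2L) {
      message("heatmap skipped for biotype '", b,
              "': fewer than 2 significant transcripts")
      next
    }
    sub <- sub[order(sub$q_value, -abs(sub$log2fc), sub$transcript_id), ]
    sub <- head(sub, top_n)
    m <- expr$values[sub$transcript_id, , drop = FALSE]
    m <- m[order(rownames(m)), , drop = FALSE]  # deterministic tie-break
    sds <- apply(m, 1, sd)
    const <- sds == 0
    if (any(const)) {
      warning(sum(const), " constant row(s) emitted as zeros", call. = FALSE)
    }
    z <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
    z[const, ] <- 0
    hc <- hclust(dist(z, method = "euclidean"), method = "average")
    heat[[b]] <- z[hc$order, , drop = FALSE]
  }
  list(volcano = volcano, heatmap = if (length(heat)) heat else NULL)
}
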