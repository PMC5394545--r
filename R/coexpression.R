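## Bipartite lncRNA x mRNA co-expression with a permutation null.
##
## The COR value is the raw Pearson r between the expression vectors of a
## lncRNA and an mRNA across all samples of both groups jointly (default
## scale: log10(RPKM+1)). Because sample sizes are small (n < 8), the
## p-value comes from a permutation test: the null distribution of r under
## relabelings of one vector's sample order. The Z score standardizes the
## observed r against that null (mean/sd); the operative p-value is the
## permutation p, with a normal-tail p from Z available for comparison.
## Edges require both |COR| > cor_threshold and p < alpha.

#' Pearson correlation of two expression vectors
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Pearson product-moment r; `NA` with a warning if either vector
#'   has zero variance.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  if (length(x) < 3L) stop_domain("need at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)
}

## All permutations of 1..n as an (n! x n) integer matrix, in a stable
## insertion order. Guarded at n <= 9 (9! = 362,880 <= 1e6).
all_permutations <- function(n) {
  if (n > 9L) stop_domain("exhaustive permutations limited to n <= 9; ",
                          "use monte_carlo mode")
  P <- matrix(1L, 1L, 1L)
  for (k in 2L:max(2L, n)) {
    if (n == 1L) break
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    r <- 0L
    for (pos in seq_len(k)) {
      blk <- matrix(0L, m, k)
      if (pos > 1L) blk[, seq_len(pos - 1L)] <- P[, seq_len(pos - 1L), drop = FALSE]
      blk[, pos] <- k
      if (pos < k) blk[, (pos + 1L):k] <- P[, pos:(k - 1L), drop = FALSE]
      out[r + seq_len(m), ] <- blk
      r <- r + m
    }
    P <- out
  }
  if (n == 1L) matrix(1L, 1L, 1L) else P
}

#' Permutation test for a Pearson correlation
#'
#' Builds the null distribution of r by permuting the sample order of `y`.
#' In exhaustive mode all `n!` permutations (identity included) are
#' enumerated; in Monte-Carlo mode `n_perm` seeded random permutations are
#' drawn and the add-one correction `p = (1 + hits) / (n_perm + 1)` is
#' applied. The two-sided p-value counts permutations with
#' `|r_perm| >= |r_obs|`; `z = (r_obs - null_mean) / null_sd`.
#'
#' @param x,y Numeric vectors, equal length >= 3.
#' @param mode `"auto"` (exhaustive for n <= 9, else Monte-Carlo),
#'   `"exhaustive"` or `"monte_carlo"`.
#' @param n_perm Number of Monte-Carlo permutations (default 10000).
#' @param seed Seed for Monte-Carlo sampling (local RNG scope).
#' @return List: `r` (observed), `p_value`, `z`, `null_mean`, `null_sd`,
#'   `n_perm`, `mode`. `z` is `NA` when the null sd is zero (p still
#'   reported).
#' @export
permutation_test <- function(x, y, mode = c("auto", "exhaustive",
                                            "monte_carlo"),
                             n_perm = 10000, seed = NULL) {
  mode <- match.arg(mode)
  n <- length(x)
  if (length(y) != n) stop_domain("x and y must have equal length")
  if (n < 3L) stop_domain("need at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_domain("zero variance: correlation undefined")
  }
  if (mode == "auto") mode <- if (n <= 9L) "exhaustive" else "monte_carlo"
  xs <- (x - mean(x)) / sd(x)
  ys <- (y - mean(y)) / sd(y)
  r_obs <- sum(xs * ys) / (n - 1)
  if (mode == "exhaustive") {
    P <- all_permutations(n)
    M <- matrix(ys[t(P)], nrow(P), n, byrow = TRUE)
    r_null <- as.vector(M %*% xs) / (n - 1)
    p <- mean(abs(r_null) >= abs(r_obs) - 1e-12)
    used <- nrow(P)
  } else {
    r_null <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) sum(xs * ys[sample.int(n)]) / (n - 1),
             numeric(1))
    })
    p <- (1 + sum(abs(r_null) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
    used <- n_perm
  }
  mu <- mean(r_null)
  s <- sd(r_null)
  z <- if (s == 0) NA_real_ else (r_obs - mu) / s
  list(r = r_obs,
       p_value = p,
       z = z,
       ## normal-tail alternative to the permutation p, for comparison
       ## only; the permutation p is the operative value
       p_normal = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
       null_mean = mu, null_sd = s,
       n_perm = used, mode = mode)
}

## Vectorized exhaustive permutation p-values/z for all pairs of rows of
## two standardized matrices Xl (L x n) and Xm (M x n). Returns list of
## L x M matrices r, p, z.
perm_null_bipartite <- function(Xl, Xm, mode = "exhaustive",
                                n_perm = 10000, seed = NULL) {
  n <- ncol(Xl)
  r_obs <- Xl %*% t(Xm) / (n - 1)
  if (mode == "exhaustive") {
    P <- all_permutations(n)
    m <- nrow(P)
    cnt <- matrix(0, nrow(Xl), nrow(Xm))
    s1 <- cnt; s2 <- cnt
    for (i in seq_len(m)) {
      rp <- Xl %*% t(Xm[, P[i, ], drop = FALSE]) / (n - 1)
      cnt <- cnt + (abs(rp) >= abs(r_obs) - 1e-12)
      s1 <- s1 + rp
      s2 <- s2 + rp^2
    }
    p <- cnt / m
    mu <- s1 / m
    sdv <- sqrt(pmax(0, (s2 - m * mu^2) / (m - 1)))
  } else {
    res <- with_seed(seed, {
      cnt <- matrix(0, nrow(Xl), nrow(Xm))
      s1 <- cnt; s2 <- cnt
      for (i in seq_len(n_perm)) {
        rp <- Xl %*% t(Xm[, sample.int(n), drop = FALSE]) / (n - 1)
        cnt <- cnt + (abs(rp) >= abs(r_obs) - 1e-12)
        s1 <- s1 + rp
        s2 <- s2 + rp^2
      }
      list(cnt = cnt, s1 = s1, s2 = s2)
    })
    p <- (1 + res$cnt) / (n_perm + 1)
    mu <- res$s1 / n_perm
    sdv <- sqrt(pmax(0, (res$s2 - n_perm * mu^2) / (n_perm - 1)))
  }
  z <- (r_obs - mu) / sdv
  z[sdv == 0] <- NA_real_
  list(r = r_obs, p = p, z = z)
}

#' Build the bipartite lncRNA x mRNA co-expression network
#'
#' Evaluates every lncRNA x mRNA pair (never lncRNA-lncRNA or mRNA-mRNA)
#' on expression across all samples of both groups jointly, and retains
#' edges with `|COR| > cor_threshold` and permutation `p < alpha`. Rows
#' with zero variance are excluded with a reason. When `de_records` is
#' supplied the inputs are first restricted to significant transcripts (the
#' study computes the network on differentially expressed transcripts) and
#' node regulation attributes are taken from its `direction` column.
#'
#' @param lnc_expr,mrna_expr Numeric matrices (transcripts x samples, same
#'   sample columns), typically log10(RPKM+1) slices of an
#'   [expression_matrix()].
#' @param cor_threshold Absolute Pearson-r threshold (default 0.95).
#' @param alpha Permutation p-value threshold (default 0.05).
#' @param de_records Optional `de_table` with `significant`/`direction`
#'   columns (from [significance_filter()]).
#' @param mode,n_perm,seed Permutation settings as in [permutation_test()].
#' @return An object of class `coexpression_network`: list with `nodes`
#'   (id, kind, regulation), `edges` (lncrna_id, mrna_id, cor, z, p_value,
#'   sign), `excluded` (zero-variance transcripts), `params`.
#' @export
build_network <- function(lnc_expr, mrna_expr, cor_threshold = 0.95,
                          alpha = 0.05, de_records = NULL,
                          mode = c("auto", "exhaustive", "monte_carlo"),
                          n_perm = 10000, seed = NULL) {
  mode <- match.arg(mode)
  n <- ncol(lnc_expr)
  stopifnot(ncol(mrna_expr) == n, n >= 3L)
  if (mode == "auto") mode <- if (n <= 9L) "exhaustive" else "monte_carlo"

  direction <- NULL
  if (!is.null(de_records)) {
    if (!"significant" %in% names(de_records)) {
      stop_domain("de_records must carry a 'significant' column ",
                  "(apply significance_filter first)")
    }
    sig <- de_records$transcript_id[de_records$significant]
    lnc_expr <- lnc_expr[rownames(lnc_expr) %in% sig, , drop = FALSE]
    mrna_expr <- mrna_expr[rownames(mrna_expr) %in% sig, , drop = FALSE]
    direction <- setNames(de_records$direction, de_records$transcript_id)
  }

  excl <- character(0)
  keep_l <- apply(lnc_expr, 1, sd) > 0
  keep_m <- apply(mrna_expr, 1, sd) > 0
  excl <- c(rownames(lnc_expr)[!keep_l], rownames(mrna_expr)[!keep_m])
  if (length(excl)) {
    warning(length(excl), " zero-variance transcript(s) excluded",
            call. = FALSE)
  }
  lnc_expr <- lnc_expr[keep_l, , drop = FALSE]
  mrna_expr <- mrna_expr[keep_m, , drop = FALSE]

  empty_net <- function() {
    structure(list(nodes = data.frame(id = character(0), kind = character(0),
                                      regulation = character(0)),
                   edges = data.frame(lncrna_id = character(0),
                                      mrna_id = character(0), cor = numeric(0),
                                      z = numeric(0), p_value = numeric(0),
                                      sign = character(0)),
                   excluded = excl,
                   params = list(cor_threshold = cor_threshold, alpha = alpha,
                                 mode = mode, n_samples = n)),
              class = "coexpression_network")
  }
  if (nrow(lnc_expr) == 0L || nrow(mrna_expr) == 0L) {
    message("empty co-expression network: no eligible transcripts")
    return(empty_net())
  }

  std <- function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    (m - mu) / s
  }
  Xl <- std(lnc_expr)
  Xm <- std(mrna_expr)
  nul <- perm_null_bipartite(Xl, Xm, mode = mode, n_perm = n_perm,
                             seed = seed)
  pass <- abs(nul$r) > cor_threshold & nul$p < alpha
  idx <- which(pass, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    message("empty co-expression network: no pair passes |COR| > ",
            cor_threshold, " and p < ", alpha)
    return(empty_net())
  }
  edges <- data.frame(
    lncrna_id = rownames(lnc_expr)[idx[, 1]],
    mrna_id = rownames(mrna_expr)[idx[, 2]],
    cor = nul$r[idx],
    z = nul$z[idx],
    p_value = nul$p[idx])
  edges$sign <- ifelse(edges$cor > 0, "positive", "negative")
  edges <- edges[order(edges$lncrna_id, edges$mrna_id), , drop = FALSE]
  rownames(edges) <- NULL
  ids <- c(unique(edges$lncrna_id), unique(edges$mrna_id))
  nodes <- data.frame(
    id = ids,
    kind = rep(c("lncRNA", "mRNA"),
               c(length(unique(edges$lncrna_id)),
                 length(unique(edges$mrna_id)))),
    regulation = if (is.null(direction)) NA_character_
                 else unname(direction[ids]))
  net <- empty_net()
  net$nodes <- nodes
  net$edges <- edges
  net
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$kind == "lncRNA"), "lncRNA /",
      sum(x$nodes$kind == "mRNA"), "mRNA ),",
      nrow(x$edges), "edges; |COR| >", x$params$cor_threshold,
      "& p <", x$params$alpha, "\n")
  invisible(x)
}

#' Select the top-k network nodes by correlation strength
#'
#' Nodes are ranked by the maximum `|COR|` over their incident edges, ties
#' broken by degree (descending) then id; returns the top `k` and the
#' subnetwork of all passing edges incident to them.
#'
#' @param network A `coexpression_network`.
#' @param k Number of nodes to keep (default 10; if `k` exceeds the node
#'   count, all nodes are returned with a notice).
#' @return List with `nodes` (ranked data.frame with `max_abs_cor` and
#'   `degree`) and `network` (induced subnetwork).
#' @export
select_top_nodes <- function(network, k = 10) {
  stopifnot(inherits(network, "coexpression_network"))
  if (nrow(network$nodes) == 0L) stop_domain("network is empty")
  e <- network$edges
  inc <- rbind(data.frame(id = e$lncrna_id, cor = abs(e$cor)),
               data.frame(id = e$mrna_id, cor = abs(e$cor)))
  stats <- aggregate(cor ~ id, inc, max)
  names(stats)[2] <- "max_abs_cor"
  stats$degree <- as.integer(table(inc$id)[stats$id])
  stats <- stats[order(-stats$max_abs_cor, -stats$degree, stats$id), ]
  rownames(stats) <- NULL
  if (k > nrow(stats)) {
    message("k exceeds node count; returning all ", nrow(stats), " nodes")
    k <- nrow(stats)
  }
  top <- head(stats, k)
  keep <- e$lncrna_id %in% top$id | e$mrna_id %in% top$id
  sub <- network
  sub$edges <- e[keep, , drop = FALSE]
  ids <- unique(c(sub$edges$lncrna_id, sub$edges$mrna_id))
  sub$nodes <- network$nodes[network$nodes$id %in% ids, , drop = FALSE]
  rownames(sub$nodes) <- rownames(sub$edges) <- NULL
  list(nodes = top, network = sub)
}

#' Rank the lncRNA partners of an mRNA by correlation strength
#'
#' @param network A `coexpression_network`.
#' @param query_mrna mRNA transcript id present in the network.
#' @return data.frame of the query's edges sorted by `|cor|` descending,
#'   ties by lncRNA id.
#' @export
rank_partner_correlations <- function(network, query_mrna) {
  stopifnot(inherits(network, "coexpression_network"))
  if (!query_mrna %in% network$nodes$id) {
    stop_domain("query '", query_mrna, "' not present in the network")
  }
  e <- network$edges[network$edges$mrna_id == query_mrna, , drop = FALSE]
  e <- e[order(-abs(e$cor), e$lncrna_id), , drop = FALSE]
  rownames(e) <- NULL
  e
}

as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$lncrna_id,
                   to = network$edges$mrna_id,
                   cor = network$edges$cor,
                   z = network$edges$z,
                   p_value = network$edges$p_value,
                   sign = network$edges$sign),
    directed = FALSE,
    vertices = network$nodes)
  g
}

#' Export a co-expression network for Cytoscape
#'
#' Formats: `"sif"` (one line per edge, interaction `pos`/`neg`, plus node
#' and edge attribute TSVs), `"graphml"` (igraph writer; node `kind` /
#' `regulation` and edge `cor` / `p_value` / `sign` attributes), or
#' `"tsv"` (edge table only). Output is byte-stable for a fixed network.
#'
#' @param network A `coexpression_network`.
#' @param dir Output directory (created if needed).
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @param prefix File-name prefix (default `"network"`).
#' @return Character vector of written file paths.
#' @export
export_network <- function(network, dir, format = c("sif", "graphml", "tsv"),
                           prefix = "network") {
  stopifnot(inherits(network, "coexpression_network"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- network$edges
  paths <- character(0)
  if (format == "sif") {
    sif <- file.path(dir, paste0(prefix, ".sif"))
    writeLines(sprintf("%s\t%s\t%s", e$lncrna_id,
                       ifelse(e$sign == "positive", "pos", "neg"),
                       e$mrna_id), sif)
    nodes <- file.path(dir, paste0(prefix, "_nodes.tsv"))
    write.table(network$nodes, nodes, sep = "\t", quote = FALSE,
                row.names = FALSE)
    edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
    write.table(e, edges, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(sif, nodes, edges)
  } else if (format == "graphml") {
    gml <- file.path(dir, paste0(prefix, ".graphml"))
    igraph::write_graph(as_igraph(network), gml, format = "graphml")
    paths <- gml
  } else {
    edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
    write.table(e, edges, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- edges
  }
  paths
}
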