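# Independent oracles used to cross-check the package's statistics. These
# deliberately use different algorithms from the implementation (recursive
# permutation enumeration + stats::cor; explicit choose() arithmetic).

# All permutations of 1..n by head-recursion (differs from the package's
# iterative insertion construction).
perms_oracle <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_oracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Two-sided exhaustive permutation p for Pearson r, by direct enumeration.
perm_p_oracle <- function(x, y) {
  P <- perms_oracle(length(x))
  r_obs <- stats::cor(x, y)
  r_all <- apply(P, 1, function(idx) stats::cor(x, y[idx]))
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# Conditional binomial two-sided p by explicit pmf arithmetic.
binom_p_oracle <- function(k1, k2, n1, n2) {
  n <- k1 + k2
  pr <- n1 / (n1 + n2)
  pmf <- vapply(0:n, function(k) {
    choose(n, k) * pr^k * (1 - pr)^(n - k)
  }, numeric(1))
  min(1, sum(pmf[pmf <= pmf[k1 + 1] * (1 + 1e-7)]))
}

# Upper-tail hypergeometric P(X >= k) by combinatorial counting.
hyper_p_oracle <- function(k, K, n, M) {
  kk <- max(0, k):min(K, n)
  sum(choose(K, kk) * choose(M - K, n - kk)) / choose(M, n)
}

# Brute-force per-base region label for a single-block read: fraction of
# bases in exons (majority rule), transcript overlap, junction irrelevant.
region_label_oracle <- function(chrom, start, end, ann) {
  bases <- start:end
  tx <- ann$transcripts
  in_tx <- FALSE
  exonic <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(tx))) {
    if (tx$chrom[i] != chrom) next
    if (start <= tx$end[i] && end >= tx$start[i]) in_tx <- TRUE
    ex <- ann$exons[ann$exons$transcript_id == tx$transcript_id[i], ]
    for (j in seq_len(nrow(ex))) {
      exonic <- exonic | (bases >= ex$start[j] & bases <= ex$end[j])
    }
  }
  if (!in_tx) return("intergenic")
  if (mean(exonic) >= 0.5) "exonic" else "intronic"
}
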