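test_that("conditional binomial test matches hand-derivable cases", {
  # symmetric mode: equal counts, equal libraries
  expect_equal(de_test(25, 25, 1e6, 1e6), 1.0)
  # k1=10, k2=0, equal libraries: p = 2 * 0.5^10
  expect_equal(de_test(10, 0, 1e6, 1e6), 2 * 0.5^10)
  # swapping the groups leaves p unchanged
  expect_equal(de_test(17, 4, 2e6, 3e6), de_test(4, 17, 3e6, 2e6))
  # untestable record
  expect_warning(p <- de_test(0, 0, 1e6, 1e6), "untestable")
  expect_true(is.na(p))
})

test_that("exact branch agrees with pmf enumeration for k1+k2 <= 50", {
  for (ratio in c(1, 2, 10)) {
    n1 <- 1e6
    n2 <- ratio * 1e6
    for (tot in c(1, 2, 5, 17, 50)) {
      for (k1 in unique(c(0, 1, tot %/% 3, tot %/% 2, tot))) {
        expect_equal(de_test(k1, tot - k1, n1, n2),
                     binom_p_oracle(k1, tot - k1, n1, n2),
                     tolerance = 1e-12,
                     info = sprintf("ratio=%d tot=%d k1=%d", ratio, tot, k1))
      }
    }
  }
})

test_that("normal-approximation branch is close to exact at the boundary", {
  # same inputs through both branches, just across the threshold
  p_exact <- de_test(5200, 4800, 1e6, 1e6, exact_max = 1e4)
  p_approx <- de_test(5200, 4800, 1e6, 1e6, exact_max = 1e3)
  expect_equal(p_exact, p_approx, tolerance = 0.01)
})

test_that("fold change reproduces the published worked examples", {
  # FC 15.82 -> log2FC 3.98; FC 2.51 -> log2FC 1.33 (2 dp, pseudocount 0)
  fc1 <- fold_change(1, 15.82, pseudocount = 0)
  expect_equal(round(fc1$log2fc, 2), 3.98)
  fc2 <- fold_change(1, 2.51, pseudocount = 0)
  expect_equal(round(fc2$log2fc, 2), 1.33)
  # equal means -> FC 1, log2fc 0 (with and without pseudocount)
  expect_equal(fold_change(7, 7)$fold_change, 1)
  expect_equal(fold_change(7, 7)$log2fc, 0)
  # invariant: log2fc = log2(fold_change)
  fc <- fold_change(runif(20, 0, 50), runif(20, 0, 50))
  expect_equal(fc$log2fc, log2(fc$fold_change), tolerance = 1e-9)
  expect_error(fold_change(0, 0, pseudocount = 0), "undefined")
})

test_that("BH q-values follow step-up and are permutation-invariant", {
  expect_equal(adjust_q(0.037), 0.037)            # single p: q = p
  expect_equal(adjust_q(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_q(rep(1, 5)), rep(1, 5))
  # dual route: matches stats::p.adjust on random input, in input order
  set.seed(3)
  p <- runif(100)
  expect_equal(adjust_q(p), p.adjust(p, "BH"))
  perm <- sample(100)
  expect_equal(adjust_q(p[perm]), adjust_q(p)[perm])
  # Storey variant shrinks towards BH * pi0 and stays in [0, 1]
  qs <- adjust_q(p, method = "storey")
  expect_true(all(qs <= adjust_q(p) + 1e-12))
  expect_error(adjust_q(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance filter applies the dual threshold and reports classes", {
  rec <- data.frame(
    transcript_id = c("up1", "weak", "down1", "na1"),
    biotype = c("mRNA", "mRNA", "known-lncRNA", "mRNA"),
    log2fc = c(3.98, 0.5, -2.54, 2.0),
    q_value = c(1e-5, 1e-9, 0.0485, NA))
  out <- significance_filter(rec)
  expect_equal(out$records$direction, c("up", "none", "down", "none"))
  expect_equal(nrow(out$up), 1L)
  expect_equal(nrow(out$down), 1L)
  # monotone: tightening the threshold never adds significant calls
  loose <- significance_filter(rec, log2fc_threshold = 1)$records
  tight <- significance_filter(rec, log2fc_threshold = 1.5)$records
  expect_true(all(tight$transcript_id[tight$significant] %in%
                    loose$transcript_id[loose$significant]))
})

test_that("published top-table values pass the stated filters", {
  # the 10 up / 10 down new-lncRNA rows: |log2FC| >= 2.54, q <= 0.0485
  log2fc <- c(3.579309818, 3.435888747, 3.407071645, 3.105719533,
              3.10367252, 2.863694799, 2.854429136, 2.753874179,
              2.673461266, 2.546936401,
              -2.785739111, -2.845027227, -2.890310541, -3.09197587,
              -3.138016002, -3.208470573, -3.289274477, -3.519838355,
              -3.684227245, -4.152719101)
  q <- c(4.25e-07, 2.79e-10, 0.0037973, 3.29e-07, 0.0001139, 0.00106288,
         0.04845512, 0.00212182, 0.00039418, 0.00032681,
         0.03815687, 0.00249637, 0.02281791, 0.03014613, 0.02275018,
         0.02846326, 4.31e-05, 0.02898882, 0.03668885, 0.01282738)
  rec <- data.frame(transcript_id = sprintf("t%02d", 1:20),
                    log2fc = log2fc, q_value = q)
  out <- significance_filter(rec, log2fc_threshold = 1, alpha = 0.05)
  expect_true(all(out$records$significant))
  expect_equal(sum(out$records$direction == "up"), 10L)
  expect_equal(sum(out$records$direction == "down"), 10L)
})

test_that("run_de has controlled type-I error and recovers planted effects", {
  # calibration is defined under the test's own sampling model (technical,
  # Poisson-like noise); biological overdispersion makes the conditional
  # binomial test anticonservative by construction, so the null world here
  # carries counting noise only
  fp <- numeric(5)
  for (s in 1:5) {
    cfg <- small_config(seed = 100 + s, de_fraction = 0,
                        n_planted_pairs = 0L, nb_dispersion = 1e-9)
    sim <- simulate_annotation(cfg)
    cnt <- simulate_counts(sim$annotation, cfg)
    de <- run_de(cnt$counts)
    fp[s] <- mean(de$p_value < 0.05, na.rm = TRUE)
  }
  expect_lte(mean(fp), 0.06)

  cfg <- small_config(seed = 200, de_fraction = 0.2, nb_dispersion = 0.1)
  sim <- simulate_annotation(cfg)
  cnt <- simulate_counts(sim$annotation, cfg)
  de <- significance_filter(run_de(cnt$counts))$records
  truth <- cnt$truth$de_transcripts
  strong <- truth[abs(truth$log2fc) >= 2, ]
  called <- de$significant[match(strong$transcript_id, de$transcript_id)]
  expect_gte(mean(called), 0.9)
})

test_that("plot selections truncate, standardize and stay monotone", {
  set.seed(11)
  n <- 150
  ids <- sprintf("t%03d", 1:n)
  rec <- data.frame(transcript_id = ids,
                    biotype = "mRNA",
                    log2fc = runif(n, 1.6, 5),
                    q_value = runif(n, 0, 0.04))
  rec$q_value[1] <- 1e-12   # force the constant row into the selection
  vals <- matrix(runif(n * 6), n, 6,
                 dimnames = list(ids, paste0("s", 1:6)))
  vals[1, ] <- 0.25  # constant row
  expr <- expression_matrix(vals, "rpkm")
  expr <- log_transform(expr)
  expect_warning(sel <- plot_selections(rec, expr), "constant row")
  expect_equal(nrow(sel$heatmap$mRNA), 100L)
  expect_equal(nrow(sel$volcano), n)
  # constant row standardized to zeros
  expect_true(all(sel$heatmap$mRNA[ids[1], ] == 0))
  # non-constant rows standardized to mean 0, sd 1
  expect_equal(unname(rowMeans(sel$heatmap$mRNA[2:5, ])), rep(0, 4),
               tolerance = 1e-12)
  # selection at 1.5 is a subset of selection at 1.0
  sel_all <- suppressWarnings(
    plot_selections(rec, expr, log2fc_threshold = 1.0, top_n = n))
  expect_true(all(rownames(sel$heatmap$mRNA) %in%
                    rownames(sel_all$heatmap$mRNA)))
  # fewer than 2 passing transcripts: heatmap skipped with a notice
  rec2 <- rec
  rec2$q_value <- 0.9
  expect_message(out <- plot_selections(rec2, expr), "skipped")
  expect_null(out$heatmap)
})
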