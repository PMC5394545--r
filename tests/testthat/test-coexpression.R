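test_that("pearson_cor matches hand computation and flags degeneracy", {
  x <- c(1, 2, 3)
  expect_equal(pearson_cor(x, 2 * x + 3), 1.0)
  expect_equal(pearson_cor(x, -x), -1.0)
  expect_equal(pearson_cor(x, c(1, 2, 4)), 0.98198, tolerance = 1e-5)
  expect_warning(r <- pearson_cor(x, c(5, 5, 5)), "zero variance")
  expect_true(is.na(r))
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("exhaustive permutation p matches enumeration on hand cases", {
  # n=3, perfect correlation: only identity and full reversal give |r|=1
  res3 <- permutation_test(c(1, 2, 3), c(2, 4, 6), mode = "exhaustive")
  expect_equal(res3$p_value, 2 / 6)
  expect_equal(res3$n_perm, 6L)
  # n=6, perfect correlation: p = 2/720
  x6 <- c(1, 2, 3, 4, 5, 6)
  res6 <- permutation_test(x6, 10 * x6 + 1, mode = "exhaustive")
  expect_equal(res6$p_value, 2 / 720)
  # null mean ~ 0, z = (r - mean)/sd well-defined
  expect_equal(res6$null_mean, 0, tolerance = 1e-12)
  expect_gt(res6$z, 2)
  # exhaustive mode refuses n > 9
  expect_error(permutation_test(rnorm(10), rnorm(10), mode = "exhaustive"),
               "monte_carlo")
})

test_that("permutation p equals the brute-force oracle for n <= 6", {
  set.seed(77)
  for (n in 3:6) {
    for (rep in 1:3) {
      x <- rnorm(n)
      y <- rnorm(n)
      res <- permutation_test(x, y, mode = "exhaustive")
      expect_equal(res$p_value, perm_p_oracle(x, y), tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  set.seed(5)
  x <- rnorm(6)
  y <- x + rnorm(6, sd = 0.8)
  ex <- permutation_test(x, y, mode = "exhaustive")
  mc <- permutation_test(x, y, mode = "monte_carlo", n_perm = 1e5, seed = 42)
  expect_lt(abs(mc$p_value - ex$p_value), 0.01)
  # seeded reproducibility without touching the caller's RNG stream
  mc2 <- permutation_test(x, y, mode = "monte_carlo", n_perm = 1e5, seed = 42)
  expect_identical(mc$p_value, mc2$p_value)
})

test_that("n=3 designs can never reach significance", {
  # documented guard: minimum exhaustive two-sided p at n=3 is 2/6 > 0.05
  res <- permutation_test(c(1, 2, 3), c(1.1, 2.2, 2.9), mode = "exhaustive")
  expect_gte(res$p_value, 1 / 3)
})

test_that("build_network is bipartite and applies the dual threshold", {
  set.seed(13)
  n <- 6
  mk <- function(ids, rows) {
    matrix(rows, length(ids), n, byrow = TRUE,
           dimnames = list(ids, paste0("s", 1:n)))
  }
  base <- rnorm(n)
  lnc <- mk(c("L1", "L2"), c(base, rnorm(n)))
  mrna <- mk(c("M1", "M2", "M3"),
             c(base + rnorm(n, sd = 0.01), rnorm(n), rnorm(n)))
  net <- build_network(lnc, mrna, cor_threshold = 0.95, alpha = 0.05)
  # 2 x 3 candidates, never lncRNA-lncRNA or mRNA-mRNA
  expect_true(all(net$edges$lncrna_id %in% c("L1", "L2")))
  expect_true(all(net$edges$mrna_id %in% c("M1", "M2", "M3")))
  # planted near-perfect pair is recovered
  expect_true(any(net$edges$lncrna_id == "L1" & net$edges$mrna_id == "M1"))
  # conjunction rule: |r| above threshold but p above alpha -> no edge
  r_l1m1 <- cor(lnc["L1", ], mrna["M1", ])
  strict <- build_network(lnc, mrna, cor_threshold = 0.95, alpha = 0.001)
  expect_equal(nrow(strict$edges), 0L)
  expect_gt(abs(r_l1m1), 0.95)
  # zero-variance rows are excluded with a warning
  lnc2 <- rbind(lnc, mk("Lconst", rep(1, n)))
  expect_warning(build_network(lnc2, mrna), "zero-variance")
})

test_that("network pair p-values agree with single-pair permutation tests", {
  set.seed(29)
  lnc <- matrix(rnorm(3 * 6), 3, 6,
                dimnames = list(paste0("L", 1:3), paste0("s", 1:6)))
  mrna <- matrix(rnorm(4 * 6), 4, 6,
                 dimnames = list(paste0("M", 1:4), paste0("s", 1:6)))
  nul <- sahnet:::perm_null_bipartite(
    t(scale(t(lnc))), t(scale(t(mrna))), mode = "exhaustive")
  for (i in 1:3) {
    for (j in 1:4) {
      single <- permutation_test(lnc[i, ], mrna[j, ], mode = "exhaustive")
      expect_equal(nul$p[i, j], single$p_value, tolerance = 1e-12)
      expect_equal(nul$r[i, j], single$r, tolerance = 1e-12)
      expect_equal(nul$z[i, j], single$z, tolerance = 1e-9)
    }
  }
})

test_that("DE restriction, top-node selection and partner ranking work", {
  set.seed(17)
  n <- 6
  shared1 <- rnorm(n)
  shared2 <- rnorm(n)
  lnc <- rbind(LA = shared1 + rnorm(n, sd = 0.01),
               LB = shared2 + rnorm(n, sd = 0.05),
               LX = rnorm(n))
  mrna <- rbind(MA = shared1 + rnorm(n, sd = 0.01),
                MB = shared2 + rnorm(n, sd = 0.05),
                MX = rnorm(n))
  colnames(lnc) <- colnames(mrna) <- paste0("s", 1:n)
  de <- data.frame(
    transcript_id = c("LA", "LB", "LX", "MA", "MB", "MX"),
    direction = c("up", "down", "up", "up", "down", "none"),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  net <- build_network(lnc, mrna, de_records = de)
  # MX not significant -> never a node
  expect_false("MX" %in% net$nodes$id)
  expect_equal(net$nodes$regulation[net$nodes$id == "LA"], "up")
  # partner ranking: strongest |cor| first
  if ("MA" %in% net$nodes$id) {
    ranked <- rank_partner_correlations(net, "MA")
    expect_equal(ranked$lncrna_id[1], "LA")
    expect_true(all(diff(abs(ranked$cor)) <= 0))
  }
  expect_error(rank_partner_correlations(net, "nope"), "not present")
  # top-node selection: argmax first, k > node count returns all
  top1 <- select_top_nodes(net, k = 1)
  best_edge <- net$edges[which.max(abs(net$edges$cor)), ]
  expect_true(top1$nodes$id[1] %in% c(best_edge$lncrna_id,
                                      best_edge$mrna_id))
  expect_message(all_nodes <- select_top_nodes(net, k = 100), "all")
  expect_equal(nrow(all_nodes$nodes), nrow(net$nodes))
  expect_equal(nrow(all_nodes$network$edges), nrow(net$edges))
})

test_that("network export formats are consistent and round-trip", {
  set.seed(19)
  n <- 6
  shared <- rnorm(n)
  lnc <- rbind(L1 = shared + rnorm(n, sd = 0.01),
               L2 = -shared + rnorm(n, sd = 0.01))
  mrna <- rbind(M1 = shared + rnorm(n, sd = 0.01))
  colnames(lnc) <- colnames(mrna) <- paste0("s", 1:n)
  net <- build_network(lnc, mrna)
  expect_gt(nrow(net$edges), 0)
  td <- withr::local_tempdir()
  sif_files <- export_network(net, td, format = "sif")
  # SIF line count equals edge count
  expect_length(readLines(sif_files[1]), nrow(net$edges))
  # negative correlations exported as 'neg'
  if (any(net$edges$sign == "negative")) {
    expect_true(any(grepl("\tneg\t", readLines(sif_files[1]))))
  }
  gml <- export_network(net, td, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$kind, net$nodes$kind)
  expect_equal(sort(igraph::E(g)$cor), sort(net$edges$cor))
  # byte-stable export
  sif2 <- export_network(net, file.path(td, "b"), format = "sif")
  expect_identical(readLines(sif_files[1]), readLines(sif2[1]))
  # empty network -> header-only/empty files, no error
  empty <- suppressMessages(
    build_network(matrix(rnorm(6), 1, 6, dimnames = list("L", NULL)),
                  matrix(rnorm(6), 1, 6, dimnames = list("M", NULL)),
                  cor_threshold = 0.999999, alpha = 1e-9))
  ef <- export_network(empty, file.path(td, "empty"), format = "sif")
  expect_length(readLines(ef[1]), 0)
  expect_length(readLines(ef[2]), 1)  # header only
})
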