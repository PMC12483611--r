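sim_cells <- function(n_a, n_b, p_a, p_b, clusters = paste0("C", seq_along(p_a)),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    cluster = c(sample(clusters, n_a, TRUE, p_a),
                sample(clusters, n_b, TRUE, p_b)),
    group = rep(c("a", "b"), c(n_a, n_b)),
    stringsAsFactors = FALSE
  )
}

test_that("proportion_test null case and log2FD arithmetic", {
  # identical deterministic composition: log2FD 0, nothing significant
  cells <- data.frame(cluster = rep(c("C1", "C2"), 100),
                      group = rep(c("a", "b"), each = 100))
  res <- proportion_test(cells, "a", "b", n_perm = 200, n_boot = 100, seed = 1)
  expect_equal(res$log2fd, c(0, 0))
  expect_false(any(res$significant))

  # prop 0.1 vs 0.5: log2FD = log2(5)
  cells2 <- data.frame(
    cluster = c(rep(c("C1", "C2"), c(10, 90)), rep(c("C1", "C2"), c(50, 50))),
    group = rep(c("a", "b"), each = 100))
  res2 <- proportion_test(cells2, "a", "b", n_perm = 200, n_boot = 0, seed = 1)
  expect_equal(res2$log2fd[res2$cluster == "C1"], log2(5), tolerance = 1e-12)

  # zero-count cluster gets the pseudo-proportion and a flag
  cells3 <- data.frame(
    cluster = c(rep("C1", 100), rep(c("C1", "C2"), c(80, 20))),
    group = rep(c("a", "b"), each = 100))
  res3 <- proportion_test(cells3, "a", "b", n_perm = 100, n_boot = 0, seed = 1)
  expect_true(res3$zero_substituted[res3$cluster == "C2"])
  expect_equal(res3$prop_a[res3$cluster == "C2"], 1 / 200)
  expect_error(proportion_test(cells3, "a", "zz", 10, 0, 1), "non-empty")
})

test_that("swapping groups negates log2FD and preserves p-values", {
  cells <- sim_cells(150, 180, c(0.2, 0.5, 0.3), c(0.4, 0.4, 0.2), seed = 33)
  r_ab <- proportion_test(cells, "a", "b", n_perm = 400, n_boot = 0, seed = 5)
  r_ba <- proportion_test(cells, "b", "a", n_perm = 400, n_boot = 0, seed = 5)
  expect_equal(r_ab$log2fd, -r_ba$log2fd, tolerance = 1e-12)
  expect_true(all(abs(r_ab$p_value - r_ba$p_value) <= 0.05))
})

test_that("BH adjustment matches the hand-coded step-up oracle", {
  set.seed(88)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # and the fdr column of a real run is the BH transform of p_value
  cells <- sim_cells(100, 100, rep(1 / 4, 4), rep(1 / 4, 4), seed = 4)
  res <- proportion_test(cells, "a", "b", n_perm = 100, n_boot = 0, seed = 2)
  expect_equal(res$fdr, oracle_bh(res$p_value), tolerance = 1e-12)
})

test_that("permutation p-values are super-uniform under the null", {
  # label exchange on null data: P(p <= x) <= x (+ MC slack)
  n_sim <- 500
  p1 <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    cells <- sim_cells(120, 120, c(0.3, 0.4, 0.3), c(0.3, 0.4, 0.3),
                       seed = 7000 + i)
    res <- proportion_test(cells, "a", "b", n_perm = 200, n_boot = 0,
                           seed = 100 + i)
    p1[i] <- res$p_value[1]
  }
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_p <- ecdf(p1)(grid)
  mc_slack <- 3 * sqrt(grid * (1 - grid) / n_sim)
  expect_true(all(ecdf_p <= grid + mc_slack + 1 / 201))
})

test_that("subject-weighted proportions use the subject as exchangeable unit", {
  set.seed(55)
  mk_subj <- function(subject, group, p, n = 60) {
    data.frame(cluster = sample(paste0("C", 1:3), n, TRUE, p),
               group = group, subject = subject, stringsAsFactors = FALSE)
  }
  cells <- rbind(
    do.call(rbind, lapply(1:4, function(i) mk_subj(paste0("a", i), "a", c(0.6, 0.3, 0.1)))),
    do.call(rbind, lapply(1:4, function(i) mk_subj(paste0("b", i), "b", c(0.2, 0.3, 0.5))))
  )
  res <- proportion_test(cells, "a", "b", n_perm = 300, n_boot = 200,
                         seed = 2, weight_by_subject = TRUE)
  expect_equal(nrow(res), 3)
  # observed proportions are means of per-subject proportions
  per_subj <- do.call(rbind, lapply(split(cells, cells$subject), function(d) {
    c(table(factor(d$cluster, paste0("C", 1:3))) / nrow(d),
      grp = d$group[1])
  }))
  pa <- colMeans(matrix(as.numeric(per_subj[per_subj[, "grp"] == "a", 1:3]), ncol = 3))
  expect_equal(res$prop_a, pa, tolerance = 1e-12)
  # strong shift in C1/C3 detected even at subject-level exchangeability
  expect_true(res$log2fd[res$cluster == "C3"] > 0.58)
  expect_error(proportion_test(cells, "a", "b", 10, 0, 1,
                               weight_by_subject = TRUE)[0, ], NA)
  bad <- cells; bad$subject <- "s1"
  expect_error(proportion_test(bad, "a", "b", 10, 0, 1,
                               weight_by_subject = TRUE), "both groups")
})

test_that("find_degs applies the dual rule (adjusted p and fold-change gate)", {
  set.seed(12)
  n_genes <- 40; n_cells <- 100
  base <- matrix(rpois(n_genes * n_cells, 5), n_genes,
                 dimnames = list(sprintf("g%02d", 1:n_genes), NULL))
  # identical distributions: no DEGs
  a <- matrix(rpois(n_genes * n_cells, 5), n_genes,
              dimnames = dimnames(base))
  d0 <- find_degs(base, a)
  expect_equal(sum(d0$deg), 0)

  # one gene shifted x2 (log2FC about 1) is flagged
  b <- a
  b["g01", ] <- rpois(n_cells, 11)   # (11+1)/(5+1) = 2 on pseudo-count scale
  d1 <- find_degs(base, b)
  expect_true(d1$deg[d1$gene == "g01"])
  expect_equal(sum(d1$deg), 1)

  # strong separation but log2FC 0.5 fails the 0.6 gate
  c1 <- a
  c1["g02", ] <- rpois(n_cells, 5) + 0L
  shift <- (mean(base["g02", ]) + 1) * 2^0.5 - 1
  c1["g02", ] <- stats::rnorm(n_cells, shift, 0.01)
  d2 <- find_degs(base, c1)
  expect_lt(d2$p_adj[d2$gene == "g02"], 0.05)
  expect_false(d2$deg[d2$gene == "g02"])

  # zero variance in both groups: p = 1 by convention
  za <- matrix(3, 2, 10); zb <- matrix(3, 2, 10)
  expect_equal(find_degs(za, zb)$p_value, c(1, 1))
})
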