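test_that("fit_ec50 recovers truth on noiseless series and flags degeneracy", {
  dil <- exp(seq(log(1 / 5), log(1 / 327680), length.out = 10))
  s <- gen_dilution_series(1e-3, top_od = 2, hill = 1.2, blank_od = 0.05,
                           dilutions = dil, noise_sd = 0)
  f <- fit_ec50(s, blank_od = 0.05)
  expect_identical(f$status, "ok")
  expect_lt(abs(f$ec50 - 1e-3) / 1e-3, 0.01)

  # all ODs at blank: no signal
  flat <- data.frame(dilution = dil, od = rep(0.05, 10))
  expect_identical(fit_ec50(flat, blank_od = 0.05)$status, "no_signal")

  # scale invariance: doubling every OD (blank included) leaves EC50 put
  s2 <- s; s2$od <- 2 * s2$od
  f2 <- fit_ec50(s2, blank_od = 0.10)
  expect_equal(f2$ec50, f$ec50, tolerance = 1e-6)

  expect_error(fit_ec50(s[1:3, ]), "at least 4")
})

test_that("fit_ec50 median error under 5% noise is within 10%", {
  dil <- exp(seq(log(1 / 5), log(1 / 327680), length.out = 10))
  errs <- vapply(1:100, function(seed) {
    s <- gen_dilution_series(1e-3, top_od = 2, hill = 1.2, blank_od = 0.05,
                             dilutions = dil, noise_sd = 0.05, seed = seed)
    f <- fit_ec50(s, blank_od = 0.05)
    abs(f$ec50 - 1e-3) / 1e-3
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("score_avidity reproduces the stated worked example and bounds", {
  m <- setNames(c(1.0, 0.8, 0.5, 0.2), c(0, 0.5, 1, 2))
  av <- score_avidity(m)
  expect_equal(unname(av$rai), c(80, 50, 20))
  expect_equal(unname(av$fractional), c(20, 30, 30, 20))
  expect_equal(av$trai, 150)

  # fully resistant: high = 100%, TRAI at the 300 AU maximum
  hi <- score_avidity(setNames(c(1, 1, 1, 1), c(0, 0.5, 1, 2)))
  expect_equal(unname(hi$fractional), c(0, 0, 0, 100))
  expect_equal(hi$trai, 300)

  # fully eluted: very low = 100%, TRAI 0
  lo <- score_avidity(setNames(c(1, 0, 0, 0), c(0, 0.5, 1, 2)))
  expect_equal(unname(lo$fractional), c(100, 0, 0, 0))
  expect_equal(lo$trai, 0)

  expect_error(score_avidity(setNames(c(0, 1, 1, 1), c(0, 0.5, 1, 2))),
               "positive")
  expect_error(score_avidity(setNames(c(1, 1, 1), c(0.5, 1, 2))), "reference")
})

test_that("avidity invariants: category identity, scale invariance, monotonicity", {
  set.seed(21)
  for (i in 1:100) {
    m <- sort(runif(4, 0.01, 2), decreasing = TRUE)
    names(m) <- c(0, 0.5, 1, 2)
    av <- score_avidity(m)
    expect_equal(sum(av$fractional), 100, tolerance = 1e-6)
    expect_true(all(av$fractional >= 0 & av$fractional <= 100))
    # TRAI = 3*high + 2*medium + 1*low (exact algebraic identity)
    f <- av$fractional
    expect_equal(av$trai,
                 3 * f[["high"]] + 2 * f[["medium"]] + 1 * f[["low"]],
                 tolerance = 1e-9)
    expect_true(all(diff(unname(av$rai)) <= 1e-12))
    # scale invariance
    av_k <- score_avidity(m * runif(1, 0.1, 10))
    expect_equal(av_k$fractional, av$fractional, tolerance = 1e-9)
    expect_equal(av_k$trai, av$trai, tolerance = 1e-9)
    # raising m(2) within the monotone bound never lowers TRAI or high
    m_up <- m
    m_up[4] <- min(m[3], m[4] * 1.5)
    av_up <- score_avidity(m_up)
    expect_gte(av_up$trai, av$trai - 1e-9)
    expect_gte(av_up$fractional[["high"]], av$fractional[["high"]] - 1e-9)
  }
})

test_that("replicate noise is absorbed by the monotonicity repair", {
  d <- data.frame(chaotrope_M = rep(c(0, 0.5, 1, 2), each = 3),
                  od = c(1.0, 1.1, 0.9, 1.05, 1.0, 0.95, 0.5, 0.55, 0.45,
                         0.2, 0.25, 0.15))
  av <- score_avidity(d)
  expect_true(all(av$fractional >= 0))
  expect_equal(sum(av$fractional), 100, tolerance = 1e-9)
  expect_warning(score_avidity(within(d, od[12] <- -0.05)), "clipped")
})

test_that("group TRAI deficit is recovered within 10 AU at every dose", {
  cc <- cohort_config(groups = c("healthy", "anti-TNF"),
                      subjects_per_group = 50, seed = 19)
  ser <- serology_config(od_noise_sd = 0.05, group_deficit = c("anti-TNF" = 40))
  s <- gen_serology_cohort(cc, ser)
  av <- score_avidity_table(s$chaotrope)
  est <- tapply(av$trai, list(av$group, av$dose), mean)
  tru <- tapply(s$truth$trai_true, list(s$truth$group, s$truth$dose), mean)
  diff_est <- est["healthy", ] - est["anti-TNF", ]
  diff_tru <- tru["healthy", ] - tru["anti-TNF", ]
  expect_true(all(abs(diff_est - diff_tru) <= 10))
})
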