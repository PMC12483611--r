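test_that("gen_repertoire honours zero-rate, determinism and the binomial law", {
  cc <- cohort_config(groups = c("healthy", "anti-TNF"),
                      subjects_per_group = 1, timepoints = "post-dose-2",
                      seed = 11)
  rc0 <- repertoire_config(cells_per_subject = 20, shm_rate = 0)
  r0 <- gen_repertoire(cc, rc0)
  expect_identical(r0$sequence_alignment, r0$germline_alignment)
  expect_true(all(r0$true_mut_count == 0L))

  rc <- repertoire_config(cells_per_subject = 25)
  expect_identical(gen_repertoire(cc, rc), gen_repertoire(cc, rc))

  # empirical mean mutations/cell within 3 SE of n*p (binomial law)
  cc1 <- cohort_config(groups = c("healthy", "anti-TNF"),
                       subjects_per_group = c(1, 1),
                       timepoints = "post-dose-2", seed = 202)
  rc1 <- repertoire_config(cells_per_subject = 500, shm_rate = 0.04)
  r1 <- gen_repertoire(cc1, rc1)
  counts <- r1$true_mut_count[r1$chain == "heavy"]
  n_cells <- length(counts)
  expect_equal(n_cells, 1000L)
  se <- sqrt(300 * 0.04 * 0.96 / n_cells)
  expect_lt(abs(mean(counts) - 12), 3 * se)
})

test_that("generative moments match configured parameters at large n", {
  cc <- cohort_config(groups = c("healthy", "anti-TNF"),
                      subjects_per_group = 1, timepoints = "post-dose-2",
                      seed = 77)
  rc <- repertoire_config(cells_per_subject = 5000)
  r <- gen_repertoire(cc, rc)
  h <- r[r$chain == "heavy" & r$group == "healthy", ]
  n <- nrow(h)
  props <- table(factor(h$subset, c("cMBC", "MZ-like", "aMBC"))) / n
  target <- rc$subset_props["healthy", ]
  tol <- 4 * sqrt(target * (1 - target) / n)
  expect_true(all(abs(props - target) < tol))
  iso_obs <- table(factor(h$c_call[h$subset == "cMBC"], rc$isotypes))
  iso_n <- sum(iso_obs)
  iso_p <- iso_obs / iso_n
  iso_t <- rc$isotype_probs["cMBC", ]
  expect_true(all(abs(iso_p - iso_t) < 4 * sqrt(iso_t * (1 - iso_t) / iso_n)))
})

test_that("probability-vector misconfiguration is rejected", {
  bad <- rbind("healthy" = c(0.5, 0.2, 0.2), "anti-TNF" = c(0.4, 0.45, 0.15))
  colnames(bad) <- c("cMBC", "MZ-like", "aMBC")
  expect_error(repertoire_config(subset_props = bad), "sum to 1")
  expect_error(repertoire_config(shm_rate = 0.3), "0.25")
  expect_error(cohort_config(groups = "one", seed = 1), "at least 2")
  expect_error(cohort_config(), "seed")
})

test_that("gen_serology_cohort encodes the configured TRAI trajectories", {
  cc <- cohort_config(seed = 5)
  # null effect, no noise: identical trajectories across groups
  ser0 <- serology_config(od_noise_sd = 0, group_deficit = c("anti-TNF" = 0))
  s0 <- gen_serology_cohort(cc, ser0)
  by_gd <- tapply(s0$truth$trai_true, list(s0$truth$group, s0$truth$dose), mean)
  expect_true(all(apply(by_gd, 2, function(x) diff(range(x)) == 0)))

  # round-trip: score_avidity recovers true TRAI exactly without noise
  av <- score_avidity_table(s0$chaotrope)
  m <- merge(av, s0$truth, by = c("subject", "group", "dose"))
  expect_equal(m$trai, m$trai_true, tolerance = 1e-8)

  # Monte-Carlo: with a positive deficit, anti-TNF mean TRAI is below the
  # healthy mean at every dose over 100 simulated subjects
  cc2 <- cohort_config(groups = c("healthy", "anti-TNF"),
                       subjects_per_group = 50, seed = 6)
  ser <- serology_config(od_noise_sd = 0.05)
  s <- gen_serology_cohort(cc2, ser)
  av <- score_avidity_table(s$chaotrope)
  means <- tapply(av$trai, list(av$group, av$dose), mean)
  expect_true(all(means["anti-TNF", ] < means["healthy", ]))
})

test_that("gen_dilution_series evaluates the 4PL exactly when noiseless", {
  # half-response at d = ec50
  s <- gen_dilution_series(1e-3, top_od = 2, hill = 1.3, blank_od = 0.1,
                           dilutions = 1e-3, noise_sd = 0)
  expect_equal(s$od, (2 + 0.1) / 2)
  # asymptote
  s2 <- gen_dilution_series(1e-3, top_od = 2, hill = 1, blank_od = 0,
                            dilutions = 1e6, noise_sd = 0)
  expect_equal(s2$od, 2, tolerance = 1e-6)
  # direct evaluation of the logistic form
  s3 <- gen_dilution_series(1e-3, top_od = 2, hill = 1, blank_od = 0,
                            dilutions = 1e-3 * c(1 / 9, 1, 9), noise_sd = 0)
  expect_equal(s3$od, c(0.2, 1.0, 1.8), tolerance = 1e-12)
})

test_that("gen_hto_qc produces separable singlets and detectable doublets", {
  cc <- cohort_config(seed = 8)
  # separable case: demux recovers all true labels
  h0 <- gen_hto_qc(cc, n_cells = 500, doublet_rate = 0, seed = 21)
  d0 <- demux_hashtags(h0$hto)
  expect_identical(d0$assignment[d0$status == "singlet"],
                   h0$truth$true_hashtag[d0$status == "singlet"])
  expect_gte(mean(d0$status == "singlet"), 0.99)

  # forced exclusion under the 10% mito rule
  qc_all15 <- data.frame(cell_id = h0$qc$cell_id, mito_pct = 15,
                         n_features = 3000)
  expect_length(filter_cells(qc_all15)$retained, 0)

  # margin-failure fraction >= 0.08 at doublet_rate 0.1 over 20 seeds
  fails <- vapply(1:20, function(s) {
    h <- gen_hto_qc(cc, n_cells = 1000, doublet_rate = 0.1, seed = s)
    d <- demux_hashtags(h$hto)
    mean(d$status != "singlet")
  }, numeric(1))
  expect_gte(mean(fails), 0.08)
})

test_that("AIRR TSV and HTO CSV writers round-trip", {
  cc <- cohort_config(seed = 31)
  rc <- repertoire_config(cells_per_subject = 3)
  r <- gen_repertoire(cc, rc)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_airr(r, tsv)
  r2 <- read_airr(tsv)
  expect_equal(r2$sequence_alignment, r$sequence_alignment)
  expect_equal(sort(names(r2)), sort(names(r)))

  h <- gen_hto_qc(cc, 50, 0, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_hto_csv(h$hto, csv)
  expect_identical(read_hto_csv(csv), h$hto)
})
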