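# retention ratio rho in [0,1] such that sum_{k=1..K} rho^k = trai/100,
# for K nonzero chaotrope concentrations; closed monotone root
solve_retention <- function(trai, k_nonzero) {
  target <- trai / 100
  if (target <= 0) return(0)
  if (target >= k_nonzero) return(1)
  stats::uniroot(function(r) sum(r^seq_len(k_nonzero)) - target,
                 c(0, 1), tol = 1e-12)$root
}

#' Generate one 4-parameter-logistic dilution series
#'
#' OD(d) = blank + (top - blank) / (1 + (ec50_true / d)^hill) at each plasma
#' concentration d, with multiplicative lognormal noise. Truth is recorded
#' in attributes for round-trip tests.
#'
#' @param ec50_true true half-point on the plasma concentration scale (> 0).
#' @param top_od upper asymptote.
#' @param hill Hill slope (> 0).
#' @param blank_od lower asymptote (assay blank), >= 0.
#' @param dilutions plasma concentrations (1/dilution factor), > 0.
#' @param noise_sd lognormal sigma; 0 gives the exact curve.
#' @param seed integer seed.
#' @return data.frame with `dilution` and `od`; attributes `ec50_true`,
#'   `top_od`, `hill`, `blank_od`.
#' @export
gen_dilution_series <- function(ec50_true, top_od = 2, hill = 1, blank_od = 0.05,
                                dilutions = 1 / (100 * 3^(0:6)),
                                noise_sd = 0, seed = 1L) {
  stopifnot(ec50_true > 0, all(dilutions > 0), noise_sd >= 0, top_od > blank_od)
  set.seed(seed)
  od <- blank_od + (top_od - blank_od) / (1 + (ec50_true / dilutions)^hill)
  if (noise_sd > 0) od <- od * exp(stats::rnorm(length(od), 0, noise_sd))
  out <- data.frame(dilution = dilutions, od = od)
  attr(out, "ec50_true") <- ec50_true
  attr(out, "top_od") <- top_od
  attr(out, "hill") <- hill
  attr(out, "blank_od") <- blank_od
  out
}

#' Generate chaotrope-displacement and dilution plates for a cohort
#'
#' Per subject x dose: a triplicate chaotrope series at the configured
#' molar concentrations, constructed so the true TRAI equals
#' `baseline_trai + dose * dose_increment - group_deficit`, with retention
#' fractions geometric in concentration rank (hence non-increasing before
#' noise); a 7-point 3-fold avidity dilution series from 1:100; and a
#' 10-point EC50 dilution series spanning 1:5 to 1:327,680.
#'
#' @param cohort a [cohort_config()].
#' @param ser a [serology_config()].
#' @return list with data.frames `chaotrope` (sample_id, subject, group,
#'   dose, replicate, chaotrope_M, od), `dilution` (sample_id, subject,
#'   group, dose, series, dilution, od), and `truth` (subject, group, dose,
#'   trai_true, ec50_true, m0).
#' @export
gen_serology_cohort <- function(cohort, ser) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(ser, "serology_config"))
  set.seed(cohort$seed + 7919L)
  concs <- ser$chaotrope_concs
  kz <- length(concs) - 1L
  ec50_dil <- exp(seq(log(1 / 5), log(1 / 327680), length.out = 10))
  avidity_dil <- 1 / (100 * 3^(0:6))
  chao <- list(); dil <- list(); truth <- list()
  for (g in cohort$groups) {
    deficit <- if (g %in% names(ser$group_deficit)) ser$group_deficit[[g]] else 0
    ec50_g <- if (!is.null(names(ser$ec50_true)) && g %in% names(ser$ec50_true)) {
      ser$ec50_true[[g]]
    } else {
      ser$ec50_true[[1]]
    }
    for (s in seq_len(cohort$subjects_per_group[[g]])) {
      subj <- sprintf("%s_S%d", gsub("[^A-Za-z0-9]", "", g), s)
      subj_ec50 <- ec50_g * exp(stats::rnorm(1, 0, 0.15))
      for (d in ser$doses) {
        trai <- min(max(ser$baseline_trai + d * ser$dose_increment - deficit, 0),
                    100 * kz)
        rho <- solve_retention(trai, kz)
        m0 <- 1.5 * exp(stats::rnorm(1, 0, 0.1))
        m <- m0 * c(1, rho^seq_len(kz))
        sid <- sprintf("%s_dose%d", subj, d)
        od <- rep(m, each = 3L)
        if (ser$od_noise_sd > 0) {
          od <- od * exp(stats::rnorm(length(od), 0, ser$od_noise_sd))
        }
        chao[[length(chao) + 1L]] <- data.frame(
          sample_id = sid, subject = subj, group = g, dose = d,
          replicate = rep(1:3, times = length(concs)),
          chaotrope_M = rep(concs, each = 3L), od = od,
          stringsAsFactors = FALSE
        )
        av <- gen_dilution_series(subj_ec50, top_od = m0, hill = 1.2,
                                  blank_od = 0.04, dilutions = avidity_dil,
                                  noise_sd = ser$od_noise_sd,
                                  seed = sample.int(2^30, 1))
        ec <- gen_dilution_series(subj_ec50, top_od = 2, hill = 1.2,
                                  blank_od = 0.04, dilutions = ec50_dil,
                                  noise_sd = ser$od_noise_sd,
                                  seed = sample.int(2^30, 1))
        dil[[length(dil) + 1L]] <- rbind(
          data.frame(sample_id = sid, subject = subj, group = g, dose = d,
                     series = "avidity", dilution = av$dilution, od = av$od,
                     stringsAsFactors = FALSE),
          data.frame(sample_id = sid, subject = subj, group = g, dose = d,
                     series = "ec50", dilution = ec$dilution, od = ec$od,
                     stringsAsFactors = FALSE)
        )
        truth[[length(truth) + 1L]] <- data.frame(
          subject = subj, group = g, dose = d, trai_true = trai,
          ec50_true = subj_ec50, m0 = m0, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(chaotrope = do.call(rbind, chao), dilution = do.call(rbind, dil),
       truth = do.call(rbind, truth))
}
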