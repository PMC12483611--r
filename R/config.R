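#' Cohort configuration
#'
#' Describes the study design being simulated: treatment groups, subjects
#' per group, and sampling timepoints. Defaults mirror a small vaccinated
#' IBD cohort: 3 healthy controls, 4 subjects on anti-IL-12/23, 5 on
#' anti-TNF, sampled after vaccine doses 2 and 3.
#'
#' @param groups character vector of group labels (>= 2 groups).
#' @param subjects_per_group positive integer scalar, or a vector with one
#'   entry per group (named or positional).
#' @param timepoints character vector of timepoint labels.
#' @param seed integer seed; mandatory, drives all downstream generators.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(groups = c("healthy", "anti-IL-12/23", "anti-TNF"),
                          subjects_per_group = c(3L, 4L, 5L),
                          timepoints = c("post-dose-2", "post-dose-3"),
                          seed) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("cohort_config: `seed` is mandatory and must be a single integer",
         call. = FALSE)
  }
  if (length(groups) < 2L) stop("cohort_config: need at least 2 groups", call. = FALSE)
  if (anyDuplicated(groups)) stop("cohort_config: duplicated group labels", call. = FALSE)
  n <- length(subjects_per_group)
  if (!n %in% c(1L, length(groups))) {
    stop("cohort_config: subjects_per_group must be scalar or one per group",
         call. = FALSE)
  }
  spg <- as.integer(rep_len(subjects_per_group, length(groups)))
  if (any(spg < 1L)) stop("cohort_config: subjects_per_group must be >= 1", call. = FALSE)
  names(spg) <- groups
  structure(list(groups = as.character(groups), subjects_per_group = spg,
                 timepoints = as.character(timepoints),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

check_prob_vec <- function(p, what, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > tol) {
    stop(what, ": probability vector must be nonnegative and sum to 1 (got sum ",
         format(sum(p), digits = 12), ")", call. = FALSE)
  }
  invisible(p)
}

# expand a per-group scalar/vector or group x subset matrix to a full matrix
expand_group_subset <- function(x, groups, subsets, what) {
  if (is.matrix(x)) {
    if (!setequal(rownames(x), groups) || !setequal(colnames(x), subsets)) {
      stop(what, ": matrix must have groups as rows and subsets as columns",
           call. = FALSE)
    }
    return(x[groups, subsets, drop = FALSE])
  }
  v <- rep_len(x, length(groups))
  if (!is.null(names(x)) && all(groups %in% names(x))) v <- x[groups]
  m <- matrix(rep(as.numeric(v), length(subsets)), nrow = length(groups),
              dimnames = list(groups, subsets))
  m
}

#' Repertoire generator configuration
#'
#' Holds the generative knobs for synthetic BCR repertoires: memory-B-cell
#' subset composition per group, per-group somatic hypermutation rates,
#' isotype usage per subset, a truncated power-law clone-size law, the V/J
#' usage spectrum, and the germline/region geometry.
#'
#' Default effect sizes (anti-TNF SHM rate 0.025 vs 0.045 in the other
#' groups; reduced classical-MBC share under anti-TNF) are plausible values
#' chosen for power testing, not published numbers.
#'
#' @param cells_per_subject cells simulated per subject x timepoint.
#' @param subset_props group x subset matrix (or per-group list) of
#'   probabilities over `c("cMBC","MZ-like","aMBC")`; rows sum to 1.
#' @param shm_rate per-group scalar (or group x subset matrix) mean
#'   substitution probability per position; each value in \[0, 0.25\].
#' @param isotype_probs subset x isotype matrix of probabilities over
#'   `c("IGHM","IGHG1","IGHG2","IGHG3","IGHG4","IGHA1")`; rows sum to 1.
#' @param clone_size_exponent power-law exponent (> 1) for clone sizes,
#'   truncated at 10 cells.
#' @param vj_usage V/J frequency table as from [default_vj_usage()].
#' @param germline_length nucleotides (fixed 300 for the packaged germline).
#' @param region_layout data.frame of region boundaries; see
#'   [default_region_layout()].
#' @param multiplet_frac fraction of cells given a second heavy chain, used
#'   only to exercise the multi-heavy-chain exclusion filter. Default 0.
#' @return A `repertoire_config` list.
#' @export
repertoire_config <- function(cells_per_subject = 50L,
                              subset_props = NULL,
                              shm_rate = c("healthy" = 0.045,
                                           "anti-IL-12/23" = 0.045,
                                           "anti-TNF" = 0.025),
                              isotype_probs = NULL,
                              clone_size_exponent = 2.5,
                              vj_usage = default_vj_usage(),
                              germline_length = 300L,
                              region_layout = default_region_layout(),
                              multiplet_frac = 0) {
  subsets <- c("cMBC", "MZ-like", "aMBC")
  isotypes <- c("IGHM", "IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHA1")
  if (is.null(subset_props)) {
    subset_props <- rbind(
      "healthy"       = c(0.65, 0.25, 0.10),
      "anti-IL-12/23" = c(0.60, 0.28, 0.12),
      "anti-TNF"      = c(0.40, 0.45, 0.15)
    )
    colnames(subset_props) <- subsets
  }
  if (is.null(isotype_probs)) {
    isotype_probs <- rbind(
      "cMBC"    = c(0.10, 0.45, 0.12, 0.08, 0.05, 0.20),
      "MZ-like" = c(0.60, 0.15, 0.05, 0.03, 0.02, 0.15),
      "aMBC"    = c(0.25, 0.35, 0.10, 0.05, 0.05, 0.20)
    )
    colnames(isotype_probs) <- isotypes
  }
  stopifnot(cells_per_subject >= 1, clone_size_exponent > 1,
            germline_length >= 3, multiplet_frac >= 0, multiplet_frac < 1)
  for (i in seq_len(nrow(subset_props))) {
    check_prob_vec(subset_props[i, ], paste0("subset_props[", rownames(subset_props)[i], "]"))
  }
  for (i in seq_len(nrow(isotype_probs))) {
    check_prob_vec(isotype_probs[i, ], paste0("isotype_probs[", rownames(isotype_probs)[i], "]"))
  }
  if (any(shm_rate < 0) || any(shm_rate > 0.25)) {
    stop("repertoire_config: shm_rate must lie in [0, 0.25]", call. = FALSE)
  }
  validate_region_layout(region_layout, germline_length)
  structure(list(cells_per_subject = as.integer(cells_per_subject),
                 subset_props = subset_props, shm_rate = shm_rate,
                 isotype_probs = isotype_probs,
                 clone_size_exponent = clone_size_exponent,
                 vj_usage = vj_usage,
                 germline_length = as.integer(germline_length),
                 region_layout = region_layout,
                 multiplet_frac = multiplet_frac,
                 subsets = subsets, isotypes = isotypes),
            class = "repertoire_config")
}

#' Serology generator configuration
#'
#' Generative truth for chaotrope-displacement avidity plates and ELISA
#' dilution series. True total relative avidity (TRAI, avidity units) per
#' subject x dose is `baseline_trai + dose * dose_increment -
#' group_deficit(group)`, clamped to the attainable range \[0, 300\] AU for
#' three nonzero chaotrope concentrations.
#'
#' @param doses integer vector of vaccine dose numbers.
#' @param baseline_trai AU at dose 0.
#' @param dose_increment AU gained per dose.
#' @param group_deficit named numeric: AU subtracted per group (default 40
#'   for anti-TNF, 0 otherwise — a plausible effect size for power testing,
#'   not a published number).
#' @param od_noise_sd lognormal sigma applied multiplicatively to ODs.
#' @param ec50_true named per-group geometric-mean true EC50 on the plasma
#'   concentration scale (1/dilution), or a scalar.
#' @param chaotrope_concs molar chaotrope series, strictly increasing from 0.
#' @return A `serology_config` list.
#' @export
serology_config <- function(doses = 1:4,
                            baseline_trai = 80,
                            dose_increment = 45,
                            group_deficit = c("anti-TNF" = 40),
                            od_noise_sd = 0.05,
                            ec50_true = 5e-3,
                            chaotrope_concs = c(0, 0.5, 1, 2)) {
  if (od_noise_sd < 0) stop("serology_config: od_noise_sd must be >= 0", call. = FALSE)
  if (chaotrope_concs[1] != 0 || any(diff(chaotrope_concs) <= 0)) {
    stop("serology_config: chaotrope_concs must be strictly increasing starting at 0",
         call. = FALSE)
  }
  structure(list(doses = as.integer(doses), baseline_trai = baseline_trai,
                 dose_increment = dose_increment, group_deficit = group_deficit,
                 od_noise_sd = od_noise_sd, ec50_true = ec50_true,
                 chaotrope_concs = chaotrope_concs),
            class = "serology_config")
}
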