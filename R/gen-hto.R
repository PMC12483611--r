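#' Generate a cell QC table and hashtag (HTO) count matrix
#'
#' Emulates a hashed single-cell capture: hashtags map to subject x
#' timepoint; singlets get one dominant hashtag (Poisson mean 200) over a
#' low background (Poisson mean 3, dominant:background >= 20:1 in
#' expectation), while injected doublets carry two comparable hashtags.
#' Per-cell mitochondrial percentage and unique-feature counts are drawn
#' from unimodal distributions with realistic tails so a minority of cells
#' violates the QC thresholds. True labels are retained.
#'
#' @param cohort a [cohort_config()].
#' @param n_cells total cells to simulate.
#' @param doublet_rate fraction in \[0, 1) of cells made two-hashtag doublets.
#' @param seed integer seed.
#' @param dominant_mean,background_mean Poisson means for singlet HTO counts.
#' @return list with `qc` (cell_id, mito_pct, n_features), `hto` (cells x
#'   hashtags integer matrix, rownames = cell ids), `hashtag_map` (hashtag,
#'   subject, timepoint), and `truth` (cell_id, true_hashtag, is_doublet).
#' @export
gen_hto_qc <- function(cohort, n_cells, doublet_rate = 0, seed = 1L,
                       dominant_mean = 200, background_mean = 3) {
  stopifnot(inherits(cohort, "cohort_config"),
            doublet_rate >= 0, doublet_rate < 1, n_cells >= 1)
  set.seed(seed)
  subj <- unlist(lapply(cohort$groups, function(g) {
    sprintf("%s_S%d", gsub("[^A-Za-z0-9]", "", g),
            seq_len(cohort$subjects_per_group[[g]]))
  }))
  map <- expand.grid(subject = subj, timepoint = cohort$timepoints,
                     stringsAsFactors = FALSE)
  map$hashtag <- sprintf("HTO%02d", seq_len(nrow(map)))
  H <- nrow(map)
  cell_id <- sprintf("cell%05d", seq_len(n_cells))
  is_doublet <- stats::runif(n_cells) < doublet_rate
  lab1 <- sample.int(H, n_cells, replace = TRUE)
  lab2 <- ifelse(is_doublet,
                 ((lab1 - 1L + sample.int(H - 1L, n_cells, replace = TRUE)) %% H) + 1L,
                 NA_integer_)
  hto <- matrix(stats::rpois(n_cells * H, background_mean), nrow = n_cells,
                dimnames = list(cell_id, map$hashtag))
  hto[cbind(seq_len(n_cells), lab1)] <- stats::rpois(n_cells, dominant_mean)
  dbl <- which(is_doublet)
  if (length(dbl)) {
    hto[cbind(dbl, lab2[dbl])] <- stats::rpois(length(dbl), dominant_mean * 0.8)
  }
  qc <- data.frame(
    cell_id = cell_id,
    mito_pct = pmin(stats::rgamma(n_cells, shape = 4, scale = 1.25), 100),
    n_features = pmax(stats::rnbinom(n_cells, mu = 3000, size = 8), 0L),
    stringsAsFactors = FALSE
  )
  list(qc = qc, hto = hto,
       hashtag_map = map[, c("hashtag", "subject", "timepoint")],
       truth = data.frame(cell_id = cell_id,
                          true_hashtag = map$hashtag[lab1],
                          is_doublet = is_doublet,
                          stringsAsFactors = FALSE))
}
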