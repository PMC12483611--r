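#' Cell-level QC parameters
#'
#' Thresholds follow the conventional single-cell exclusion rule set:
#' cells are dropped when mitochondrial percentage exceeds 10, or the
#' number of unique features falls below 200 or above 6500. Exclusions use
#' strict inequalities, so a cell sitting exactly on a threshold is kept.
#'
#' @param mito_max maximum mitochondrial percentage retained (default 10).
#' @param feat_min,feat_max retained unique-feature range (defaults 200, 6500).
#' @param hto_margin minimum CLR margin between top two hashtag signals
#'   (default 2.0).
#' @return A `cell_qc_params` list.
#' @export
cell_qc_params <- function(mito_max = 10, feat_min = 200L, feat_max = 6500L,
                           hto_margin = 2.0) {
  stopifnot(feat_min < feat_max, mito_max > 0, mito_max <= 100)
  structure(list(mito_max = mito_max, feat_min = as.integer(feat_min),
                 feat_max = as.integer(feat_max), hto_margin = hto_margin),
            class = "cell_qc_params")
}

#' Filter cells on mitochondrial content and feature counts
#'
#' A cell is retained iff `mito_pct <= mito_max` and
#' `feat_min <= n_features <= feat_max` (exclusion by strict inequality,
#' so boundary values are retained). The exclusion tally attributes each
#' dropped cell to every rule it violates, so rule counts can exceed the
#' number of dropped cells.
#'
#' @param qc_table data.frame with `cell_id`, `mito_pct`, `n_features`.
#' @param params a [cell_qc_params()].
#' @return list: `retained` (character cell ids), `table` (qc_table with a
#'   logical `retained` column), `tally` (rule, n_excluded).
#' @export
filter_cells <- function(qc_table, params = cell_qc_params()) {
  need <- c("cell_id", "mito_pct", "n_features")
  if (!all(need %in% names(qc_table))) {
    stop("filter_cells: qc_table must have columns ",
         paste(setdiff(need, names(qc_table)), collapse = ", "), call. = FALSE)
  }
  bad_mito <- qc_table$mito_pct > params$mito_max
  bad_low  <- qc_table$n_features < params$feat_min
  bad_high <- qc_table$n_features > params$feat_max
  keep <- !(bad_mito | bad_low | bad_high)
  out <- qc_table
  out$retained <- keep
  list(
    retained = qc_table$cell_id[keep],
    table = out,
    tally = data.frame(
      rule = c("mito_pct_gt_max", "n_features_lt_min", "n_features_gt_max"),
      n_excluded = c(sum(bad_mito), sum(bad_low), sum(bad_high))
    )
  )
}

#' CLR-normalize a hashtag count matrix across hashtags within each cell
#'
#' y_h = ln(x_h + 1) - mean_h ln(x_h + 1). The +1 pseudo-count and natural
#' log are conventions; both are configurable.
#'
#' @param hto cells x hashtags nonnegative count matrix.
#' @param pseudo_count added before the log (default 1).
#' @return matrix of the same shape.
#' @export
clr_normalize <- function(hto, pseudo_count = 1) {
  stopifnot(is.matrix(hto), all(hto >= 0))
  lx <- log(hto + pseudo_count)
  sweep(lx, 1L, rowMeans(lx), "-")
}

#' Demultiplex cells by max-margin hashtag assignment
#'
#' After CLR normalization across hashtags, each cell is assigned to its
#' argmax hashtag iff the margin between the max and secondary-max CLR
#' signals is at least `margin`; otherwise it is excluded. Exact ties for
#' the max give margin 0 and are excluded; all-zero rows are excluded with
#' reason "no signal".
#'
#' @param hto cells x hashtags count matrix (>= 2 hashtags).
#' @param margin minimum CLR margin (default 2.0).
#' @param pseudo_count CLR pseudo-count (default 1).
#' @return data.frame: `cell_id`, `assignment` (hashtag label or NA),
#'   `margin`, `status` ("singlet", "margin_fail", "no_signal").
#' @export
demux_hashtags <- function(hto, margin = 2.0, pseudo_count = 1) {
  stopifnot(is.matrix(hto), ncol(hto) >= 2L)
  labels <- colnames(hto)
  if (is.null(labels)) labels <- paste0("HTO", seq_len(ncol(hto)))
  cell_id <- rownames(hto)
  if (is.null(cell_id)) cell_id <- sprintf("cell%05d", seq_len(nrow(hto)))
  y <- clr_normalize(hto, pseudo_count)
  ord <- t(apply(y, 1L, function(r) sort(r, decreasing = TRUE)[1:2]))
  marg <- ord[, 1] - ord[, 2]
  best <- max.col(y, ties.method = "first")
  no_signal <- rowSums(hto) == 0
  ok <- marg >= margin & !no_signal
  data.frame(
    cell_id = cell_id,
    assignment = ifelse(ok, labels[best], NA_character_),
    margin = marg,
    status = ifelse(no_signal, "no_signal",
                    ifelse(ok, "singlet", "margin_fail")),
    stringsAsFactors = FALSE
  )
}
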