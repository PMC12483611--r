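#' Ordinary least squares with optional interaction and cluster-robust SEs
#'
#' Thin, contract-checked wrapper around `lm`: dummy-codes categorical
#' predictors at their reference level, optionally adds one interaction
#' pair, errors on rank deficiency naming the collinear columns, and can
#' replace the classical covariance with CR1 cluster-robust standard
#' errors (the pooled-OLS stand-in for longitudinal models whose
#' covariance structure is unspecified).
#'
#' @param data data.frame.
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @param interaction optional length-2 character vector: a pair of
#'   predictors whose interaction is added.
#' @param cluster optional column name for cluster-robust (CR1) SEs.
#' @return list of class `ols_fit`: `coefficients` (data.frame: term,
#'   estimate, std_error, t_value, p_value), `r_squared`, `n`, `model`.
#' @export
ols_fit <- function(data, response, predictors, interaction = NULL,
                    cluster = NULL) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  rhs <- paste(predictors, collapse = " + ")
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2L, all(interaction %in% names(data)))
    rhs <- paste(rhs, paste(interaction, collapse = ":"), sep = " + ")
  }
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = data)
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    stop("ols_fit: rank-deficient design; collinear terms: ",
         paste(names(stats::coef(fit))[alias], collapse = ", "), call. = FALSE)
  }
  n <- length(stats::residuals(fit))
  k <- length(stats::coef(fit))
  if (n <= k) stop("ols_fit: need n > number of parameters", call. = FALSE)
  if (is.null(cluster)) {
    sm <- summary(fit)
    ct <- as.data.frame(sm$coefficients)
    names(ct) <- c("estimate", "std_error", "t_value", "p_value")
  } else {
    stopifnot(cluster %in% names(data))
    X <- stats::model.matrix(fit)
    u <- stats::residuals(fit)
    if (nrow(X) != nrow(data)) {
      stop("ols_fit: missing values not allowed with cluster-robust SEs",
           call. = FALSE)
    }
    cl <- data[[cluster]]
    XtXinv <- chol2inv(chol(crossprod(X)))
    meat <- matrix(0, ncol(X), ncol(X))
    for (g in unique(cl)) {
      xg <- X[cl == g, , drop = FALSE]
      ug <- u[cl == g]
      sg <- crossprod(xg, ug)
      meat <- meat + tcrossprod(sg)
    }
    G <- length(unique(cl))
    adj <- G / (G - 1) * (n - 1) / (n - k)
    V <- adj * XtXinv %*% meat %*% XtXinv
    se <- sqrt(diag(V))
    est <- stats::coef(fit)
    tv <- est / se
    ct <- data.frame(estimate = est, std_error = se, t_value = tv,
                     p_value = 2 * stats::pt(-abs(tv), df = G - 1))
  }
  ct <- cbind(term = rownames(ct), ct)
  rownames(ct) <- NULL
  structure(list(coefficients = ct,
                 r_squared = summary(fit)$r.squared,
                 n = n, model = fit),
            class = "ols_fit")
}

# Dunn's pairwise z statistics after a Kruskal-Wallis test, with tie
# correction; standard rank-sum formulation
dunn_pairwise <- function(values, groups, p_adjust = "bonferroni") {
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  levs <- unique(groups)
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  res <- do.call(rbind, lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (mean_r[[i]] - mean_r[[j]]) / se
    data.frame(group_1 = i, group_2 = j, z = z,
               p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p_value, method = p_adjust)
  rownames(res) <- NULL
  res
}

#' Nonparametric group comparison
#'
#' Unpaired: Kruskal-Wallis one-way ANOVA across >= 2 groups followed by
#' Dunn's pairwise post-hoc z tests (Bonferroni adjustment by default).
#' Paired: two-sided Wilcoxon matched-pairs signed-rank test. All-tied
#' input returns p = 1 with a warning.
#'
#' @param values numeric vector (unpaired) or the first member of each
#'   pair (paired).
#' @param groups group label per value (unpaired) or the second member of
#'   each pair (paired).
#' @param paired logical.
#' @param p_adjust adjustment method for Dunn's pairwise p-values.
#' @return list of class `group_compare`: for unpaired, `method`,
#'   `statistic`, `p_value`, `pairwise`; for paired, `method`,
#'   `statistic`, `p_value`.
#' @export
group_compare <- function(values, groups, paired = FALSE,
                          p_adjust = "bonferroni") {
  if (paired) {
    x <- values; y <- groups
    stopifnot(is.numeric(y), length(x) == length(y))
    if (all(x == y)) {
      warning("group_compare: all pairs tied; p = 1 by convention")
      return(structure(list(method = "wilcoxon_signed_rank", statistic = NA_real_,
                            p_value = 1), class = "group_compare"))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    return(structure(list(method = "wilcoxon_signed_rank",
                          statistic = unname(wt$statistic),
                          p_value = wt$p.value), class = "group_compare"))
  }
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (length(unique(groups)) < 2L) {
    stop("group_compare: need at least 2 groups", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    warning("group_compare: all values tied; p = 1 by convention")
    return(structure(list(method = "kruskal_wallis", statistic = NA_real_,
                          p_value = 1, pairwise = NULL),
                     class = "group_compare"))
  }
  kw <- stats::kruskal.test(values, factor(groups))
  structure(list(method = "kruskal_wallis",
                 statistic = unname(kw$statistic),
                 p_value = kw$p.value,
                 pairwise = dunn_pairwise(values, groups, p_adjust)),
            class = "group_compare")
}

#' Subject-level summary joining repertoire and serology outputs
#'
#' One row per subject x dose/timepoint with mean heavy-chain SHM
#' frequency and TRAI, the inputs to the SHM-avidity association model.
#' Where SHM is measured at fewer timepoints than serology doses, the
#' subject mean SHM is used for unmatched doses.
#'
#' @param shm data.frame from [shm_profiles()] (heavy chains are selected
#'   if a `chain` column is present).
#' @param avidity data.frame from [score_avidity_table()].
#' @return data.frame: subject, group, dose, mean_shm, trai.
#' @export
subject_summary <- function(shm, avidity) {
  if ("chain" %in% names(shm)) shm <- shm[shm$chain == "heavy", , drop = FALSE]
  agg <- stats::aggregate(mu_freq ~ subject, data = shm, FUN = mean)
  names(agg)[2] <- "mean_shm"
  out <- merge(avidity[, c("subject", "group", "dose", "trai")], agg,
               by = "subject", all.x = TRUE)
  out[order(out$subject, out$dose), c("subject", "group", "dose", "mean_shm", "trai")]
}
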