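#' Fit a four-parameter logistic to a dilution series and estimate EC50
#'
#' Model: OD(d) = blank + (top - blank) / (1 + (ec50 / d)^hill) with d the
#' plasma concentration (1/dilution factor). The lower asymptote is
#' anchored at the blank mean; top, log(ec50) and hill are estimated by
#' nonlinear least squares (`nls`, port algorithm with bounds), with a
#' Nelder-Mead fallback on the same residual sum of squares. The EC50 is
#' by construction the concentration giving a response halfway between the
#' blank and the fitted top, and is invariant to rescaling all readouts.
#'
#' @param series data.frame with `dilution` (concentration scale, > 0) and
#'   `od`; needs >= 4 points.
#' @param blank_od blank (lower-asymptote) readout mean; defaults to the
#'   `blank_od` attribute of `series` if present, else the minimum OD.
#' @return list of class `ec50_fit`: `ec50`, `top`, `hill`, `blank`,
#'   `status` ("ok", "no_signal", "not_converged"), `rss`, `fitted`.
#' @export
fit_ec50 <- function(series, blank_od = NULL) {
  stopifnot(all(c("dilution", "od") %in% names(series)))
  d <- series$dilution; y <- series$od
  if (length(d) < 4L) stop("fit_ec50: need at least 4 dilution points", call. = FALSE)
  if (any(d <= 0)) stop("fit_ec50: dilutions must be positive", call. = FALSE)
  if (is.null(blank_od)) {
    blank_od <- attr(series, "blank_od")
    if (is.null(blank_od)) blank_od <- min(y)
  }
  span <- max(y) - blank_od
  if (span <= 0 || span < 0.05 * max(abs(y), 1e-12)) {
    return(structure(list(ec50 = NA_real_, top = NA_real_, hill = NA_real_,
                          blank = blank_od, status = "no_signal",
                          rss = NA_real_, fitted = rep(NA_real_, length(d))),
                     class = "ec50_fit"))
  }
  half <- blank_od + span / 2
  start <- list(top = max(y),
                lec50 = log(d[which.min(abs(y - half))]),
                hill = 1)
  rss_fun <- function(par) {
    mu <- blank_od + (par[1] - blank_od) / (1 + (exp(par[2]) / d)^par[3])
    sum((y - mu)^2)
  }
  fit <- tryCatch(
    stats::nls(y ~ blank_od + (top - blank_od) / (1 + (exp(lec50) / d)^hill),
               start = start, algorithm = "port",
               lower = c(top = blank_od, lec50 = log(min(d)) - 10, hill = 1e-3),
               upper = c(top = 10 * max(y) + 1, lec50 = log(max(d)) + 10, hill = 50),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    status <- "ok"
  } else {
    op <- stats::optim(unlist(start), rss_fun, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    cf <- op$par
    names(cf) <- c("top", "lec50", "hill")
    status <- if (op$convergence == 0) "ok" else "not_converged"
  }
  mu <- blank_od + (cf[["top"]] - blank_od) / (1 + (exp(cf[["lec50"]]) / d)^cf[["hill"]])
  structure(list(ec50 = exp(cf[["lec50"]]), top = cf[["top"]],
                 hill = cf[["hill"]], blank = blank_od, status = status,
                 rss = sum((y - mu)^2), fitted = mu),
            class = "ec50_fit")
}

#' Score a chaotrope-displacement series into avidity indices
#'
#' With replicate-mean ODs m(0) > 0 at the reference well and m(c) at each
#' nonzero chaotrope concentration (typically 0.5, 1, 2 M ammonium
#' thiocyanate), after a running-minimum monotonicity repair:
#' \itemize{
#'   \item RAI(c) = 100 * m(c) / m(0), the percentage of signal resisting
#'     elution at c;
#'   \item fractional RAI: very low = 100 * (m(0)-m(0.5))/m(0),
#'     low = 100 * (m(0.5)-m(1))/m(0), medium = 100 * (m(1)-m(2))/m(0),
#'     high = 100 * m(2)/m(0) — the share of antibody eluted between
#'     successive washes; categories sum to 100;
#'   \item TRAI = RAI(0.5) + RAI(1) + RAI(2) in avidity units (AU), equal
#'     to 3*high + 2*medium + 1*low (+ 0*very low) / 1 by algebra.
#' }
#' Negative readouts are clipped to 0 with a warning.
#'
#' @param series data.frame with `chaotrope_M` and `od` (replicate rows),
#'   or a named numeric of replicate-mean ODs with concentrations as names.
#' @param category_names labels for the elution categories, weakest first.
#' @return list of class `avidity_result`: `rai` (named, %), `fractional`
#'   (named, %), `trai` (AU), `m` (repaired means), `conc`.
#' @export
score_avidity <- function(series,
                          category_names = c("very_low", "low", "medium", "high")) {
  if (is.data.frame(series)) {
    stopifnot(all(c("chaotrope_M", "od") %in% names(series)))
    od <- series$od
    if (any(od < 0)) {
      warning("score_avidity: negative ODs clipped to 0")
      od <- pmax(od, 0)
    }
    m <- tapply(od, series$chaotrope_M, mean)
    conc <- as.numeric(names(m))
  } else {
    m <- series
    conc <- as.numeric(names(m))
    if (any(m < 0)) {
      warning("score_avidity: negative ODs clipped to 0")
      m <- pmax(m, 0)
    }
  }
  o <- order(conc)
  conc <- conc[o]; m <- as.numeric(m)[o]
  if (conc[1] != 0) stop("score_avidity: reference (0 M) well required", call. = FALSE)
  if (m[1] <= 0) stop("score_avidity: reference mean OD must be positive", call. = FALSE)
  if (length(conc) != length(category_names)) {
    stop("score_avidity: need one concentration per category (",
         length(category_names), ")", call. = FALSE)
  }
  m <- cummin(m)  # monotonicity repair
  rai <- 100 * m[-1] / m[1]
  names(rai) <- paste0("RAI_", conc[-1])
  frac <- 100 * c(-diff(m), m[length(m)]) / m[1]
  names(frac) <- category_names
  structure(list(rai = rai, fractional = frac, trai = sum(rai),
                 m = stats::setNames(m, conc), conc = conc),
            class = "avidity_result")
}

#' Score all chaotrope series in a tidy plate table
#'
#' @param plates data.frame as produced by [gen_serology_cohort()]'s
#'   `chaotrope` element (columns sample_id, subject, group, dose,
#'   chaotrope_M, od).
#' @return data.frame with one row per sample: annotations, TRAI, RAI and
#'   fractional-RAI columns.
#' @export
score_avidity_table <- function(plates) {
  out <- lapply(split(plates, plates$sample_id), function(d) {
    av <- score_avidity(d)
    cbind(d[1, intersect(c("sample_id", "subject", "group", "dose"), names(d)),
            drop = FALSE],
          as.data.frame(as.list(c(trai = av$trai, av$rai, av$fractional))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit EC50 for every sample in a tidy dilution table
#'
#' @param dilutions data.frame with `sample_id`, `dilution`, `od` and
#'   optionally a `series` column; when present, only rows with
#'   `series == use_series` are fitted.
#' @param use_series which series to fit (default "ec50").
#' @param blank_od lower-asymptote anchor passed to [fit_ec50()].
#' @return data.frame: sample annotations, ec50, top, hill, status.
#' @export
fit_ec50_table <- function(dilutions, use_series = "ec50", blank_od = NULL) {
  d <- dilutions
  if ("series" %in% names(d)) d <- d[d$series == use_series, , drop = FALSE]
  out <- lapply(split(d, d$sample_id), function(s) {
    f <- fit_ec50(s[, c("dilution", "od")], blank_od = blank_od)
    cbind(s[1, intersect(c("sample_id", "subject", "group", "dose"), names(s)),
            drop = FALSE],
          data.frame(ec50 = f$ec50, top = f$top, hill = f$hill,
                     status = f$status, rss = f$rss))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
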