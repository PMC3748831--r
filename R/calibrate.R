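#' Standard curves
#'
#' A fitted spike-in calibration mapping measured FPKM (x) to known molecules
#' per embryo (y), on either the `log10` or `linear` scale, by ordinary least
#' squares or Huber robust regression.
#'
#' @param slope,intercept fitted coefficients (y on x).
#' @param scale `"log10"` or `"linear"` — the scale both coordinates were
#'   transformed to before fitting.
#' @param method `"ols"` or `"robust"`.
#' @param r_squared coefficient of determination of the fit.
#' @param n_points number of points used in the fit (>= 3).
#' @param sample_id sample the curve belongs to.
#' @param converged,iterations IRLS convergence state (robust fits).
#' @return a `standard_curve` object.
#' @export
standard_curve <- function(slope, intercept, scale = c("log10", "linear"),
                           method = c("ols", "robust"), r_squared = NA_real_,
                           n_points = NA_integer_, sample_id = NA_character_,
                           converged = TRUE, iterations = 0L) {
  structure(list(slope = slope, intercept = intercept,
                 scale = match.arg(scale), method = match.arg(method),
                 r_squared = r_squared, n_points = as.integer(n_points),
                 sample_id = sample_id, converged = converged,
                 iterations = as.integer(iterations)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve [%s, %s]: slope %.4f, intercept %.4f, R^2 %.4f, n = %d%s\n",
    x$method, x$scale, x$slope, x$intercept, x$r_squared, x$n_points,
    if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

check_xy <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (length(x) < 3L)
    stop(sprintf("need at least 3 points to fit a curve (got %d)", length(x)))
  if (max(x) - min(x) <= 0)
    stop("degenerate x: all values equal")
}

ols_coef <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  xm <- sum(w * x) / sw
  ym <- sum(w * y) / sw
  slope <- sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
  c(intercept = ym - slope * xm, slope = slope)
}

r_squared_of <- function(x, y, beta) {
  res <- y - beta[1] - beta[2] * x
  sstot <- sum((y - mean(y))^2)
  if (sstot <= 0) return(1)
  max(0, min(1, 1 - sum(res^2) / sstot))
}

#' Fit a standard curve by ordinary least squares
#'
#' Least-squares regression of y on x with
#' `r_squared = 1 - SS_res / SS_tot`. Requires at least 3 finite points and
#' non-degenerate x.
#'
#' @param x,y numeric coordinates (already transformed to the fitting scale).
#' @inheritParams standard_curve
#' @return a `standard_curve` with `method = "ols"`.
#' @export
fit_ols <- function(x, y, scale = "log10", sample_id = NA_character_) {
  check_xy(x, y)
  beta <- ols_coef(x, y)
  standard_curve(beta[["slope"]], beta[["intercept"]], scale = scale,
                 method = "ols", r_squared = r_squared_of(x, y, beta),
                 n_points = length(x), sample_id = sample_id)
}

#' Fit a standard curve by Huber robust regression
#'
#' Iteratively reweighted least squares with Huber weights
#' `w = min(1, c * s / |r|)`, the scale `s` re-estimated each iteration as
#' the median absolute deviation of the residuals divided by 0.6745.
#' Iteration starts from the OLS fit and stops when the largest coefficient
#' change falls below `tol` or after `max_iter` iterations (the curve is then
#' flagged non-converged; `max_iter = 0` returns the OLS start itself,
#' flagged non-converged).
#'
#' @inheritParams fit_ols
#' @param tuning_c Huber tuning constant (default 1.345, 95% efficiency at
#'   the Gaussian).
#' @param tol convergence tolerance on coefficients (default 1e-8).
#' @param max_iter iteration cap (default 50).
#' @return a `standard_curve` with `method = "robust"`.
#' @export
fit_robust <- function(x, y, tuning_c = 1.345, tol = 1e-8, max_iter = 50L,
                       scale = "log10", sample_id = NA_character_) {
  check_xy(x, y)
  beta <- ols_coef(x, y)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - beta[1] - beta[2] * x
    s <- median(abs(r - median(r))) / 0.6745
    if (s <= .Machine$double.eps^0.5 * max(1, max(abs(y)))) {
      converged <- TRUE  # (near-)perfect fit: all weights 1
      break
    }
    u <- abs(r) / s
    w <- ifelse(u <= tuning_c, 1, tuning_c / u)
    new_beta <- ols_coef(x, y, w)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  standard_curve(beta[["slope"]], beta[["intercept"]], scale = scale,
                 method = "robust", r_squared = r_squared_of(x, y, beta),
                 n_points = length(x), sample_id = sample_id,
                 converged = converged, iterations = iter)
}

#' Calibrate a sample against the spike-in design
#'
#' Builds the dose-response standard curve for one sample by regressing the
#' known spike-in molecules per embryo (y) on the measured spike-in FPKM (x).
#' On the `log10` scale (the default, since spike-in designs span orders of
#' magnitude) spike-ins with zero FPKM are excluded before the transform;
#' `n_points` records the points actually used. Fewer than 3 usable
#' spike-ins is an error.
#'
#' @param fpkm spike-in FPKM values for the sample: a named numeric vector,
#'   or a `SummarizedExperiment` from [build_expression_matrix()] (the
#'   spike-in rows for `sample_id` are extracted; design spike-ins absent
#'   from the matrix count as undetected).
#' @param design spike-in design data frame (`spike_id`, `known_mpe`), e.g.
#'   from [read_spikein_design()].
#' @param sample_id sample to calibrate (required when `fpkm` is a matrix).
#' @param method `"robust"` (default) or `"ols"`.
#' @param scale `"log10"` (default) or `"linear"`.
#' @param ... passed on to [fit_robust()].
#' @return a `standard_curve`.
#' @export
calibrate <- function(fpkm, design, sample_id = NA_character_,
                      method = c("robust", "ols"),
                      scale = c("log10", "linear"), ...) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  if (is(fpkm, "SummarizedExperiment")) {
    if (is.na(sample_id)) stop("sample_id is required with a matrix input")
    fm <- SummarizedExperiment::assay(fpkm, "fpkm")
    if (!sample_id %in% colnames(fm))
      stop(sprintf("sample '%s' not in expression matrix", sample_id))
    v <- rep(0, nrow(design))
    hit <- match(design$spike_id, rownames(fm))
    v[!is.na(hit)] <- fm[hit[!is.na(hit)], sample_id]
    fpkm <- stats::setNames(v, design$spike_id)
  }
  fpkm <- fpkm[match(design$spike_id, names(fpkm))]
  fpkm[is.na(fpkm)] <- 0
  keep <- if (scale == "log10") fpkm > 0 else !is.na(fpkm)
  if (sum(keep) < 3L)
    stop(sprintf("too few detected spike-ins to calibrate: %d of %d",
                 sum(keep), nrow(design)))
  tr <- if (scale == "log10") log10 else identity
  x <- tr(unname(fpkm[keep]))
  y <- tr(design$known_mpe[keep])
  if (method == "ols") fit_ols(x, y, scale = scale, sample_id = sample_id)
  else fit_robust(x, y, scale = scale, sample_id = sample_id, ...)
}

#' @rdname calibrate
#' @param mat a `SummarizedExperiment` with an `fpkm` assay.
#' @return `calibrate_all()`: a named list of `standard_curve`s, one per
#'   sample column.
#' @export
calibrate_all <- function(mat, design, method = "robust", scale = "log10",
                          ...) {
  samples <- colnames(SummarizedExperiment::assay(mat, "fpkm"))
  stats::setNames(lapply(samples, function(s)
    calibrate(mat, design, sample_id = s, method = method, scale = scale,
              ...)), samples)
}

#' @rdname calibrate
#' @param curves a list of `standard_curve`s.
#' @return `curve_table()`: a data frame summarising fitted curves (sample,
#'   method, scale, slope, intercept, r_squared, n_points, converged).
#' @export
curve_table <- function(curves) {
  if (inherits(curves, "standard_curve")) curves <- list(curves)
  do.call(rbind, lapply(curves, function(cv)
    data.frame(sample_id = cv$sample_id, method = cv$method, scale = cv$scale,
               slope = cv$slope, intercept = cv$intercept,
               r_squared = cv$r_squared, n_points = cv$n_points,
               converged = cv$converged)))
}

#' Predict molecules per embryo from FPKM
#'
#' Inverse use of the standard curve: zero FPKM maps to zero MPE; otherwise
#' on the `log10` scale `mpe = 10^(intercept + slope * log10(fpkm))` and on
#' the linear scale `mpe = max(0, intercept + slope * fpkm)`. Monotone
#' non-decreasing in FPKM whenever the slope is positive.
#'
#' @param curve a `standard_curve`.
#' @param fpkm non-negative FPKM value(s).
#' @return predicted molecules per embryo (vectorised).
#' @examples
#' cv <- standard_curve(1, 0, "log10", "ols")
#' predict_mpe(cv, c(0, 100))
#' @export
predict_mpe <- function(curve, fpkm) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(fpkm < 0)) stop("fpkm must be non-negative")
  if (curve$scale == "log10") {
    out <- ifelse(fpkm == 0, 0,
                  10^(curve$intercept + curve$slope * log10(pmax(fpkm, 1e-300))))
  } else {
    out <- ifelse(fpkm == 0, 0, pmax(0, curve$intercept + curve$slope * fpkm))
  }
  unname(out)
}
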