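#' Linear safety factors
#'
#' Fits a constant multiplier applied to the estimated peak SAR so that
#' corrected values bound the true values seen in a validation set.
#' `method = "worst_case"` takes the maximum of the ratios
#' `psar_t / psar_e` — the smallest factor with zero underestimation on
#' the fit set. `method = "outer_fence"` first discards ratio outliers
#' above the Tukey upper outer fence (third quartile + 3 x IQR, quartiles
#' by linear interpolation of order statistics) and takes the maximum of
#' the remainder; this makes the factor insensitive to the one extreme
#' point that would otherwise set its slope, at the price of a small
#' residual underestimation probability.
#'
#' @param samples a [paired_samples()] frame (or any data frame with
#'   positive `psar_e`, `psar_t` columns), at least 10 rows.
#' @param method `"outer_fence"` (default) or `"worst_case"`.
#' @return An object of classes `sar_lsf`, `sar_margin` with elements
#'   `value` (the factor), `method`, `n`, `outliers_removed` and `fence`
#'   (the ratio threshold, `Inf` for worst-case).
#' @examples
#' p <- generate_joint_pairs(joint_spec(n_samples = 2000, seed = 1))
#' lsf(p, "worst_case")$value >= lsf(p, "outer_fence")$value
#' @export
lsf <- function(samples, method = c("outer_fence", "worst_case")) {
  method <- match.arg(method)
  check_pairs(samples, min_n = 10L)
  r <- samples$psar_t / samples$psar_e
  if (method == "worst_case") {
    value <- max(r)
    fence <- Inf
    removed <- 0L
  } else {
    q <- stats::quantile(r, c(0.25, 0.75), names = FALSE, type = 7)
    fence <- q[2L] + 3 * (q[2L] - q[1L])
    keep <- r <= fence
    removed <- sum(!keep)
    value <- max(r[keep])
  }
  structure(list(value = value, method = method, n = length(r),
                 outliers_removed = removed, fence = fence),
            class = c("sar_lsf", "sar_margin"))
}

#' Empirical upper bound on true peak SAR
#'
#' The `level`-quantile (default 99.9\%) of the true peak SAR values in a
#' validation set, by linear interpolation of order statistics: the peak
#' SAR not exceeded in a fraction `level` of cases, regardless of the
#' estimate. Used on its own as a constant margin or as the cap of a
#' [capped_lsf()].
#'
#' @param true_values positive numeric vector of true peak SAR values, or
#'   a [paired_samples()] frame (its `psar_t` column is used).
#' @param level probability (default 0.999). Fewer than 1000 values for
#'   level >= 0.999 triggers a warning: the extreme quantile is then
#'   poorly determined.
#' @param mode_tag optional driving-mode label carried in the object.
#' @return Classes `sar_upper_bound`, `sar_margin`; element `value` is the
#'   bound in W/kg.
#' @export
upper_bound <- function(true_values, level = 0.999, mode_tag = NA_character_) {
  if (inherits(true_values, "paired_samples") || is.data.frame(true_values)) {
    mode_tag <- true_values$mode_tag[1L] %||% mode_tag
    true_values <- true_values$psar_t
  }
  if (length(true_values) == 0L) stop("no values supplied", call. = FALSE)
  if (any(true_values <= 0)) stop("true peak SAR values must be positive", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  if (level >= 0.999 && length(true_values) < 1000L)
    warning("fewer than 1000 values: the ", level,
            " quantile is poorly determined", call. = FALSE)
  structure(list(value = stats::quantile(true_values, level, names = FALSE,
                                         type = 7),
                 level = level, n = length(true_values), mode_tag = mode_tag),
            class = c("sar_upper_bound", "sar_margin"))
}

#' Linear safety factor capped by an upper bound
#'
#' Combines a [lsf()] with an [upper_bound()]: the corrected value is the
#' pointwise minimum `min(LSF * psar_e, UB)`. Below `UB / LSF` the linear
#' correction applies unchanged; above it the bound replaces the (by then
#' unrealistically high) linear correction.
#'
#' @param lsf_fit a fitted [lsf()] (or a plain numeric factor).
#' @param ub_fit a fitted [upper_bound()] (or a plain numeric bound, W/kg).
#' @return Classes `sar_capped_lsf`, `sar_margin`.
#' @export
capped_lsf <- function(lsf_fit, ub_fit) {
  if (is.numeric(lsf_fit))
    lsf_fit <- structure(list(value = lsf_fit, method = "given", n = NA_integer_,
                              outliers_removed = NA_integer_, fence = NA_real_),
                         class = c("sar_lsf", "sar_margin"))
  if (is.numeric(ub_fit))
    ub_fit <- structure(list(value = ub_fit, level = NA_real_, n = NA_integer_,
                             mode_tag = NA_character_),
                        class = c("sar_upper_bound", "sar_margin"))
  stopifnot(inherits(lsf_fit, "sar_lsf"), inherits(ub_fit, "sar_upper_bound"))
  structure(list(lsf = lsf_fit, ub = ub_fit),
            class = c("sar_capped_lsf", "sar_margin"))
}

#' Apply a fitted safety margin
#'
#' Maps estimated peak SAR values to corrected values under a fitted
#' margin: `value * psar_e` for a linear safety factor, the constant bound
#' for an upper bound, `min(value * psar_e, bound)` for a capped factor,
#' and interpolation of the fitted curve for a conditional safety margin
#' (see [csm()] for the out-of-support extrapolation rules).
#'
#' @param object a fitted `sar_margin`.
#' @param psar_e positive numeric vector of estimated peak SAR, W/kg.
#' @param ... unused.
#' @return Corrected peak SAR, W/kg.
#' @name predict.sar_margin
NULL

check_psar_e <- function(psar_e) {
  if (any(!is.finite(psar_e)) || any(psar_e <= 0))
    stop("`psar_e` must be finite and positive", call. = FALSE)
  as.numeric(psar_e)
}

#' @rdname predict.sar_margin
#' @export
predict.sar_lsf <- function(object, psar_e, ...) {
  object$value * check_psar_e(psar_e)
}

#' @rdname predict.sar_margin
#' @export
predict.sar_upper_bound <- function(object, psar_e, ...) {
  rep_len(object$value, length(check_psar_e(psar_e)))
}

#' @rdname predict.sar_margin
#' @export
predict.sar_capped_lsf <- function(object, psar_e, ...) {
  pmin(object$lsf$value * check_psar_e(psar_e), object$ub$value)
}

#' @export
coef.sar_lsf <- function(object, ...) c(lsf = object$value)

#' @export
coef.sar_upper_bound <- function(object, ...) c(upper_bound = object$value)

#' @export
coef.sar_capped_lsf <- function(object, ...)
  c(lsf = object$lsf$value, upper_bound = object$ub$value)

#' @export
print.sar_lsf <- function(x, ...) {
  cat(sprintf("Linear safety factor (%s): %.4g  [n = %d, outliers removed = %d]\n",
              x$method, x$value, x$n, x$outliers_removed))
  invisible(x)
}

#' @export
print.sar_upper_bound <- function(x, ...) {
  cat(sprintf("%.4g%% certain peak SAR upper bound: %.4g W/kg  [n = %d]\n",
              100 * x$level, x$value, x$n))
  invisible(x)
}

#' @export
print.sar_capped_lsf <- function(x, ...) {
  cat(sprintf("Capped linear safety factor: min(%.4g x psar_e, %.4g W/kg)\n",
              x$lsf$value, x$ub$value))
  invisible(x)
}

#' Underestimation rate of a margin on a sample set
#'
#' Fraction of rows whose true peak SAR exceeds the corrected value — the
#' empirical probability that the margin fails to cover the truth. For an
#' honest estimate, evaluate on samples disjoint from the fit set (see
#' [make_splits()]).
#'
#' @param margin a fitted `sar_margin`.
#' @param samples a [paired_samples()] frame.
#' @return A probability in \[0, 1\].
#' @export
underestimation_rate <- function(margin, samples) {
  check_pairs(samples, min_n = 1L)
  mean(samples$psar_t > predict(margin, samples$psar_e))
}

check_pairs <- function(samples, min_n = 1L) {
  if (!is.data.frame(samples) ||
      !all(c("psar_e", "psar_t") %in% names(samples)))
    stop("`samples` must have `psar_e` and `psar_t` columns", call. = FALSE)
  if (nrow(samples) < min_n)
    stop(sprintf("at least %d samples required", min_n), call. = FALSE)
  if (any(samples$psar_e <= 0) || any(samples$psar_t <= 0))
    stop("pSAR values must be positive", call. = FALSE)
  invisible(samples)
}
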