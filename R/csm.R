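#' Conditional safety margin for peak local SAR
#'
#' Fits the estimate-dependent safety margin: for each possible estimated
#' peak 10g-averaged SAR value \eqn{E}, the corrected value
#' \eqn{pSAR^{E,C}} is the \eqn{(1-\epsilon)} tail quantile of the
#' conditional distribution of the true peak SAR \eqn{T} given \eqn{E},
#' \deqn{P(T > pSAR^{E,C} \mid E) = \epsilon,}
#' so the accepted probability of underestimation is \eqn{\epsilon}
#' uniformly in the estimate — unlike a linear safety factor, which
#' under-covers low estimates and grossly over-corrects high ones.
#'
#' The fit proceeds in the steps the procedure defines:
#' \enumerate{
#'   \item the joint density \eqn{f_{E,T}} of the validation pairs is
#'     modelled as a full-covariance Gaussian mixture; the number of
#'     components is chosen by BIC over `k`;
#'   \item the marginal \eqn{f_E} is fitted with a gamma distribution by
#'     maximum likelihood;
#'   \item both are discretised on a lattice with spacing `delta`
#'     (default 0.01 W/kg) up to 1.25 x the largest observed value;
#'   \item each lattice column \eqn{f_{T|E}(\cdot \mid e)} is renormalised
#'     to unit mass and integrated from the top of the T-axis downward;
#'     the corrected value at `e` is the T-node where the accumulated
#'     tail mass first reaches `epsilon`;
#'   \item the curve is restricted to estimates where the fitted gamma
#'     density exceeds `density_floor` times its peak — outside that
#'     range too few validation samples exist for the conditional density
#'     to be trustworthy.
#' }
#' [predict()] interpolates the curve linearly between nodes. Below the
#' supported range the leftmost node's ratio `corrected / e` is applied
#' (a conservative linear rule); above it, the rightmost node's ratio.
#'
#' @param samples a [paired_samples()] frame of validation pairs (at least
#'   1000 rows recommended for `epsilon = 0.001`; a warning is issued
#'   below that).
#' @param epsilon accepted underestimation probability, in (0, 0.5);
#'   default 0.001.
#' @param delta lattice spacing in W/kg (default 0.01).
#' @param k candidate numbers of mixture components (default 1:6).
#' @param seed integer seed controlling the mixture initialisation
#'   subsample.
#' @param density_floor relative gamma-density threshold defining the
#'   curve's domain (default 1e-6).
#' @param grid_expand lattice upper limit as a multiple of the largest
#'   observed value (default 1.25).
#' @return An object of classes `sar_csm`, `sar_margin`: list with
#'   `e_nodes`, `corrected` (the curve), `epsilon`, `delta`, `K` (chosen
#'   components), `bic` (BIC per candidate K), `gamma_shape`,
#'   `gamma_rate`, `gmm` (mixture parameters), `n`, `seed`.
#' @examples
#' \donttest{
#' p <- generate_joint_pairs(joint_spec(rho = 0.9, n_samples = 5750, seed = 1))
#' fit <- csm(p, epsilon = 0.001)
#' predict(fit, c(1, 2, 3))
#' }
#' @export
csm <- function(samples, epsilon = 0.001, delta = 0.01, k = 1:6, seed = 1L,
                density_floor = 1e-6, grid_expand = 1.25) {
  check_pairs(samples, min_n = 2L)
  stopifnot_scalar_number(epsilon, "epsilon", positive = TRUE)
  if (epsilon >= 0.5) stop("`epsilon` must be in (0, 0.5)", call. = FALSE)
  stopifnot_scalar_number(delta, "delta", positive = TRUE)
  if (nrow(samples) < 1000L)
    warning("fewer than 1000 validation pairs: tail quantiles at epsilon = ",
            epsilon, " will be poorly determined", call. = FALSE)
  e <- samples$psar_e
  t <- samples$psar_t

  gmm <- fit_gmm_joint(cbind(e, t), k = k, seed = seed)
  gam <- fit_gamma_marginal(e)

  upper <- max(e, t) * grid_expand
  e_axis <- seq(delta, upper, by = delta)
  t_axis <- seq(delta, upper, by = delta)

  # restrict the E-support before evaluating the lattice: outside it the
  # marginal says estimates essentially never occur
  ge <- stats::dgamma(e_axis, shape = gam$shape, rate = gam$rate)
  keep <- ge >= density_floor * max(ge)
  e_nodes <- e_axis[keep]
  if (length(e_nodes) < 2L)
    stop("degenerate estimate support: gamma marginal collapsed", call. = FALSE)

  joint <- gmm_density_grid(gmm, e_nodes, t_axis)  # length(e_nodes) x length(t_axis)
  corrected <- tail_quantile_columns(joint, t_axis, delta, epsilon)

  structure(list(e_nodes = e_nodes, corrected = corrected, epsilon = epsilon,
                 delta = delta, K = gmm$K, bic = gmm$bic,
                 gamma_shape = gam$shape, gamma_rate = gam$rate,
                 gmm = gmm[c("weights", "means", "covs")],
                 n = length(e), seed = as.integer(seed)),
            class = c("sar_csm", "sar_margin"))
}

# Full-covariance Gaussian mixture with BIC selection over K.
# mclust's model-based agglomerative initialisation is deterministic; for
# large n it runs on a seeded subsample.
fit_gmm_joint <- function(x, k, seed) {
  n <- nrow(x)
  init <- if (n > 5000L)
    list(subset = with_seed(seed, sample.int(n, 2000L))) else NULL
  fit <- with_seed(seed, suppressWarnings(
    mclust::Mclust(x, G = k, modelNames = "VVV", initialization = init,
                   verbose = FALSE)))
  if (is.null(fit))
    stop("Gaussian mixture fit failed for every candidate K", call. = FALSE)
  p <- fit$parameters
  covs <- lapply(seq_len(fit$G), function(j) unname(p$variance$sigma[, , j]))
  bic_tab <- fit$BIC[, "VVV"]
  list(K = fit$G, weights = unname(p$pro), means = unname(t(p$mean)),
       covs = covs,
       bic = -bic_tab,  # mclust maximises 2*loglik - penalty; report the usual sign
       loglik = fit$loglik)
}

fit_gamma_marginal <- function(e) {
  m <- mean(e)
  v <- stats::var(e)
  start <- list(shape = max(m^2 / v, 1e-3), rate = max(m / v, 1e-6))
  fit <- suppressWarnings(
    MASS::fitdistr(e, "gamma", start = start, lower = c(1e-8, 1e-8)))
  list(shape = unname(fit$estimate["shape"]), rate = unname(fit$estimate["rate"]))
}

# Mixture density on the (e, t) lattice, rows indexed by e.
gmm_density_grid <- function(gmm, e_nodes, t_axis) {
  ne <- length(e_nodes)
  nt <- length(t_axis)
  dens <- matrix(0, ne, nt)
  for (j in seq_along(gmm$weights)) {
    mu <- gmm$means[j, ]
    S <- gmm$covs[[j]]
    det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (det_s <= 0) next
    i11 <- S[2, 2] / det_s
    i22 <- S[1, 1] / det_s
    i12 <- -S[1, 2] / det_s
    de <- e_nodes - mu[1]
    dt <- t_axis - mu[2]
    qf <- outer(i11 * de^2, i22 * dt^2, "+") + (2 * i12) * outer(de, dt)
    dens <- dens + gmm$weights[j] * exp(-0.5 * qf) / (2 * pi * sqrt(det_s))
  }
  dens
}

# Per column (fixed e): renormalise to unit mass, then accumulate cell mass
# density * delta from the top of the T-axis downward; the corrected value
# is the node (cell lower edge) where the accumulated mass first reaches
# epsilon.
tail_quantile_columns <- function(joint, t_axis, delta, epsilon) {
  ne <- nrow(joint)
  corrected <- numeric(ne)
  for (i in seq_len(ne)) {
    col <- joint[i, ]
    total <- sum(col) * delta
    if (total <= 0) { corrected[i] <- t_axis[length(t_axis)]; next }
    col <- col / total
    tail_mass <- rev(cumsum(rev(col))) * delta
    j <- which(tail_mass >= epsilon)
    corrected[i] <- t_axis[j[length(j)]]
  }
  corrected
}

#' @rdname predict.sar_margin
#' @export
predict.sar_csm <- function(object, psar_e, ...) {
  psar_e <- check_psar_e(psar_e)
  en <- object$e_nodes
  cn <- object$corrected
  out <- stats::approx(en, cn, xout = psar_e, rule = 1)$y
  lo <- psar_e < en[1L]
  hi <- psar_e > en[length(en)]
  if (any(lo)) out[lo] <- psar_e[lo] * (cn[1L] / en[1L])
  if (any(hi)) {
    ratio <- cn[length(cn)] / en[length(en)]
    out[hi] <- pmax(cn[length(cn)], psar_e[hi] * ratio)
  }
  out
}

#' @export
coef.sar_csm <- function(object, ...) {
  c(epsilon = object$epsilon, K = object$K,
    gamma_shape = object$gamma_shape, gamma_rate = object$gamma_rate)
}

#' @export
print.sar_csm <- function(x, ...) {
  cat(sprintf(paste0("Conditional safety margin (epsilon = %g)\n",
                     "  fitted on %d pairs; mixture components K = %d ",
                     "(BIC over K = %s)\n",
                     "  curve: %d nodes on [%.3g, %.3g] W/kg, spacing %g\n"),
              x$epsilon, x$n, x$K,
              paste(names(x$bic) %||% seq_along(x$bic), collapse = ","),
              length(x$e_nodes), x$e_nodes[1L], x$e_nodes[length(x$e_nodes)],
              x$delta))
  invisible(x)
}

#' @export
summary.sar_csm <- function(object, ...) {
  ratios <- object$corrected / object$e_nodes
  structure(list(csm = object, ratio_range = range(ratios),
                 corrected_range = range(object$corrected)),
            class = "summary.sar_csm")
}

#' @export
print.summary.sar_csm <- function(x, ...) {
  print(x$csm)
  cat(sprintf("  corrected/estimate ratio: %.3g to %.3g\n",
              x$ratio_range[1L], x$ratio_range[2L]))
  cat(sprintf("  corrected values span %.3g to %.3g W/kg\n",
              x$corrected_range[1L], x$corrected_range[2L]))
  invisible(x)
}

#' Plot a conditional safety margin
#'
#' Draws the fitted correction curve; optionally overlays validation or
#' test pairs and comparator margins.
#'
#' @param x a fitted [csm()].
#' @param samples optional [paired_samples()] to overlay as points.
#' @param margins optional named list of other fitted `sar_margin`s to
#'   overlay as lines.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sar_csm <- function(x, samples = NULL, margins = NULL, ...) {
  xlim <- range(x$e_nodes, samples$psar_e)
  ylim <- range(x$corrected, samples$psar_t)
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "estimated pSAR10g (W/kg)",
                 ylab = "true / corrected pSAR10g (W/kg)", ...)
  if (!is.null(samples))
    graphics::points(samples$psar_e, samples$psar_t, pch = 16,
                     col = grDevices::adjustcolor("grey40", 0.3), cex = 0.4)
  graphics::abline(0, 1, lty = 3, col = "red")
  if (!is.null(margins)) {
    cols <- seq_along(margins) + 2L
    for (i in seq_along(margins)) {
      ee <- seq(xlim[1L], xlim[2L], length.out = 200L)
      graphics::lines(ee, predict(margins[[i]], ee), col = cols[i], lwd = 1.5)
    }
    graphics::legend("topleft", legend = c("CSM", names(margins)),
                     col = c("forestgreen", cols), lwd = 2, bty = "n")
  }
  graphics::lines(x$e_nodes, x$corrected, col = "forestgreen", lwd = 2)
  invisible(x)
}
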