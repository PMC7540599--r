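#' Q-matrix SAR model for an 8-channel transmit array
#'
#' A body model is represented by its set of 10g-averaged Q-matrices: one
#' 8x8 complex Hermitian positive-semidefinite matrix per voxel, scaled so
#' that for a drive vector `s` (per-channel amplitudes in sqrt(W)) the
#' quadratic form \eqn{s^H Q s} is the local 10g-averaged SAR in W/kg.
#'
#' @param q complex array of dimension `c(8, 8, n_voxels)` (or a single
#'   8x8 matrix for a one-voxel model).
#' @param model_id character scalar identifying the model.
#' @param grid_shape integer triple giving the nominal voxel grid; defaults
#'   to a flat `c(n_voxels, 1, 1)` layout.
#' @param metadata optional list of generator parameters, carried along.
#' @param validate check Hermitian symmetry and positive semidefiniteness
#'   of every voxel (default `TRUE`).
#' @return An object of class `body_model`: a list with elements `model_id`,
#'   `grid_shape`, `q` (the complex array) and `metadata`.
#' @examples
#' q <- array(0i, c(8, 8, 2))
#' q[, , 1] <- diag(8) + 0i
#' q[, , 2] <- 2 * diag(8) + 0i
#' bm <- body_model(q, "toy")
#' psar_true(bm, drive_vector(rep(1 + 0i, 8)))
#' @export
body_model <- function(q, model_id, grid_shape = NULL, metadata = list(),
                       validate = TRUE) {
  if (is.matrix(q)) q <- array(q, c(dim(q), 1L))
  if (!is.array(q) || length(dim(q)) != 3L || dim(q)[1] != 8L || dim(q)[2] != 8L)
    stop("`q` must be an 8 x 8 x n_voxels array", call. = FALSE)
  if (dim(q)[3] < 1L) stop("a body model needs at least one voxel", call. = FALSE)
  if (!is.complex(q)) q <- q + 0i
  if (!all(is.finite(Re(q))) || !all(is.finite(Im(q))))
    stop("Q-matrix entries must be finite", call. = FALSE)
  if (validate) {
    for (v in seq_len(dim(q)[3])) check_qmatrix(q[, , v], voxel = v)
  }
  structure(list(model_id = as.character(model_id),
                 grid_shape = as.integer(grid_shape %||% c(dim(q)[3], 1L, 1L)),
                 q = q, metadata = metadata),
            class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model '%s': %d voxels, 8-channel Q-matrices>\n",
              x$model_id, n_voxels(x)))
  invisible(x)
}

#' @rdname body_model
#' @param model a `body_model`.
#' @export
n_voxels <- function(model) dim(model$q)[3]

# Hermitian and PSD checks, relative tolerances per the type contract.
check_qmatrix <- function(Q, tol = 1e-8, voxel = NA) {
  scale <- max(Mod(Q), 1e-300)
  if (max(Mod(Q - Conj(t(Q)))) > tol * scale)
    stop(sprintf("Q-matrix%s is not Hermitian within tolerance",
                 if (is.na(voxel)) "" else paste0(" at voxel ", voxel)),
         call. = FALSE)
  ev <- eigen((Q + Conj(t(Q))) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(ev, 0))
    stop(sprintf("Q-matrix%s is not positive semidefinite",
                 if (is.na(voxel)) "" else paste0(" at voxel ", voxel)),
         call. = FALSE)
  invisible(TRUE)
}

#' Construct a drive vector
#'
#' A drive vector is the complex per-channel excitation of the 8-channel
#' array; amplitudes are in sqrt(W) so that squared moduli are per-channel
#' input powers in W.
#'
#' @param s complex vector of length 8.
#' @param mode_tag optional driving-mode label (see [sample_random_phase()]).
#' @return An object of class `drive_vector` (a complex vector with a
#'   `mode_tag` attribute).
#' @export
drive_vector <- function(s, mode_tag = NA_character_) {
  if (length(s) != 8L) stop("a drive vector has 8 channels", call. = FALSE)
  s <- as.complex(s)
  if (!all(is.finite(Re(s)))) stop("drive amplitudes must be finite", call. = FALSE)
  structure(s, mode_tag = mode_tag, class = "drive_vector")
}

#' Local SAR at one voxel
#'
#' Evaluates the quadratic form \eqn{\mathrm{Re}(s^H Q s)} giving the
#' 10g-averaged SAR (W/kg) deposited at the voxel of Q-matrix `Q` by drive
#' vector `s`. Tiny negative values from floating point (above
#' `-1e-12` W/kg) are clipped to zero; larger negatives signal a non-PSD
#' matrix and raise an error.
#'
#' @param Q an 8x8 complex Hermitian matrix.
#' @param s a length-8 complex drive vector (plain vector or
#'   [drive_vector()]).
#' @return SAR in W/kg (non-negative scalar).
#' @export
sar_at_voxel <- function(Q, s) {
  if (!is.matrix(Q) || any(dim(Q) != c(8L, 8L)))
    stop("`Q` must be an 8 x 8 matrix", call. = FALSE)
  if (length(s) != 8L) stop("`s` must have 8 channels", call. = FALSE)
  scale <- max(Mod(Q), 1e-300)
  if (max(Mod(Q - Conj(t(Q)))) > 1e-8 * scale)
    stop("`Q` is not Hermitian within tolerance", call. = FALSE)
  s <- as.complex(s)
  val <- Re(sum(Conj(s) * (Q %*% s)))
  clip_sar(val)
}

clip_sar <- function(val) {
  neg <- val < 0
  if (any(neg)) {
    if (min(val) < -1e-12)
      stop("negative SAR beyond floating-point tolerance: non-PSD Q-matrix?",
           call. = FALSE)
    val[neg] <- 0
  }
  val
}

# SAR of every drive (columns of complex 8 x n matrix S) at every voxel of
# `model`: returns an n_voxels x n_drives matrix. The workhorse behind
# psar_true() and the batch evaluators.
sar_all_voxels <- function(model, S) {
  nv <- n_voxels(model)
  nd <- ncol(S)
  out <- matrix(0, nv, nd)
  for (v in seq_len(nv)) {
    QS <- model$q[, , v] %*% S
    out[v, ] <- Re(colSums(Conj(S) * QS))
  }
  clip_sar(out)
}

#' True peak local SAR of a drive vector on a body model
#'
#' The peak 10g-averaged SAR over all voxels,
#' \eqn{\max_r \mathrm{Re}(s^H Q_{10g}(r) s)}.
#'
#' @param model a [body_model()].
#' @param s a length-8 complex drive vector.
#' @return A list with `value` (peak SAR, W/kg) and `voxel` (the argmax
#'   voxel index).
#' @export
psar_true <- function(model, s) {
  if (!inherits(model, "body_model")) stop("`model` must be a body_model", call. = FALSE)
  if (n_voxels(model) < 1L) stop("empty body model", call. = FALSE)
  vals <- sar_all_voxels(model, matrix(as.complex(s), 8L, 1L))[, 1L]
  v <- which.max(vals)
  list(value = vals[v], voxel = v)
}

#' Worst-case SAR map under 8 x 1W input power
#'
#' For each voxel, approximates the maximum SAR attainable with unit
#' per-channel amplitude over all phase settings,
#' \eqn{\max_{|s_i|=1} s^H Q s}. Two approximations are provided:
#' `method = "bound"` returns the certified upper bound
#' \eqn{\sum_{ij} |Q_{ij}|} (attained when all phases can be aligned);
#' `method = "multistart"` runs coordinate-ascent phase optimisation from
#' `n_starts` random initialisations and returns the best value found,
#' which is a lower bound on the true worst case and never exceeds the
#' closed-form bound. Worst-case maps are used only for between-model
#' similarity ranking, where the multistart approximation is the default.
#'
#' @param model a [body_model()].
#' @param method `"multistart"` (default) or `"bound"`.
#' @param n_starts number of random phase initialisations per voxel.
#' @param seed integer seed for the random starts.
#' @return An object of class `worst_case_map`: list with `model_id` and
#'   `values` (per-voxel worst-case SAR, W/kg).
#' @export
worst_case_map <- function(model, method = c("multistart", "bound"),
                           n_starts = 32L, seed = 1L) {
  method <- match.arg(method)
  nv <- n_voxels(model)
  vals <- numeric(nv)
  if (method == "bound") {
    for (v in seq_len(nv)) vals[v] <- sum(Mod(model$q[, , v]))
  } else {
    if (n_starts < 1L) stop("`n_starts` must be >= 1", call. = FALSE)
    starts <- with_seed(seed, {
      matrix(stats::runif(8L * n_starts, -pi, pi), 8L, n_starts)
    })
    for (v in seq_len(nv))
      vals[v] <- wc_multistart(model$q[, , v], starts)
  }
  structure(list(model_id = model$model_id, values = vals, method = method),
            class = "worst_case_map")
}

# Coordinate ascent on phases: with s_i = exp(i phi_i) and Hermitian Q,
# the objective is Q_ii-terms + 2 Re(conj(s_i) b_i) with
# b_i = sum_{j != i} Q_ij s_j, maximised per channel by s_i = b_i / |b_i|.
# Monotone, so it converges to a local maximum; restarted from each column
# of `starts` (channel-1 phase is redundant but harmless).
wc_multistart <- function(Q, starts, max_iter = 200L, tol = 1e-10) {
  best <- 0
  for (k in seq_len(ncol(starts))) {
    s <- exp(1i * starts[, k])
    obj <- Re(sum(Conj(s) * (Q %*% s)))
    for (it in seq_len(max_iter)) {
      for (i in 1:8) {
        b <- sum(Q[i, -i] * s[-i])
        if (Mod(b) > 0) s[i] <- b / Mod(b)
      }
      new_obj <- Re(sum(Conj(s) * (Q %*% s)))
      if (new_obj - obj < tol * max(1, abs(obj))) { obj <- new_obj; break }
      obj <- new_obj
    }
    if (obj > best) best <- obj
  }
  best
}

#' @export
print.worst_case_map <- function(x, ...) {
  cat(sprintf("<worst_case_map '%s' (%s): %d voxels, max %.3g W/kg>\n",
              x$model_id, x$method, length(x$values), max(x$values)))
  invisible(x)
}
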