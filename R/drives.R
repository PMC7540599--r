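#' Drive-vector ensembles for the three driving modes
#'
#' Samplers for the drive settings used to exercise a body model:
#' \describe{
#'   \item{`sample_random_phase()`}{uniform amplitude (8 x 1W input power),
#'     channel-1 phase fixed at 0, channels 2-8 phases i.i.d. uniform on
#'     \[-180, 180) degrees. Represents an arbitrary examination.}
#'   \item{`sample_prostate_shim()`}{uniform amplitude, phases normally
#'     distributed (sd 33 degrees by default) around a supplied
#'     phase-shimming set, re-referenced to channel 1. Represents a
#'     shimmed prostate examination.}
#'   \item{`sample_amp_phase()`}{random amplitudes U(0,1) and random
#'     relative phases, rescaled to either 1W maximum input power per
#'     channel or 8W total input power. Represents arbitrary RF-pulse
#'     design strategies.}
#' }
#' All samplers are deterministic given `(n, seed)` and return a
#' `drive_ensemble`: a list with `s` (complex n x 8 matrix, rows = drives),
#' `mode_tag`, `seed` and `n`.
#'
#' @param n number of drive vectors (>= 1).
#' @param seed integer seed.
#' @return A `drive_ensemble`.
#' @examples
#' de <- sample_random_phase(5, seed = 1)
#' rowSums(Mod(de$s)^2)  # total power 8 W per drive
#' @export
sample_random_phase <- function(n, seed = 1L) {
  n <- check_n(n)
  ph <- with_seed(seed, matrix(stats::runif(n * 7L, -180, 180), n, 7L))
  s <- exp(1i * cbind(0, ph) * pi / 180)
  new_drive_ensemble(s, "random_phase", seed, n)
}

#' @rdname sample_random_phase
#' @param shim_phases length-8 numeric vector of shim phases in degrees.
#'   There is no universal default: the set depends on the array and the
#'   anatomy being shimmed. [fixture_shim_phases()] provides a documented
#'   stand-in (45 degrees per channel increment) for fixtures and examples.
#' @param sigma standard deviation of the per-channel phase perturbation,
#'   degrees (default 33).
#' @export
sample_prostate_shim <- function(n, seed = 1L, shim_phases, sigma = 33) {
  n <- check_n(n)
  if (missing(shim_phases) || is.null(shim_phases))
    stop("`shim_phases` is required: supply the array's average ",
         "phase-shimming set (see fixture_shim_phases() for a fixture value)",
         call. = FALSE)
  if (length(shim_phases) != 8L)
    stop("`shim_phases` must have 8 entries (degrees)", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  delta <- with_seed(seed, matrix(stats::rnorm(n * 8L, 0, sigma), n, 8L))
  ph <- sweep(delta, 2L, as.numeric(shim_phases), "+")
  ph <- ph - ph[, 1L]  # only relative phases are physical
  s <- exp(1i * ph * pi / 180)
  new_drive_ensemble(s, "prostate_shim", seed, n)
}

#' @rdname sample_random_phase
#' @export
fixture_shim_phases <- function() seq(0, 315, by = 45)

#' @rdname sample_random_phase
#' @param normalization `"per_channel_1W"` (rescale so the largest channel
#'   power is exactly 1 W) or `"total_8W"` (rescale so total power is
#'   exactly 8 W).
#' @export
sample_amp_phase <- function(n, seed = 1L,
                             normalization = c("per_channel_1W", "total_8W")) {
  n <- check_n(n)
  normalization <- match.arg(normalization)
  draw <- with_seed(seed, {
    a <- matrix(stats::runif(n * 8L), n, 8L)
    # an all-zero amplitude row is a probability-zero event; resample it
    while (any(bad <- rowSums(a) == 0))
      a[bad, ] <- matrix(stats::runif(sum(bad) * 8L), sum(bad), 8L)
    ph <- cbind(0, matrix(stats::runif(n * 7L, -180, 180), n, 7L))
    list(a = a, ph = ph)
  })
  s <- draw$a * exp(1i * draw$ph * pi / 180)
  if (normalization == "per_channel_1W") {
    s <- s / apply(Mod(s), 1L, max)
    tag <- "amp_phase_1W_per_ch"
  } else {
    s <- s * sqrt(8 / rowSums(Mod(s)^2))
    tag <- "amp_phase_8W_total"
  }
  new_drive_ensemble(s, tag, seed, n)
}

check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1", call. = FALSE)
  as.integer(n)
}

new_drive_ensemble <- function(s, mode_tag, seed, n) {
  structure(list(s = s, mode_tag = mode_tag, seed = as.integer(seed), n = n),
            class = "drive_ensemble")
}

#' @export
print.drive_ensemble <- function(x, ...) {
  cat(sprintf("<drive_ensemble: %d drives, mode '%s', seed %d>\n",
              x$n, x$mode_tag, x$seed))
  invisible(x)
}

#' Extract one drive from an ensemble
#' @param ensemble a `drive_ensemble`.
#' @param i drive index.
#' @export
get_drive <- function(ensemble, i) {
  drive_vector(ensemble$s[i, ], mode_tag = ensemble$mode_tag)
}

#' Write or read a drive ensemble as columnar text
#'
#' One row per drive: `drive_id`, eight amplitude columns (sqrt(W)), eight
#' phase columns (degrees), `mode_tag`. The seed is recorded in a header
#' comment so a round-tripped ensemble keeps its provenance.
#'
#' @param ensemble a `drive_ensemble`.
#' @param path file path.
#' @export
write_drives <- function(ensemble, path) {
  amp <- Mod(ensemble$s)
  ph <- Arg(ensemble$s) * 180 / pi
  df <- data.frame(drive_id = seq_len(ensemble$n))
  for (i in 1:8) df[[paste0("amp", i)]] <- fmt_num(amp[, i])
  for (i in 1:8) df[[paste0("phase", i)]] <- fmt_num(ph[, i])
  df$mode_tag <- ensemble$mode_tag
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", ensemble$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drives
#' @export
read_drives <- function(path) {
  header <- readLines(path, n = 1L)
  seed <- if (grepl("^# seed:", header)) as.integer(sub("^# seed:\\s*", "", header)) else NA_integer_
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  amp <- unname(as.matrix(df[paste0("amp", 1:8)]))
  ph <- unname(as.matrix(df[paste0("phase", 1:8)]))
  s <- amp * exp(1i * ph * pi / 180)
  new_drive_ensemble(s, df$mode_tag[1L], seed, nrow(df))
}
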