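#' Split paired samples into validation and test sets
#'
#' Per model, draws disjoint validation and test subsets of drives,
#' deterministically given `seed`. Margins are fitted on the validation
#' rows and evaluated on the test rows only; the split provenance is
#' recorded in a `split` attribute on each returned frame.
#'
#' @param pairs a [paired_samples()] frame.
#' @param n_validation_per_model validation drives per model (default 250).
#' @param n_test_per_model test drives per model (default 1000).
#' @param seed integer seed.
#' @return List with elements `validation` and `test`, both
#'   [paired_samples()] frames.
#' @examples
#' p <- generate_joint_pairs(joint_spec(n_samples = 300, seed = 1))
#' sp <- make_splits(p, n_validation_per_model = 100, n_test_per_model = 200)
#' nrow(sp$validation); nrow(sp$test)
#' @export
make_splits <- function(pairs, n_validation_per_model = 250L,
                        n_test_per_model = 1000L, seed = 1L) {
  check_pairs(pairs)
  need <- n_validation_per_model + n_test_per_model
  models <- unique(pairs$model_id)
  take_val <- take_test <- logical(nrow(pairs))
  seeds <- derive_seeds(seed, length(models))
  for (i in seq_along(models)) {
    idx <- which(pairs$model_id == models[i])
    if (length(idx) < need)
      stop(sprintf("model '%s' has %d drives; %d needed for the split",
                   models[i], length(idx), need), call. = FALSE)
    pick <- with_seed(seeds[i], sample(idx, need))
    take_val[pick[seq_len(n_validation_per_model)]] <- TRUE
    take_test[pick[n_validation_per_model + seq_len(n_test_per_model)]] <- TRUE
  }
  val <- pairs[take_val, , drop = FALSE]
  test <- pairs[take_test, , drop = FALSE]
  attr(val, "split") <- "validation"
  attr(test, "split") <- "test"
  class(val) <- class(test) <- c("paired_samples", "data.frame")
  list(validation = val, test = test)
}

#' Mean overestimation of corrected peak SAR
#'
#' Signed mean relative error of the corrected values against the truth,
#' as a percentage: `mean((corrected - true) / true) * 100`. Rows where
#' the margin underestimates contribute negatively; set
#' `over_only = TRUE` to average only over the overestimated rows.
#'
#' @param corrected,true equal-length positive numeric vectors, W/kg.
#' @param over_only average only rows with `corrected >= true`.
#' @return Percentage (can be negative when `over_only = FALSE`).
#' @export
mean_overestimation <- function(corrected, true, over_only = FALSE) {
  if (length(corrected) != length(true))
    stop("`corrected` and `true` must have equal length", call. = FALSE)
  if (any(true <= 0)) stop("`true` values must be positive", call. = FALSE)
  rel <- (corrected - true) / true
  if (over_only) rel <- rel[rel >= 0]
  mean(rel) * 100
}

#' Fit and compare peak SAR correction methods
#'
#' The evaluation protocol: margins are fitted on a validation split and
#' scored on a disjoint test split, reporting for each correction method
#' the mean overestimation percentage and the empirical underestimation
#' rate.
#'
#' `evaluate_corrections()` operates on one paired sample set.
#' `compare_methods()` drives the full pipeline from a config list and
#' can span several estimators/sample sets at once.
#'
#' @param pairs a [paired_samples()] frame with enough drives per model
#'   for the requested split.
#' @param corrections character subset of
#'   `c("lsf_worst_case", "lsf_outer_fence", "capped_lsf", "upper_bound",
#'   "csm")`.
#' @param epsilon CSM underestimation probability (default 0.001).
#' @param level upper-bound probability level (default 0.999).
#' @param n_validation_per_model,n_test_per_model,seed split parameters,
#'   see [make_splits()].
#' @param delta,k CSM fit parameters, see [csm()].
#' @return An object of classes `sar_evaluation`, `data.frame`: one row
#'   per correction with columns `correction`, `mean_overestimation_pct`,
#'   `underestimation_rate`, `n_test`; fitted margins in the `margins`
#'   attribute, splits in the `splits` attribute.
#' @export
evaluate_corrections <- function(pairs,
                                 corrections = c("lsf_outer_fence",
                                                 "capped_lsf", "csm"),
                                 epsilon = 0.001, level = 0.999,
                                 n_validation_per_model = 250L,
                                 n_test_per_model = 1000L, seed = 1L,
                                 delta = 0.01, k = 1:6) {
  all_corr <- c("lsf_worst_case", "lsf_outer_fence", "capped_lsf",
                "upper_bound", "csm")
  bad <- setdiff(corrections, all_corr)
  if (length(bad))
    stop("unknown correction(s): ", paste(bad, collapse = ", "), call. = FALSE)
  sp <- make_splits(pairs, n_validation_per_model, n_test_per_model, seed)
  val <- sp$validation
  test <- sp$test
  margins <- list()
  for (corr in corrections) {
    margins[[corr]] <- switch(corr,
      lsf_worst_case = lsf(val, "worst_case"),
      lsf_outer_fence = lsf(val, "outer_fence"),
      upper_bound = upper_bound(val, level = level),
      capped_lsf = capped_lsf(lsf(val, "outer_fence"),
                              upper_bound(val, level = level)),
      csm = csm(val, epsilon = epsilon, delta = delta, k = k, seed = seed))
  }
  rows <- lapply(corrections, function(corr) {
    corrected <- predict(margins[[corr]], test$psar_e)
    data.frame(correction = corr,
               mean_overestimation_pct =
                 mean_overestimation(corrected, test$psar_t),
               underestimation_rate =
                 underestimation_rate(margins[[corr]], test),
               n_test = nrow(test))
  })
  report <- do.call(rbind, rows)
  attr(report, "margins") <- margins
  attr(report, "splits") <- sp
  attr(report, "seed") <- seed
  class(report) <- c("sar_evaluation", "data.frame")
  report
}

#' @rdname evaluate_corrections
#' @param config a named list describing the full run. Required: either
#'   `pairs` (a [paired_samples()] frame or named list of them) or
#'   `joint_spec` (a [joint_spec()]) or `cohort_spec` (a [cohort_spec()])
#'   plus `modes` (driving-mode names) and `estimators` (names understood
#'   by [cohort_pairs()]). Optional: `corrections`, `epsilon`, `level`,
#'   `n_validation_per_model`, `n_test_per_model`, `seed`, `delta`,
#'   `plot_dir` (write comparison figures there).
#' @export
compare_methods <- function(config) {
  defaults <- list(corrections = c("lsf_outer_fence", "capped_lsf", "csm"),
                   epsilon = 0.001, level = 0.999,
                   n_validation_per_model = 250L, n_test_per_model = 1000L,
                   seed = 1L, delta = 0.01, plot_dir = NULL)
  unknown <- setdiff(names(config),
                     c(names(defaults), "pairs", "joint_spec", "cohort_spec",
                       "modes", "estimators", "drive_seed"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  pair_sets <- gather_pair_sets(cfg)
  reports <- vector("list", length(pair_sets))
  for (i in seq_along(pair_sets)) {
    rep_i <- evaluate_corrections(
      pair_sets[[i]], corrections = cfg$corrections, epsilon = cfg$epsilon,
      level = cfg$level, n_validation_per_model = cfg$n_validation_per_model,
      n_test_per_model = cfg$n_test_per_model, seed = cfg$seed,
      delta = cfg$delta)
    rep_i$set <- names(pair_sets)[i]
    reports[[i]] <- rep_i
  }
  out <- do.call(rbind, lapply(reports, as.data.frame))
  attr(out, "reports") <- stats::setNames(reports, names(pair_sets))
  class(out) <- c("sar_evaluation", "data.frame")
  if (!is.null(cfg$plot_dir)) {
    dir.create(cfg$plot_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(reports)) {
      f <- file.path(cfg$plot_dir, paste0("margins_", names(pair_sets)[i], ".png"))
      grDevices::png(f, width = 900, height = 700)
      plot(reports[[i]])
      grDevices::dev.off()
    }
    f <- file.path(cfg$plot_dir, "mean_overestimation.png")
    grDevices::png(f, width = 900, height = 500)
    barplot_evaluation(out)
    grDevices::dev.off()
  }
  out
}

gather_pair_sets <- function(cfg) {
  if (!is.null(cfg$pairs)) {
    if (is.data.frame(cfg$pairs)) return(list(pairs = cfg$pairs))
    if (!is.list(cfg$pairs) || is.null(names(cfg$pairs)))
      stop("config `pairs` must be a paired_samples frame or a named list ",
           "of them", call. = FALSE)
    return(cfg$pairs)
  }
  if (!is.null(cfg$joint_spec))
    return(list(parametric = generate_joint_pairs(cfg$joint_spec)))
  if (is.null(cfg$cohort_spec))
    stop("config must supply one of `pairs`, `joint_spec`, `cohort_spec`",
         call. = FALSE)
  modes <- cfg$modes %||% "random_phase"
  estimators <- cfg$estimators %||% "library"
  lib <- generate_cohort(cfg$cohort_spec)
  n_drives <- cfg$n_validation_per_model + cfg$n_test_per_model
  table <- if (any(estimators %in% c("selected", "multi_selected")))
    build_selection_table(lib, seed = cfg$seed) else NULL
  sets <- list()
  dseed <- cfg$drive_seed %||% (cfg$seed + 1L)
  for (mode in modes) {
    de <- switch(mode,
      random_phase = sample_random_phase(n_drives, seed = dseed),
      prostate_shim = sample_prostate_shim(n_drives, seed = dseed,
                                           shim_phases = fixture_shim_phases()),
      amp_phase_1W_per_ch = sample_amp_phase(n_drives, seed = dseed,
                                             normalization = "per_channel_1W"),
      amp_phase_8W_total = sample_amp_phase(n_drives, seed = dseed,
                                            normalization = "total_8W"),
      stop(sprintf("unknown driving mode '%s'", mode), call. = FALSE))
    for (est in estimators)
      sets[[paste(est, mode, sep = ".")]] <-
        cohort_pairs(lib, de, estimator = est, table = table)
  }
  sets
}

#' @export
print.sar_evaluation <- function(x, ...) {
  cat("Peak SAR correction comparison (fitted on validation, scored on test)\n")
  df <- as.data.frame(x)
  df$mean_overestimation_pct <- round(df$mean_overestimation_pct, 2)
  df$underestimation_rate <- signif(df$underestimation_rate, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot an evaluation report
#'
#' Scatter of test pairs with the fitted correction curves overlaid (when
#' the report carries its splits), in the style of the per-estimator
#' comparison figures.
#'
#' @param x a `sar_evaluation` from [evaluate_corrections()].
#' @param ... passed on to the underlying plot.
#' @export
plot.sar_evaluation <- function(x, ...) {
  margins <- attr(x, "margins")
  sp <- attr(x, "splits")
  if (is.null(margins) || is.null(sp)) {
    barplot_evaluation(x, ...)
    return(invisible(x))
  }
  test <- sp$test
  csm_fit <- margins[["csm"]]
  others <- margins[setdiff(names(margins), "csm")]
  if (!is.null(csm_fit)) {
    plot(csm_fit, samples = test, margins = others, ...)
  } else {
    plot(NA, xlim = range(test$psar_e), ylim = range(test$psar_t),
         xlab = "estimated pSAR10g (W/kg)", ylab = "true pSAR10g (W/kg)", ...)
    graphics::points(test$psar_e, test$psar_t, pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor("grey40", 0.3))
    ee <- seq(min(test$psar_e), max(test$psar_e), length.out = 200)
    for (i in seq_along(others))
      graphics::lines(ee, predict(others[[i]], ee), col = i + 2L, lwd = 1.5)
    graphics::legend("topleft", legend = names(others),
                     col = seq_along(others) + 2L, lwd = 2, bty = "n")
  }
  invisible(x)
}

barplot_evaluation <- function(x, ...) {
  df <- as.data.frame(x)
  if (!"set" %in% names(df)) df$set <- "pairs"
  m <- tapply(df$mean_overestimation_pct, list(df$correction, df$set), mean)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "mean overestimation (%)", ...)
}
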