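#' Peak local SAR estimation methods
#'
#' Estimators of a subject's true peak 10g-averaged SAR for a given drive
#' vector, using other models as proxies (leave-one-out discipline: except
#' in degenerate cases no estimator reads the subject's own Q-matrices):
#' \describe{
#'   \item{`estimate_generic()`}{evaluate the drive on one designated
#'     generic body model, whoever the subject is.}
#'   \item{`estimate_library()`}{maximum true peak SAR over all other
#'     models in the library — conservative population coverage.}
#'   \item{`estimate_selected()`}{true peak SAR of the single most
#'     representative model, ranked by RMS similarity of worst-case SAR
#'     maps (see [build_selection_table()]).}
#'   \item{`estimate_multi_selected()`}{maximum over the top-`a_size`
#'     (default 5) most representative models.}
#' }
#'
#' @param generic a [body_model()] designated as the generic model.
#' @param s a length-8 complex drive vector.
#' @return Estimated peak SAR, W/kg.
#' @export
estimate_generic <- function(generic, s) {
  psar_true(generic, s)$value
}

#' @rdname estimate_generic
#' @param library a `model_library` with at least 2 models.
#' @param m model_id of the subject (excluded from the maximum).
#' @export
estimate_library <- function(library, m, s) {
  others <- setdiff(names(library), m)
  if (length(others) < 1L)
    stop("library must contain at least one model besides the subject",
         call. = FALSE)
  if (length(library) < 2L) stop("single-model library", call. = FALSE)
  max(vapply(others, function(k) psar_true(library[[k]], s)$value, 0))
}

#' Rank models by worst-case SAR map similarity
#'
#' Computes every model's worst-case SAR map (see [worst_case_map()]),
#' the pairwise RMS error between maps on the shared voxel grid, and for
#' each model an ascending-RMSE ranking of the others. Ties are broken by
#' lexicographic model_id so tables are deterministic. The top `a_size`
#' models form the representative set used by
#' [estimate_multi_selected()].
#'
#' @param library a `model_library` on a shared grid.
#' @param wc_method,n_starts,seed passed to [worst_case_map()].
#' @param a_size size of the representative set (default 5, or all others
#'   if the library is smaller).
#' @return A `selection_table`: list with `rmse` (symmetric matrix),
#'   `ranking` (per model, ordered character vector of the other models),
#'   `a_sets` (per model, the top `a_size` ids) and `a_size`.
#' @export
build_selection_table <- function(library, wc_method = "multistart",
                                  n_starts = 32L, seed = 1L, a_size = 5L) {
  ids <- names(library)
  nv <- vapply(library, n_voxels, 0L)
  if (length(unique(nv)) != 1L)
    stop("all models must share one voxel grid", call. = FALSE)
  maps <- vapply(library, function(bm)
    worst_case_map(bm, method = wc_method, n_starts = n_starts,
                   seed = seed)$values,
    numeric(nv[1L]))
  nm <- length(ids)
  rmse <- matrix(0, nm, nm, dimnames = list(ids, ids))
  for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
    r <- sqrt(mean((maps[, i] - maps[, j])^2))
    rmse[i, j] <- r
    rmse[j, i] <- r
  }
  a_size <- min(as.integer(a_size), nm - 1L)
  ranking <- a_sets <- stats::setNames(vector("list", nm), ids)
  for (m in ids) {
    others <- setdiff(ids, m)
    ord <- others[order(rmse[m, others], others)]
    ranking[[m]] <- ord
    a_sets[[m]] <- ord[seq_len(a_size)]
  }
  structure(list(rmse = rmse, ranking = ranking, a_sets = a_sets,
                 a_size = a_size, wc_method = wc_method, seed = seed),
            class = "selection_table")
}

#' @export
print.selection_table <- function(x, ...) {
  cat(sprintf("<selection_table: %d models, representative sets of %d>\n",
              nrow(x$rmse), x$a_size))
  invisible(x)
}

#' @rdname estimate_generic
#' @param table a [build_selection_table()] result for the same library.
#' @export
estimate_selected <- function(library, table, m, s) {
  best <- selection_lookup(table, m)[1L]
  psar_true(library[[best]], s)$value
}

#' @rdname estimate_generic
#' @export
estimate_multi_selected <- function(library, table, m, s) {
  a_m <- table$a_sets[[m]] %||% selection_lookup(table, m)
  max(vapply(a_m, function(k) psar_true(library[[k]], s)$value, 0))
}

selection_lookup <- function(table, m) {
  r <- table$ranking[[m]]
  if (is.null(r)) stop(sprintf("model '%s' not in selection table", m),
                       call. = FALSE)
  r
}

#' Surrogate parametric estimator
#'
#' A multiplicative-lognormal estimator standing in for any image-based or
#' learned peak-SAR predictor: `psar_e = psar_t * exp(eta)` with `eta`
#' i.i.d. normal(`bias`, `log_sd^2`). Since peak SAR is positive and
#' estimator scatter fans out proportionally, log-scale noise is the
#' natural error model; `log_sd` tunes estimator quality from near-perfect
#' (small) to nearly uninformative (large).
#'
#' @param psar_t positive numeric vector of true peak SAR values (or a
#'   [paired_samples()] frame, whose `psar_t` column is used).
#' @param bias log-scale mean error (0 = unbiased; `-log(2)` halves every
#'   estimate).
#' @param log_sd log-scale error sd (>= 0).
#' @param seed integer seed.
#' @return A [paired_samples()] frame with the simulated `psar_e`.
#' @export
surrogate_estimator <- function(psar_t, bias = 0, log_sd = 0.15, seed = 1L) {
  prov <- NULL
  if (inherits(psar_t, "paired_samples") || is.data.frame(psar_t)) {
    prov <- psar_t
    psar_t <- psar_t$psar_t
  }
  if (log_sd < 0) stop("`log_sd` must be >= 0", call. = FALSE)
  eta <- with_seed(seed, stats::rnorm(length(psar_t), bias, log_sd))
  psar_e <- psar_t * exp(eta)
  paired_samples(psar_e, psar_t,
                 model_id = prov$model_id %||% NA_character_,
                 drive_id = prov$drive_id %||% seq_along(psar_t),
                 mode_tag = prov$mode_tag %||% NA_character_,
                 estimator_tag = "SURROGATE")
}

#' Evaluate a cohort into paired samples
#'
#' Runs an estimator and the true peak SAR over every (model, drive)
#' combination of a library and a drive ensemble, producing the paired
#' sample set the safety-margin fits consume.
#'
#' @param library a `model_library`.
#' @param ensemble a `drive_ensemble`.
#' @param estimator one of `"library"`, `"selected"`, `"multi_selected"`,
#'   `"generic"`.
#' @param table a [build_selection_table()] (required for the selection
#'   estimators; built on the fly if missing).
#' @param generic a [body_model()] (required for `estimator = "generic"`).
#' @return A [paired_samples()] frame with one row per (model, drive).
#' @export
cohort_pairs <- function(library, ensemble,
                         estimator = c("library", "selected",
                                       "multi_selected", "generic"),
                         table = NULL, generic = NULL) {
  estimator <- match.arg(estimator)
  ids <- names(library)
  S <- t(ensemble$s)  # 8 x n_drives
  nd <- ncol(S)
  # true peak SAR of every model for every drive, one pass
  P <- vapply(library, function(bm) {
    vals <- sar_all_voxels(bm, S)
    apply(vals, 2L, max)
  }, numeric(nd))           # n_drives x n_models
  if (estimator %in% c("selected", "multi_selected") && is.null(table))
    table <- build_selection_table(library)
  if (estimator == "generic") {
    if (is.null(generic)) stop("`generic` model required", call. = FALSE)
    g <- apply(sar_all_voxels(generic, S), 2L, max)
  }
  est_tag <- switch(estimator, library = "ML", selected = "MS",
                    multi_selected = "MMS", generic = "GM")
  out <- vector("list", length(ids))
  for (mi in seq_along(ids)) {
    m <- ids[mi]
    psar_e <- switch(estimator,
      library = apply(P[, setdiff(ids, m), drop = FALSE], 1L, max),
      selected = P[, selection_lookup(table, m)[1L]],
      multi_selected = apply(P[, table$a_sets[[m]], drop = FALSE], 1L, max),
      generic = g)
    out[[mi]] <- paired_samples(psar_e, P[, m], model_id = m,
                                drive_id = seq_len(nd),
                                mode_tag = ensemble$mode_tag,
                                estimator_tag = est_tag)
  }
  res <- do.call(rbind, lapply(out, as.data.frame))
  res <- paired_samples(res$psar_e, res$psar_t, model_id = res$model_id,
                        drive_id = res$drive_id, mode_tag = res$mode_tag,
                        estimator_tag = est_tag)
  res
}

#' Write or read a selection table as structured text
#' @param table a `selection_table`.
#' @param path file path.
#' @export
write_selection_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# selection_table a_size: %d wc_method: %s seed: %d",
                     table$a_size, table$wc_method, table$seed), con)
  for (m in names(table$ranking)) {
    r <- table$ranking[[m]]
    writeLines(sprintf("model: %s", m), con)
    writeLines(sprintf("ranked: %s", paste(r, collapse = " ")), con)
    writeLines(sprintf("rmse: %s",
                       paste(fmt_num(table$rmse[m, r]), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_selection_table
#' @export
read_selection_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  a_size <- as.integer(sub(".*a_size:\\s*(\\d+).*", "\\1", hdr))
  wc_method <- sub(".*wc_method:\\s*(\\S+).*", "\\1", hdr)
  seed <- as.integer(sub(".*seed:\\s*(\\d+).*", "\\1", hdr))
  lines <- lines[-1L]
  ids <- sub("^model:\\s*", "", lines[grepl("^model:", lines)])
  nm <- length(ids)
  rmse <- matrix(0, nm, nm, dimnames = list(ids, ids))
  ranking <- a_sets <- stats::setNames(vector("list", nm), ids)
  for (k in seq_len(nm)) {
    base <- (k - 1L) * 3L
    m <- sub("^model:\\s*", "", lines[base + 1L])
    r <- strsplit(sub("^ranked:\\s*", "", lines[base + 2L]), "\\s+")[[1L]]
    vals <- as.numeric(strsplit(sub("^rmse:\\s*", "", lines[base + 3L]),
                                "\\s+")[[1L]])
    ranking[[m]] <- r
    a_sets[[m]] <- r[seq_len(min(a_size, length(r)))]
    rmse[m, r] <- vals
  }
  structure(list(rmse = rmse, ranking = ranking, a_sets = a_sets,
                 a_size = a_size, wc_method = wc_method, seed = seed),
            class = "selection_table")
}
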