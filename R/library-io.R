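# Plain-text serialisation of model libraries and generator configs.
# One block per voxel: 8 rows of 16 columns (interleaved real/imag parts of
# the 8x8 Q-matrix), preceded by per-model header lines. Intended for small
# fixtures; libraries of realistic size are regenerated from their
# cohort_spec instead.

#' Write or read a model library as plain text
#'
#' @param library a `model_library` (see [generate_cohort()]).
#' @param path file path.
#' @export
write_model_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model_library: %d models", length(library)), con)
  for (bm in library) {
    writeLines(sprintf("model_id: %s", bm$model_id), con)
    writeLines(sprintf("grid_shape: %s", paste(bm$grid_shape, collapse = " ")), con)
    writeLines(sprintf("n_voxels: %d", n_voxels(bm)), con)
    for (v in seq_len(n_voxels(bm))) {
      writeLines(sprintf("voxel: %d", v), con)
      Q <- bm$q[, , v]
      for (i in 1:8) {
        row <- as.vector(rbind(fmt_num(Re(Q[i, ])), fmt_num(Im(Q[i, ]))))
        writeLines(paste(row, collapse = " "), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_model_library
#' @export
read_model_library <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  models <- list()
  i <- 1L
  while (i <= length(lines)) {
    stopifnot(grepl("^model_id:", lines[i]))
    model_id <- sub("^model_id:\\s*", "", lines[i])
    grid_shape <- as.integer(strsplit(sub("^grid_shape:\\s*", "", lines[i + 1L]),
                                      "\\s+")[[1L]])
    nv <- as.integer(sub("^n_voxels:\\s*", "", lines[i + 2L]))
    i <- i + 3L
    q <- array(0i, c(8L, 8L, nv))
    for (v in seq_len(nv)) {
      stopifnot(grepl("^voxel:", lines[i]))
      i <- i + 1L
      for (r in 1:8) {
        vals <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]])
        q[r, , v] <- complex(real = vals[c(TRUE, FALSE)],
                             imaginary = vals[c(FALSE, TRUE)])
        i <- i + 1L
      }
    }
    models[[model_id]] <- body_model(q, model_id, grid_shape, validate = FALSE)
  }
  structure(models, class = "model_library")
}

#' Read a generator spec from a plain-text config file
#'
#' The config is `key: value` text (YAML). Keys match the arguments of
#' [cohort_spec()] or [joint_spec()]; the `kind` key (`"cohort"` or
#' `"joint"`) selects which.
#'
#' @param path config file path.
#' @return A `cohort_spec` or `joint_spec`.
#' @export
read_spec_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  kind <- cfg$kind %||% stop("config needs a `kind: cohort` or `kind: joint` key",
                             call. = FALSE)
  cfg$kind <- NULL
  switch(kind,
         cohort = do.call(cohort_spec, cfg),
         joint = do.call(joint_spec, cfg),
         stop(sprintf("unknown config kind '%s'", kind), call. = FALSE))
}
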