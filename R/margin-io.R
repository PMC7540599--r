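# Structured-text serialisation of fitted margins. Numbers are written
# with 17 significant digits so a write/read round trip is bit-exact.

#' Write or read a fitted safety margin as structured text
#'
#' All margin types ([lsf()], [upper_bound()], [capped_lsf()], [csm()])
#' serialise to a `key: value` text document; arrays are whitespace
#' separated. Reading restores an object identical to the one written.
#'
#' @param margin a fitted `sar_margin`.
#' @param path file path.
#' @export
write_margin <- function(margin, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  arr <- function(x) paste(fmt_num(x), collapse = " ")
  if (inherits(margin, "sar_lsf")) {
    w("type: lsf")
    w("value: %s", fmt_num(margin$value))
    w("method: %s", margin$method)
    w("n: %d", margin$n)
    w("outliers_removed: %d", margin$outliers_removed)
    w("fence: %s", fmt_num(margin$fence))
  } else if (inherits(margin, "sar_upper_bound")) {
    w("type: upper_bound")
    w("value: %s", fmt_num(margin$value))
    w("level: %s", fmt_num(margin$level))
    w("n: %d", margin$n)
    w("mode_tag: %s", margin$mode_tag)
  } else if (inherits(margin, "sar_capped_lsf")) {
    w("type: capped_lsf")
    w("lsf_value: %s", fmt_num(margin$lsf$value))
    w("lsf_method: %s", margin$lsf$method)
    w("lsf_n: %d", margin$lsf$n)
    w("lsf_outliers_removed: %d", margin$lsf$outliers_removed)
    w("lsf_fence: %s", fmt_num(margin$lsf$fence))
    w("ub_value: %s", fmt_num(margin$ub$value))
    w("ub_level: %s", fmt_num(margin$ub$level))
    w("ub_n: %d", margin$ub$n)
    w("ub_mode_tag: %s", margin$ub$mode_tag)
  } else if (inherits(margin, "sar_csm")) {
    w("type: csm")
    w("epsilon: %s", fmt_num(margin$epsilon))
    w("delta: %s", fmt_num(margin$delta))
    w("K: %d", margin$K)
    w("n: %d", margin$n)
    w("seed: %d", margin$seed)
    w("gamma_shape: %s", fmt_num(margin$gamma_shape))
    w("gamma_rate: %s", fmt_num(margin$gamma_rate))
    w("bic_k: %s", paste(names(margin$bic), collapse = " "))
    w("bic: %s", arr(as.numeric(margin$bic)))
    w("gmm_weights: %s", arr(margin$gmm$weights))
    w("gmm_means: %s", arr(as.numeric(margin$gmm$means)))
    w("gmm_covs: %s", arr(unlist(lapply(margin$gmm$covs, as.numeric))))
    w("e_nodes: %s", arr(margin$e_nodes))
    w("corrected: %s", arr(margin$corrected))
  } else stop("unknown margin type", call. = FALSE)
  invisible(path)
}

#' @rdname write_margin
#' @export
read_margin <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else "", "")
  g <- function(k) vals[match(k, keys)]
  num <- function(k) as.numeric(g(k))
  int <- function(k) as.integer(g(k))
  arr <- function(k) as.numeric(strsplit(g(k), "\\s+")[[1L]])
  type <- g("type")
  switch(type,
    lsf = structure(list(value = num("value"), method = g("method"),
                         n = int("n"),
                         outliers_removed = int("outliers_removed"),
                         fence = num("fence")),
                    class = c("sar_lsf", "sar_margin")),
    upper_bound = structure(list(value = num("value"), level = num("level"),
                                 n = int("n"), mode_tag = g("mode_tag")),
                            class = c("sar_upper_bound", "sar_margin")),
    capped_lsf = capped_lsf(
      structure(list(value = num("lsf_value"), method = g("lsf_method"),
                     n = int("lsf_n"),
                     outliers_removed = int("lsf_outliers_removed"),
                     fence = num("lsf_fence")),
                class = c("sar_lsf", "sar_margin")),
      structure(list(value = num("ub_value"), level = num("ub_level"),
                     n = int("ub_n"), mode_tag = g("ub_mode_tag")),
                class = c("sar_upper_bound", "sar_margin"))),
    csm = {
      k_names <- strsplit(g("bic_k"), "\\s+")[[1L]]
      K <- int("K")
      nw <- length(arr("gmm_weights"))
      covs_flat <- arr("gmm_covs")
      covs <- lapply(seq_len(nw), function(j)
        matrix(covs_flat[(j - 1L) * 4L + 1:4], 2L, 2L))
      structure(list(e_nodes = arr("e_nodes"), corrected = arr("corrected"),
                     epsilon = num("epsilon"), delta = num("delta"), K = K,
                     bic = stats::setNames(arr("bic"), k_names),
                     gamma_shape = num("gamma_shape"),
                     gamma_rate = num("gamma_rate"),
                     gmm = list(weights = arr("gmm_weights"),
                                means = matrix(arr("gmm_means"), nw, 2L),
                                covs = covs),
                     n = int("n"), seed = int("seed")),
                class = c("sar_csm", "sar_margin"))
    },
    stop(sprintf("unknown margin type '%s'", type), call. = FALSE))
}
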