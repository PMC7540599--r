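# Surrogate cohorts and the parametric pair generator with its analytic
# conditional-quantile oracle.

test_that("degenerate cohort (zero spread) gives identical models", {
  lib <- generate_cohort(cohort_spec(n_models = 3, n_voxels = 4,
                                     intersubject_sd = 0,
                                     intrasubject_jitter = 0, seed = 2))
  expect_equal(lib[[1]]$q, lib[[2]]$q)
  s <- random_drive(1)
  truth <- psar_true(lib[[1]], s)$value
  expect_equal(estimate_library(lib, "model01", s), truth)
})

test_that("cohort Q-matrices are PSD by construction and pairs positive", {
  lib <- generate_cohort(cohort_spec(n_models = 3, n_voxels = 5,
                                     intersubject_sd = 0.5, seed = 6))
  for (bm in lib) for (v in seq_len(n_voxels(bm))) {
    ev <- eigen(bm$q[, , v], symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9 * max(ev))
  }
  de <- sample_random_phase(20, seed = 1)
  pairs <- cohort_pairs(lib, de, estimator = "library")
  expect_true(all(pairs$psar_t > 0))
  expect_true(all(pairs$psar_e > 0))
  expect_equal(nrow(pairs), 3 * 20)
})

test_that("between-model pSAR correlation decreases with intersubject_sd", {
  # monotone over sd in {0.05, 0.2, 0.5}, averaged over 3 seeds
  mean_cor <- function(sd_val) {
    cors <- vapply(1:3, function(seed) {
      lib <- generate_cohort(cohort_spec(n_models = 3, n_voxels = 10,
                                         intersubject_sd = sd_val,
                                         intrasubject_jitter = 0.02,
                                         seed = seed))
      de <- sample_random_phase(80, seed = seed)
      S <- t(de$s)
      p1 <- apply(sarmargin:::sar_all_voxels(lib[[1]], S), 2, max)
      p2 <- apply(sarmargin:::sar_all_voxels(lib[[2]], S), 2, max)
      cor(p1, p2)
    }, 0)
    mean(cors)
  }
  cs <- vapply(c(0.05, 0.2, 0.5), mean_cor, 0)
  expect_true(all(diff(cs) < 0))
})

test_that("generate_joint_pairs is seed-deterministic and family-faithful", {
  sp <- joint_spec(rho = 0.9, n_samples = 2000, seed = 5)
  expect_identical(generate_joint_pairs(sp), generate_joint_pairs(sp))

  ind <- generate_joint_pairs(joint_spec("independent", n_samples = 1e5,
                                         seed = 3))
  expect_lt(abs(cor(ind$psar_e, ind$psar_t)), 0.01)

  gm <- generate_joint_pairs(joint_spec(
    "gaussian_mixture", weights = c(0.6, 0.4),
    means = rbind(c(1.5, 1.5), c(2.5, 2.8)),
    covs = list(diag(2) * 0.04, matrix(c(0.09, 0.05, 0.05, 0.09), 2)),
    n_samples = 5000, seed = 4))
  expect_true(all(gm$psar_e > 0 & gm$psar_t > 0))
  expect_equal(nrow(gm), 5000)
})

test_that("closed-form conditional quantile matches Monte Carlo", {
  sp <- joint_spec(rho = 0.8, sdlog = c(0.35, 0.35), n_samples = 10, seed = 1)
  big <- generate_joint_pairs(joint_spec(rho = 0.8, n_samples = 1e6, seed = 42))
  for (e0 in c(1.0, 1.35, 2.0)) {
    in_bin <- abs(big$psar_e - e0) < 0.02
    mc_q <- quantile(big$psar_t[in_bin], 0.95, names = FALSE)
    cf_q <- closed_form_conditional_quantile(sp, e0, level = 0.95)
    expect_equal(cf_q, mc_q, tolerance = 0.02)
  }
  # rho = 0 reduces to the independent family's marginal quantile
  sp0 <- joint_spec(rho = 0, n_samples = 10, seed = 1)
  spI <- joint_spec("independent", n_samples = 10, seed = 1)
  expect_equal(closed_form_conditional_quantile(sp0, 1.7, 0.999),
               closed_form_conditional_quantile(spI, 0.4, 0.999))
  expect_equal(closed_form_conditional_quantile(spI, 2.2, 0.999),
               qlnorm(0.999, 0.3, 0.35))
})

test_that("spec validation catches invalid parameters", {
  expect_error(cohort_spec(n_models = 1), ">= 2")
  expect_error(cohort_spec(intersubject_sd = -1), ">= 0")
  expect_error(joint_spec(rho = 1.2), "rho")
  expect_error(joint_spec("gaussian_mixture", weights = c(0.5, 0.4),
                          means = rbind(c(1, 1), c(2, 2)),
                          covs = list(diag(2), diag(2))), "sum to 1")
  expect_error(closed_form_conditional_quantile(
    joint_spec("gaussian_mixture", weights = 1, means = rbind(c(1, 1)),
               covs = list(diag(2) * 0.1)), 1), "closed-form")
})

test_that("pairs round-trip through tab-separated text", {
  p <- generate_joint_pairs(joint_spec(n_samples = 50, seed = 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(p, path)
  back <- read_pairs(path)
  expect_equal(back$psar_e, p$psar_e)
  expect_equal(back$psar_t, p$psar_t)
  expect_equal(attr(back, "estimator_tag"), attr(p, "estimator_tag"))
})

test_that("generator specs load from key-value config text", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("kind: joint", "family: bivariate_lognormal", "rho: 0.7",
               "n_samples: 123", "seed: 9"), path)
  sp <- read_spec_config(path)
  expect_s3_class(sp, "joint_spec")
  expect_equal(sp$rho, 0.7)
  expect_equal(sp$n_samples, 123L)

  path2 <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("kind: cohort", "n_models: 4", "n_voxels: 6", "seed: 2"), path2)
  sp2 <- read_spec_config(path2)
  expect_s3_class(sp2, "cohort_spec")
  expect_equal(sp2$n_models, 4L)
})
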