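# Shared fixture builders; everything is generated in code under fixed seeds.

# One random complex Hermitian PSD 8x8 matrix, Q = A^H A.
random_psd_q <- function(seed, rank = 8L, scale = 1) {
  set.seed(seed)
  A <- matrix(complex(real = rnorm(rank * 8L), imaginary = rnorm(rank * 8L)),
              rank, 8L) * scale
  Conj(t(A)) %*% A
}

random_drive <- function(seed) {
  set.seed(seed)
  drive_vector(complex(real = rnorm(8), imaginary = rnorm(8)))
}

# A small random body model.
random_model <- function(seed, n_vox = 10L, model_id = "fix") {
  q <- array(0i, c(8L, 8L, n_vox))
  for (v in seq_len(n_vox)) q[, , v] <- random_psd_q(seed * 1000L + v)
  body_model(q, model_id)
}

# Brute-force quadratic form: element-wise double loop.
sar_double_loop <- function(Q, s) {
  acc <- 0 + 0i
  for (i in 1:8) for (j in 1:8) acc <- acc + Conj(s[i]) * Q[i, j] * s[j]
  Re(acc)
}

toy_identity_cohort <- function(n_models = 4L, n_vox = 3L) {
  q <- array(0i, c(8L, 8L, n_vox))
  for (v in seq_len(n_vox)) q[, , v] <- v * diag(8) + 0i
  models <- lapply(seq_len(n_models), function(m)
    body_model(q, sprintf("model%02d", m)))
  names(models) <- vapply(models, `[[`, "", "model_id")
  structure(models, class = "model_library")
}
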