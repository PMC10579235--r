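# generators for model-recovery oracles, shared across test files

# per-condition trial arrays with a planted low-rank signal
planted_rank_data <- function(seed, rank = 4L, snr = 3, U = 20L, T = 150L,
                              n_cond = 2L, n_tr = 60L, noise_sd = 1) {
  set.seed(seed)
  load <- qr.Q(qr(matrix(rnorm(U * rank), U, rank)))
  lapply(seq_len(n_cond), function(ci) {
    basis <- qr.Q(qr(matrix(rnorm(T * rank), T, rank))) %*%
      diag(seq(2, 1, length.out = rank)) * sqrt(T)
    sig <- 20 + snr * basis %*% t(load)
    arr <- array(NA_real_, c(T, U, n_tr))
    for (k in seq_len(n_tr)) {
      arr[, , k] <- sig + matrix(rnorm(T * U, sd = noise_sd), T, U)
    }
    arr
  })
}

# latent trajectories evolving as X(t+1) = X(t) (I + J) + noise
planted_lds <- function(J, n_trials = 10L, T = 30L, seed = 1L,
                        noise_sd = 0) {
  set.seed(seed)
  d <- nrow(J)
  A <- diag(d) + J
  lapply(seq_len(n_trials), function(m) {
    L <- matrix(NA_real_, T, d)
    L[1L, ] <- rnorm(d)
    for (t in 2:T) {
      L[t, ] <- L[t - 1L, ] %*% A + rnorm(d, sd = noise_sd)
    }
    L
  })
}
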