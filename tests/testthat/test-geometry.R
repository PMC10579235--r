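# rate_tensor with given values, no masking (internal test fixture)
fake_tensor <- function(vals_list, time_ms = NULL) {
  n_lev <- length(vals_list) / 2L
  arr <- simplify2array(vals_list)
  if (is.null(time_ms)) time_ms <- seq_len(nrow(vals_list[[1L]])) - 1
  cells <- data.frame(
    level = rep(sprintf("l%d", seq_len(n_lev)), 2L),
    level_index = rep(seq_len(n_lev), 2L),
    level_value = rep(seq_len(n_lev), 2L),
    choice = rep(c("left", "right"), each = n_lev),
    end_ms = max(time_ms) + 1, n_trials = 1L)
  structure(list(values = arr, time_ms = time_ms, cells = cells,
                 unit_ids = sprintf("u%d", seq_len(ncol(vals_list[[1L]]))),
                 grouping = "test", event = "checkerboard",
                 trial_rows = replicate(length(vals_list), 1L,
                                        simplify = FALSE)),
            class = "rate_tensor")
}

test_that("soft normalization centers and scales by sqrt(99th percentile)", {
  v1 <- cbind(rep(7, 50), rep(25, 50), seq(0, 10, length.out = 50))
  v2 <- cbind(rep(7, 50), rep(25, 50), 4 * seq(0, 10, length.out = 50))
  tens <- fake_tensor(list(v1, v2))
  st <- soft_normalize_stack(tens)
  # constant-rate units become zero columns
  expect_true(all(st$x[, 1L] == 0))
  expect_true(all(st$x[, 2L] == 0))
  # a unit whose 99th percentile is 25 is divided by 5
  expect_equal(st$normalizers[2L], 5)
  expect_equal(colMeans(st$x), rep(0, 3), tolerance = 1e-12)
  # scaling rates by a^2 scales the normalized column by a
  tens4 <- fake_tensor(list(cbind(v1[, 3L], 4 * v1[, 3L]),
                            cbind(v2[, 3L], 4 * v2[, 3L])))
  st4 <- soft_normalize_stack(tens4)
  expect_equal(st4$x[, 2L], 2 * st4$x[, 1L], tolerance = 1e-10)
})

test_that("PCA recovers rank and reconstructs exactly", {
  set.seed(1)
  base <- matrix(rnorm(200), 100, 2)
  X <- base %*% matrix(rnorm(2 * 8), 2, 8)
  pc <- fit_pca(X)
  expect_true(all(pc$eigenvalues[3:8] < 1e-10))
  # full reconstruction on the centered scale
  Xc <- scale(X, center = TRUE, scale = FALSE)
  scores <- Xc %*% pc$loadings
  expect_equal(scores %*% t(pc$loadings), Xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # loading sign convention: largest-magnitude element positive
  expect_true(all(apply(pc$loadings, 2L,
                        function(v) v[which.max(abs(v))] >= 0)))
  expect_error(fit_pca(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("isotropic data spreads variance evenly", {
  set.seed(2)
  pc <- fit_pca(matrix(rnorm(20000 * 10), 20000, 10))
  expect_lt(max(pc$explained_var) / min(pc$explained_var), 1.2)
})

test_that("projection reproduces the PCA scores of the fitting data", {
  s <- small_session(seed = 17L, n_trials = 60L)
  tens <- condition_average(s, grouping = "coherence")
  st <- soft_normalize_stack(tens)
  pc <- fit_pca(st)
  ts <- project(tens, pc, n_dims = 4L)
  scores <- st$x %*% pc$loadings[, 1:4]
  got <- do.call(rbind, ts$trajectories)
  expect_equal(got, scores, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(project(tens, pc, n_dims = 999L), "n_dims")
})

test_that("projection is affine in the input rates", {
  v <- replicate(4, cbind(seq(0, 5, length.out = 30),
                          rnorm(30, 10)), simplify = FALSE)
  tens <- fake_tensor(v)
  pc <- fit_pca(soft_normalize_stack(tens))
  pc$col_means <- rep(0, 2)     # disable re-centering/normalization
  pc$normalizers <- rep(1, 2)
  ts1 <- project(tens, pc, n_dims = 2L)
  tens2 <- tens
  tens2$values <- tens$values * 3
  ts2 <- project(tens2, pc, n_dims = 2L)
  expect_equal(ts2$trajectories[[1L]], 3 * ts1$trajectories[[1L]],
               tolerance = 1e-10)
})

test_that("signal-dimension estimation separates signal from noise", {
  # duplicate trials: no noise, so the 3-SEM rule never fires
  dup <- planted_rank_data(1, noise_sd = 0, n_tr = 6L, T = 40L, U = 8L)
  est <- estimate_signal_dims(dup, n_boot = 10L, seed = 1L)
  expect_lt(max(est$noise_eigs), 1e-12)
  expect_equal(est$n_signal_dims, 8L)
  # planted rank 4 recovered
  for (s in 1:3) {
    est <- estimate_signal_dims(planted_rank_data(s), n_boot = 50L, seed = s)
    expect_equal(est$n_signal_dims, 4L)
  }
  # pure noise: zero dimensions
  est0 <- estimate_signal_dims(planted_rank_data(4, snr = 0), n_boot = 50L,
                               seed = 4L)
  expect_equal(est0$n_signal_dims, 0L)
  expect_error(estimate_signal_dims(list(array(0, c(5, 2, 1)))), "fewer")
})

test_that("spectra are non-increasing and SEMs finite", {
  est <- estimate_signal_dims(planted_rank_data(5), n_boot = 20L, seed = 5L)
  expect_true(all(diff(est$signal_plus_noise_eigs) <= 1e-12))
  expect_true(all(diff(est$noise_eigs) <= 1e-12))
  expect_true(all(is.finite(est$eig_sems)))
})

test_that("bootstrap trajectories are deterministic and match the point
           estimate when resampling is disabled", {
  s <- small_session(seed = 23L, n_trials = 60L, n_increased = 8L,
                     n_decreased = 4L, n_perimovement = 2L,
                     coherence_levels = c(8, 30, 90))
  point <- project(condition_average(s, grouping = "coherence"),
                   fit_pca(soft_normalize_stack(
                     condition_average(s, grouping = "coherence"))),
                   n_dims = 3L)
  b0 <- bootstrap_trajectories(s, grouping = "coherence", n_boot = 1L,
                               seed = 1L, n_dims = 3L, resample = FALSE)
  expect_equal(b0[[1L]]$trajectories, point$trajectories, tolerance = 1e-8)
  b1 <- bootstrap_trajectories(s, grouping = "coherence", n_boot = 2L,
                               seed = 5L, n_dims = 3L)
  b2 <- bootstrap_trajectories(s, grouping = "coherence", n_boot = 2L,
                               seed = 5L, n_dims = 3L)
  expect_identical(b1[[2L]]$trajectories, b2[[2L]]$trajectories)
})

test_that("bootstrap spread shrinks roughly as 1/sqrt(trials)", {
  coord_sd <- function(n_trials, seed) {
    s <- small_session(seed = seed, n_trials = n_trials, n_increased = 6L,
                       n_decreased = 3L, n_perimovement = 2L,
                       coherence_levels = c(8, 30, 90))
    bs <- bootstrap_trajectories(s, grouping = "coherence", n_boot = 25L,
                                 seed = 2L, n_dims = 3L)
    # spread of a rotation-invariant statistic (PCA is refit per bootstrap,
    # so raw coordinates are only defined up to rotation)
    sd(vapply(bs, function(ts)
      mean(cs_from_trajset(ts, 1L)$cs[1:100]), numeric(1)))
  }
  r <- coord_sd(56L, 41L) / coord_sd(224L, 42L)
  expect_gt(r, 1.2)   # ~2 expected under CLT scaling
  expect_lt(r, 3.5)
})
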