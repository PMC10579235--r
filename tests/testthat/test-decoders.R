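# session whose bin-(0,20) spike counts determine RT exactly
linear_rt_session <- function(n = 48L) {
  k <- rep(0:3, length.out = n)
  rt <- 300 + 20 * k
  spikes <- list(
    lapply(k, function(ki) rep(1005, ki)),          # counts encode RT
    lapply(seq_len(n), function(i) numeric(0))      # silent second unit
  )
  manual_session(spikes, rt_ms = rt)
}

test_that("RT regression finds an exact linear code", {
  s <- linear_rt_session()
  res <- rt_decoder(s, bin_ms = 20, window = c(0, 20), n_shuffles = 50L,
                    seed = 2L)
  expect_equal(res$bins$r2, 1, tolerance = 1e-10)
  expect_true(res$bins$r2 > res$bins$null_p99)
})

test_that("null spiking rarely beats the shuffle threshold", {
  set.seed(4)
  n <- 60L
  spikes <- lapply(1:5, function(u)
    lapply(seq_len(n), function(i) sort(runif(rpois(1, 4), 1000, 1400))))
  s <- manual_session(spikes, rt_ms = runif(n, 300, 900))
  res <- rt_decoder(s, bin_ms = 20, window = c(0, 400), n_shuffles = 200L,
                    seed = 3L)
  expect_gte(mean(res$bins$r2 < res$bins$null_p99), 0.9)
})

test_that("shuffle nulls are seed-deterministic", {
  s <- linear_rt_session()
  r1 <- rt_decoder(s, bin_ms = 20, window = c(0, 20), n_shuffles = 50L,
                   seed = 7L)
  r2 <- rt_decoder(s, bin_ms = 20, window = c(0, 20), n_shuffles = 50L,
                   seed = 7L)
  expect_identical(r1$bins, r2$bins)
})

test_that("the choice decoder separates a clean margin and stays at
           chance on random labels", {
  n <- 60L
  choice <- rep(c("left", "right"), length.out = n)
  spikes <- list(lapply(seq_len(n), function(i)
    if (choice[i] == "left") 1002 + 0:4 else numeric(0)))
  s <- manual_session(spikes, rt_ms = rep(400, n), choice = choice)
  res <- choice_decoder(s, bin_ms = 20, window = c(0, 20),
                        n_shuffles = 30L, seed = 5L)
  expect_gte(res$bins$accuracy, 0.95)
  # random labels: accuracy within the null band around 0.5
  set.seed(6)
  s2 <- s
  s2$trials$choice <- sample(choice)
  res2 <- choice_decoder(s2, bin_ms = 20, window = c(0, 20),
                         n_shuffles = 100L, seed = 6L)
  expect_lt(res2$bins$accuracy, res2$bins$null_p99)
  expect_gt(res2$bins$accuracy, 0.25)
  expect_lt(res2$bins$accuracy, 0.75)
})

test_that("decoding accuracy is invariant to per-unit count rescaling", {
  s <- small_session(seed = 25L, n_trials = 60L)
  res1 <- choice_decoder(s, bin_ms = 200, window = c(0, 200),
                         n_shuffles = 2L, seed = 9L)
  # doubling every spike (two spikes per original) rescales counts by 2
  s2 <- s
  s2$spikes <- lapply(s$spikes, function(sl) lapply(sl, function(st)
    sort(c(st, st))))
  res2 <- choice_decoder(s2, bin_ms = 200, window = c(0, 200),
                         n_shuffles = 2L, seed = 9L)
  expect_equal(res2$bins$accuracy, res1$bins$accuracy, tolerance = 1e-10)
})

test_that("the outcome decoder uses the overlapping-bin layout", {
  s <- small_session(seed = 27L, n_trials = 120L)
  res <- outcome_decoder(s, window = c(-100, 100), n_shuffles = 2L,
                         seed = 3L)
  expect_equal(diff(res$bins$bin_start_ms)[1L], 25)
  expect_equal(nrow(res$bins), (200 - 50) / 25 + 1)
  expect_true(all(res$bins$accuracy >= 0 & res$bins$accuracy <= 1))
})

test_that("per-neuron regression recovers an exact choice effect", {
  n <- 40L
  choice <- rep(c("left", "right"), length.out = n)
  spikes <- list(lapply(seq_len(n), function(i)
    if (choice[i] == "left") 1005 + (0:3) * 10 else 1005))
  s <- manual_session(spikes, rt_ms = rep(400, n), choice = choice)
  res <- per_neuron_regression(s, target = "choice", bin_ms = 50,
                               window = c(0, 50))
  # FR: left 80 sp/s (4 spikes), right 20 sp/s (1 spike); choice coded 1/0
  expect_equal(res$beta[1L, 1L], 60, tolerance = 1e-10)
  expect_true(res$significant[1L, 1L])
})

test_that("the 99% confidence intervals are calibrated on null units", {
  set.seed(31)
  n_units <- 1000L; n <- 150L
  spikes <- lapply(seq_len(n_units), function(u)
    lapply(seq_len(n), function(i) sort(runif(rpois(1, 1.5), 1000, 1100))))
  rt <- runif(n, 300, 700)
  s <- manual_session(spikes, rt_ms = rt)
  res <- per_neuron_regression(s, target = "rt", bin_ms = 50,
                               window = c(0, 100))
  fp <- mean(res$fraction_significant)
  expect_lt(fp, 0.01 + 3 * sqrt(0.01 * 0.99 / n_units))
  expect_gt(fp, 0.0005)
})
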