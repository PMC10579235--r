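test_that("simulate_rt matches the gamma RT model", {
  rt <- simulate_rt(1e5, seed = 3L)
  expect_true(all(rt > 200))
  # analytic mean 200 + 100*5*0.5 = 450, SD 100*sqrt(5*0.25) = 111.8
  se_mean <- 111.80 / sqrt(1e5)
  expect_lt(abs(mean(rt) - 450), 3 * se_mean)
  se_sd <- 111.80 / sqrt(2 * 1e5)
  expect_lt(abs(sd(rt) - 111.80), 3 * se_sd)
  expect_gt(simulate_rt(1, seed = 1L), 200)
  expect_error(simulate_rt(0))
})

test_that("increased-unit rate profile has the documented structure", {
  cfg <- sim_config()
  trial <- list(rt_ms = 500, choice = "left")
  draws <- list(chosen = TRUE, rc1 = 8, rc2 = 2.5, base_neuron = 1,
                jitter = 0, rt_covary = FALSE)
  p <- build_rate_profile("increased", trial, cfg, draws)
  t_lag <- 100 + 0.2 * 500
  pre <- p$times_ms < t_lag
  expect_true(all(p$rate[pre] == 5))          # baseline only before the lag
  # at movement onset: 5 + rc1 * (1 - t_lag/RT) + 15 * (RT - t_lag)/1000
  at_mv <- p$rate[p$times_ms == 500]
  expect_equal(at_mv, 5 + 8 * (500 - t_lag) / 500 + 15 * (500 - t_lag) / 1000,
               tolerance = 1e-10)
  # rates are held after movement onset
  expect_true(all(p$rate[p$times_ms >= 500] == at_mv))
  # non-chosen direction subtracts the smaller gain
  p2 <- build_rate_profile("increased", trial, cfg,
                           modifyList(draws, list(chosen = FALSE)))
  expect_true(all(p2$rate[pre] == 5))
  expect_lt(p2$rate[p2$times_ms == 400], 5 + 15 * (400 - t_lag) / 1000)
})

test_that("decreased units are the matched increased profile minus 10", {
  cfg <- sim_config()
  trial <- list(rt_ms = 430, choice = "right")
  draws <- list(chosen = TRUE, rc1 = 11, rc2 = 3, base_neuron = 2,
                jitter = 0, rt_covary = FALSE)
  inc <- build_rate_profile("increased", trial, cfg, draws)
  dec <- build_rate_profile("decreased", trial, cfg, draws)
  expect_equal(dec$rate, pmax(inc$rate - 10, 0), tolerance = 1e-12)
})

test_that("sim3 designated units carry the RT-dependent prestimulus rate", {
  cfg <- sim_config(hypothesis = "sim3_rt_covariation")
  trial <- list(rt_ms = 450, choice = "left")
  draws <- list(chosen = TRUE, rc1 = 8, rc2 = 2.5, base_neuron = 0.25,
                jitter = 0, rt_covary = TRUE)
  p <- build_rate_profile("increased", trial, cfg, draws)
  pre <- p$times_ms < 0
  # (2 + 0.25) / 0.45 s = 5 spikes/s, replacing the baseline
  expect_equal(unique(p$rate[pre]), 5, tolerance = 1e-12)
  expect_error(build_rate_profile("bogus", trial, cfg, draws), "unknown")
})

test_that("generate_spikes draws an inhomogeneous Poisson process", {
  expect_identical(generate_spikes(rep(0, 1000)), numeric(0))
  expect_error(generate_spikes(c(1, -1, 2)), "rate")
  set.seed(5)
  counts <- replicate(3000, length(generate_spikes(rep(20, 1000),
                                                   seq_len(1000) - 1)))
  se <- sqrt(20 / 3000)
  expect_lt(abs(mean(counts) - 20), 3 * se)
  # spike times live on the supplied clock
  st <- generate_spikes(rep(50, 500), seq(-200, 299))
  expect_true(all(st >= -200 & st < 300))
})

test_that("rescaled inter-spike intervals are unit-rate exponential", {
  set.seed(8)
  pass <- replicate(100, {
    tms <- seq(0, 1999)
    rate <- 30 + 20 * sin(tms / 150)           # inhomogeneous intensity
    st <- generate_spikes(rate, tms)
    cum <- cumsum(rate) / 1000
    lam <- approx(tms, cum, xout = st)$y       # rescaled spike times
    stats::ks.test(diff(lam), "pexp", 1)$p.value > 0.01
  })
  expect_gte(mean(pass), 0.95)
})

test_that("simulate_session is deterministic and correctly sized", {
  s1 <- small_session(seed = 9L)
  s2 <- simulate_session(sim_config(hypothesis = "sim1_no_prestim",
                                    seed = 9L, n_trials = 80L,
                                    n_increased = 16L, n_decreased = 8L,
                                    n_perimovement = 4L))
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$spikes, s2$spikes)
  expect_equal(nrow(s1$units), 28L)
  expect_equal(sum(s1$trials$choice == "left"), 40L)
  # spikes stay inside the simulated trial window
  for (u in seq_along(s1$spikes)) {
    for (i in seq_along(s1$spikes[[u]])) {
      rel <- s1$spikes[[u]][[i]] - s1$trials$checkerboard_onset_ms[i]
      # the last 1 ms rate bin starts at rt + 100, so spikes may land in it
      expect_true(all(rel >= -600 & rel <= s1$trials$rt_ms[i] + 101))
    }
  }
})

test_that("sim3 flags exactly the configured fraction of units", {
  s <- small_session("sim3_rt_covariation", seed = 12L)
  expect_equal(mean(s$units$rt_covary), round(0.2 * 28) / 28)
})

test_that("sim1 prestimulus rates are uncorrelated with RT", {
  s <- small_session(seed = 31L, n_trials = 120L, n_increased = 40L,
                     n_decreased = 20L, n_perimovement = 10L)
  rt <- s$trials$rt_ms
  n_perm <- 200L
  set.seed(2)
  perms <- replicate(n_perm, sample(rt))
  ok <- vapply(seq_along(s$spikes), function(u) {
    pre <- vapply(seq_along(s$spikes[[u]]), function(i)
      sum(s$spikes[[u]][[i]] - s$trials$checkerboard_onset_ms[i] < 0 &
            s$spikes[[u]][[i]] - s$trials$checkerboard_onset_ms[i] >= -600),
      numeric(1))
    if (sd(pre) == 0) return(TRUE)
    r <- abs(cor(pre, rt))
    null_r <- apply(perms, 2L, function(p) abs(cor(pre, p)))
    r <= quantile(null_r, 0.99)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
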