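test_that("the choice-selectivity curve is a pointwise distance", {
  tms <- seq(-100, 100)
  a <- cbind(sin(tms / 30), cos(tms / 30), tms / 100)
  expect_true(all(cs_curve(a, a, tms)$cs == 0))
  offset <- c(2, 0, 0)
  b <- sweep(a, 2L, offset, "+")
  expect_equal(range(cs_curve(a, b, tms)$cs), c(2, 2), tolerance = 1e-12)
  # joint rotation invariance
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(cs_curve(a %*% Q, b %*% Q, tms)$cs,
               cs_curve(a, b, tms)$cs, tolerance = 1e-10)
  expect_error(cs_curve(a, b[1:50, ]), "share")
})

test_that("prestimulus choice selectivity is flat without a choice bias", {
  s <- small_session(seed = 19L, n_trials = 200L, n_increased = 30L,
                     n_decreased = 15L, n_perimovement = 5L)
  tens <- condition_average(s, grouping = "coherence")
  ts <- project(tens, fit_pca(soft_normalize_stack(tens)), n_dims = 6L)
  cur <- cs_from_trajset(ts, 4L)
  pre <- mean(cur$cs[cur$time_ms < -50])
  post <- mean(cur$cs[cur$time_ms > 250])
  expect_gt(post, 2 * pre)   # rises after the cue, flat before
})

test_that("the piecewise CS fit recovers parameters", {
  tms <- seq(-100, 400, by = 5)
  gen <- function(b, m, tl) ifelse(tms <= tl, b, m * (tms - tl)^2)
  fit <- fit_piecewise_cs(list(time_ms = tms, cs = gen(1, 1e-4, 150)))
  expect_equal(fit$b, 1, tolerance = 1e-10)
  expect_equal(fit$m, 1e-4, tolerance = 1e-10)
  expect_equal(fit$t_latency, 150)
  expect_false(fit$flat)
  # constant curve: slope ~ 0, latency at the window end, flagged flat
  fitc <- fit_piecewise_cs(list(time_ms = tms, cs = rep(2, length(tms))))
  expect_lt(abs(fitc$m), 1e-8)
  expect_equal(fitc$t_latency, max(tms))
  expect_true(fitc$flat)
})

test_that("latency is unbiased to within a grid step under noise", {
  tms <- seq(-100, 400, by = 5)
  set.seed(14)
  recovered <- replicate(50, {
    cs <- ifelse(tms <= 150, 1, 1 + 1e-4 * (tms - 150)^2) - 1 +
      rnorm(length(tms), sd = 0.05 * (1e-4 * 250^2))
    fit_piecewise_cs(list(time_ms = tms, cs = cs))$t_latency
  })
  expect_lt(abs(mean(recovered) - 150), 5)
})

test_that("piecewise recovery holds across random parameter draws", {
  tms <- seq(0, 500, by = 5)
  set.seed(15)
  for (rep in 1:20) {
    b <- runif(1, 0.1, 1)
    m <- 10^runif(1, -4.5, -3.5)
    tl <- sample(tms[20:50], 1)
    plateau <- m * (max(tms) - tl)^2
    cs <- ifelse(tms <= tl, b, m * (tms - tl)^2) +
      rnorm(length(tms), sd = 0.1 * plateau)
    fit <- fit_piecewise_cs(list(time_ms = tms, cs = cs))
    expect_lt(abs(fit$t_latency - tl), 50)
  }
})

test_that("initial-condition axis scores reflect planted structure", {
  # identical cells: centered scores are all zero
  same <- matrix(3, 9, 12)
  expect_true(all(abs(initial_condition_axis(same,
                                             order_values = 1:9)$scores)
                  < 1e-12))
  # cells planted on a line: scores reproduce the order exactly
  set.seed(16)
  dirn <- rnorm(12)
  states <- outer(seq(-4, 4), dirn) + matrix(rnorm(12), 9, 12,
                                             byrow = TRUE)
  ic <- initial_condition_axis(states, order_values = 1:9)
  expect_equal(order(ic$scores), 9:1)  # sign oriented against the ordering
  expect_equal(sqrt(sum(ic$axis^2)), 1, tolerance = 1e-12)
  states[2L, 1L] <- NA
  expect_error(initial_condition_axis(states), "rows 2")
})

test_that("partial correlations behave on planted relations", {
  set.seed(17)
  x1 <- rnorm(200); x2 <- rnorm(200)
  pc1 <- partial_corr(x1, x1, x2, n_boot = 50L)
  expect_equal(pc1$r_x1$estimate, 1, tolerance = 1e-10)
  pc0 <- partial_corr(sample(x1), x1, x2, n_boot = 50L)
  expect_lt(abs(pc0$r_x1$estimate), 0.3)
  expect_lt(abs(pc0$r_x2$estimate), 0.3)
  # orthogonal equal contributions: symmetric positive partials
  n <- 400
  a <- rep(c(-1, 1), n / 2); b <- rep(c(-1, 1), each = n / 2)
  pcs <- partial_corr(a + b, a, b, n_boot = 50L)
  expect_equal(pcs$r_x1$estimate, pcs$r_x2$estimate, tolerance = 1e-10)
  expect_gt(pcs$r_x1$estimate, 0.9)
  expect_lte(pcs$r_x1$p, 1 / 51 + 1e-12)
  expect_error(partial_corr(x1, rep(1, 200), x2), "constant")
})

test_that("cs_window_mean averages the 125-375 ms period", {
  cur <- list(time_ms = seq(0, 500), cs = seq(0, 500) / 100)
  expect_equal(cs_window_mean(cur), mean(seq(125, 375) / 100))
})
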