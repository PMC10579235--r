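test_that("a single spike smooths to the Gaussian kernel peak", {
  s <- manual_session(list(list(1000)), rt_ms = 900)  # spike at cue onset
  a <- align_and_rate(s, 1L, "checkerboard", window = c(-200, 200))
  peak <- a$rate[1L, a$time_ms == 0]
  expect_equal(peak, 1000 * dnorm(0, 0, 30), tolerance = 1e-4)
  expect_equal(a$time_ms[which.max(a$rate[1L, ])], 0)
})

test_that("no spikes give an all-zero rate", {
  s <- manual_session(list(list(numeric(0))), rt_ms = 900)
  a <- align_and_rate(s, 1L, "checkerboard", window = c(-200, 200))
  expect_true(all(a$rate[1L, ] == 0))
})

test_that("movement masking removes late spikes for checkerboard alignment", {
  # spike 20 ms before movement onset falls inside the 50 ms guard
  s <- manual_session(list(list(1000 + 480)), rt_ms = 500)
  a <- align_and_rate(s, 1L, "checkerboard", window = c(-100, 600))
  expect_equal(sum(a$counts[1L, ] * a$mask[1L, ]), 0)
  expect_true(all(a$mask[1L, a$time_ms >= 450] == 0))
  # the same spike survives movement alignment
  am <- align_and_rate(s, 1L, "movement", window = c(-100, 100))
  expect_equal(sum(am$counts[1L, ]), 1)
})

test_that("smoothing conserves spike mass away from edges", {
  s <- manual_session(list(list(c(900, 1000, 1100, 1150))), rt_ms = 900)
  a <- align_and_rate(s, 1L, "checkerboard", window = c(-400, 600))
  expect_equal(sum(a$rate[1L, ]) / 1000, 4, tolerance = 0.01)
  # a causal boxcar conserves mass the same way
  ab <- align_and_rate(s, 1L, "checkerboard", window = c(-400, 600),
                       kernel = rate_kernel("causal_boxcar", 50))
  expect_equal(sum(ab$rate[1L, ]) / 1000, 4, tolerance = 0.01)
})

test_that("averaging two identical trials reproduces the single trial", {
  spikes <- list(list(c(950, 1020, 1100), c(950, 1020, 1100)))
  s <- manual_session(spikes, rt_ms = c(480, 480),
                      choice = c("left", "left"))
  # add a right-choice pair so the grouping is complete
  spikes2 <- list(list(c(950, 1020, 1100), c(950, 1020, 1100),
                       c(980, 1060), c(980, 1060)))
  s2 <- manual_session(spikes2, rt_ms = rep(480, 4),
                       choice = c("left", "left", "right", "right"))
  tens <- condition_average(s2, grouping = "coherence")
  one <- align_and_rate(s2, 1L, "checkerboard",
                        window = c(min(tens$time_ms), max(tens$time_ms) + 1))
  keep <- !is.na(tens$values[, 1L, 1L])
  expect_equal(tens$values[keep, 1L, 1L], one$rate[1L, keep],
               tolerance = 1e-10)
})

test_that("condition windows end 25 ms before the masking boundary", {
  rts <- rep(c(450, 500, 550), 2)
  spikes <- list(replicate(6, numeric(0), simplify = FALSE))
  s <- manual_session(spikes, rt_ms = rts,
                      choice = rep(c("left", "right"), each = 3))
  tens <- condition_average(s, grouping = "coherence")
  expect_true(all(tens$cells$end_ms == 475))   # median RT 500 - 25
  expect_true(all(is.na(tens$values[tens$time_ms >= 475, 1L, 1L])))

  # RT-bin cells end at the bin's lower bound minus 25 ms
  bs <- make_rt_bins("overlapping")
  rts_all <- rep(c(bs$centers[-11L], 700), 2)   # one trial per bin
  spikes_all <- list(replicate(22, numeric(0), simplify = FALSE))
  s_all <- manual_session(spikes_all, rt_ms = rts_all,
                          choice = rep(c("left", "right"), each = 11))
  tens_rt <- condition_average(s_all, grouping = "rt_bins")
  first_cell <- which(tens_rt$cells$level_index == 1L)[1L]
  expect_equal(tens_rt$cells$end_ms[first_cell], 275)
})

test_that("condition averages are invariant to trial order", {
  s <- small_session(seed = 17L, n_trials = 60L)
  tens <- condition_average(s, grouping = "coherence")
  set.seed(3)
  perm <- sample.int(nrow(s$trials))
  s_perm <- popdyn:::subset_trials(s, perm)
  tens_perm <- condition_average(s_perm, grouping = "coherence")
  expect_equal(tens_perm$values, tens$values, tolerance = 1e-12)
})

test_that("empty condition groups raise a named error", {
  spikes <- list(replicate(2, numeric(0), simplify = FALSE))
  s <- manual_session(spikes, rt_ms = c(400, 450),
                      choice = c("left", "left"))
  expect_error(condition_average(s, grouping = "coherence"),
               "right")
})
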