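#' Configuration for the synthetic population simulator
#'
#' Three hypotheses about prestimulus activity are implemented:
#' \describe{
#'   \item{sim1_no_prestim}{no prestimulus covariation with choice or RT;
#'     firing rates carry choice- and RT-dependence only after the cue.}
#'   \item{sim2_choice_bias}{a per-trial prestimulus bias toward one choice
#'     (uniform 0-4 spikes/s for the preferred choice, 0-2 for the other).}
#'   \item{sim3_rt_covariation}{a fraction of units (default 20%) trade their
#'     baseline for an RT-dependent prestimulus rate
#'     \eqn{r_{base2} = (2 + b)/RT} with \eqn{b \sim U(0,3)} and RT in
#'     seconds.}
#' }
#'
#' Defaults reproduce the reference synthetic population: 200 increased, 100
#' decreased and 50 perimovement units; 600 trials (300 left, 300 right);
#' RT = 200 + 100*Gamma(shape 5, scale 0.5) ms; baseline 5 spikes/s; choice
#' gain ramps after a lag t_latency + 0.2*RT.
#'
#' @param hypothesis one of "sim1_no_prestim", "sim2_choice_bias",
#'   "sim3_rt_covariation".
#' @param n_increased,n_decreased,n_perimovement unit counts per class.
#' @param n_trials total trials (split equally by choice).
#' @param rt_offset_ms,rt_scale_ms,rt_shape,rt_gamma_scale RT model:
#'   `rt_offset_ms + rt_scale_ms * Gamma(rt_shape, scale = rt_gamma_scale)`.
#' @param t_latency_ms non-decision latency before post-cue rate changes.
#' @param baseline_rate baseline firing rate, spikes/s.
#' @param rt_covary_fraction fraction of units given the sim3 prestimulus
#'   RT term (assigned deterministically within the increased class).
#' @param coherence_levels unsigned coherences (%) sampled per trial.
#' @param weibull_alpha,weibull_gamma psychometric parameters used to draw
#'   the `correct` flag from the coherence.
#' @param peri_amp_rate,peri_sigma_ms,peri_jitter_ms perimovement bump:
#'   amplitude (spikes/s), width, and per-unit uniform lead/lag range.
#' @param pre_window_ms simulated time before checkerboard onset.
#' @param post_hold_ms rates are held for this long after movement onset.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(hypothesis = c("sim1_no_prestim", "sim2_choice_bias",
                                      "sim3_rt_covariation"),
                       n_increased = 200L, n_decreased = 100L,
                       n_perimovement = 50L, n_trials = 600L,
                       rt_offset_ms = 200, rt_scale_ms = 100,
                       rt_shape = 5, rt_gamma_scale = 0.5,
                       t_latency_ms = 100, baseline_rate = 5,
                       rt_covary_fraction = 0.2,
                       coherence_levels = c(4, 7, 11, 19, 32, 54, 90),
                       weibull_alpha = 10.89, weibull_gamma = 1.26,
                       peri_amp_rate = 20, peri_sigma_ms = 50,
                       peri_jitter_ms = 100,
                       pre_window_ms = 600, post_hold_ms = 100,
                       seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  counts <- c(n_increased, n_decreased, n_perimovement, n_trials)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (n_trials %% 2L != 0L) stop("n_trials must be even (equal left/right)")
  if (rt_covary_fraction < 0 || rt_covary_fraction > 1) {
    stop("rt_covary_fraction must be in [0, 1]")
  }
  if (n_decreased > n_increased) {
    stop("n_decreased must not exceed n_increased (decreased units are paired)")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Draw reaction times from the gamma RT model
#'
#' RT = offset + scale * Gamma(shape, scale = gamma_scale), in ms; with the
#' defaults 200 + 100*Gamma(5, 0.5), giving mean 450 ms and SD ~111.8 ms.
#'
#' @param n number of draws.
#' @param config a `sim_config` (RT fields used).
#' @param seed optional seed set before drawing.
#' @return numeric vector of RTs in ms, all greater than the offset.
#' @export
simulate_rt <- function(n, config = sim_config(), seed = NULL) {
  if (n <= 0) stop("n must be > 0")
  if (!is.null(seed)) set.seed(seed)
  config$rt_offset_ms + config$rt_scale_ms *
    stats::rgamma(n, shape = config$rt_shape, scale = config$rt_gamma_scale)
}

# Unclipped component sum for an increased-class unit (internal).
# times in ms relative to checkerboard onset; rt in ms; draws carries the
# per-trial/per-unit random terms.
increased_component_sum <- function(times, rt, config, draws) {
  rt_s <- rt / 1000
  t_lag <- config$t_latency_ms + 0.2 * rt
  base <- if (isTRUE(draws$rt_covary)) 0 else config$baseline_rate
  # choice gain ramp, capped at its value at movement onset, held afterwards
  gate <- pmin(pmax((times - t_lag) / rt, 0), max((rt - t_lag) / rt, 0))
  choice_term <- if (draws$chosen) draws$rc1 * gate else -draws$rc2 * gate
  # condition-independent ramp; slope 15 spikes/s per second
  r_time <- pmin(pmax(15 * (times - t_lag) / 1000, 0),
                 max(15 * (rt - t_lag) / 1000, 0))
  extra <- 0
  if (config$hypothesis == "sim2_choice_bias") {
    extra <- draws$bias
  } else if (config$hypothesis == "sim3_rt_covariation" &&
             isTRUE(draws$rt_covary)) {
    extra <- (2 + draws$base_neuron) / rt_s
  }
  base + choice_term + r_time + extra
}

perimovement_component_sum <- function(times, rt, config, draws) {
  base <- if (config$hypothesis == "sim3_rt_covariation" &&
              isTRUE(draws$rt_covary)) {
    (2 + draws$base_neuron) / (rt / 1000)
  } else {
    config$baseline_rate
  }
  bias <- if (config$hypothesis == "sim2_choice_bias") draws$bias else 0
  base + bias +
    config$peri_amp_rate *
    exp(-((times - (rt + draws$jitter))^2) / (2 * config$peri_sigma_ms^2))
}

# rate vector (clipped at zero) for one unit class / one trial (internal)
rate_vec <- function(unit_class, times, rt, config, draws) {
  s <- switch(unit_class,
    increased = increased_component_sum(times, rt, config, draws),
    decreased = increased_component_sum(times, rt, config, draws) - 10,
    perimovement = perimovement_component_sum(times, rt, config, draws),
    stop("unknown unit class: ", unit_class)
  )
  pmax(s, 0)
}

#' Build the firing-rate profile for one unit on one trial
#'
#' Increased units combine a baseline (5 spikes/s), a choice-selective ramp
#' (gain `5 + 7 U(0,1)` added for the preferred choice or `2 + U(0,1)`
#' subtracted otherwise, gated by `max((t - t_lag)/RT, 0)` with
#' `t_lag = t_latency + 0.2 RT`), and a condition-independent ramp
#' `max(15 (t - t_lag), 0)` (t in seconds). Decreased units are the matched
#' increased profile minus 10 spikes/s. Perimovement units add a Gaussian
#' bump (sigma 50 ms, 20 spikes/s) around movement onset with per-unit
#' jitter. Rates are clipped at zero; the gain and ramp are capped at their
#' movement-onset values.
#'
#' @param unit_class "increased", "decreased" or "perimovement".
#' @param trial one-row data.frame with `rt_ms` and `choice`, or a list with
#'   those fields.
#' @param config a `sim_config`.
#' @param draws list of random terms: `chosen` (logical: trial choice equals
#'   the unit's preferred direction), `rc1`, `rc2`, `bias`, `base_neuron`,
#'   `jitter`, `rt_covary`. Missing terms are drawn from the current RNG.
#' @return list of class `rate_profile` with `times_ms` (relative to
#'   checkerboard onset), `rate` (spikes/s) and `components`.
#' @export
build_rate_profile <- function(unit_class, trial, config = sim_config(),
                               draws = list()) {
  rt <- if (!is.null(trial$rt_ms)) trial$rt_ms else trial$rt
  if (is.null(rt) || is.null(trial$choice)) {
    stop("trial must carry rt and choice")
  }
  defaults <- list(chosen = TRUE,
                   rc1 = 5 + 7 * stats::runif(1),
                   rc2 = 2 + stats::runif(1),
                   bias = NULL, base_neuron = stats::runif(1, 0, 3),
                   jitter = stats::runif(1, -config$peri_jitter_ms,
                                         config$peri_jitter_ms),
                   rt_covary = FALSE)
  for (nm in names(defaults)) {
    if (is.null(draws[[nm]])) draws[[nm]] <- defaults[[nm]]
  }
  if (is.null(draws$bias)) {
    draws$bias <- if (draws$chosen) stats::runif(1, 0, 4)
                  else stats::runif(1, 0, 2)
  }
  times <- seq(-config$pre_window_ms, rt + config$post_hold_ms, by = 1)
  rate <- rate_vec(unit_class, times, rt, config, draws)
  components <- list(
    r_base1 = if (isTRUE(draws$rt_covary)) 0 else config$baseline_rate,
    r_choice = if (draws$chosen) draws$rc1 else -draws$rc2,
    decreased_shift = if (unit_class == "decreased") -10 else 0,
    r_base2 = if (config$hypothesis == "sim3_rt_covariation" &&
                  isTRUE(draws$rt_covary)) (2 + draws$base_neuron) / (rt / 1000)
              else 0,
    bias = if (config$hypothesis == "sim2_choice_bias") draws$bias else 0
  )
  structure(list(times_ms = times, rate = rate, components = components,
                 unit_class = unit_class, draws = draws),
            class = "rate_profile")
}

#' Generate spike times from a rate profile (time-rescaling construction)
#'
#' Draws an inhomogeneous Poisson spike train whose piecewise-constant
#' intensity is `rate` on a uniform time grid. Under time rescaling by the
#' cumulative intensity the inter-spike intervals are unit-rate exponential;
#' equivalently the spike count is Poisson with mean equal to the integrated
#' rate and the rescaled times are uniform order statistics, which is how the
#' draw is implemented.
#'
#' @param rate numeric vector of intensities (spikes/s), or a `rate_profile`.
#' @param times_ms uniform time grid (ms); taken from the profile if omitted.
#' @return sorted numeric vector of spike times (ms), on the same clock as
#'   `times_ms`.
#' @export
generate_spikes <- function(rate, times_ms = NULL) {
  if (inherits(rate, "rate_profile")) {
    times_ms <- rate$times_ms
    rate <- rate$rate
  }
  if (any(rate < 0) || any(!is.finite(rate))) {
    stop("rate must be finite and >= 0 everywhere")
  }
  if (is.null(times_ms)) times_ms <- seq_along(rate) - 1
  dt <- if (length(times_ms) > 1L) times_ms[2L] - times_ms[1L] else 1
  mass <- rate * dt / 1000            # expected spikes per grid bin
  cum <- cumsum(mass)
  total <- cum[length(cum)]
  if (total <= 0) return(numeric(0))
  n <- stats::rpois(1L, total)
  if (n == 0L) return(numeric(0))
  u <- sort(stats::runif(n, 0, total))
  k <- findInterval(u, cum) + 1L       # first bin with cumulative mass >= u
  k[k > length(mass)] <- length(mass)
  prev <- c(0, cum)[k]
  frac <- (u - prev) / mass[k]
  frac[!is.finite(frac)] <- 0
  times_ms[k] + frac * dt
}

#' Simulate a full synthetic session
#'
#' Generates trials (RT, choice, coherence, outcome) and inhomogeneous
#' Poisson spike trains for every unit under the configured hypothesis.
#' Units are ordered increased, decreased, perimovement; decreased unit j is
#' paired with the j-th unit of the last `n_decreased` increased units and
#' receives that unit's rate minus 10 spikes/s. Preferred directions
#' alternate left/right within each class. Under sim3 the RT-covarying flag
#' is assigned to the first `round(rt_covary_fraction * n_units)` increased
#' units, so the flagged fraction of the population is exact.
#'
#' Spike times are stored in ms from trial start; the checkerboard onset per
#' trial is randomized (700-1485 ms) and spiking is simulated from
#' `pre_window_ms` before the cue to `post_hold_ms` after movement onset.
#'
#' @param config a `sim_config`.
#' @return a `session_data`; deterministic given `config$seed`.
#' @export
simulate_session <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_trials
  n_units <- config$n_increased + config$n_decreased + config$n_perimovement

  choice <- sample(rep(c("left", "right"), each = n / 2L))
  rt <- simulate_rt(n, config)
  coh <- sample(config$coherence_levels, n, replace = TRUE)
  p_corr <- weibull_p(coh, config$weibull_alpha, config$weibull_gamma)
  correct <- stats::runif(n) < p_corr
  # stimulus side agrees with the choice on correct trials (right <=> red)
  stim_right <- (choice == "right") == correct
  signed <- ifelse(stim_right, coh, -coh)
  cb_onset <- round(stats::runif(n, 700, 1485))
  prev <- c("none", ifelse(correct[-n], "correct", "error"))
  trials <- data.frame(
    trial_index = seq_len(n),
    signed_coherence = signed,
    choice = choice,
    correct = correct,
    rt_ms = rt,
    checkerboard_onset_ms = cb_onset,
    movement_onset_ms = cb_onset + rt,
    previous_outcome = prev,
    stringsAsFactors = FALSE
  )

  unit_class <- rep(c("increased", "decreased", "perimovement"),
                    c(config$n_increased, config$n_decreased,
                      config$n_perimovement))
  class_pos <- unlist(lapply(c(config$n_increased, config$n_decreased,
                               config$n_perimovement), seq_len))
  preferred <- ifelse(class_pos %% 2L == 1L, "left", "right")
  n_flagged <- round(config$rt_covary_fraction * n_units)
  if (n_flagged > config$n_increased) {
    stop("rt_covary_fraction too large to place all flagged units in the ",
         "increased class")
  }
  rt_covary <- unit_class == "increased" & class_pos <= n_flagged
  # pair decreased units with the tail of the increased class (unflagged
  # under the defaults), so flags stay class-local
  pair_of <- ifelse(unit_class == "decreased",
                    config$n_increased - config$n_decreased + class_pos, NA)
  base_neuron <- stats::runif(n_units, 0, 3)
  jitter <- stats::runif(n_units, -config$peri_jitter_ms,
                         config$peri_jitter_ms)
  isi <- round(stats::rexp(n_units, rate = 1.5), 2)
  units <- data.frame(
    unit_id = sprintf("u%03d", seq_len(n_units)),
    isi_violation_pct = isi,
    label = classify_unit(isi),
    unit_class = unit_class,
    preferred = preferred,
    rt_covary = rt_covary,
    stringsAsFactors = FALSE
  )

  # per-unit x per-trial random components (drawn once, shared by pairing)
  rc1 <- matrix(5 + 7 * stats::runif(n_units * n), n_units, n)
  rc2 <- matrix(2 + stats::runif(n_units * n), n_units, n)
  bias <- NULL
  if (config$hypothesis == "sim2_choice_bias") {
    chosen_mat <- outer(preferred, choice, "==")
    bias <- matrix(stats::runif(n_units * n), n_units, n) *
      ifelse(chosen_mat, 4, 2)
  }

  spikes <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    src <- if (unit_class[u] == "decreased") pair_of[u] else u
    ucl <- unit_class[u]
    per_trial <- vector("list", n)
    for (i in seq_len(n)) {
      draws <- list(
        chosen = preferred[src] == choice[i],
        rc1 = rc1[src, i], rc2 = rc2[src, i],
        bias = if (!is.null(bias)) bias[src, i] else 0,
        base_neuron = base_neuron[u],
        jitter = jitter[u],
        rt_covary = rt_covary[if (ucl == "decreased") src else u]
      )
      times <- seq(-config$pre_window_ms, rt[i] + config$post_hold_ms, by = 1)
      r <- rate_vec(ucl, times, rt[i], config, draws)
      per_trial[[i]] <- generate_spikes(r, times) + cb_onset[i]
    }
    spikes[[u]] <- per_trial
  }

  session_data(trials, units, spikes,
               session_id = paste0(config$hypothesis, "_seed",
                                   config$seed))
}
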