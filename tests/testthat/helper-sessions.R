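# cached small simulated sessions shared across test files
.session_cache <- new.env(parent = emptyenv())

small_session <- function(hypothesis = "sim1_no_prestim", seed = 7L,
                          n_trials = 80L, n_increased = 16L,
                          n_decreased = 8L, n_perimovement = 4L, ...) {
  key <- paste(hypothesis, seed, n_trials, n_increased, n_decreased,
               n_perimovement, sep = "|")
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- simulate_session(sim_config(
      hypothesis = hypothesis, seed = seed, n_trials = n_trials,
      n_increased = n_increased, n_decreased = n_decreased,
      n_perimovement = n_perimovement, ...))
  }
  .session_cache[[key]]
}

# hand-built session: spike lists given per unit per trial, fixed geometry
manual_session <- function(spikes_per_unit, rt_ms, choice = NULL,
                           cb_onset = 1000, coherence = 20,
                           correct = NULL) {
  n <- length(rt_ms)
  if (is.null(choice)) choice <- rep(c("left", "right"), length.out = n)
  if (is.null(correct)) correct <- rep(TRUE, n)
  trials <- data.frame(
    trial_index = seq_len(n),
    signed_coherence = rep_len(coherence, n),
    choice = choice,
    correct = correct,
    rt_ms = rt_ms,
    checkerboard_onset_ms = rep_len(cb_onset, n),
    movement_onset_ms = rep_len(cb_onset, n) + rt_ms,
    previous_outcome = c("none", ifelse(correct[-n], "correct", "error")),
    stringsAsFactors = FALSE
  )
  n_units <- length(spikes_per_unit)
  units <- data.frame(unit_id = sprintf("m%02d", seq_len(n_units)),
                      isi_violation_pct = rep(0.1, n_units),
                      label = rep("single", n_units),
                      stringsAsFactors = FALSE)
  session_data(trials, units, spikes_per_unit, session_id = "manual")
}

# trajectory_set constructor for geometric oracles: trajs is a list (per
# level, in order) of time x d matrices used for both choices
manual_trajset <- function(trajs, times, reference_level = NULL,
                           level_values = seq_along(trajs)) {
  n <- length(trajs)
  cells <- data.frame(
    level = rep(sprintf("l%d", seq_len(n)), 2L),
    level_index = rep(seq_len(n), 2L),
    level_value = rep(level_values, 2L),
    choice = rep(c("left", "right"), each = n),
    end_ms = NA, n_trials = 1L, stringsAsFactors = FALSE)
  if (is.null(reference_level)) reference_level <- ceiling(n / 2)
  structure(list(trajectories = c(trajs, trajs),
                 time = rep(if (is.list(times)) times else
                   replicate(n, times, simplify = FALSE), 2L),
                 cells = cells, reference_level = reference_level,
                 d = ncol(trajs[[1L]])),
            class = "trajectory_set")
}
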