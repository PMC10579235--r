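#' Assemble a recording session
#'
#' A session bundles a trial table, a unit table and per-unit, per-trial spike
#' times. All times are milliseconds from trial start. The trial table must
#' satisfy `movement_onset_ms - checkerboard_onset_ms == rt_ms` and every unit
#' must have exactly one spike vector per trial.
#'
#' @param trials data.frame with columns `trial_index`, `signed_coherence`,
#'   `choice` ("left"/"right"), `correct` (logical), `rt_ms`,
#'   `checkerboard_onset_ms`, `movement_onset_ms`, `previous_outcome`
#'   ("correct"/"error"/"none").
#' @param units data.frame with columns `unit_id`, `isi_violation_pct`,
#'   `label`; extra columns (e.g. simulator metadata) are preserved.
#' @param spikes list of length `nrow(units)`; element `u` is a list of
#'   length `nrow(trials)` of sorted numeric spike-time vectors (ms from
#'   trial start), ordered as the trial table.
#' @param session_id character identifier.
#' @return An object of class `session_data`.
#' @export
session_data <- function(trials, units, spikes, session_id = "session") {
  required <- c("trial_index", "signed_coherence", "choice", "correct",
                "rt_ms", "checkerboard_onset_ms", "movement_onset_ms",
                "previous_outcome")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trials is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(trials$trial_index)) {
    stop("trial indices must be unique")
  }
  bad <- which(abs(trials$movement_onset_ms - trials$checkerboard_onset_ms -
                     trials$rt_ms) > 1e-6)
  if (length(bad) > 0L) {
    stop("rt_ms inconsistent with movement - checkerboard for trial indices: ",
         paste(trials$trial_index[bad], collapse = ", "))
  }
  if (any(trials$rt_ms <= 0)) stop("rt_ms must be positive")
  if (length(spikes) != nrow(units)) {
    stop("spikes must have one element per unit")
  }
  for (u in seq_along(spikes)) {
    if (length(spikes[[u]]) != nrow(trials)) {
      stop("unit ", units$unit_id[u], " does not have one spike list per trial")
    }
    for (tr in seq_along(spikes[[u]])) {
      st <- spikes[[u]][[tr]]
      if (is.unsorted(st)) {
        stop("spike times not sorted for unit ", units$unit_id[u],
             " trial ", trials$trial_index[tr])
      }
    }
  }
  structure(
    list(session_id = session_id, trials = trials, units = units,
         spikes = spikes),
    class = "session_data"
  )
}

#' @export
print.session_data <- function(x, ...) {
  cat("<session_data> ", x$session_id, "\n",
      "  trials: ", nrow(x$trials),
      " (left ", sum(x$trials$choice == "left"),
      ", right ", sum(x$trials$choice == "right"), ")\n",
      "  units:  ", nrow(x$units), "\n", sep = "")
  invisible(x)
}

#' Classify a unit as single neuron or multi-unit
#'
#' A unit is a single neuron iff at most 1.5% of its inter-spike intervals
#' violate a 1.5 ms refractory period; otherwise it is a multi-unit.
#'
#' @param isi_violation_pct percent of ISIs <= 1.5 ms (vectorized).
#' @return character vector, "single" or "multi".
#' @export
classify_unit <- function(isi_violation_pct) {
  if (any(!is.finite(isi_violation_pct)) || any(isi_violation_pct < 0)) {
    stop("isi_violation_pct must be finite and >= 0")
  }
  ifelse(isi_violation_pct <= 1.5, "single", "multi")
}

#' Reaction-time bins
#'
#' Overlapping mode: eleven bins — ten 100 ms windows stepped by 25 ms
#' (300-400, 325-425, ..., 525-625) and a final 600-1000 ms catch-all.
#' Non-overlapping mode: contiguous bins covering 300-1000 ms (tertiles by
#' default).
#'
#' @param mode "overlapping" or "nonoverlapping".
#' @param n_nonoverlapping number of contiguous bins in non-overlapping mode.
#' @return list of class `rt_bin_set` with `bins` (two-column matrix
#'   low/high in ms), `centers` and `overlapping`.
#' @export
make_rt_bins <- function(mode = c("overlapping", "nonoverlapping"),
                         n_nonoverlapping = 3L) {
  mode <- match.arg(mode)
  if (mode == "overlapping") {
    lows <- c(seq(300, 525, by = 25), 600)
    highs <- c(seq(400, 625, by = 25), 1000)
  } else {
    edges <- seq(300, 1000, length.out = n_nonoverlapping + 1L)
    lows <- edges[-length(edges)]
    highs <- edges[-1L]
  }
  bins <- cbind(low_ms = lows, high_ms = highs)
  structure(list(bins = bins, centers = (lows + highs) / 2,
                 overlapping = mode == "overlapping"),
            class = "rt_bin_set")
}

#' Map reaction times to RT bins
#'
#' @param rt_ms numeric RTs in ms.
#' @param bin_set an `rt_bin_set`.
#' @return logical matrix, trials x bins; `TRUE` where the RT falls in the bin
#'   (half-open `[low, high)`, closed at 1000 ms for the final bin).
#' @export
assign_rt_bins <- function(rt_ms, bin_set) {
  b <- bin_set$bins
  n <- nrow(b)
  out <- matrix(FALSE, length(rt_ms), n)
  for (k in seq_len(n)) {
    hi_closed <- k == n
    out[, k] <- rt_ms >= b[k, 1L] &
      (if (hi_closed) rt_ms <= b[k, 2L] else rt_ms < b[k, 2L])
  }
  colnames(out) <- sprintf("rt_%g_%g", b[, 1L], b[, 2L])
  out
}

#' Write a session bundle to disk
#'
#' Writes `trials.csv`, `units.csv` and `spikes.csv` (long format:
#' unit_id, trial_index, spike_time_ms) into `bundle_path`.
#'
#' @param session a `session_data`.
#' @param bundle_path directory (created if needed).
#' @return `bundle_path`, invisibly.
#' @export
write_session <- function(session, bundle_path) {
  dir.create(bundle_path, showWarnings = FALSE, recursive = TRUE)
  tr <- session$trials
  num17 <- function(x) sprintf("%.17g", x)  # lossless double round-trip
  out_tr <- data.frame(
    trial_index = tr$trial_index,
    signed_coherence = num17(tr$signed_coherence),
    choice = tr$choice,
    correct = tr$correct,
    rt_ms = num17(tr$rt_ms),
    checkerboard_onset_ms = num17(tr$checkerboard_onset_ms),
    movement_onset_ms = num17(tr$movement_onset_ms),
    previous_outcome = tr$previous_outcome
  )
  utils::write.csv(out_tr, file.path(bundle_path, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$units, file.path(bundle_path, "units.csv"),
                   row.names = FALSE)
  n_per <- lapply(session$spikes, lengths)
  spikes_long <- data.frame(
    unit_id = rep(session$units$unit_id,
                  vapply(n_per, sum, numeric(1))),
    trial_index = unlist(lapply(n_per, function(n)
      rep(tr$trial_index, n)), use.names = FALSE),
    spike_time_ms = num17(unlist(session$spikes, use.names = FALSE))
  )
  if (nrow(spikes_long) == 0L) {
    spikes_long <- data.frame(unit_id = character(0),
                              trial_index = integer(0),
                              spike_time_ms = numeric(0))
  }
  utils::write.csv(spikes_long, file.path(bundle_path, "spikes.csv"),
                   row.names = FALSE)
  invisible(bundle_path)
}

#' Read a session bundle from disk
#'
#' @param bundle_path directory containing `trials.csv`, `units.csv`,
#'   `spikes.csv`.
#' @param session_id identifier for the returned session (defaults to the
#'   directory name).
#' @return A `session_data`.
#' @export
read_session <- function(bundle_path, session_id = basename(bundle_path)) {
  paths <- file.path(bundle_path, c("trials.csv", "units.csv", "spikes.csv"))
  for (p in paths) {
    if (!file.exists(p)) stop("missing bundle file: ", basename(p))
  }
  trials <- utils::read.csv(paths[1L], stringsAsFactors = FALSE)
  units <- utils::read.csv(paths[2L], stringsAsFactors = FALSE)
  sp <- utils::read.csv(paths[3L], stringsAsFactors = FALSE)
  for (col in c("signed_coherence", "rt_ms", "checkerboard_onset_ms",
                "movement_onset_ms")) {
    if (!col %in% names(trials)) stop("trials.csv missing column: ", col)
    trials[[col]] <- as.double(trials[[col]])
  }
  if ("isi_violation_pct" %in% names(units)) {
    units$isi_violation_pct <- as.double(units$isi_violation_pct)
  }
  sp$spike_time_ms <- as.double(sp$spike_time_ms)
  for (col in c("unit_id", "trial_index", "spike_time_ms")) {
    if (!col %in% names(sp)) stop("spikes.csv missing column: ", col)
  }
  trial_pos <- match(sp$trial_index, trials$trial_index)
  unit_pos <- match(sp$unit_id, units$unit_id)
  if (nrow(sp) > 0L && (anyNA(trial_pos) || anyNA(unit_pos))) {
    stop("spikes.csv refers to unknown trial_index or unit_id")
  }
  spikes <- vector("list", nrow(units))
  empty <- replicate(nrow(trials), numeric(0), simplify = FALSE)
  for (u in seq_len(nrow(units))) spikes[[u]] <- empty
  if (nrow(sp) > 0L) {
    o <- order(unit_pos, trial_pos, sp$spike_time_ms)
    sp <- sp[o, ]; trial_pos <- trial_pos[o]; unit_pos <- unit_pos[o]
    key <- split(seq_len(nrow(sp)),
                 list(u = unit_pos, t = trial_pos), drop = TRUE)
    for (nm in names(key)) {
      idx <- key[[nm]]
      ut <- as.integer(strsplit(nm, ".", fixed = TRUE)[[1L]])
      spikes[[ut[1L]]][[ut[2L]]] <- sp$spike_time_ms[idx]
    }
  }
  session_data(trials, units, spikes, session_id = session_id)
}

#' Drop trials with RTs outside the binned analysis range
#'
#' RT-binned analyses span 300-1000 ms; trials outside that range are removed.
#'
#' @param session a `session_data`.
#' @param range_ms inclusive RT range to keep.
#' @return filtered `session_data`.
#' @export
filter_rt_range <- function(session, range_ms = c(300, 1000)) {
  keep <- session$trials$rt_ms >= range_ms[1L] &
    session$trials$rt_ms <= range_ms[2L]
  subset_trials(session, which(keep))
}

# subset a session to a set of trial row positions (internal)
subset_trials <- function(session, rows) {
  trials <- session$trials[rows, , drop = FALSE]
  spikes <- lapply(session$spikes, function(sl) sl[rows])
  session_data(trials, session$units, spikes, session$session_id)
}
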