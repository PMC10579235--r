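#' Smoothing kernel specification
#'
#' @param type "gaussian" (default, sigma = `width_ms`) or "causal_boxcar"
#'   (flat kernel over the past `width_ms`).
#' @param width_ms kernel width: Gaussian sigma or boxcar length, ms.
#' @return list of class `rate_kernel` with `weights` (summing to 1) and
#'   `lags` (ms offsets into the past/future that each weight applies to).
#' @export
rate_kernel <- function(type = c("gaussian", "causal_boxcar"), width_ms = 30) {
  type <- match.arg(type)
  if (width_ms <= 0) stop("width_ms must be > 0")
  if (type == "gaussian") {
    half <- ceiling(4 * width_ms)
    lags <- -half:half
    w <- stats::dnorm(lags, 0, width_ms)
  } else {
    lags <- 0:(ceiling(width_ms) - 1L)
    w <- rep(1, length(lags))
  }
  structure(list(type = type, width_ms = width_ms,
                 weights = w / sum(w), lags = lags),
            class = "rate_kernel")
}

# y[t] = sum_u w(u) x[t - u], zero-padded outside the window (internal)
smooth_vec <- function(x, kernel) {
  n <- length(x)
  w <- kernel$weights
  lags <- kernel$lags
  z <- stats::convolve(x, rev(w), type = "open")
  # z[m] = sum_k x[k] w[m - k + 1]; with w ordered by lag u_min..u_max,
  # y[t] = z[t - u_min] where index arithmetic is 1-based
  start <- 1L - min(lags)
  z[seq.int(start, start + n - 1L)]
}

# bin spike times (ms, relative to event) into 1 ms bins on [window[1],
# window[2]) (internal)
bin_spikes <- function(rel_times, window) {
  t0 <- window[1L]
  n <- window[2L] - window[1L]
  idx <- floor(rel_times - t0) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  tabulate(idx, nbins = n)
}

# occupancy: number of trials for which each 1 ms bin is valid, given
# per-trial validity end times (bin valid iff bin start < end) (internal)
occupancy_curve <- function(end_times, window) {
  t0 <- window[1L]
  n <- window[2L] - window[1L]
  # count ends falling in each bin, then reverse-accumulate
  idx <- pmin(pmax(ceiling(end_times - t0), 0L), n)
  ends_per_bin <- tabulate(idx + 1L, nbins = n + 1L)
  length(end_times) - cumsum(ends_per_bin)[seq_len(n)]
}

#' Event-aligned per-trial firing rates for one unit
#'
#' Bins spikes at 1 ms aligned to an event and smooths them into firing
#' rates. For checkerboard alignment, all spikes from 50 ms before movement
#' onset to the end of the trial are removed (masked) before smoothing, so
#' movement-related activity cannot leak into the stimulus period. Smoothing
#' divides the smoothed counts by the smoothed validity mask (occupancy
#' normalization), so masked samples never bias the rate; samples whose
#' smoothed mask is (near) zero are returned as `NA`.
#'
#' @param session a `session_data`.
#' @param unit unit index or `unit_id`.
#' @param event "checkerboard" or "movement".
#' @param window 2-vector, ms relative to the event (half-open).
#' @param kernel a `rate_kernel` (default Gaussian sigma 30 ms).
#' @return list with `time_ms` (bin starts), `rate` (trials x time,
#'   spikes/s, `NA` where masked), `counts`, `mask`.
#' @export
align_and_rate <- function(session, unit, event = c("checkerboard", "movement"),
                           window = c(-600, 1200),
                           kernel = rate_kernel("gaussian", 30)) {
  event <- match.arg(event)
  if (window[2L] <= window[1L]) stop("invalid window")
  if (is.character(unit)) unit <- match(unit, session$units$unit_id)
  trials <- session$trials
  sp <- session$spikes[[unit]]
  n_t <- window[2L] - window[1L]
  time_ms <- seq.int(window[1L], window[2L] - 1L)
  counts <- matrix(0, nrow(trials), n_t)
  mask <- matrix(1, nrow(trials), n_t)
  event_time <- if (event == "checkerboard") trials$checkerboard_onset_ms
                else trials$movement_onset_ms
  for (i in seq_len(nrow(trials))) {
    rel <- sp[[i]] - event_time[i]
    if (event == "checkerboard") {
      cut <- trials$rt_ms[i] - 50
      rel <- rel[rel < cut]
      mask[i, time_ms >= cut] <- 0
    }
    counts[i, ] <- bin_spikes(rel, window)
  }
  sm_counts <- t(apply(counts * mask, 1L, smooth_vec, kernel = kernel))
  sm_mask <- t(apply(mask, 1L, smooth_vec, kernel = kernel))
  rate <- 1000 * sm_counts / sm_mask
  rate[sm_mask < 1e-3] <- NA_real_
  list(time_ms = time_ms, rate = rate, counts = counts, mask = mask)
}

# trial groups for a conditioning scheme; returns list of cells, each with
# name, choice, level label, trial row indices, end_ms (internal)
condition_cells <- function(session, grouping, bin_set, window_end) {
  trials <- session$trials
  cells <- list()
  for (ch in c("left", "right")) {
    in_choice <- trials$choice == ch
    if (grouping == "rt_bins") {
      ok <- trials$rt_ms >= 300 & trials$rt_ms <= 1000
      memb <- assign_rt_bins(trials$rt_ms, bin_set)
      for (k in seq_len(nrow(bin_set$bins))) {
        rows <- which(in_choice & ok & memb[, k])
        cells[[length(cells) + 1L]] <- list(
          level = sprintf("rt_%g_%g", bin_set$bins[k, 1L],
                          bin_set$bins[k, 2L]),
          level_index = k, choice = ch, rows = rows,
          level_value = bin_set$centers[k],
          end_ms = bin_set$bins[k, 1L] - 25)
      }
    } else if (grouping == "coherence") {
      levs <- sort(unique(abs(trials$signed_coherence)))
      for (k in seq_along(levs)) {
        rows <- which(in_choice & abs(trials$signed_coherence) == levs[k])
        cells[[length(cells) + 1L]] <- list(
          level = sprintf("coh_%g", levs[k]), level_index = k, choice = ch,
          rows = rows, level_value = levs[k],
          end_ms = stats::median(trials$rt_ms[rows]) - 25)
      }
    } else if (grouping == "outcome") {
      defs <- list(
        correct = trials$correct,
        post_correct_correct = trials$correct &
          trials$previous_outcome == "correct",
        error = !trials$correct,
        post_error_correct = trials$correct &
          trials$previous_outcome == "error")
      for (k in seq_along(defs)) {
        rows <- which(in_choice & defs[[k]])
        cells[[length(cells) + 1L]] <- list(
          level = names(defs)[k], level_index = k, choice = ch, rows = rows,
          level_value = k,
          end_ms = stats::median(trials$rt_ms[rows]) - 25)
      }
    } else {
      stop("unknown grouping: ", grouping)
    }
  }
  for (cell in cells) {
    if (length(cell$rows) == 0L) {
      stop("empty condition group: ", cell$level, " / ", cell$choice)
    }
  }
  if (!is.null(window_end)) {
    cells <- lapply(cells, function(c) { c$end_ms <- window_end; c })
  }
  cells
}

#' Trial-averaged condition rate tensor
#'
#' Builds trial-averaged, smoothed firing rates per (condition level x
#' choice) cell for all units, aligned to an event. For checkerboard
#' alignment each cell's usable window runs from `window_start` to its own
#' end: RT-bin lower bound minus 25 ms for RT groupings, or the cell's median
#' RT minus 25 ms for coherence/outcome groupings (the 25 ms guards against
#' the movement mask). Samples beyond a cell's end are `NA`. Averaging is
#' occupancy-normalized: per unit and cell, spike counts and per-trial
#' validity masks are summed over trials, both are smoothed, and the rate is
#' their ratio, so partially masked trials contribute only where valid.
#'
#' @param session a `session_data`.
#' @param grouping "rt_bins", "coherence" or "outcome".
#' @param event alignment event; the movement mask and window truncation are
#'   applied for "checkerboard" only.
#' @param bin_set RT bins (used by "rt_bins").
#' @param kernel a `rate_kernel`.
#' @param window_start start of the window, ms relative to the event.
#' @param window_end optional fixed end for every cell (default: per-cell
#'   rule above for checkerboard; required for movement alignment).
#' @return object of class `rate_tensor`: `values` (time x unit x cell),
#'   `time_ms`, `cells` (data.frame: level, choice, end_ms, n_trials),
#'   `unit_ids`, `grouping`.
#' @export
condition_average <- function(session,
                              grouping = c("rt_bins", "coherence", "outcome"),
                              event = c("checkerboard", "movement"),
                              bin_set = make_rt_bins("overlapping"),
                              kernel = rate_kernel("gaussian", 30),
                              window_start = -400, window_end = NULL) {
  grouping <- match.arg(grouping)
  event <- match.arg(event)
  trials <- session$trials
  if (event == "movement" && is.null(window_end)) window_end <- 400
  cells <- condition_cells(session, grouping, bin_set, window_end)
  max_end <- max(vapply(cells, `[[`, numeric(1), "end_ms"))
  window <- c(window_start, ceiling(max_end))
  n_time <- window[2L] - window[1L]
  time_ms <- seq.int(window[1L], window[2L] - 1L)
  n_units <- nrow(session$units)
  vals <- array(NA_real_, c(n_time, n_units, length(cells)))
  event_time <- if (event == "checkerboard") trials$checkerboard_onset_ms
                else trials$movement_onset_ms
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    rows <- cell$rows
    keep <- time_ms < cell$end_ms
    if (event == "checkerboard") {
      occ <- occupancy_curve(trials$rt_ms[rows] - 50, window)
    } else {
      occ <- rep(length(rows), n_time)
    }
    sm_occ <- smooth_vec(occ, kernel)
    for (u in seq_len(n_units)) {
      rel <- unlist(session$spikes[[u]][rows], use.names = FALSE) -
        rep(event_time[rows], lengths(session$spikes[[u]][rows]))
      if (event == "checkerboard") {
        cut <- rep(trials$rt_ms[rows] - 50, lengths(session$spikes[[u]][rows]))
        rel <- rel[rel < cut]
      }
      cnt <- bin_spikes(rel, window)
      r <- 1000 * smooth_vec(cnt, kernel) / sm_occ
      r[sm_occ < 1e-3] <- NA_real_
      r[!keep] <- NA_real_
      vals[, u, ci] <- r
    }
  }
  cell_df <- data.frame(
    level = vapply(cells, `[[`, character(1), "level"),
    level_index = vapply(cells, `[[`, numeric(1), "level_index"),
    level_value = vapply(cells, `[[`, numeric(1), "level_value"),
    choice = vapply(cells, `[[`, character(1), "choice"),
    end_ms = vapply(cells, `[[`, numeric(1), "end_ms"),
    n_trials = vapply(cells, function(c) length(c$rows), numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(values = vals, time_ms = time_ms, cells = cell_df,
                 unit_ids = session$units$unit_id, grouping = grouping,
                 event = event,
                 trial_rows = lapply(cells, `[[`, "rows")),
            class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  cat("<rate_tensor> ", x$grouping, " x choice, aligned to ", x$event, "\n",
      "  time: ", min(x$time_ms), "..", max(x$time_ms), " ms; units: ",
      length(x$unit_ids), "; cells: ", nrow(x$cells), "\n", sep = "")
  invisible(x)
}
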