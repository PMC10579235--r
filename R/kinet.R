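# angle in degrees between two vectors (internal)
vec_angle <- function(a, b) {
  if (anyNA(a) || anyNA(b)) return(NA_real_)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

unit_vec <- function(v) {
  if (anyNA(v)) return(v + NA_real_)
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

# KiNeT core for one choice: trajectories ordered by condition level,
# reference index into that order (internal)
kinet_one_choice <- function(trajs, times, ref_idx) {
  n <- length(trajs)
  ref <- trajs[[ref_idx]]
  ref_time <- times[[ref_idx]]
  n_j <- nrow(ref)
  # closest state and time on every trajectory (reference included: itself)
  s <- array(NA_real_, c(n, n_j, ncol(ref)))
  t_mat <- matrix(NA_real_, n, n_j)
  for (i in seq_len(n)) {
    if (i == ref_idx) {
      s[i, , ] <- ref
      t_mat[i, ] <- ref_time
      next
    }
    tr <- trajs[[i]]
    support_end <- max(times[[i]])
    for (j in seq_len(n_j)) {
      if (ref_time[j] > support_end) next  # beyond support: missing
      d2 <- colSums((t(tr) - ref[j, ])^2)
      k <- which.min(d2)                    # earliest minimum on ties
      s[i, j, ] <- tr[k, ]
      t_mat[i, j] <- times[[i]][k]
    }
  }
  # signed distance: positive when angularly closer to the 1st condition
  dist <- matrix(NA_real_, n, n_j)
  for (j in seq_len(n_j)) {
    u_first <- s[1L, j, ] - ref[j, ]
    u_last <- s[n, j, ] - ref[j, ]
    for (i in seq_len(n)) {
      if (i == ref_idx) { dist[i, j] <- 0; next }
      u <- s[i, j, ] - ref[j, ]
      d <- sqrt(sum(u^2))
      if (is.na(d)) next
      a1 <- vec_angle(u, u_first)
      a2 <- vec_angle(u, u_last)
      sgn <- if (is.na(a1) || is.na(a2) || a1 <= a2) 1 else -1
      dist[i, j] <- sgn * d
    }
  }
  out <- list(ref_time = ref_time, closest_time = t_mat,
              signed_distance = dist)
  if (n >= 3L) {
    delta <- array(NA_real_, c(n - 1L, n_j, dim(s)[3L]))
    for (i in seq_len(n - 1L)) delta[i, , ] <- s[i + 1L, , ] - s[i, , ]
    if (n >= 3L) {
      theta <- matrix(NA_real_, n - 2L, n_j)
      for (i in seq_len(n - 2L)) {
        for (j in seq_len(n_j)) {
          theta[i, j] <- vec_angle(delta[i, j, ], delta[i + 1L, j, ])
        }
      }
      out$adjacent_angles <- theta
      out$mean_angle <- colMeans(theta, na.rm = TRUE)
    }
    # subspace similarity: normalized mean of normalized adjacent vectors
    dbar <- matrix(NA_real_, n_j, dim(s)[3L])
    for (j in seq_len(n_j)) {
      vs <- lapply(seq_len(n - 1L), function(i) unit_vec(delta[i, j, ]))
      vs <- vs[!vapply(vs, anyNA, logical(1))]
      if (length(vs)) dbar[j, ] <- unit_vec(Reduce(`+`, vs) / length(vs))
    }
    out$delta_bar <- dbar
    out$subspace_angle <- vapply(seq_len(n_j), function(j) {
      if (anyNA(dbar[j, ]) || anyNA(dbar[1L, ])) NA_real_
      else vec_angle(dbar[j, ], dbar[1L, ])
    }, numeric(1))
  }
  out
}

#' Kinematic analysis of neural trajectories (KiNeT)
#'
#' Compares every condition trajectory to a designated reference trajectory.
#' For each reference timepoint j the closest state on each non-reference
#' trajectory gives a time-to-reference (earlier = faster dynamics) and a
#' signed Euclidean distance (positive when the displacement from the
#' reference is angularly closer to the first condition's displacement than
#' to the last's). Adjacent-trajectory difference vectors give local angles
#' and, after normalization and averaging, a subspace rotation angle
#' relative to the first timepoint. All quantities are computed within each
#' choice and then averaged across choices by reference timepoint index.
#'
#' @param trajset a `trajectory_set` with at least 3 condition levels per
#'   choice (with fewer, the angle outputs are suppressed).
#' @return object of class `kinet_result`: `ref_time_ms`, `levels`
#'   (condition levels in order), `t_ref` (levels x timepoints, ms),
#'   `signed_distance`, `mean_angle`, `subspace_angle`, and `per_choice`
#'   (the per-choice results).
#' @export
kinet_analyze <- function(trajset) {
  d <- unique(vapply(trajset$trajectories, ncol, numeric(1)))
  if (length(d) != 1L) stop("trajectories must share dimensionality")
  choices <- unique(trajset$cells$choice)
  per_choice <- list()
  for (ch in choices) {
    sel <- which(trajset$cells$choice == ch)
    ord <- sel[order(trajset$cells$level_index[sel])]
    levels <- trajset$cells$level_index[ord]
    ref_idx <- match(trajset$reference_level, levels)
    if (is.na(ref_idx)) stop("reference level not present for choice ", ch)
    per_choice[[ch]] <- kinet_one_choice(trajset$trajectories[ord],
                                         trajset$time[ord], ref_idx)
    per_choice[[ch]]$levels <- levels
  }
  n_j <- min(vapply(per_choice, function(p) length(p$ref_time), numeric(1)))
  avg_mat <- function(field) {
    ms <- lapply(per_choice, function(p) p[[field]][, seq_len(n_j),
                                                    drop = FALSE])
    Reduce(`+`, ms) / length(ms)
  }
  avg_vec <- function(field) {
    vs <- lapply(per_choice, function(p) p[[field]][seq_len(n_j)])
    Reduce(`+`, vs) / length(vs)
  }
  res <- list(
    ref_time_ms = per_choice[[1L]]$ref_time[seq_len(n_j)],
    levels = per_choice[[1L]]$levels,
    reference_level = trajset$reference_level,
    t_ref = avg_mat("closest_time"),
    signed_distance = avg_mat("signed_distance"),
    per_choice = per_choice
  )
  if (!is.null(per_choice[[1L]]$mean_angle)) {
    res$mean_angle <- avg_vec("mean_angle")
    res$subspace_angle <- avg_vec("subspace_angle")
  }
  structure(res, class = "kinet_result")
}

#' @export
print.kinet_result <- function(x, ...) {
  cat("<kinet_result> ", length(x$levels), " trajectories, reference level ",
      x$reference_level, ", ", length(x$ref_time_ms), " reference timepoints\n",
      sep = "")
  invisible(x)
}

#' Scalar speed of state-space trajectories
#'
#' The L2 norm of the coordinate change across adjacent `step_ms` steps,
#' computed per condition level and choice, averaged across choices, with
#' the mean over a prestimulus window reported per level.
#'
#' @param trajset a `trajectory_set`.
#' @param step_ms step between compared states (default 10 ms).
#' @param window prestimulus averaging window, ms (default -400..0).
#' @return object of class `speed_profile`: `levels`, `time_ms`, `speed`
#'   (levels x timepoints, choice-averaged), `prestim_mean` per level.
#' @export
scalar_speed <- function(trajset, step_ms = 10, window = c(-400, 0)) {
  cells <- trajset$cells
  levels <- sort(unique(cells$level_index))
  per_cell_speed <- vector("list", nrow(cells))
  per_cell_time <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    tms <- trajset$time[[ci]]
    tr <- trajset$trajectories[[ci]]
    if (window[1L] < min(tms)) stop("window outside trajectory support")
    grid <- seq(min(tms), max(tms) - step_ms, by = step_ms)
    i0 <- match(grid, tms)
    i1 <- match(grid + step_ms, tms)
    ok <- !is.na(i0) & !is.na(i1)
    sp <- sqrt(rowSums((tr[i1[ok], , drop = FALSE] -
                          tr[i0[ok], , drop = FALSE])^2))
    per_cell_speed[[ci]] <- sp
    per_cell_time[[ci]] <- grid[ok]
  }
  n_lev <- length(levels)
  # average across choices on the common time grid per level
  speed <- list(); time_axes <- list()
  prestim <- numeric(n_lev)
  for (k in seq_along(levels)) {
    sel <- which(cells$level_index == levels[k])
    common <- Reduce(intersect, per_cell_time[sel])
    mats <- lapply(sel, function(ci)
      per_cell_speed[[ci]][match(common, per_cell_time[[ci]])])
    avg <- Reduce(`+`, mats) / length(mats)
    speed[[k]] <- avg
    time_axes[[k]] <- common
    pre <- common >= window[1L] & common < window[2L]
    prestim[k] <- mean(avg[pre])
  }
  structure(list(levels = levels, time = time_axes, speed = speed,
                 prestim_mean = prestim, step_ms = step_ms,
                 window = window),
            class = "speed_profile")
}

#' One-tailed bootstrap p-value
#'
#' Unbiased bootstrap p: `(1 + #\{S_i beyond s_test\}) / (1 + n)`. With 50
#' bootstrap replicates the smallest attainable p is 1/51 (0.0196).
#'
#' @param boot_stats numeric vector of bootstrap statistics.
#' @param s_test comparison value.
#' @param side "greater" counts `S_i > s_test`; "less" counts `S_i < s_test`.
#' @return p-value in (0, 1].
#' @export
bootstrap_p <- function(boot_stats, s_test, side = c("greater", "less")) {
  side <- match.arg(side)
  if (!length(boot_stats)) stop("empty bootstrap statistic list")
  exceed <- if (side == "greater") sum(boot_stats > s_test)
            else sum(boot_stats < s_test)
  (1 + exceed) / (1 + length(boot_stats))
}
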