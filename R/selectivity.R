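#' Choice-selectivity curve
#'
#' Euclidean distance between the left- and right-choice trajectories at
#' every shared timepoint.
#'
#' @param left_traj,right_traj time x d coordinate matrices on the same time
#'   axis and dimensionality.
#' @param time_ms optional shared time axis.
#' @return list of class `cs_curve`: `time_ms`, `cs`.
#' @export
cs_curve <- function(left_traj, right_traj, time_ms = NULL) {
  if (!all(dim(left_traj) == dim(right_traj))) {
    stop("trajectories must share time axis and dimensionality")
  }
  cs <- sqrt(rowSums((left_traj - right_traj)^2))
  if (is.null(time_ms)) time_ms <- seq_len(nrow(left_traj)) - 1
  structure(list(time_ms = time_ms, cs = cs), class = "cs_curve")
}

#' Choice-selectivity curve for one condition level of a trajectory set
#'
#' @param trajset a `trajectory_set` with left and right cells per level.
#' @param level condition `level_index`.
#' @return a `cs_curve` over the timepoints shared by the two choices.
#' @export
cs_from_trajset <- function(trajset, level) {
  il <- which(trajset$cells$level_index == level &
                trajset$cells$choice == "left")
  ir <- which(trajset$cells$level_index == level &
                trajset$cells$choice == "right")
  if (length(il) != 1L || length(ir) != 1L) {
    stop("level ", level, " must have exactly one left and one right cell")
  }
  common <- intersect(trajset$time[[il]], trajset$time[[ir]])
  cs_curve(trajset$trajectories[[il]][match(common, trajset$time[[il]]), ,
                                      drop = FALSE],
           trajset$trajectories[[ir]][match(common, trajset$time[[ir]]), ,
                                      drop = FALSE],
           time_ms = common)
}

#' Piecewise fit of the choice-selectivity latency and slope
#'
#' Fits `CS(t) = b` for `t <= t_latency` and `CS(t) = m (t - t_latency)^2`
#' afterwards (the two pieces are not constrained to meet). The latency is
#' found by grid search over the curve's timepoints, with `b` and `m` solved
#' in closed form at each candidate; the global SSE minimizer is returned
#' (earliest on ties). A flat curve yields `m ~ 0` with the latency at the
#' window end and `flat = TRUE`.
#'
#' @param curve a `cs_curve` or list with `time_ms` and `cs`.
#' @param window fit window, ms (default: the whole curve).
#' @return object of class `piecewise_cs_fit`: `b`, `m` (per ms^2),
#'   `t_latency` (ms), `sse`, `flat`.
#' @export
fit_piecewise_cs <- function(curve, window = NULL) {
  tms <- curve$time_ms
  cs <- curve$cs
  if (!is.null(window)) {
    keep <- tms >= window[1L] & tms <= window[2L]
    tms <- tms[keep]; cs <- cs[keep]
  }
  n <- length(tms)
  if (n < 3L) stop("curve too short to fit")
  best <- list(sse = Inf)
  for (k in seq_len(n)) {
    if (k == n - 1L) next  # a single post-latency point is always fit exactly
    tl <- tms[k]
    pre <- cs[seq_len(k)]
    b <- mean(pre)
    sse <- sum((pre - b)^2)
    m <- 0
    if (k < n) {
      w <- (tms[(k + 1L):n] - tl)^2
      post <- cs[(k + 1L):n]
      m <- sum(post * w) / sum(w^2)
      sse <- sse + sum((post - m * w)^2)
    }
    if (sse < best$sse - 1e-12) {
      best <- list(b = b, m = m, t_latency = tl, sse = sse)
    }
  }
  best$flat <- abs(best$m) < 1e-8 || best$t_latency == tms[n]
  structure(best, class = "piecewise_cs_fit")
}

#' @export
print.piecewise_cs_fit <- function(x, ...) {
  cat(sprintf("piecewise CS fit: b = %.4g, m = %.4g /ms^2, t_latency = %g ms%s\n",
              x$b, x$m, x$t_latency, if (x$flat) " (flat)" else ""))
  invisible(x)
}

#' Average choice selectivity in a post-cue window
#'
#' @param curve a `cs_curve`.
#' @param window ms window (default 125-375 ms after the cue).
#' @return mean CS in the window.
#' @export
cs_window_mean <- function(curve, window = c(125, 375)) {
  keep <- curve$time_ms >= window[1L] & curve$time_ms <= window[2L]
  if (!any(keep)) stop("window outside curve support")
  mean(curve$cs[keep])
}

#' Prestimulus state matrix for the initial-condition axis
#'
#' Averages each condition cell's low-dimensional state over a prestimulus
#' window and concatenates the two choices' vectors per condition level.
#'
#' @param trajset a `trajectory_set` (d dims per cell).
#' @param window prestimulus window, ms (default -400 to -100).
#' @return matrix: condition levels x (2*d), with `level_value` attribute
#'   (e.g. RT-bin centers) for sign orientation downstream.
#' @export
prestim_state_matrix <- function(trajset, window = c(-400, -100)) {
  cells <- trajset$cells
  levels <- sort(unique(cells$level_index))
  out <- matrix(NA_real_, length(levels), 2L * trajset$d)
  vals <- numeric(length(levels))
  for (k in seq_along(levels)) {
    row <- numeric(0)
    for (ch in c("left", "right")) {
      ci <- which(cells$level_index == levels[k] & cells$choice == ch)
      if (length(ci) != 1L) stop("missing cell: level ", levels[k], " ", ch)
      keep <- trajset$time[[ci]] >= window[1L] & trajset$time[[ci]] <= window[2L]
      if (!any(keep)) stop("prestimulus window missing for level ", levels[k])
      row <- c(row, colMeans(trajset$trajectories[[ci]][keep, , drop = FALSE]))
    }
    out[k, ] <- row
    vals[k] <- cells$level_value[which(cells$level_index == levels[k])][1L]
  }
  attr(out, "level_value") <- vals
  out
}

#' Initial-condition axis and scores
#'
#' PCA of the condition-cells x concatenated-prestimulus-state matrix; the
#' top component's scores summarize each cell's initial condition. The axis
#' sign is oriented so the scores correlate negatively with the supplied
#' ordering values (e.g. RT-bin centers), matching the convention that
#' higher initial-condition values precede faster responses.
#'
#' @param states matrix, condition cells x concatenated state dims (e.g.
#'   77 x 12 for 7 coherences x 11 RT bins and two choices in 6 dims).
#' @param order_values optional per-cell values (e.g. RT-bin centers) for
#'   sign orientation; taken from the matrix's `level_value` attribute when
#'   present.
#' @return object of class `ic_axis`: `axis` (unit norm), `scores`.
#' @export
initial_condition_axis <- function(states, order_values = NULL) {
  if (anyNA(states)) {
    stop("missing cells in state matrix: rows ",
         paste(which(!stats::complete.cases(states)), collapse = ", "))
  }
  if (is.null(order_values)) order_values <- attr(states, "level_value")
  centered <- scale(states, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  axis <- sv$v[, 1L]
  scores <- as.numeric(centered %*% axis)
  if (!is.null(order_values) && stats::sd(scores) > 0 &&
      stats::sd(order_values) > 0 &&
      stats::cor(scores, order_values) > 0) {
    axis <- -axis
    scores <- -scores
  }
  structure(list(axis = axis, scores = scores), class = "ic_axis")
}

#' Partial correlations with bootstrap confidence intervals
#'
#' Pearson partial correlations of `y` with `x1` controlling for `x2` and
#' with `x2` controlling for `x1`, with percentile confidence intervals and
#' one-tailed bootstrap p-values (sign test against zero) from resampling
#' the cells.
#'
#' @param y,x1,x2 numeric vectors over the same cells (length >= 3).
#' @param n_boot bootstrap replicates (default 50).
#' @param seed RNG seed.
#' @param conf confidence level for the percentile interval.
#' @return list: `r_x1` and `r_x2` (each with `estimate`, `ci`, `p`).
#' @export
partial_corr <- function(y, x1, x2, n_boot = 50L, seed = 1L, conf = 0.99) {
  if (length(y) < 3L) stop("need at least 3 cells")
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0 || stats::sd(y) == 0) {
    stop("constant regressor: partial correlation undefined")
  }
  pc <- function(y, a, b) {
    ra <- stats::resid(stats::lm(a ~ b))
    ry <- stats::resid(stats::lm(y ~ b))
    if (stats::sd(ra) == 0 || stats::sd(ry) == 0) return(NA_real_)
    stats::cor(ry, ra)
  }
  est1 <- pc(y, x1, x2)
  est2 <- pc(y, x2, x1)
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, 2L)
  n <- length(y)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    boots[b, ] <- c(tryCatch(pc(y[idx], x1[idx], x2[idx]),
                             error = function(e) NA_real_),
                    tryCatch(pc(y[idx], x2[idx], x1[idx]),
                             error = function(e) NA_real_))
  }
  a <- (1 - conf) / 2
  summarize <- function(est, bs) {
    bs <- bs[is.finite(bs)]
    list(estimate = est,
         ci = stats::quantile(bs, c(a, 1 - a), names = FALSE),
         p = bootstrap_p(bs, 0, side = if (est >= 0) "less" else "greater"))
  }
  list(r_x1 = summarize(est1, boots[, 1L]),
       r_x2 = summarize(est2, boots[, 2L]))
}
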