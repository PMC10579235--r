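#' Soft-normalized condition stack
#'
#' Stacks a rate tensor's cells vertically (all left-choice cells above all
#' right-choice cells, in condition order), dropping each cell's `NA` tail.
#' Each unit column is mean-centered and divided by the square root of its
#' 99th-percentile rate (computed before centering). Soft normalization
#' equalizes the contribution of high- and low-rate units to the PCA;
#' silent units (99th percentile zero) are left on their raw scale
#' (normalizer 1) and contribute zeros after centering.
#'
#' @param rate_tensor a `rate_tensor`.
#' @return list of class `soft_norm_stack`: `x` (rows x units), `col_means`,
#'   `normalizers`, `row_cell` (cell index per row), `row_time_ms`.
#' @export
soft_normalize_stack <- function(rate_tensor) {
  vals <- rate_tensor$values
  n_cells <- dim(vals)[3L]
  blocks <- vector("list", n_cells)
  row_cell <- integer(0)
  row_time <- numeric(0)
  for (ci in seq_len(n_cells)) {
    block <- vals[, , ci, drop = TRUE]
    if (is.null(dim(block))) block <- matrix(block, ncol = 1L)
    ok <- stats::complete.cases(block)
    blocks[[ci]] <- block[ok, , drop = FALSE]
    row_cell <- c(row_cell, rep(ci, sum(ok)))
    row_time <- c(row_time, rate_tensor$time_ms[ok])
  }
  x <- do.call(rbind, blocks)
  all_na <- colSums(!is.na(x)) == 0L
  if (any(all_na)) {
    stop("unit(s) with no observed rates: ",
         paste(rate_tensor$unit_ids[all_na], collapse = ", "))
  }
  q99 <- apply(x, 2L, stats::quantile, probs = 0.99, names = FALSE)
  normalizers <- ifelse(q99 > 0, sqrt(q99), 1)
  col_means <- colMeans(x)
  xn <- sweep(sweep(x, 2L, col_means), 2L, normalizers, "/")
  structure(list(x = xn, col_means = col_means, normalizers = normalizers,
                 row_cell = row_cell, row_time_ms = row_time,
                 unit_ids = rate_tensor$unit_ids),
            class = "soft_norm_stack")
}

# covariance eigenvalues of a (centered) matrix, divisor n - 1 (internal)
cov_eigenvalues <- function(x) {
  n <- nrow(x)
  ev <- eigen(crossprod(x) / (n - 1), symmetric = TRUE,
              only.values = TRUE)$values
  pmax(ev, 0)
}

#' Principal component analysis of a soft-normalized stack
#'
#' Standard PCA of the (already centered and normalized) stacked matrix.
#' Loading signs are fixed so each component's largest-magnitude element is
#' positive.
#'
#' @param x a `soft_norm_stack` or a numeric matrix (rows = samples,
#'   columns = units); a plain matrix is centered but not re-normalized.
#' @return object of class `pc_space`: `loadings` (units x components),
#'   `eigenvalues`, `explained_var`, `col_means`, `normalizers`,
#'   `n_signal_dims` (NA until estimated).
#' @export
fit_pca <- function(x) {
  col_means <- NULL; normalizers <- NULL; unit_ids <- NULL
  if (inherits(x, "soft_norm_stack")) {
    col_means <- x$col_means
    normalizers <- x$normalizers
    unit_ids <- x$unit_ids
    x <- x$x
  } else {
    if (any(!is.finite(x))) stop("non-finite entries in PCA input")
    col_means <- colMeans(x)
    x <- sweep(x, 2L, col_means)
    normalizers <- rep(1, ncol(x))
  }
  if (any(!is.finite(x))) stop("non-finite entries in PCA input")
  sv <- svd(x)
  eig <- sv$d^2 / (nrow(x) - 1)
  loadings <- sv$v
  flip <- apply(loadings, 2L, function(v) v[which.max(abs(v))] < 0)
  loadings[, flip] <- -loadings[, flip]
  structure(list(loadings = loadings, eigenvalues = eig,
                 explained_var = eig / sum(eig),
                 col_means = col_means, normalizers = normalizers,
                 unit_ids = unit_ids, n_signal_dims = NA_integer_),
            class = "pc_space")
}

#' @export
print.pc_space <- function(x, ...) {
  k <- min(6L, length(x$explained_var))
  cat("<pc_space> ", length(x$col_means), " units, ",
      length(x$eigenvalues), " components\n",
      "  top-", k, " explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_var[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  if (!is.na(x$n_signal_dims)) {
    cat("  signal dimensions:", x$n_signal_dims, "\n")
  }
  invisible(x)
}

#' Project a rate tensor into a PC space
#'
#' Applies the space's stored centering and normalizers, then the loadings,
#' producing one low-dimensional trajectory per (condition level x choice)
#' cell over that cell's own (truncated) time axis.
#'
#' @param rate_tensor a `rate_tensor` over the same units as `pcspace`.
#' @param pcspace a `pc_space`.
#' @param n_dims number of components to keep (default 6).
#' @param reference_level condition `level_index` of the reference
#'   trajectory (default: the middle level).
#' @return object of class `trajectory_set`: `trajectories` (list of
#'   time x n_dims matrices), `time` (list of ms axes), `cells` (data.frame),
#'   `reference_level`, `d`.
#' @export
project <- function(rate_tensor, pcspace, n_dims = 6L,
                    reference_level = NULL) {
  if (n_dims > ncol(pcspace$loadings)) {
    stop("n_dims exceeds available components")
  }
  if (length(rate_tensor$unit_ids) != nrow(pcspace$loadings)) {
    stop("unit mismatch between rate tensor and pc space")
  }
  if (!is.null(pcspace$unit_ids) &&
      !identical(rate_tensor$unit_ids, pcspace$unit_ids)) {
    stop("unit mismatch between rate tensor and pc space")
  }
  load6 <- pcspace$loadings[, seq_len(n_dims), drop = FALSE]
  n_cells <- dim(rate_tensor$values)[3L]
  trajectories <- vector("list", n_cells)
  times <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    block <- rate_tensor$values[, , ci, drop = TRUE]
    if (is.null(dim(block))) block <- matrix(block, ncol = 1L)
    ok <- stats::complete.cases(block)
    xn <- sweep(sweep(block[ok, , drop = FALSE], 2L, pcspace$col_means),
                2L, pcspace$normalizers, "/")
    trajectories[[ci]] <- xn %*% load6
    times[[ci]] <- rate_tensor$time_ms[ok]
  }
  levels <- sort(unique(rate_tensor$cells$level_index))
  if (is.null(reference_level)) {
    reference_level <- levels[ceiling(length(levels) / 2)]
  }
  structure(list(trajectories = trajectories, time = times,
                 cells = rate_tensor$cells,
                 reference_level = reference_level, d = n_dims),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", length(x$trajectories), " trajectories in ",
      x$d, " dims; reference level ", x$reference_level, "\n", sep = "")
  invisible(x)
}

#' Estimate the number of signal dimensions
#'
#' Trial-averaged rates mix signal with averaged noise, so raw PCA
#' eigenvalues overstate the signal dimensionality. Differences between
#' random disjoint trial pairs cancel the signal; scaling each pair
#' difference by \eqn{1/\sqrt{2M}} (M = number of pairs in that condition)
#' yields a conservative noise spectrum on the scale of the trial average.
#' Both the trial-averaged (signal+noise) matrix and the stacked noise
#' matrix are soft-normalized with the same normalizers and decomposed by
#' PCA; bootstrap resampling of trials gives an SEM for each signal+noise
#' eigenvalue. The estimated dimensionality is the last component before the
#' signal+noise eigenvalue first falls significantly below the noise
#' eigenvalue (by at least 3 SEM).
#'
#' @param trial_rates list over conditions; each element a 3-D array of
#'   per-trial rates, time x unit x trial (at least 2 trials per condition).
#' @param n_boot bootstrap resamples for eigenvalue SEMs.
#' @param seed RNG seed for pairing and bootstrap.
#' @return object of class `noise_dim_estimate`: `signal_plus_noise_eigs`,
#'   `noise_eigs`, `eig_sems`, `n_signal_dims`.
#' @export
estimate_signal_dims <- function(trial_rates, n_boot = 50L, seed = 1L) {
  set.seed(seed)
  if (!length(trial_rates)) stop("no conditions supplied")
  for (ci in seq_along(trial_rates)) {
    if (dim(trial_rates[[ci]])[3L] < 2L) {
      stop("condition ", ci, " has fewer than 2 trials")
    }
  }
  avg_blocks <- lapply(trial_rates, function(a) apply(a, c(1L, 2L), mean))
  signal <- do.call(rbind, avg_blocks)
  q99 <- apply(signal, 2L, stats::quantile, probs = 0.99, names = FALSE)
  normalizers <- ifelse(q99 > 0, sqrt(q99), 1)
  norm_center <- function(x) {
    scale(sweep(x, 2L, normalizers, "/"), center = TRUE, scale = FALSE)
  }
  sig_eigs <- cov_eigenvalues(norm_center(signal))

  noise_blocks <- vector("list", length(trial_rates))
  for (ci in seq_along(trial_rates)) {
    a <- trial_rates[[ci]]
    n_tr <- dim(a)[3L]
    perm <- sample.int(n_tr)
    m <- n_tr %/% 2L
    dsum <- 0
    for (p in seq_len(m)) {
      dsum <- dsum + a[, , perm[2L * p - 1L]] - a[, , perm[2L * p]]
    }
    # mean pair difference, rescaled so each entry has twice the variance of
    # the trial-averaged noise (a conservative noise floor); one block per
    # condition keeps the noise matrix the same shape as the signal matrix,
    # so the two eigenvalue spectra have comparable sampling spread
    noise_blocks[[ci]] <- dsum / (m * sqrt(2))
  }
  noise <- do.call(rbind, noise_blocks)
  noise_eigs <- cov_eigenvalues(norm_center(noise))

  n_comp <- min(length(sig_eigs), length(noise_eigs))
  boot_eigs <- matrix(NA_real_, n_boot, n_comp)
  for (b in seq_len(n_boot)) {
    boot_avg <- lapply(trial_rates, function(a) {
      idx <- sample.int(dim(a)[3L], replace = TRUE)
      apply(a[, , idx, drop = FALSE], c(1L, 2L), mean)
    })
    be <- cov_eigenvalues(norm_center(do.call(rbind, boot_avg)))
    boot_eigs[b, ] <- be[seq_len(n_comp)]
  }
  sems <- apply(boot_eigs, 2L, stats::sd)

  sig <- sig_eigs[seq_len(n_comp)]
  noi <- noise_eigs[seq_len(n_comp)]
  below <- which(sig < noi - 3 * sems)
  n_dims <- if (length(below)) below[1L] - 1L else n_comp
  structure(list(signal_plus_noise_eigs = sig_eigs,
                 noise_eigs = noise_eigs, eig_sems = sems,
                 n_signal_dims = n_dims),
            class = "noise_dim_estimate")
}

#' @export
print.noise_dim_estimate <- function(x, ...) {
  cat("<noise_dim_estimate> signal dimensions:", x$n_signal_dims, "\n")
  invisible(x)
}

#' Bootstrap trajectory sets
#'
#' For each bootstrap replicate, trials are resampled with replacement
#' independently for every unit within every condition cell; rates are
#' re-averaged, the PCA is refit and the rates are re-projected, yielding a
#' distribution of trajectory sets for error bars and bootstrap tests.
#'
#' @param session a `session_data`.
#' @param grouping conditioning passed to [condition_average()].
#' @param n_boot number of replicates.
#' @param seed RNG seed (replicates are deterministic given the seed).
#' @param n_dims projection dimensionality.
#' @param resample set `FALSE` to disable resampling (each replicate equals
#'   the point estimate; useful for testing).
#' @param ... further arguments to [condition_average()].
#' @return list of `trajectory_set` objects, length `n_boot`.
#' @export
bootstrap_trajectories <- function(session, grouping = "rt_bins",
                                   n_boot = 50L, seed = 1L, n_dims = 6L,
                                   resample = TRUE, ...) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  set.seed(seed)
  template <- condition_average(session, grouping = grouping, ...)
  kernel <- list(...)$kernel
  if (is.null(kernel)) kernel <- rate_kernel("gaussian", 30)
  trials <- session$trials
  window <- c(min(template$time_ms), max(template$time_ms) + 1L)
  event_time <- if (template$event == "checkerboard")
    trials$checkerboard_onset_ms else trials$movement_onset_ms
  n_units <- nrow(session$units)
  out <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    vals <- template$values
    for (ci in seq_along(template$trial_rows)) {
      rows_all <- template$trial_rows[[ci]]
      keep_na <- is.na(template$values[, 1L, ci])
      for (u in seq_len(n_units)) {
        rows <- if (resample) sample(rows_all, replace = TRUE) else rows_all
        rel <- unlist(session$spikes[[u]][rows], use.names = FALSE) -
          rep(event_time[rows], lengths(session$spikes[[u]][rows]))
        if (template$event == "checkerboard") {
          cut <- rep(trials$rt_ms[rows] - 50,
                     lengths(session$spikes[[u]][rows]))
          rel <- rel[rel < cut]
          occ <- occupancy_curve(trials$rt_ms[rows] - 50, window)
        } else {
          occ <- rep(length(rows), window[2L] - window[1L])
        }
        cnt <- bin_spikes(rel, window)
        sm_occ <- smooth_vec(occ, kernel)
        r <- 1000 * smooth_vec(cnt, kernel) / sm_occ
        r[sm_occ < 1e-3] <- NA_real_
        r[keep_na] <- NA_real_
        vals[, u, ci] <- r
      }
    }
    tens <- template
    tens$values <- vals
    out[[b]] <- project(tens, fit_pca(soft_normalize_stack(tens)),
                        n_dims = n_dims)
  }
  out
}
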