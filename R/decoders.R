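# spike-count tensor: trials x units x bins, aligned to checkerboard onset
# (internal). Bins start at window[1], width bin_ms, advancing by step_ms.
count_tensor <- function(session, bin_ms = 20, window = c(-600, 1200),
                         step_ms = bin_ms, units = NULL) {
  trials <- session$trials
  if (is.null(units)) units <- seq_len(nrow(session$units))
  starts <- seq(window[1L], window[2L] - bin_ms, by = step_ms)
  n_tr <- nrow(trials)
  out <- array(0, c(n_tr, length(units), length(starts)))
  for (ui in seq_along(units)) {
    sp <- session$spikes[[units[ui]]]
    for (i in seq_len(n_tr)) {
      rel <- sp[[i]] - trials$checkerboard_onset_ms[i]
      rel <- rel[rel >= window[1L] & rel < window[2L]]
      if (!length(rel)) next
      if (step_ms == bin_ms) {
        idx <- floor((rel - window[1L]) / bin_ms) + 1L
        idx <- idx[idx <= length(starts)]
        out[i, ui, ] <- tabulate(idx, nbins = length(starts))
      } else {
        for (bi in seq_along(starts)) {
          out[i, ui, bi] <- sum(rel >= starts[bi] & rel < starts[bi] + bin_ms)
        }
      }
    }
  }
  list(counts = out, bin_start_ms = starts, trial_rows = seq_len(n_tr))
}

# in-sample R^2 of OLS y ~ X (internal)
ols_r2 <- function(X, y) {
  fit <- stats::.lm.fit(cbind(1, X), y)
  res <- fit$residuals
  1 - sum(res^2) / sum((y - mean(y))^2)
}

#' Bin-wise reaction-time regression with shuffle null
#'
#' Per time bin, RT is regressed on all units' spike counts plus the
#' unsigned coherence; the in-sample R^2 is compared with a null built from
#' trial permutations of the spike matrix (RT and coherence stay aligned).
#' The coherence-only R^2 is reported as a baseline.
#'
#' @param session a `session_data`.
#' @param bin_ms bin width (default 20 ms).
#' @param window ms window around checkerboard onset (default -600..1200,
#'   i.e. 1800 ms of activity).
#' @param n_shuffles trial permutations for the null (default 500).
#' @param units optional unit indices (e.g. a random subset).
#' @param seed RNG seed for the permutations.
#' @return object of class `rt_regression_result`: data.frame `bins`
#'   (bin_start_ms, r2, null_p99, null_p01), `r2_coherence_only`,
#'   `rank_deficient` flag.
#' @export
rt_decoder <- function(session, bin_ms = 20, window = c(-600, 1200),
                       n_shuffles = 500L, units = NULL, seed = 1L) {
  if (nrow(session$units) < 2L && is.null(units)) {
    stop("need at least 2 units")
  }
  set.seed(seed)
  ct <- count_tensor(session, bin_ms, window, units = units)
  rt <- session$trials$rt_ms
  coh <- abs(session$trials$signed_coherence)
  n <- length(rt)
  perms <- replicate(n_shuffles, sample.int(n))
  n_pred <- dim(ct$counts)[2L] + 1L
  rank_deficient <- n <= n_pred
  r2 <- null_p99 <- null_p01 <- numeric(length(ct$bin_start_ms))
  for (bi in seq_along(ct$bin_start_ms)) {
    X <- cbind(ct$counts[, , bi], coh)
    r2[bi] <- ols_r2(X, rt)
    null_r2 <- vapply(seq_len(n_shuffles), function(s) {
      ols_r2(cbind(ct$counts[perms[, s], , bi], coh), rt)
    }, numeric(1))
    qs <- stats::quantile(null_r2, c(0.01, 0.99), names = FALSE)
    null_p01[bi] <- qs[1L]; null_p99[bi] <- qs[2L]
  }
  structure(list(
    bins = data.frame(bin_start_ms = ct$bin_start_ms, r2 = r2,
                      null_p99 = null_p99, null_p01 = null_p01),
    r2_coherence_only = ols_r2(matrix(coh, ncol = 1L), rt),
    rank_deficient = rank_deficient),
    class = "rt_regression_result")
}

# L2-regularized logistic regression by damped Newton iterations;
# minimizes mean log-loss + (lambda/2) sum(beta^2), intercept unpenalized
# (internal)
ridge_logit_fit <- function(X, y01, lambda, tol = 1e-6, maxit = 100L) {
  n <- nrow(X)
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  beta <- numeric(p)
  pen <- c(0, rep(lambda * n, p - 1L))
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(Xi, mu - y01)) + pen * beta
    if (max(abs(grad)) / n < tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xi * w, Xi)
    diag(H) <- diag(H) + pen + 1e-10
    beta <- beta - solve(H, grad)
  }
  beta
}

# stratified fold assignment (internal)
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# cross-validated accuracy of the ridge-logistic decoder on one bin's
# counts (internal)
cv_accuracy <- function(X, y01, n_folds = 5L) {
  fold <- stratified_folds(y01, n_folds)
  losses <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    lambda <- 1 / nrow(Xtr)             # penalty: 1 / in-fold observations
    beta <- ridge_logit_fit(Xtr, y01[tr], lambda)
    pred <- drop(cbind(1, Xte) %*% beta) > 0
    losses[f] <- mean(pred != (y01[!tr] == 1))
  }
  1 - mean(losses)
}

#' Bin-wise choice (or previous-outcome) decoding with shuffle null
#'
#' Per time bin, an L2-regularized logistic regression (penalty 1 over the
#' number of in-fold observations, predictors z-scored per training fold,
#' decision at p = 0.5) decodes the label from spike counts. Accuracy is 1
#' minus the mean 5-fold cross-validated misclassification loss. Classes are
#' balanced by random subsampling (without replacement) before fitting; a
#' label-permutation null gives per-bin significance thresholds.
#'
#' @param session a `session_data`.
#' @param target "choice" or "previous_outcome" (correct vs error; trials
#'   with no previous outcome are dropped).
#' @param bin_ms bin width (20 ms for choice; use 50 for outcome).
#' @param step_ms bin step (defaults to `bin_ms`; 25 ms steps give the
#'   72-window outcome layout over 1800 ms).
#' @param window ms window around checkerboard onset.
#' @param n_shuffles label permutations (default 500).
#' @param n_folds cross-validation folds.
#' @param units optional unit indices.
#' @param seed RNG seed (balancing, folds, permutations).
#' @return object of class `choice_decoder_result`: data.frame `bins`
#'   (bin_start_ms, accuracy, null_p99, null_p01), `class_counts`.
#' @export
choice_decoder <- function(session, target = c("choice", "previous_outcome"),
                           bin_ms = 20, step_ms = bin_ms,
                           window = c(-600, 1200), n_shuffles = 500L,
                           n_folds = 5L, units = NULL, seed = 1L) {
  target <- match.arg(target)
  set.seed(seed)
  trials <- session$trials
  if (target == "choice") {
    keep <- seq_len(nrow(trials))
    y <- trials$choice == "left"
  } else {
    keep <- which(trials$previous_outcome %in% c("correct", "error"))
    y <- trials$previous_outcome[keep] == "correct"
  }
  if (length(unique(y)) < 2L) stop("both classes must be present")
  # balance classes by subsampling the larger one
  n_min <- min(table(y))
  bal <- c(sample(which(y), n_min), sample(which(!y), n_min))
  keep <- keep[bal]
  y01 <- as.integer(y[bal])
  sub <- subset_trials(session, keep)
  ct <- count_tensor(sub, bin_ms, window, step_ms, units = units)
  acc <- null_p99 <- null_p01 <- numeric(length(ct$bin_start_ms))
  for (bi in seq_along(ct$bin_start_ms)) {
    X <- ct$counts[, , bi, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
    acc[bi] <- cv_accuracy(X, y01, n_folds)
    null_acc <- vapply(seq_len(n_shuffles), function(s) {
      cv_accuracy(X, sample(y01), n_folds)
    }, numeric(1))
    qs <- stats::quantile(null_acc, c(0.01, 0.99), names = FALSE)
    null_p01[bi] <- qs[1L]; null_p99[bi] <- qs[2L]
  }
  structure(list(
    bins = data.frame(bin_start_ms = ct$bin_start_ms, accuracy = acc,
                      null_p99 = null_p99, null_p01 = null_p01),
    class_counts = c(n_min, n_min), target = target),
    class = "choice_decoder_result")
}

#' Previous-outcome decoder (overlapping bins)
#'
#' Convenience wrapper around [choice_decoder()] with the outcome layout:
#' 50 ms windows stepped by 25 ms, giving 72 windows over 1800 ms.
#'
#' @inheritParams choice_decoder
#' @export
outcome_decoder <- function(session, bin_ms = 50, step_ms = 25,
                            window = c(-600, 1200), n_shuffles = 500L,
                            n_folds = 5L, units = NULL, seed = 1L) {
  choice_decoder(session, target = "previous_outcome", bin_ms = bin_ms,
                 step_ms = step_ms, window = window,
                 n_shuffles = n_shuffles, n_folds = n_folds, units = units,
                 seed = seed)
}

#' Per-neuron selectivity regressions
#'
#' For every unit and time bin, the firing rate (spike count over the bin
#' divided by the bin width) is regressed on the target (choice coded 0/1,
#' or RT in seconds), optionally partialling out the unsigned coherence.
#' A unit is significant in a bin when the 99% confidence interval of the
#' target coefficient excludes zero; by chance ~1% of units are expected to
#' be significant. Units with zero rate variance in a bin are skipped there
#' (counted in `n_skipped`) and treated as not significant; the reported
#' fraction is over all units.
#'
#' @param session a `session_data`.
#' @param target "choice" or "rt".
#' @param bin_ms regression bin width (default 50 ms).
#' @param step_ms bin step (default `bin_ms`; set 1 for a sliding window).
#' @param window ms window around checkerboard onset.
#' @param with_coherence include unsigned coherence as a covariate.
#' @param conf confidence level (default 0.99).
#' @return object of class `neuron_regression_result`: `bin_start_ms`,
#'   `beta` and `significant` (units x bins), `fraction_significant`,
#'   `n_skipped` per bin, `chance_level`.
#' @export
per_neuron_regression <- function(session, target = c("choice", "rt"),
                                  bin_ms = 50, step_ms = bin_ms,
                                  window = c(-600, 1200),
                                  with_coherence = FALSE, conf = 0.99) {
  target <- match.arg(target)
  trials <- session$trials
  n <- nrow(trials)
  if (n < 20L) stop("need at least 20 trials")
  y <- if (target == "choice") as.numeric(trials$choice == "left")
       else trials$rt_ms / 1000
  covar <- abs(trials$signed_coherence)
  if (with_coherence) {
    # Frisch-Waugh: residualize target and rates on the covariate
    y <- stats::resid(stats::lm(y ~ covar))
    df_loss <- 3L
  } else {
    df_loss <- 2L
  }
  yc <- y - mean(y)
  syy <- sum(yc^2)
  starts <- seq(window[1L], window[2L] - bin_ms, by = step_ms)
  n_units <- nrow(session$units)
  beta <- se <- matrix(NA_real_, n_units, length(starts))
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - df_loss)
  for (u in seq_len(n_units)) {
    cnt1 <- matrix(0, n, window[2L] - window[1L])
    for (i in seq_len(n)) {
      rel <- session$spikes[[u]][[i]] - trials$checkerboard_onset_ms[i]
      cnt1[i, ] <- bin_spikes(rel, window)
    }
    cum <- cbind(0, t(apply(cnt1, 1L, cumsum)))
    s0 <- starts - window[1L]
    fr <- (cum[, s0 + bin_ms + 1L, drop = FALSE] -
             cum[, s0 + 1L, drop = FALSE]) / (bin_ms / 1000)
    if (with_coherence) fr <- apply(fr, 2L, function(col)
      stats::resid(stats::lm(col ~ covar)))
    frc <- sweep(fr, 2L, colMeans(fr))
    sxy <- drop(crossprod(yc, frc))
    b <- sxy / syy
    rss <- colSums(frc^2) - b^2 * syy
    sigma2 <- pmax(rss, 0) / (n - df_loss)
    s <- sqrt(sigma2 / syy)
    zero_var <- colSums(frc^2) == 0
    b[zero_var] <- NA_real_; s[zero_var] <- NA_real_
    beta[u, ] <- b; se[u, ] <- s
  }
  significant <- abs(beta) > tcrit * se
  n_skipped <- colSums(is.na(beta))
  frac <- colSums(significant, na.rm = TRUE) / n_units
  structure(list(bin_start_ms = starts, beta = beta, se = se,
                 significant = significant,
                 fraction_significant = frac, n_skipped = n_skipped,
                 chance_level = 1 - conf, target = target),
            class = "neuron_regression_result")
}
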