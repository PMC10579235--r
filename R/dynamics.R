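#' Single-trial latent trajectories for dynamical-system fitting
#'
#' Bins single-trial spike counts (50 ms bins by default), converts to
#' rates, and projects them onto the top principal components of the pooled
#' single-trial data (centering only; no soft normalization at the
#' single-trial level).
#'
#' @param session a `session_data`.
#' @param epoch "prestimulus" (-600..0 ms) or "poststimulus" (0..1200 ms).
#' @param latent_dim number of PCs (2-10 typical).
#' @param bin_ms bin width.
#' @param choice fit one choice at a time ("left" default); `NULL` keeps all
#'   trials.
#' @param units optional unit indices.
#' @return list: `latents` (list of T x latent_dim matrices, one per trial),
#'   `rts` (ms), `trial_rows`, `bin_start_ms`.
#' @export
lds_latents <- function(session, epoch = c("prestimulus", "poststimulus"),
                        latent_dim = 6L, bin_ms = 50,
                        choice = "left", units = NULL) {
  epoch <- match.arg(epoch)
  window <- if (epoch == "prestimulus") c(-600, 0) else c(0, 1200)
  rows <- if (is.null(choice)) seq_len(nrow(session$trials))
          else which(session$trials$choice == choice)
  sub <- subset_trials(session, rows)
  ct <- count_tensor(sub, bin_ms, window, units = units)
  rates <- ct$counts / (bin_ms / 1000)      # trials x units x bins
  n_tr <- dim(rates)[1L]; n_b <- dim(rates)[3L]
  pooled <- do.call(rbind, lapply(seq_len(n_tr), function(i)
    t(rates[i, , , drop = TRUE])))
  if (latent_dim > ncol(pooled)) stop("latent_dim exceeds available PCs")
  mu <- colMeans(pooled)
  sv <- svd(scale(pooled, center = mu, scale = FALSE), nu = 0,
            nv = latent_dim)
  latents <- lapply(seq_len(n_tr), function(i) {
    x <- t(rates[i, , , drop = TRUE]) # bins x units
    sweep(x, 2L, mu) %*% sv$v
  })
  list(latents = latents, rts = sub$trials$rt_ms, trial_rows = rows,
       bin_start_ms = ct$bin_start_ms, loadings = sv$v, center = mu)
}

#' Fit an autonomous linear dynamical system to single-trial latents
#'
#' Models the change in latent activity over a fixed horizon as a linear
#' function of the current state: `X(t + horizon) - X(t) ~ X(t) J`, pooled
#' over trials, with J solved by least squares on the normalized Frobenius
#' objective (the normalization does not change the minimizer). The
#' cross-validated R^2 is `1 -` the normalized prediction error on each
#' held-out trial (leave-one-trial-out), averaged.
#'
#' @param latents list of T x d latent matrices (one per trial), e.g. from
#'   [lds_latents()].
#' @param horizon_bins prediction horizon in bins (default 2, i.e. 100 ms at
#'   50 ms bins).
#' @return object of class `lds_fit`: `J`, `latent_dim`, `cv_r2`,
#'   `train_r2`, `horizon_bins`.
#' @export
fit_lds <- function(latents, horizon_bins = 2L) {
  if (length(latents) < 3L) stop("need at least 3 trials")
  d <- ncol(latents[[1L]])
  s <- horizon_bins
  xs <- lapply(latents, function(L) L[seq_len(nrow(L) - s), , drop = FALSE])
  ys <- lapply(latents, function(L)
    L[(1L + s):nrow(L), , drop = FALSE] - L[seq_len(nrow(L) - s), ,
                                            drop = FALSE])
  X <- do.call(rbind, xs); Y <- do.call(rbind, ys)
  xtx <- crossprod(X); xty <- crossprod(X, Y)
  J <- solve(xtx + diag(1e-10, d), xty)
  train_r2 <- 1 - sum((Y - X %*% J)^2) / sum(Y^2)
  cv <- vapply(seq_along(latents), function(m) {
    xm <- xs[[m]]; ym <- ys[[m]]
    Jm <- solve(xtx - crossprod(xm) + diag(1e-10, d),
                xty - crossprod(xm, ym))
    denom <- sum(ym^2)
    if (denom == 0) return(NA_real_)
    1 - sum((ym - xm %*% Jm)^2) / denom
  }, numeric(1))
  structure(list(J = J, latent_dim = d, cv_r2 = mean(cv, na.rm = TRUE),
                 train_r2 = train_r2, horizon_bins = s),
            class = "lds_fit")
}

#' @export
print.lds_fit <- function(x, ...) {
  cat(sprintf("<lds_fit> dim %d, horizon %d bins, cv R2 = %.3f\n",
              x$latent_dim, x$horizon_bins, x$cv_r2))
  invisible(x)
}

#' Predicted latent trajectories under a fitted LDS
#'
#' One-step (horizon) prediction: `X_hat(t + horizon) = X(t) (I + J)`.
#'
#' @param object an `lds_fit`.
#' @param latents list of T x d latent matrices.
#' @param ... unused.
#' @return list of (T - horizon) x d predicted latent matrices.
#' @export
predict.lds_fit <- function(object, latents, ...) {
  s <- object$horizon_bins
  A <- diag(object$latent_dim) + object$J
  lapply(latents, function(L)
    L[seq_len(nrow(L) - s), , drop = FALSE] %*% A)
}

#' RT variance explained by latent activity, per time bin
#'
#' OLS of RT on the latent coordinates at each time bin, with a
#' trial-permutation null.
#'
#' @param latents list of T x d latent matrices (observed or LDS-predicted).
#' @param rts per-trial RTs (ms).
#' @param n_shuffles permutations for the null.
#' @param seed RNG seed.
#' @return data.frame: `bin`, `r2`, `null_p99`.
#' @export
lds_rt_regression <- function(latents, rts, n_shuffles = 500L, seed = 1L) {
  set.seed(seed)
  n_b <- nrow(latents[[1L]])
  n <- length(latents)
  perms <- replicate(n_shuffles, sample.int(n))
  out <- data.frame(bin = seq_len(n_b), r2 = NA_real_, null_p99 = NA_real_)
  for (t in seq_len(n_b)) {
    X <- do.call(rbind, lapply(latents, function(L) L[t, ]))
    out$r2[t] <- ols_r2(X, rts)
    null_r2 <- vapply(seq_len(n_shuffles), function(s)
      ols_r2(X[perms[, s], , drop = FALSE], rts), numeric(1))
    out$null_p99[t] <- stats::quantile(null_r2, 0.99, names = FALSE)
  }
  out
}

#' Reduced-rank regression with validation-based rank choice
#'
#' Fits `Y ~ X beta` with a rank constraint. The OLS solution is computed on
#' the training split; the rank-s solution keeps the top s singular triplets
#' of the fitted values (Eckart-Young), equivalently projects the OLS
#' coefficients onto the top right-singular vectors. The rank minimizing the
#' validation mean squared error is selected and its validation R^2
#' reported.
#'
#' @param X n x q predictor matrix (e.g. activity at t0 plus choice and
#'   coherence columns).
#' @param Y n x p response matrix (activity at t).
#' @param ranks candidate ranks (default 1..min(q, p)).
#' @param train_fraction trial fraction for the training split (default 0.8).
#' @param seed RNG seed for the split.
#' @return object of class `rrr_fit`: `beta` (q x p, chosen rank), `rank`,
#'   `val_mse` per candidate, `cv_r2`, `beta_ols`, `singular_values`.
#' @export
fit_rrr <- function(X, Y, ranks = NULL, train_fraction = 0.8, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  q <- ncol(X); p <- ncol(Y); n <- nrow(X)
  if (is.null(ranks)) ranks <- seq_len(min(q, p))
  if (any(ranks > min(q, p))) stop("candidate rank exceeds min(q, p)")
  set.seed(seed)
  tr <- sort(sample.int(n, max(2L, round(train_fraction * n))))
  va <- setdiff(seq_len(n), tr)
  if (!length(va)) stop("validation split is empty")
  Xt <- X[tr, , drop = FALSE]; Yt <- Y[tr, , drop = FALSE]
  xtx <- crossprod(Xt)
  beta_ols <- tryCatch(solve(xtx, crossprod(Xt, Yt)), error = function(e) {
    warning("singular X'X; using ridge-stabilized inverse")
    solve(xtx + diag(1e-8 * mean(diag(xtx)), q), crossprod(Xt, Yt))
  })
  yhat <- Xt %*% beta_ols
  sv <- svd(yhat)
  val_mse <- numeric(length(ranks))
  betas <- vector("list", length(ranks))
  for (k in seq_along(ranks)) {
    s <- ranks[k]
    Vs <- sv$v[, seq_len(s), drop = FALSE]
    betas[[k]] <- beta_ols %*% Vs %*% t(Vs)
    pred <- X[va, , drop = FALSE] %*% betas[[k]]
    val_mse[k] <- mean((Y[va, , drop = FALSE] - pred)^2)
  }
  # smallest rank within numerical tolerance of the minimum
  best <- which(val_mse <= min(val_mse) * (1 + 1e-9) + 1e-12)[1L]
  pred <- X[va, , drop = FALSE] %*% betas[[best]]
  Yv <- Y[va, , drop = FALSE]
  base <- sweep(Yv, 2L, colMeans(Yt))
  cv_r2 <- 1 - sum((Yv - pred)^2) / sum(base^2)
  structure(list(beta = betas[[best]], rank = ranks[best],
                 ranks = ranks, val_mse = val_mse, cv_r2 = cv_r2,
                 beta_ols = beta_ols, singular_values = sv$d,
                 train_rows = tr),
            class = "rrr_fit")
}

#' @export
print.rrr_fit <- function(x, ...) {
  cat(sprintf("<rrr_fit> chosen rank %d (of %s), validation R2 = %.3f\n",
              x$rank, paste(range(x$ranks), collapse = ".."), x$cv_r2))
  invisible(x)
}
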