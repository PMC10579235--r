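#' Weibull psychometric function
#'
#' Probability of a correct choice at unsigned coherence `C`:
#' \deqn{p(C) = 1 - 0.5 \exp(-(C/\alpha)^\gamma)}
#' At `C = alpha` the function equals `1 - 0.5/e`, i.e. 81.6% correct, which
#' is why `alpha` is called the discrimination threshold; `gamma` sets the
#' slope.
#'
#' @param C unsigned coherence (%), `>= 0` (vectorized).
#' @param alpha threshold (%), `> 0`.
#' @param gamma_slope slope, `> 0`.
#' @return proportion correct in `[0.5, 1)`.
#' @export
weibull_p <- function(C, alpha, gamma_slope) {
  if (alpha <= 0 || gamma_slope <= 0) {
    stop("alpha and gamma_slope must be positive")
  }
  if (any(C < 0)) stop("C must be >= 0")
  1 - 0.5 * exp(-(C / alpha)^gamma_slope)
}

#' Fit the Weibull psychometric function
#'
#' Nonlinear least squares on per-coherence proportions correct,
#' initialized at `alpha = median(coherences)`, `gamma = 1`.
#'
#' @param coherences unsigned coherences (%), at least 3 distinct values.
#' @param p_correct proportion correct per coherence.
#' @return list of class `psychometric_fit`: `alpha`, `gamma_slope`, `r2`,
#'   `fitted`.
#' @export
fit_weibull <- function(coherences, p_correct) {
  if (length(unique(coherences)) < 3L) {
    stop("need at least 3 distinct coherences")
  }
  if (length(coherences) != length(p_correct)) {
    stop("coherences and p_correct lengths differ")
  }
  if (stats::sd(p_correct) == 0) {
    stop("degenerate input: all proportions equal; cannot fit")
  }
  df <- data.frame(C = coherences, p = p_correct)
  fit <- tryCatch(
    stats::nls(p ~ 1 - 0.5 * exp(-(C / alpha)^gam), data = df,
               start = list(alpha = stats::median(coherences), gam = 1),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE),
               lower = c(alpha = 1e-6, gam = 1e-6), algorithm = "port"),
    error = function(e) stop("Weibull fit failed: ", conditionMessage(e))
  )
  cf <- stats::coef(fit)
  fitted_p <- weibull_p(coherences, cf[["alpha"]], cf[["gam"]])
  ss_res <- sum((p_correct - fitted_p)^2)
  ss_tot <- sum((p_correct - mean(p_correct))^2)
  structure(list(alpha = unname(cf[["alpha"]]),
                 gamma_slope = unname(cf[["gam"]]),
                 r2 = 1 - ss_res / ss_tot,
                 fitted = fitted_p),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Weibull psychometric fit: alpha = %.3f%%, gamma = %.3f, R2 = %.4f\n",
              x$alpha, x$gamma_slope, x$r2))
  invisible(x)
}

#' Variance in RT explained by log10 coherence
#'
#' Ordinary least-squares regression of RT on `log10(C)`; returns the R^2 of
#' the fit (1 minus the residual sum of squares over the total sum of
#' squares).
#'
#' @param rts reaction times (ms).
#' @param C unsigned coherences (%), all positive.
#' @return R^2 as a proportion.
#' @export
rt_coherence_r2 <- function(rts, C) {
  if (any(C <= 0)) stop("coherences must be positive")
  fit <- stats::lm(rts ~ log10(C))
  pred <- stats::fitted(fit)
  1 - sum((rts - pred)^2) / sum((rts - mean(rts))^2)
}

#' Post-outcome reaction-time comparison
#'
#' Identifies error-then-correct (EC) trial pairs and correct-then-correct
#' (CC) pairs, matching each EC pair to the nearest CC pair in trial order
#' (earlier preferred on ties) where the sequences do not already align, and
#' compares the second-trial RTs with a two-sided Wilcoxon rank-sum test.
#'
#' @param trials trial table with `correct` and `rt_ms` (trial order given by
#'   row order).
#' @return list of class `outcome_sequence_stats`: `ec_rts`, `cc_rts`,
#'   `median_ec`, `median_cc`, `p_value` (NA when either group has fewer than
#'   two members).
#' @export
post_outcome_rt_comparison <- function(trials) {
  correct <- trials$correct
  rt <- trials$rt_ms
  n <- length(correct)
  if (n < 2L) stop("need at least two trials")
  second <- 2:n
  ec_idx <- second[!correct[second - 1L] & correct[second]]
  cc_idx <- second[correct[second - 1L] & correct[second]]
  if (length(ec_idx) == 0L) {
    return(structure(list(ec_rts = numeric(0), cc_rts = numeric(0),
                          median_ec = NA_real_, median_cc = NA_real_,
                          p_value = NA_real_, n_ec = 0L, n_cc = 0L),
                     class = "outcome_sequence_stats"))
  }
  if (length(cc_idx) == 0L) {
    stop("no CC sequences available for comparison")
  }
  # each EC is matched to the nearest CC in trial index (earlier on ties)
  matched_cc <- vapply(ec_idx, function(i) {
    d <- abs(cc_idx - i)
    cc_idx[which.min(d)]   # which.min takes the first (earlier) minimum
  }, numeric(1))
  ec_rts <- rt[ec_idx]
  cc_rts <- rt[matched_cc]
  p <- if (length(ec_rts) >= 2L && length(cc_rts) >= 2L) {
    stats::wilcox.test(ec_rts, cc_rts, exact = FALSE)$p.value
  } else {
    NA_real_
  }
  structure(list(ec_rts = ec_rts, cc_rts = cc_rts,
                 median_ec = stats::median(ec_rts),
                 median_cc = stats::median(cc_rts),
                 p_value = p,
                 n_ec = length(ec_rts), n_cc = length(cc_rts)),
            class = "outcome_sequence_stats")
}

#' @export
print.outcome_sequence_stats <- function(x, ...) {
  cat(sprintf("EC vs CC second-trial RTs: median %.1f vs %.1f ms (n = %d/%d), rank-sum p = %s\n",
              x$median_ec, x$median_cc, x$n_ec, x$n_cc,
              format(x$p_value, digits = 3)))
  invisible(x)
}
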