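#' Subspace alignment index
#'
#' Fraction of one conditioning's firing-rate variance captured by another
#' conditioning's top principal subspace:
#' \deqn{A = tr(D^T C D) / \sum_i \sigma_i}
#' where C is the covariance of the target conditioning's (soft-normalized,
#' stacked) rates, D holds the source conditioning's top eigenvectors, and
#' the denominator is the target's total variance (all eigenvalues).
#'
#' @param cov_target symmetric covariance matrix of the target conditioning.
#' @param basis_source units x k orthonormal basis (e.g. top-6 loadings of
#'   the other conditioning's PC space).
#' @param eigs_target eigenvalues of `cov_target` (computed if omitted).
#' @return object of class `alignment_index_result`: `A`,
#'   `n_dims_numerator`, `captured_variance`, `total_variance`.
#' @export
alignment_index <- function(cov_target, basis_source, eigs_target = NULL) {
  D <- as.matrix(basis_source)
  C <- as.matrix(cov_target)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8) {
    stop("cov_target must be symmetric")
  }
  if (max(abs(crossprod(D) - diag(ncol(D)))) > 1e-6) {
    stop("basis_source must be orthonormal")
  }
  if (is.null(eigs_target)) {
    eigs_target <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  }
  captured <- sum(diag(crossprod(D, C %*% D)))
  total <- sum(eigs_target)
  structure(list(A = captured / total, n_dims_numerator = ncol(D),
                 captured_variance = captured, total_variance = total),
            class = "alignment_index_result")
}

#' @export
print.alignment_index_result <- function(x, ...) {
  cat(sprintf("alignment index A = %.3f (%d numerator dims)\n",
              x$A, x$n_dims_numerator))
  invisible(x)
}

#' Alignment index between two conditionings of the same session
#'
#' Builds both conditionings' soft-normalized stacks, takes the covariance
#' and full eigenvalue spectrum of the target conditioning and the top-k
#' loadings of the source conditioning, and evaluates the alignment index.
#' Both stacks share the preprocessing used for PCA.
#'
#' @param tensor_target,tensor_source `rate_tensor`s over the same units.
#' @param n_dims numerator dimensions (default 6).
#' @return an `alignment_index_result`.
#' @export
alignment_between <- function(tensor_target, tensor_source, n_dims = 6L) {
  st_t <- soft_normalize_stack(tensor_target)
  st_s <- soft_normalize_stack(tensor_source)
  pc_t <- fit_pca(st_t)
  pc_s <- fit_pca(st_s)
  C <- stats::cov(st_t$x)
  alignment_index(C, pc_s$loadings[, seq_len(n_dims), drop = FALSE],
                  eigs_target = pc_t$eigenvalues)
}

#' Cross-project one conditioning's rates into another's PC space
#'
#' Applies the source space's centering, normalizers and loadings to the
#' target tensor's rates, returning the projected trajectories and the
#' fraction of the target's (normalized) variance the source subspace
#' captures. Structured trajectories under cross-projection indicate
#' overlapping subspaces; an unstructured projection indicates independent
#' ones.
#'
#' @param rate_tensor target conditioning's `rate_tensor`.
#' @param pcspace source conditioning's `pc_space` (same units).
#' @param n_dims projection dimensionality (default 6).
#' @return list of class `cross_projection`: `trajset` (a `trajectory_set`),
#'   `captured_fraction`.
#' @export
cross_project <- function(rate_tensor, pcspace, n_dims = 6L) {
  trajset <- project(rate_tensor, pcspace, n_dims = n_dims)
  stack <- soft_normalize_stack(rate_tensor)
  # re-apply the source space's preprocessing to the raw stacked rates
  raw <- sweep(sweep(stack$x, 2L, stack$normalizers, "*"), 2L,
               stack$col_means, "+")
  xn <- sweep(sweep(raw, 2L, pcspace$col_means), 2L, pcspace$normalizers,
              "/")
  xn <- scale(xn, center = TRUE, scale = FALSE)
  total <- sum(xn^2)
  scores <- xn %*% pcspace$loadings[, seq_len(n_dims), drop = FALSE]
  structure(list(trajset = trajset, captured_fraction = sum(scores^2) / total),
            class = "cross_projection")
}
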