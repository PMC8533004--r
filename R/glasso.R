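#' Maximum-likelihood empirical covariance
#'
#' Covariance of the binned log-count matrix with cells as observations and
#' bins as variables, normalized by the number of cells m (the ML form of
#' the Gaussian likelihood, not m - 1).
#'
#' @param X cells x bins numeric matrix (a `binned_matrix$values` or an
#'   imputed completion).
#' @return symmetric positive semi-definite bins x bins covariance matrix.
#' @export
empirical_covariance <- function(X) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 2L) stopf("need at least 2 cells to estimate a covariance")
  if (ncol(X) < 2L) stopf("need at least 2 bins")
  Xc <- sweep(X, 2L, colMeans(X))
  crossprod(Xc) / m
}

#' Sparse precision estimation by graphical lasso with a penalty matrix
#'
#' Maximizes `log det(Theta) - tr(S Theta) - sum_ij rho_ij |Theta_ij|` over
#' positive-definite `Theta` by block coordinate descent, where the L1
#' penalty `rho` may differ per bin pair (only off-diagonal entries are
#' penalized; the penalty diagonal is zero). Pairs with large `rho_ij` are
#' shrunk exactly to zero; pairs with prior Hi-C contact evidence receive a
#' small penalty and survive.
#'
#' Singular covariances (more bins than cells, the usual single-cell regime)
#' are stabilized by a jitter `1e-6 * trace(S)/p` on the diagonal before
#' fitting.
#'
#' @param cov symmetric covariance matrix (e.g. [empirical_covariance()]).
#' @param rho a `penalty_matrix`, or a symmetric non-negative matrix with
#'   zero diagonal, or a single non-negative scalar.
#' @param tol relative objective-change convergence tolerance (default 1e-4).
#' @param max_iter maximum outer sweeps (default 100).
#' @return object of class `precision_fit`: `theta` (symmetric positive
#'   definite precision), `cov` (the input covariance), `rho`, `pcor`
#'   (partial correlations), `objective_trace`, `converged`, `n_edges`
#'   (off-diagonal nonzeros of theta above 1e-10, unordered pairs).
#' @export
fit_glasso <- function(cov, rho, tol = 1e-4, max_iter = 100L) {
  S <- as.matrix(cov)
  p <- nrow(S)
  if (p != ncol(S) || max(abs(S - t(S))) > 1e-8 * max(abs(S), 1))
    stopf("cov must be a symmetric square matrix")
  S <- 0.5 * (S + t(S))
  R <- penalty_as_matrix(rho, p)
  if (any(R < 0)) stopf("penalty must be non-negative")
  if (max(abs(R - t(R))) > 1e-12) stopf("penalty must be symmetric")
  diag(R) <- 0

  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8 * mean(diag(S))) {
    lambda <- 1e-6 * sum(diag(S)) / p
    S <- S + diag(lambda + max(0, -ev_min), p)
  }

  fit <- glasso_cd(S, R, tol = tol, max_iter = as.integer(max_iter),
                   inner_tol = tol * 1e-2, inner_max = 1000L)
  theta <- fit$theta
  if (!isTRUE(fit$converged))
    warnf("fit_glasso did not converge in %d sweeps (rel. objective change > %g)",
          fit$sweeps, tol)
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stopf("estimated precision matrix is not positive definite")
  theta[abs(theta) < 1e-10] <- 0          # numerical zero convention
  structure(list(theta = theta, cov = cov, rho = R,
                 pcor = partial_correlations(theta),
                 objective_trace = fit$objective_trace,
                 converged = isTRUE(fit$converged),
                 n_edges = sum(theta[upper.tri(theta)] != 0)),
            class = "precision_fit")
}

penalty_as_matrix <- function(rho, p) {
  if (inherits(rho, "penalty_matrix")) rho <- rho$rho
  if (is.matrix(rho)) {
    if (nrow(rho) != p) stopf("penalty dimension %d != covariance dimension %d",
                              nrow(rho), p)
    return(rho)
  }
  if (length(rho) == 1L) {
    R <- matrix(as.numeric(rho), p, p); diag(R) <- 0
    return(R)
  }
  stopf("rho must be a penalty_matrix, a matrix, or a scalar")
}

#' Partial correlations from a precision matrix
#'
#' `pcor_ij = -theta_ij / sqrt(theta_ii * theta_jj)`, with unit diagonal.
#' The partial correlation is the association between two bins after
#' conditioning on all other bins, the co-accessibility score used for
#' interaction calls.
#'
#' @param theta symmetric matrix with positive diagonal.
#' @return symmetric matrix of partial correlations in \[-1, 1\].
#' @export
partial_correlations <- function(theta) {
  d <- diag(theta)
  if (any(d <= 0)) stopf("precision diagonal must be positive")
  s <- 1 / sqrt(d)
  pc <- -theta * tcrossprod(s)
  diag(pc) <- 1
  pc
}

#' @export
print.precision_fit <- function(x, ...) {
  cat(sprintf(
    "<precision_fit> %d bins, %d edges, objective %.6g (%s, %d sweeps)\n",
    nrow(x$theta), x$n_edges, tail(x$objective_trace, 1),
    if (x$converged) "converged" else "NOT converged",
    length(x$objective_trace)))
  invisible(x)
}
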