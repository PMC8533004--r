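#' Initialize the right factor from a singular value decomposition
#'
#' Returns the top-`r` right singular vectors of `X` as the rows of the
#' initial factor `Vf` (r x n) for [mm_factorize()].
#'
#' @param X m x n matrix, finite.
#' @param r target rank, `r < min(m, n)`.
#' @return r x n matrix whose rows are orthonormal.
#' @export
svd_init <- function(X, r) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("svd_init requires a finite matrix")
  if (r >= min(dim(X)) || r < 1L)
    stopf("rank r must satisfy 1 <= r < min(m, n); got r = %s", format(r))
  sv <- svd(X, nu = 0L, nv = r)
  t(sv$v)
}

#' One majorization step of the masked completion objective
#'
#' Computes the surrogate target `B = Xk + (1/a) * A * (Y - A * Xk)` where
#' the mask operator `A` acts elementwise (Hadamard) and is its own adjoint
#' for 0/1 masks. On observed entries with `a = 1` this replaces the current
#' estimate by the data; unobserved entries keep the current estimate.
#'
#' @param Y observed matrix. @param A 0/1 mask, same shape (1 = observed).
#' @param Xk current completed estimate. @param a scalar step constant > 0;
#'   valid majorization needs `a >=` the spectral norm of the mask operator,
#'   which is 1 for a binary elementwise mask.
#' @return matrix B, same shape as Y.
#' @export
majorize_step <- function(Y, A, Xk, a = 1) {
  if (a <= 0) stopf("majorization constant a must be > 0")
  Xk + (1 / a) * (A * (Y - A * Xk))
}

#' Alternating least-squares factor updates
#'
#' Updates `Uf` with `Vf` fixed, then `Vf` with the new `Uf` fixed, each by
#' minimizing the Frobenius distance to `B`. Rank-deficient Gram matrices are
#' handled by the pseudoinverse, so the update never fails.
#'
#' @param B surrogate target (m x n). @param Uf m x r. @param Vf r x n.
#' @return list with updated `Uf`, `Vf`.
#' @export
update_factors <- function(B, Uf, Vf) {
  Uf <- t(pinv_solve(tcrossprod(Vf), Vf %*% t(B)))     # argmin ||B - U Vf||
  Vf <- pinv_solve(crossprod(Uf), crossprod(Uf, B))    # argmin ||B - Uf V||
  list(Uf = Uf, Vf = Vf)
}

pinv_solve <- function(G, rhs) {
  # solve G x = rhs via pseudoinverse when G is singular
  out <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (!is.null(out)) return(out)
  sv <- svd(G)
  pos <- sv$d > max(dim(G)) * .Machine$double.eps * max(sv$d, 1)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (dinv * (t(sv$u) %*% rhs))
}

#' Low-rank matrix completion by majorization-minimization
#'
#' Denoises/completes a cells x bins matrix by alternating low-rank
#' factorization under an elementwise observation mask, with a non-negativity
#' truncation of the completed estimate after every iteration. The masked
#' Frobenius cost `||A * (Y - X)||_F^2` is non-increasing across iterations.
#'
#' @param Y observed matrix (m x n).
#' @param A 0/1 mask, 1 = observed. Default all ones (pure low-rank
#'   denoising). `mask = "zeros"` in [run_pipeline()] marks exact zeros
#'   unobserved instead.
#' @param r target rank; default `min(50, floor(min(m, n) / 2))`.
#' @param a majorization step constant (>= spectral norm of the mask, i.e. 1).
#' @param max_iter,tol stop when the relative cost change drops below `tol`
#'   or after `max_iter` iterations.
#' @return list of class `mm_fit`: `X` (completed, non-negative), `Uf`, `Vf`,
#'   `cost` (per-iteration masked cost trace), `iterations`, `converged`,
#'   `singular_values` (of Y, to aid rank choice).
#' @export
mm_factorize <- function(Y, A = NULL, r = NULL, a = 1,
                         max_iter = 200L, tol = 1e-5) {
  Y <- as.matrix(Y)
  m <- nrow(Y); n <- ncol(Y)
  if (is.null(A)) A <- matrix(1, m, n) else A <- (as.matrix(A) != 0) * 1
  if (a <= 0) stopf("majorization constant a must be > 0")
  if (all(A == 0)) {
    warnf("all-zero observation mask: nothing observed, returning zeros")
    return(structure(list(X = matrix(0, m, n), cost = 0, iterations = 0L,
                          converged = TRUE), class = "mm_fit"))
  }
  if (is.null(r)) r <- max(1L, min(50L, floor(min(m, n) / 2)))
  if (r >= min(m, n)) stopf("rank r must be < min(m, n)")
  Yobs <- A * Y
  sv <- svd(Yobs, nu = 0L, nv = r)
  Vf <- t(sv$v)
  Uf <- Yobs %*% t(Vf)                  # Vf rows orthonormal
  Xk <- pmax(Uf %*% Vf, 0)
  cost <- sum((A * (Y - Xk))^2)
  trace <- cost
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    B <- majorize_step(Y, A, Xk, a)
    fu <- update_factors(B, Uf, Vf)
    Uf <- fu$Uf; Vf <- fu$Vf
    Xk <- pmax(Uf %*% Vf, 0)
    new_cost <- sum((A * (Y - Xk))^2)
    trace <- c(trace, new_cost)
    if (abs(cost - new_cost) <= tol * max(cost, .Machine$double.eps)) {
      converged <- TRUE; cost <- new_cost; break
    }
    cost <- new_cost
  }
  structure(list(X = Xk, Uf = Uf, Vf = Vf, cost = trace,
                 iterations = length(trace) - 1L, converged = converged,
                 singular_values = sv$d),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> %d x %d, %d iterations, final masked cost %.4g%s\n",
              nrow(x$X), ncol(x$X), x$iterations, tail(x$cost, 1),
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}
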