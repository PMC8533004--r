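# Independent oracles for the graphical-model tests. These never call the
# package's own solver path.

# penalized log-likelihood: log det Theta - tr(S Theta) - sum Rho |Theta|
oracle_objective <- function(Theta, S, Rho) {
  ev <- eigen((Theta + t(Theta)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(-Inf)
  sum(log(ev)) - sum(S * Theta) - sum(Rho * abs(Theta))
}

# Proximal-gradient (ISTA with backtracking) maximizer of the penalized
# log-likelihood; independent convex-optimization route used as the oracle
# for the block coordinate-descent solver.
oracle_glasso <- function(S, Rho, tol = 1e-10, max_iter = 50000L) {
  p <- nrow(S)
  Rho <- Rho; diag(Rho) <- 0
  Theta <- diag(1 / pmax(diag(S), 1e-8))
  g <- function(Th) {          # smooth part of the NEGATIVE objective
    ev <- eigen((Th + t(Th)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(Inf)
    -sum(log(ev)) + sum(S * Th)
  }
  gk <- g(Theta)
  t_step <- 1
  for (k in seq_len(max_iter)) {
    Grad <- S - solve(Theta)           # gradient of g
    repeat {
      Z <- Theta - t_step * Grad
      Cand <- sign(Z) * pmax(abs(Z) - t_step * Rho, 0)
      Cand <- (Cand + t(Cand)) / 2
      gc_ <- g(Cand)
      D <- Cand - Theta
      if (is.finite(gc_) &&
          gc_ <= gk + sum(Grad * D) + sum(D * D) / (2 * t_step) + 1e-14)
        break
      t_step <- t_step / 2
      if (t_step < 1e-14) { Cand <- Theta; gc_ <- gk; break }
    }
    delta <- max(abs(Cand - Theta))
    Theta <- Cand; gk <- gc_
    t_step <- min(t_step * 2, 1)
    if (delta < tol) break
  }
  list(theta = Theta, objective = oracle_objective(Theta, S, Rho))
}

# random well-conditioned covariance of dimension p
random_cov <- function(p, n = 10 * p) {
  X <- matrix(rnorm(n * p), n, p)
  crossprod(X) / n + diag(0.1, p)
}

# random symmetric non-negative penalty with zero diagonal
random_penalty <- function(p, max_rho = 0.3) {
  R <- matrix(runif(p * p, 0, max_rho), p, p)
  R <- (R + t(R)) / 2
  diag(R) <- 0
  R
}

# scikit-learn graphical lasso as the scalar-penalty reference (same image
# provides `python`); returns the precision matrix.
sklearn_glasso <- function(S, alpha) {
  f_in <- tempfile(fileext = ".csv"); f_out <- tempfile(fileext = ".csv")
  utils::write.table(S, f_in, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.covariance import graphical_lasso\n",
    "S = np.loadtxt('%s', delimiter=',')\n",
    "cov, prec = graphical_lasso(S, alpha=%.17g, tol=1e-12, enet_tol=1e-12,\n",
    "                            max_iter=10000)\n",
    "np.savetxt('%s', prec, delimiter=',')\n"), f_in, alpha, f_out)
  f_py <- tempfile(fileext = ".py")
  writeLines(script, f_py)
  status <- system2("python", f_py, stdout = TRUE, stderr = TRUE)
  if (!file.exists(f_out))
    stop("sklearn reference failed: ", paste(status, collapse = "\n"))
  as.matrix(utils::read.table(f_out, sep = ","))
}

# brute-force two-pass covariance (independent of empirical_covariance)
brute_cov <- function(X) {
  m <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    out[i, j] <- sum((X[, i] - mu[i]) * (X[, j] - mu[j])) / m
  out
}
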