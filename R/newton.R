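# Ridge-penalized logistic regression by damped Newton iteration.
# Used for the prediction-stage models: groups are small (p of order
# tens), the ridge floor keeps the Hessian positive definite even under
# perfect separation, and Newton converges in a handful of iterations.
.newtonRidgeLogistic <- function(X, y, ridge, max_iter = 200L,
                                 tol = 1e-10) {
  n <- nrow(X)
  Xa <- cbind(`(Intercept)` = 1, X)
  k <- ncol(Xa)
  pen <- c(0, rep(ridge, k - 1L))  # intercept unpenalized
  beta <- numeric(k)
  obj <- function(b) {
    eta <- drop(Xa %*% b)
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      sum(pen * b^2) / 2
  }
  f0 <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    pr <- plogis(eta)
    g <- drop(crossprod(Xa, pr - y)) / n + pen * beta
    W <- pmax(pr * (1 - pr), 1e-10)
    H <- crossprod(Xa, Xa * W) / n + diag(pen, k)
    step <- solve(H, g)
    # halve until the objective does not increase
    s <- 1
    repeat {
      bnew <- beta - s * step
      fnew <- obj(bnew)
      if (fnew <= f0 + 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    delta <- max(abs(bnew - beta))
    beta <- bnew
    f0 <- fnew
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = beta[-1L], intercept = beta[1L], converged = converged,
       n_iter = it)
}
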