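# Independent oracles used to check package computations.  Each one is
# a direct, brute-force or closed-form route that shares no code with
# the implementation it checks.

# dense Newton solver for ridge-penalized logistic regression
# (objective: (1/n) NLL + lambda * sum_j w_j beta_j^2 / 2)
oracle_ridge_logistic <- function(X, y, lambda, w = rep(1, ncol(X))) {
  n <- nrow(X)
  Xa <- cbind(1, X)
  beta <- numeric(ncol(Xa))
  pen <- c(0, lambda * w)
  for (it in 1:500) {
    eta <- drop(Xa %*% beta)
    pr <- plogis(eta)
    g <- drop(crossprod(Xa, pr - y)) / n + pen * beta
    H <- crossprod(Xa, Xa * pmax(pr * (1 - pr), 1e-12)) / n + diag(pen)
    d <- solve(H, g)
    beta <- beta - d
    if (max(abs(d)) < 1e-13) break
  }
  list(intercept = beta[1L], beta = beta[-1L])
}

# KKT residual of the weighted elastic-net logistic objective at a fit
kkt_residual <- function(fit, X, y) {
  n <- nrow(X)
  pr <- plogis(fit$intercept + drop(X %*% fit$beta))
  g <- drop(crossprod(X, pr - y)) / n +
    fit$lambda * (1 - fit$alpha) * fit$weights * fit$beta
  l1 <- fit$lambda * fit$alpha * fit$weights
  r <- ifelse(abs(fit$beta) > 1e-10,
              abs(g + l1 * sign(fit$beta)),
              pmax(0, abs(g) - l1))
  max(c(r, abs(mean(pr - y))))
}

# penalized objective value of a fit (for descent checks)
enet_objective <- function(fit, X, y) {
  eta <- fit$intercept + drop(X %*% fit$beta)
  nll <- mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  nll + fit$lambda * sum(fit$weights *
    ((1 - fit$alpha) * fit$beta^2 / 2 + fit$alpha * abs(fit$beta)))
}

# all-pairs AUC with half credit for ties
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# hand-rolled quantile normalization: per-rank means, ties averaged
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    out[, j] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  out
}

# Benjamini-Hochberg step-up closed form
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)
}

# exact two-sided rank-sum p by enumerating all group assignments
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- combn(length(pooled), n1)
  us <- apply(sets, 2L, function(i)
    sum(r[i]) - n1 * (n1 + 1) / 2)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# standardize columns to mean 0, population SD 1
stdcols <- function(X) {
  X <- scale(X)
  X <- X * sqrt(nrow(X) / (nrow(X) - 1L))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}
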