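test_that("ridge fits match the independent Newton oracle on random instances", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(12:30, 1)
    p <- sample(2:5, 1)
    X <- stdcols(matrix(rnorm(n * p), n, p))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    w <- runif(p, 0.5, 2)
    lam <- runif(1, 0.05, 0.5)
    fit <- fitEnetLogistic(X, y, lam, weights = w,
                           control = enetControl(alpha = 0, tol = 1e-11))
    ora <- oracle_ridge_logistic(X, y, lam, w)
    expect_lt(max(abs(c(fit$intercept - ora$intercept,
                        fit$beta - ora$beta))), 1e-6)
  }
})

test_that("KKT conditions hold at elastic-net solutions", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(12:30, 1)
    p <- sample(2:5, 1)
    X <- stdcols(matrix(rnorm(n * p), n, p))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    w <- runif(p, 0.5, 2)
    fit <- fitEnetLogistic(X, y, runif(1, 0.02, 0.4), weights = w,
                           control = enetControl(alpha = 0.5, tol = 1e-9))
    expect_lt(kkt_residual(fit, X, y), 1e-6)
    # objective no worse than the intercept-only start
    null_fit <- fit
    null_fit$beta[] <- 0
    null_fit$intercept <- qlogis(mean(y))
    expect_lte(enet_objective(fit, X, y),
               enet_objective(null_fit, X, y) + 1e-12)
  }
})

test_that("solution is invariant under (w, lambda) -> (c w, lambda / c)", {
  set.seed(7)
  X <- stdcols(matrix(rnorm(20 * 4), 20, 4))
  y <- rep(c(0, 1), each = 10)
  w <- runif(4, 0.5, 2)
  cc <- 3.7
  fa <- fitEnetLogistic(X, y, 0.2, weights = w,
                        control = enetControl(tol = 1e-11))
  fb <- fitEnetLogistic(X, y, 0.2 / cc, weights = cc * w,
                        control = enetControl(tol = 1e-11))
  expect_lt(max(abs(fa$beta - fb$beta)), 1e-8)
  expect_lt(abs(fa$intercept - fb$intercept), 1e-8)
})

test_that("fully penalized limit gives zero coefficients and the null intercept", {
  set.seed(8)
  X <- stdcols(matrix(rnorm(24 * 3), 24, 3))
  y <- rep(c(0, 1), c(9, 15))
  fit <- fitEnetLogistic(X, y, 1e6, control = enetControl(tol = 1e-10))
  expect_identical(unname(fit$beta), rep(0, 3))
  expect_lt(abs(fit$intercept - qlogis(mean(y))), 1e-6)
})

test_that("lambdaMax marks the all-zero boundary from both sides", {
  # single-column closed form: |x . (y - ybar)| / (n alpha w) = 1
  Xe <- matrix(c(1, 1, -1, -1), 4, 1)
  ye <- c(1, 1, 0, 0)
  expect_equal(lambdaMax(Xe, ye, alpha = 0.5), 1.0)
  # doubling a gene's weight halves its contribution to the max
  set.seed(9)
  X <- stdcols(matrix(rnorm(20 * 3), 20, 3))
  y <- rep(c(0, 1), each = 10)
  score <- abs(drop(crossprod(X, y - mean(y)))) / (20 * 0.5)
  expect_equal(lambdaMax(X, y, weights = c(2, 1, 1)),
               max(score / c(2, 1, 1)))
  expect_error(lambdaMax(X, y, alpha = 0), "alpha")

  lm <- lambdaMax(X, y)
  up <- fitEnetLogistic(X, y, 1.001 * lm,
                        control = enetControl(tol = 1e-10))
  dn <- fitEnetLogistic(X, y, 0.5 * lm,
                        control = enetControl(tol = 1e-10))
  expect_length(activeSet(up), 0)
  expect_gte(length(activeSet(dn)), 1)
})

test_that("a lambda path shares subproblem solutions with one-off fits", {
  set.seed(10)
  X <- stdcols(matrix(rnorm(20 * 6), 20, 6))
  y <- rep(c(0, 1), each = 10)
  grid <- c(0.05, 0.2, 0.5)
  path <- fitEnetLogistic(X, y, grid, control = enetControl(tol = 1e-10))
  for (i in seq_along(grid)) {
    single <- fitEnetLogistic(X, y, grid[i],
                              control = enetControl(tol = 1e-10))
    expect_lt(max(abs(path[[i]]$beta - single$beta)), 1e-7)
  }
})

test_that("prediction probabilities follow the logistic closed form", {
  X <- matrix(c(-1, 0, 1), 3, 1)
  f0 <- structure(list(beta = 0, intercept = 0), class = "enetFit")
  expect_equal(predict(f0, X), rep(0.5, 3))
  f1 <- structure(list(beta = 0, intercept = log(3)), class = "enetFit")
  expect_equal(predict(f1, X), rep(0.75, 3))
  f2 <- structure(list(beta = 2, intercept = -0.3), class = "enetFit")
  expect_true(all(diff(predict(f2, X)) > 0))
  expect_error(predict(f2, cbind(X, X)), "one column per")
})

test_that("active set applies the zero threshold", {
  f <- structure(list(beta = c(0, 0.3, -1e-12), zero_tol = 1e-8),
                 class = "enetFit")
  expect_identical(activeSet(f), 2L)
  f$beta <- c(0, 0, 0)
  expect_length(activeSet(f), 0)
})

test_that("uniform-weight fits agree with glmnet", {
  # with all penalty factors equal glmnet's internal rescaling is a
  # no-op and the two objectives coincide
  skip_if_not_installed("glmnet")
  set.seed(77)
  X <- stdcols(matrix(rnorm(30 * 5), 30, 5))
  y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  for (lam in c(0.02, 0.1, 0.3)) {
    mine <- fitEnetLogistic(X, y, lam,
                            control = enetControl(alpha = 0.5, tol = 1e-11))
    g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0.5,
                        lambda = lam, standardize = FALSE,
                        thresh = 1e-14)
    expect_lt(max(abs(mine$beta - as.numeric(g$beta))), 1e-4)
    expect_lt(abs(mine$intercept - as.numeric(g$a0)), 1e-4)
  }
})

test_that("solver rejects invalid inputs", {
  X <- stdcols(matrix(rnorm(20), 10, 2))
  expect_error(fitEnetLogistic(X, rep(1, 10), 0.1), "both classes")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(fitEnetLogistic(Xb, rep(c(0, 1), 5), 0.1), "non-finite")
  expect_error(fitEnetLogistic(X, rep(c(0, 1), 5), 0.1,
                               weights = c(1, -1)),
               "strictly positive")
  expect_error(fitEnetLogistic(X, rep(c(0, 1), 5), -0.1), "positive")
})
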