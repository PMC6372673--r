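#' Solver settings for the weighted elastic-net logistic regression
#'
#' @param alpha elastic-net mixing parameter in [0, 1]; 1 = lasso,
#'   0 = ridge.  Default 0.5.
#' @param max_iter total coordinate-descent sweep budget per penalty
#'   value.
#' @param tol convergence tolerance on the largest coefficient update.
#' @param zero_tol threshold below which a coefficient counts as zero.
#' @return A list of class \code{enetControl}.
#' @export
enetControl <- function(alpha = 0.5, max_iter = 10000L, tol = 1e-7,
                        zero_tol = 1e-8) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (max_iter < 1L) stop("'max_iter' must be positive")
  structure(list(alpha = alpha, max_iter = as.integer(max_iter),
                 tol = tol, zero_tol = zero_tol),
            class = "enetControl")
}

.checkEnetInput <- function(X, y, weights) {
  if (!is.matrix(X) || !all(is.finite(X)))
    stop("'X' must be a numeric matrix without non-finite values")
  if (length(y) != nrow(X)) stop("'y' must have one entry per row of X")
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("both classes must be present in 'y'")
  if (length(weights) != ncol(X) || any(weights <= 0))
    stop("'weights' must be strictly positive, one per column of X")
  invisible(TRUE)
}

#' Fit a weighted elastic-net logistic regression
#'
#' Minimizes the penalized binomial negative log-likelihood
#' \deqn{(1/n)\,\mathrm{NLL}(y, X\beta + \beta_0) +
#'   \lambda \sum_j w_j\,[(1-\alpha)\beta_j^2/2 + \alpha|\beta_j|]}
#' by cyclic coordinate descent; the intercept is unpenalized and the
#' per-gene penalty factor \eqn{w_j} multiplies both penalty terms, so
#' the solution is invariant under \eqn{(w, \lambda) \to (cw,
#' \lambda/c)}.  When \code{lambda} is a vector the whole path is fitted
#' with warm starts (same data, decreasing order internally) and a list
#' of fits is returned.
#'
#' @param X numeric matrix, samples x genes; columns are expected
#'   standardized (mean 0, SD 1).
#' @param y binary response, 1 = good responder.
#' @param lambda penalty strength(s), > 0.
#' @param weights per-gene penalty factors, > 0 (default all 1).
#' @param control an \code{\link{enetControl}} list.
#' @return For scalar \code{lambda}, an object of class \code{enetFit}:
#'   list with \code{beta} (named), \code{intercept}, \code{lambda},
#'   \code{alpha}, \code{weights}, \code{converged}, \code{n_iter}.  For
#'   a vector, a list of such objects (in the input lambda order).
#' @examples
#' set.seed(1)
#' X <- scale(matrix(rnorm(40), 20, 2)) * sqrt(20 / 19)
#' y <- rep(c(0, 1), each = 10)
#' fit <- fitEnetLogistic(X, y, lambda = 0.1)
#' activeSet(fit)
#' @export
fitEnetLogistic <- function(X, y, lambda, weights = rep(1, ncol(X)),
                            control = enetControl()) {
  .checkEnetInput(X, y, weights)
  if (any(lambda <= 0)) stop("'lambda' must be strictly positive")
  res <- .cd_enet_logistic_path(X, as.numeric(y), as.numeric(lambda),
                                control$alpha, as.numeric(weights),
                                control$max_iter, control$tol)
  if (any(!res$converged))
    warning("solver did not converge at ", sum(!res$converged),
            " lambda value(s)")
  fits <- lapply(seq_along(lambda), function(l) {
    structure(list(beta = stats::setNames(res$beta[, l], colnames(X)),
                   intercept = res$intercept[l], lambda = lambda[l],
                   alpha = control$alpha, weights = weights,
                   zero_tol = control$zero_tol,
                   converged = res$converged[l], n_iter = res$n_iter[l]),
              class = "enetFit")
  })
  if (length(lambda) == 1L) fits[[1L]] else fits
}

#' Smallest penalty at which no gene enters the model
#'
#' Returns \eqn{\max_j |x_j \cdot (y - \bar y)| / (n \alpha w_j)}; for
#' any \eqn{\lambda} at or above this value the elastic-net logistic
#' solution is all-zero (intercept only).
#'
#' @inheritParams fitEnetLogistic
#' @param alpha elastic-net mixing parameter, must be > 0.
#' @return Positive scalar.
#' @export
lambdaMax <- function(X, y, weights = rep(1, ncol(X)), alpha = 0.5) {
  .checkEnetInput(X, y, weights)
  if (alpha <= 0)
    stop("'alpha' must be > 0: the all-zero threshold is infinite for ridge")
  n <- nrow(X)
  score <- abs(drop(crossprod(X, y - mean(y))))
  max(score / (n * alpha * weights))
}

#' Predicted response probabilities from a fitted model
#'
#' @param object an \code{enetFit}.
#' @param newdata numeric matrix, samples x genes, columns matching the
#'   fit.
#' @param ... ignored.
#' @return Per-sample probability of being a good responder.
#' @export
predict.enetFit <- function(object, newdata, ...) {
  if (ncol(newdata) != length(object$beta))
    stop("'newdata' must have one column per model coefficient")
  drop(plogis(object$intercept + newdata %*% object$beta))
}

#' Genes with non-zero coefficients
#'
#' @param fit an \code{enetFit}.
#' @param zero_tol zero threshold; defaults to the fit's own.
#' @return Integer indices of genes with \eqn{|\beta_j|} above
#'   \code{zero_tol}.
#' @export
activeSet <- function(fit, zero_tol = fit$zero_tol) {
  which(abs(fit$beta) > zero_tol)
}

#' @export
print.enetFit <- function(x, ...) {
  cat("Weighted elastic-net logistic fit: lambda =", x$lambda,
      "alpha =", x$alpha, "\n  active genes:", length(activeSet(x)),
      "of", length(x$beta),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}
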