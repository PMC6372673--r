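#' Fit the prediction-stage logistic model
#'
#' Maximum-likelihood logistic regression with a small ridge term
#' (default 1e-4) for numerical stability: gene groups are small, but
#' at two dozen samples perfect separation is common and the ridge
#' floor keeps coefficients finite and the fit deterministic.
#'
#' @param X numeric matrix, samples x genes (the selected group).
#' @param y binary response (1 = good responder).
#' @param ridge ridge strength.
#' @return An \code{enetFit} (see \code{\link{fitEnetLogistic}});
#'   element \code{separable} flags fits whose coefficients ran into
#'   the ridge floor under perfect separation.
#' @export
fitPredictionModel <- function(X, y, ridge = 1e-4) {
  if (length(unique(y)) < 2L) stop("both classes must be present")
  X <- as.matrix(X)
  nf <- .newtonRidgeLogistic(X, y, ridge)
  # a mean training log-loss this close to zero only occurs when the
  # classes are (near-)perfectly separated and the ridge floor alone is
  # bounding the coefficients
  eta <- nf$intercept + drop(X %*% nf$beta)
  nll <- mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  structure(list(beta = stats::setNames(nf$beta, colnames(X)),
                 intercept = nf$intercept, lambda = ridge, alpha = 0,
                 weights = rep(1, ncol(X)), zero_tol = 0,
                 converged = nf$converged, n_iter = nf$n_iter,
                 separable = nll < 1e-2),
            class = "enetFit")
}

.classify <- function(prob) as.integer(prob >= 0.5)

#' Leave-one-out accuracy at one time point
#'
#' Each sample in turn is held out, the model is refit on the rest and
#' the held-out sample classified at probability threshold 0.5.  If
#' removing a sample empties its class, that fold predicts the majority
#' class of the remaining training labels.
#'
#' @param X numeric matrix, samples x genes (construction time point,
#'   restricted to the gene group).
#' @param y binary response.
#' @param ridge passed to \code{\link{fitPredictionModel}}.
#' @return Accuracy in percent.
#' @export
looAccuracy <- function(X, y, ridge = 1e-4) {
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out needs at least 3 samples")
  correct <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      pred <- as.integer(mean(ytr) >= 0.5)
    } else {
      fit <- fitPredictionModel(X[-i, , drop = FALSE], ytr, ridge)
      pred <- .classify(predict(fit, X[i, , drop = FALSE]))
    }
    if (pred == y[i]) correct <- correct + 1L
  }
  100 * correct / n
}

#' Cross-time accuracy of a fitted model
#'
#' Applies a model built from one time point's data to all samples'
#' expression at another time point.
#'
#' @param fit an \code{enetFit} built at the construction time point.
#' @param X_d numeric matrix, samples x genes at the prediction time
#'   point (same gene columns as the fit).
#' @param y binary response.
#' @return Accuracy in percent.
#' @export
crossTimeAccuracy <- function(fit, X_d, y) {
  pred <- .classify(predict(fit, X_d))
  100 * mean(pred == y)
}

#' Mean and minimum of a set of per-time-point accuracies
#'
#' @param acc_o leave-one-out accuracy at the construction time point
#'   (percent).
#' @param acc_cross named vector of cross-time accuracies at the other
#'   time points (percent).
#' @return List with \code{acc_mean} (arithmetic mean of all T values)
#'   and \code{acc_min}.
#' @export
summarizeAccuracies <- function(acc_o, acc_cross) {
  vals <- c(acc_o, acc_cross)
  list(acc_mean = mean(vals), acc_min = min(vals))
}

#' Accuracy table for one gene group and construction time point
#'
#' Assembles the leave-one-out accuracy at the construction time point,
#' the cross-time accuracy at every other time point (model fitted on
#' all samples at the construction time point), and their mean and
#' minimum.
#'
#' @param x a preprocessed \linkS4class{TimeCourseSet}.
#' @param genes character vector, the gene group.
#' @param t_build construction time-point label.
#' @param ridge passed to \code{\link{fitPredictionModel}}.
#' @return List: \code{t_build}, \code{acc_o}, \code{acc_cross} (named
#'   by time point), \code{acc_mean}, \code{acc_min}, \code{fit} (the
#'   all-sample model).
#' @export
accuracyTable <- function(x, genes, t_build, ridge = 1e-4) {
  if (!length(genes)) stop("gene group must be non-empty")
  if (!all(genes %in% rownames(x)))
    stop("gene(s) absent from dataset: ",
         paste(setdiff(genes, rownames(x)), collapse = ", "))
  if (!t_build %in% timePoints(x))
    stop("unknown construction time point: ", t_build)
  y <- responseBinary(x)
  Xb <- designMatrix(x, t_build)[, genes, drop = FALSE]
  acc_o <- looAccuracy(Xb, y, ridge)
  fit <- fitPredictionModel(Xb, y, ridge)
  others <- setdiff(timePoints(x), t_build)
  acc_cross <- vapply(others, function(d) {
    crossTimeAccuracy(fit, designMatrix(x, d)[, genes, drop = FALSE], y)
  }, numeric(1))
  s <- summarizeAccuracies(acc_o, acc_cross)
  list(t_build = t_build, acc_o = acc_o, acc_cross = acc_cross,
       acc_mean = s$acc_mean, acc_min = s$acc_min, fit = fit)
}

#' Search gene-group prefixes and construction time points
#'
#' Grows the gene group along the ranking one gene at a time (prefixes
#' of the ranked list), builds a logistic model for every (prefix,
#' construction time point) pair, and returns the pair with the best
#' mean accuracy.  Ties prefer the smaller group, then the earlier
#' construction time point.
#'
#' @param x a preprocessed \linkS4class{TimeCourseSet}.
#' @param ranking a \linkS4class{RankedGeneList}, or a character vector
#'   of genes in rank order.
#' @param k_max largest prefix size (default: full ranking, capped at
#'   30).
#' @param ridge passed to \code{\link{fitPredictionModel}}.
#' @return A \linkS4class{BestModel}.
#' @export
searchBestModel <- function(x, ranking, k_max = NULL, ridge = 1e-4) {
  genes <- if (is(ranking, "RankedGeneList")) rankedGenes(ranking)
           else as.character(ranking)
  if (!length(genes)) stop("empty ranking")
  if (is.null(k_max)) k_max <- min(length(genes), 30L)
  k_max <- min(k_max, length(genes))
  tps <- timePoints(x)

  # one accuracy column per time point; at the construction time point the
  # entry is the leave-one-out accuracy (the parenthesised value in the
  # published table layout)
  asRow <- function(at, k) {
    acc <- stats::setNames(numeric(length(tps)), paste0("acc_", tps))
    acc[paste0("acc_", at$t_build)] <- at$acc_o
    acc[paste0("acc_", names(at$acc_cross))] <- at$acc_cross
    data.frame(k = k, t_build = at$t_build, as.list(acc),
               acc_mean = at$acc_mean, acc_min = at$acc_min,
               check.names = FALSE)
  }
  rows <- list()
  best <- NULL
  for (k in seq_len(k_max)) {
    for (t in tps) {
      at <- accuracyTable(x, genes[seq_len(k)], t, ridge)
      rows[[length(rows) + 1L]] <- asRow(at, k)
      # strict improvement only: earlier (smaller k, earlier t) wins ties
      if (is.null(best) || at$acc_mean > best$acc_mean + 1e-12)
        best <- c(at, list(k = k))
    }
  }
  grid <- do.call(rbind, rows)
  at <- best
  acc_row <- asRow(at, at$k)
  new("BestModel", genes = genes[seq_len(at$k)], tBuild = at$t_build,
      coefficients = at$fit$beta, intercept = at$fit$intercept,
      accuracy = acc_row, grid = grid)
}

#' Accessors for BestModel
#'
#' @param x a \linkS4class{BestModel}.
#' @name BestModel-accessors
NULL

#' @rdname BestModel-accessors
#' @export
setMethod("bestGenes", "BestModel", function(x) x@genes)

#' @rdname BestModel-accessors
#' @export
setMethod("buildTimePoint", "BestModel", function(x) x@tBuild)

#' @rdname BestModel-accessors
#' @export
setMethod("accTable", "BestModel", function(x) x@accuracy)

#' @rdname BestModel-accessors
#' @export
setMethod("searchGrid", "BestModel", function(x) x@grid)

#' @rdname BestModel-accessors
#' @param object a \linkS4class{BestModel}.
#' @export
setMethod("coef", "BestModel", function(object)
  c(`(Intercept)` = object@intercept, object@coefficients))

setMethod("show", "BestModel", function(object) {
  cat("BestModel:", length(object@genes), "genes built at",
      object@tBuild, "\n  mean accuracy:",
      round(object@accuracy$acc_mean, 1), "%, min:",
      round(object@accuracy$acc_min, 1), "%\n  genes:",
      paste(utils::head(object@genes, 8L), collapse = ", "),
      if (length(object@genes) > 8L) "..." else "", "\n")
})

#' Predicted probabilities from a BestModel
#'
#' @param object a \linkS4class{BestModel}.
#' @param x a \linkS4class{TimeCourseSet}.
#' @param t time point at which to predict (default: the construction
#'   time point).
#' @return Per-sample probability of being a good responder.
#' @export
predictResponse <- function(object, x, t = buildTimePoint(object)) {
  stopifnot(is(object, "BestModel"))
  X <- designMatrix(x, t)[, bestGenes(object), drop = FALSE]
  drop(plogis(object@intercept + X %*% object@coefficients))
}

#' Write the candidate grid of the model search as TSV
#'
#' One row per (prefix size, construction time point) candidate with
#' its leave-one-out, cross-time, mean and minimum accuracies — the
#' layout of a per-method accuracy table.
#'
#' @param model a \linkS4class{BestModel}.
#' @param path output file.
#' @export
writeCandidateGrid <- function(model, path) {
  write.table(searchGrid(model), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
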