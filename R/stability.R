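#' Settings for stability selection
#'
#' Defaults follow the study conditions of the method: 500 subsample
#' draws per penalty value, stratified subsamples of 12 good and 8 poor
#' responders, a lambda grid of 0.01 to 1.00 in 0.01 steps, selection
#' threshold 0.5, and elastic-net mixing 0.5.
#'
#' @param n_iterations subsample draws (shared across the whole lambda
#'   grid).
#' @param n_good_sub,n_poor_sub per-class subsample sizes (without
#'   replacement within a draw).
#' @param lambda_grid strictly positive, sorted penalty values.
#' @param theta_ss selection-probability threshold in (0, 1]
#'   (inclusive comparison, so 1.0 remains attainable).
#' @param seed master RNG seed for the subsample draws.
#' @param enet an \code{\link{enetControl}} list (its \code{alpha} is
#'   the elastic-net mixing used throughout).
#' @return A list of class \code{ssControl}.
#' @export
ssControl <- function(n_iterations = 500L, n_good_sub = 12L,
                      n_poor_sub = 8L,
                      lambda_grid = seq(0.01, 1, by = 0.01),
                      theta_ss = 0.5, seed = 1L,
                      enet = enetControl()) {
  if (any(lambda_grid <= 0) || is.unsorted(lambda_grid))
    stop("'lambda_grid' must be strictly positive and sorted")
  if (theta_ss <= 0 || theta_ss > 1)
    stop("'theta_ss' must lie in (0, 1]")
  if (n_iterations < 1L || n_good_sub < 1L || n_poor_sub < 1L)
    stop("iteration and subsample counts must be positive")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_good_sub = as.integer(n_good_sub),
                 n_poor_sub = as.integer(n_poor_sub),
                 lambda_grid = lambda_grid, theta_ss = theta_ss,
                 seed = as.integer(seed), enet = enet),
            class = "ssControl")
}

# deterministic per-stage seed derivation from a master seed
.deriveSeed <- function(master, stage, index = 0L) {
  as.integer((as.numeric(master) + 7919 * stage + 104729 * index) %%
               .Machine$integer.max)
}

#' Draw one stratified subsample
#'
#' @param y binary labels (1 = good responder).
#' @param n_good_sub,n_poor_sub per-class subsample sizes.
#' @return Integer sample indices: \code{n_good_sub} good plus
#'   \code{n_poor_sub} poor, drawn without replacement (uses the
#'   current RNG state).
#' @export
stratifiedSubsample <- function(y, n_good_sub, n_poor_sub) {
  good <- which(y == 1)
  poor <- which(y == 0)
  if (length(good) < n_good_sub || length(poor) < n_poor_sub)
    stop("class counts (", length(good), " good, ", length(poor),
         " poor) cannot supply a ", n_good_sub, "/", n_poor_sub,
         " subsample")
  c(good[sample.int(length(good), n_good_sub)],
    poor[sample.int(length(poor), n_poor_sub)])
}

#' Run stability selection
#'
#' Draws \code{n_iterations} stratified subsamples (the same subsamples
#' are reused for every lambda, via warm-started path fits), fits the
#' weighted elastic-net logistic model on each, and records per-gene
#' selection frequencies per lambda.  The per-gene selection
#' probability is the maximum frequency over the grid.  A fit that does
#' not converge counts as "no selection" (with one warning).
#'
#' @param X numeric matrix, samples x genes (standardized columns).
#' @param y binary response (1 = good responder).
#' @param control an \code{\link{ssControl}} list.
#' @param weights per-gene penalty factors (default all 1).
#' @param seed RNG seed for the subsample draws; defaults to
#'   \code{control$seed}.
#' @return A \linkS4class{SelectionProfile}.
#' @export
runStabilitySelection <- function(X, y, control = ssControl(),
                                  weights = rep(1, ncol(X)),
                                  seed = control$seed) {
  .checkEnetInput(X, y, weights)
  p <- ncol(X)
  L <- length(control$lambda_grid)
  B <- control$n_iterations
  counts <- matrix(0L, p, L,
                   dimnames = list(colnames(X), NULL))
  set.seed(seed)
  idx <- replicate(B, stratifiedSubsample(y, control$n_good_sub,
                                          control$n_poor_sub),
                   simplify = FALSE)
  n_failed <- 0L
  for (b in seq_len(B)) {
    res <- .cd_enet_logistic_path(
      X[idx[[b]], , drop = FALSE], as.numeric(y[idx[[b]]]),
      as.numeric(control$lambda_grid), control$enet$alpha,
      as.numeric(weights), control$enet$max_iter, control$enet$tol)
    act <- abs(res$beta) > control$enet$zero_tol
    if (any(!res$converged)) {
      n_failed <- n_failed + sum(!res$converged)
      act[, !res$converged] <- FALSE
    }
    counts <- counts + act
  }
  if (n_failed > 0L)
    warning(n_failed, " non-converged fit(s) counted as no selection")
  freq <- counts / B
  new("SelectionProfile", freq = freq,
      selProb = apply(freq, 1L, max),
      lambda = as.numeric(control$lambda_grid),
      nIterations = B)
}

#' Accessors for SelectionProfile
#'
#' \code{selProb} returns the per-gene selection probability (max over
#' lambda), \code{selFreq} the genes x lambda frequency matrix,
#' \code{lambdaGrid} the penalty grid.
#'
#' @param x a \linkS4class{SelectionProfile}.
#' @name SelectionProfile-accessors
NULL

#' @rdname SelectionProfile-accessors
#' @export
setMethod("selProb", "SelectionProfile", function(x) x@selProb)

#' @rdname SelectionProfile-accessors
#' @export
setMethod("selFreq", "SelectionProfile", function(x) x@freq)

#' @rdname SelectionProfile-accessors
#' @export
setMethod("lambdaGrid", "SelectionProfile", function(x) x@lambda)

setMethod("show", "SelectionProfile", function(object) {
  cat("SelectionProfile:", nrow(object@freq), "genes x",
      length(object@lambda), "lambda values (",
      object@nIterations, "subsamples )\n",
      " selection probability: median",
      signif(median(object@selProb), 3), ", max",
      signif(max(object@selProb), 3), "\n")
})

#' Threshold a selection profile
#'
#' @param profile a \linkS4class{SelectionProfile}.
#' @param theta_ss threshold in (0, 1]; genes with selection
#'   probability \eqn{\ge \theta_{ss}} are kept.
#' @return Character vector of selected gene names (or integer indices
#'   if the profile is unnamed).
#' @export
thresholdSelect <- function(profile, theta_ss = 0.5) {
  stopifnot(is(profile, "SelectionProfile"))
  if (theta_ss <= 0 || theta_ss > 1)
    stop("'theta_ss' must lie in (0, 1]")
  sel <- which(profile@selProb >= theta_ss)
  if (!is.null(names(profile@selProb))) names(profile@selProb)[sel]
  else sel
}

#' Write a selection profile as TSV
#'
#' Columns: gene, selection probability, and the lambda at which the
#' maximum frequency is attained (first maximum on ties).
#'
#' @param profile a \linkS4class{SelectionProfile}.
#' @param path output file.
#' @export
writeSelectionProfile <- function(profile, path) {
  amax <- apply(profile@freq, 1L, which.max)
  df <- data.frame(gene = rownames(profile@freq),
                   sel_prob = profile@selProb,
                   lambda_argmax = profile@lambda[amax])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
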