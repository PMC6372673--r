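#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (column) to share the same multiset of values:
#' the per-rank mean across samples, with ties receiving the mean of
#' the tied ranks' reference values.  Backed by
#' \code{limma::normalizeQuantiles}.
#'
#' @param m numeric matrix, genes x samples, no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantileNormalize <- function(m) {
  if (!is.matrix(m) || length(m) == 0L) stop("'m' must be a non-empty matrix")
  if (!all(is.finite(m))) stop("'m' contains missing or non-finite values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Log2 transformation of an expression matrix
#'
#' @param m numeric matrix (genes x samples).
#' @param mode \code{"none"} (identity), \code{"log2"} (elementwise), or
#'   \code{"log2fc"} (log2 of the per-gene, per-sample ratio against
#'   \code{ref}).
#' @param ref reference matrix for \code{mode = "log2fc"}, same shape.
#' @return Transformed matrix.
#' @export
applyLog2 <- function(m, mode = c("none", "log2", "log2fc"), ref = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(m)
  if (mode == "log2fc") {
    if (is.null(ref) || !identical(dim(ref), dim(m)))
      stop("'ref' must be a matrix of the same shape for mode 'log2fc'")
    ratio <- m / ref
    if (any(ratio <= 0))
      stop("non-positive ratios under log2 fold change for gene(s): ",
           paste(utils::head(rownames(m)[apply(ratio <= 0, 1L, any)], 10L),
                 collapse = ", "))
    return(log2(ratio))
  }
  if (any(m <= 0))
    stop("non-positive values under log2 for gene(s): ",
         paste(utils::head(rownames(m)[apply(m <= 0, 1L, any)], 10L),
               collapse = ", "))
  log2(m)
}

#' Per-gene Z-scores within a time point
#'
#' Centers and scales each gene (row) to mean 0 and SD 1 across samples.
#' The population SD (divide by n) is the default; it makes the
#' operation idempotent.
#'
#' @param m numeric matrix, genes x samples.
#' @param sd \code{"population"} or \code{"sample"}.
#' @return Standardized matrix.
#' @export
zscoreGenes <- function(m, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  mu <- rowMeans(m)
  ctr <- m - mu
  v <- rowMeans(ctr^2)
  if (sd == "sample") v <- v * ncol(m) / (ncol(m) - 1L)
  if (any(v <= 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(m)[v <= 0], 10L), collapse = ", "))
  ctr / sqrt(v)
}

#' Preprocess a time-course dataset
#'
#' Applies, in order: the log2 step, quantile normalization across
#' samples within each time point, and per-gene Z-scoring within each
#' time point.  When \code{log2 = "log2fc"} the reference time point's
#' matrix becomes identically zero, so it is removed from the returned
#' dataset (with a message).
#'
#' @param x a \linkS4class{TimeCourseSet}.
#' @param log2 one of \code{"none"}, \code{"log2"}, \code{"log2fc"}.
#' @param ref reference time-point label, required for \code{"log2fc"}.
#' @param quantile logical; quantile-normalize across samples.
#' @param zscore logical; per-gene Z-scores.
#' @param sd SD convention for Z-scores (see \code{\link{zscoreGenes}}).
#' @return A preprocessed \linkS4class{TimeCourseSet}.
#' @export
preprocessTimeCourse <- function(x, log2 = c("none", "log2", "log2fc"),
                                 ref = NULL, quantile = TRUE,
                                 zscore = TRUE,
                                 sd = c("population", "sample")) {
  log2 <- match.arg(log2)
  sd <- match.arg(sd)
  tps <- timePoints(x)
  if (log2 == "log2fc") {
    if (is.null(ref) || !ref %in% tps)
      stop("'ref' must name a time point of the dataset")
    if (length(tps) < 2L)
      stop("log2 fold change needs at least two time points")
  }
  mats <- list()
  refmat <- if (log2 == "log2fc") exprMatrix(x, ref) else NULL
  for (t in tps) {
    m <- exprMatrix(x, t)
    m <- switch(log2,
      none = m,
      log2 = applyLog2(m, "log2"),
      log2fc = {
        if (t == ref) NULL else applyLog2(m, "log2fc", ref = refmat)
      })
    if (is.null(m)) next
    if (quantile) m <- quantileNormalize(m)
    if (zscore) m <- zscoreGenes(m, sd = sd)
    mats[[t]] <- m
  }
  if (log2 == "log2fc")
    message("reference time point '", ref,
            "' dropped after log2 fold change")
  TimeCourseSet(mats, response = responseLabels(x))
}
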