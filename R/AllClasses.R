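#' TimeCourseSet: labelled expression matrices indexed by time point
#'
#' A \linkS4class{SummarizedExperiment} whose assays are the per-time-point
#' expression matrices (genes in rows, samples in columns; one assay per
#' time point, in chronological order) and whose \code{colData} carries a
#' \code{response} factor with levels \code{poor} and \code{good}
#' (encoded 0/1 for modelling).  Every assay shares the same gene and
#' sample sets; both response classes must be present.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{TimeCourseSet}} (constructor),
#'   \code{\link{readTimeCourse}}, \code{\link{simulateTimeCourse}}
#' @export
setClass("TimeCourseSet", contains = "SummarizedExperiment")

setValidity("TimeCourseSet", function(object) {
  msg <- character()
  if (length(assays(object)) < 1L)
    msg <- c(msg, "at least one time-point assay is required")
  an <- assayNames(object)
  if (is.null(an) || anyNA(an) || any(an == "") || anyDuplicated(an))
    msg <- c(msg, "assays must carry unique, non-empty time-point names")
  if (!"response" %in% colnames(colData(object))) {
    msg <- c(msg, "colData must contain a 'response' column")
  } else {
    resp <- colData(object)$response
    if (!is.factor(resp) || !identical(levels(resp), c("poor", "good")))
      msg <- c(msg, "'response' must be a factor with levels poor, good")
    else if (anyNA(resp))
      msg <- c(msg, "'response' contains missing labels")
    else if (length(unique(resp)) < 2L)
      msg <- c(msg, "both responder classes must be present")
  }
  for (t in an) {
    a <- assay(object, t)
    if (!is.numeric(a) || !all(is.finite(a))) {
      msg <- c(msg, sprintf("assay '%s' contains non-finite values", t))
      break
    }
  }
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene (row) and sample (column) names are required")
  if (length(msg)) msg else TRUE
})

#' SelectionProfile: stability-selection frequencies and probabilities
#'
#' Per-gene selection frequencies across a penalty (lambda) grid from
#' repeated stratified subsampling, and the per-gene selection
#' probability defined as the maximum frequency over the grid.
#'
#' @slot freq numeric matrix, genes x lambda values; entries in [0, 1]
#'   and multiples of 1 / \code{nIterations}.
#' @slot selProb named numeric vector, per-gene max over lambda.
#' @slot lambda numeric, the penalty grid (column order of \code{freq}).
#' @slot nIterations integer, subsample draws per lambda.
#' @export
setClass("SelectionProfile",
  representation(freq = "matrix", selProb = "numeric",
                 lambda = "numeric", nIterations = "integer"))

setValidity("SelectionProfile", function(object) {
  msg <- character()
  if (ncol(object@freq) != length(object@lambda))
    msg <- c(msg, "freq must have one column per lambda value")
  if (nrow(object@freq) != length(object@selProb))
    msg <- c(msg, "selProb must have one entry per gene")
  if (any(object@freq < 0 | object@freq > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (length(object@selProb) &&
      max(abs(object@selProb - apply(object@freq, 1L, max))) > 1e-12)
    msg <- c(msg, "selProb must equal the per-gene max over lambda")
  if (length(msg)) msg else TRUE
})

#' RankedGeneList: time-course consistency ranking of the gene pool
#'
#' Per-time-point selection probabilities for every pool gene, their
#' product across time points (the consistency score), and the pool
#' sorted by that score in descending order.
#'
#' @slot spTable numeric matrix, pool genes x time points, the
#'   per-time-point selection probabilities.
#' @slot spFinal named numeric vector, the row products of
#'   \code{spTable}.
#' @slot ranking character, pool genes in descending score order (ties
#'   keep pool order).
#' @slot geneLists list of character vectors, the thresholded selection
#'   at each time point (drives the next step's penalty weights).
#' @export
setClass("RankedGeneList",
  representation(spTable = "matrix", spFinal = "numeric",
                 ranking = "character", geneLists = "list"))

setValidity("RankedGeneList", function(object) {
  msg <- character()
  if (nrow(object@spTable) != length(object@spFinal))
    msg <- c(msg, "spFinal must have one entry per pool gene")
  if (!setequal(object@ranking, rownames(object@spTable)) ||
      length(object@ranking) != nrow(object@spTable))
    msg <- c(msg, "ranking must be a permutation of the pool")
  sp <- object@spFinal[object@ranking]
  if (length(sp) > 1L && any(diff(sp) > 1e-15))
    msg <- c(msg, "score must be non-increasing along the ranking")
  if (any(object@spFinal < 0 | object@spFinal > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' BestModel: the selected gene group, construction time point and fit
#'
#' @slot genes character, the winning ranking prefix.
#' @slot tBuild character, the construction time point.
#' @slot coefficients named numeric, logistic coefficients for
#'   \code{genes}.
#' @slot intercept numeric scalar.
#' @slot accuracy data.frame, one row: leave-one-out accuracy at
#'   \code{tBuild}, cross-time accuracies, their mean and minimum (all
#'   percentages).
#' @slot grid data.frame, every evaluated (prefix size, time point)
#'   candidate with its accuracy summary.
#' @export
setClass("BestModel",
  representation(genes = "character", tBuild = "character",
                 coefficients = "numeric", intercept = "numeric",
                 accuracy = "data.frame", grid = "data.frame"))

setValidity("BestModel", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@genes))
    msg <- c(msg, "one coefficient per gene is required")
  if (length(object@tBuild) != 1L)
    msg <- c(msg, "tBuild must be a single time point")
  if (length(msg)) msg else TRUE
})
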