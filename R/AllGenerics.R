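#' @rdname TimeCourseSet-accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname TimeCourseSet-accessors
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' @rdname TimeCourseSet-accessors
#' @export
setGeneric("responseLabels", function(x) standardGeneric("responseLabels"))

#' @rdname TimeCourseSet-accessors
#' @export
setGeneric("responseBinary", function(x) standardGeneric("responseBinary"))

#' @rdname TimeCourseSet-accessors
#' @export
setGeneric("exprMatrix", function(x, t) standardGeneric("exprMatrix"))

#' @rdname TimeCourseSet-accessors
#' @export
setGeneric("designMatrix", function(x, t) standardGeneric("designMatrix"))

#' @rdname SelectionProfile-accessors
#' @export
setGeneric("selProb", function(x) standardGeneric("selProb"))

#' @rdname SelectionProfile-accessors
#' @export
setGeneric("selFreq", function(x) standardGeneric("selFreq"))

#' @rdname SelectionProfile-accessors
#' @export
setGeneric("lambdaGrid", function(x) standardGeneric("lambdaGrid"))

#' @rdname RankedGeneList-accessors
#' @export
setGeneric("spFinal", function(x) standardGeneric("spFinal"))

#' @rdname RankedGeneList-accessors
#' @export
setGeneric("spTable", function(x) standardGeneric("spTable"))

#' @rdname RankedGeneList-accessors
#' @export
setGeneric("rankedGenes", function(x) standardGeneric("rankedGenes"))

#' @rdname BestModel-accessors
#' @export
setGeneric("bestGenes", function(x) standardGeneric("bestGenes"))

#' @rdname BestModel-accessors
#' @export
setGeneric("buildTimePoint", function(x) standardGeneric("buildTimePoint"))

#' @rdname BestModel-accessors
#' @export
setGeneric("accTable", function(x) standardGeneric("accTable"))

#' @rdname BestModel-accessors
#' @export
setGeneric("searchGrid", function(x) standardGeneric("searchGrid"))
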