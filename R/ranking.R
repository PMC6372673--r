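#' Build the gene pool by per-time-point stability selection
#'
#' Runs unweighted stability selection on every time point and returns
#' the union of genes passing the selection threshold at least once —
#' the candidate set for the sequential ranking stage.
#'
#' @param x a preprocessed \linkS4class{TimeCourseSet}.
#' @param control an \code{\link{ssControl}} list; \code{control$seed}
#'   is the master seed, each time point uses a derived seed.
#' @return Character vector of pool genes (in dataset gene order), with
#'   attribute \code{per_time}: the per-time-point selections.
#' @export
buildGenePool <- function(x, control = ssControl()) {
  y <- responseBinary(x)
  per_time <- list()
  for (i in seq_along(timePoints(x))) {
    t <- timePoints(x)[i]
    prof <- runStabilitySelection(designMatrix(x, t), y, control,
                                  seed = .deriveSeed(control$seed, 1L, i))
    per_time[[t]] <- thresholdSelect(prof, control$theta_ss)
  }
  pool <- rownames(x)[rownames(x) %in% unique(unlist(per_time))]
  if (!length(pool))
    stop("empty gene pool: no gene passed theta_ss = ", control$theta_ss,
         " at any time point; consider lowering the threshold or ",
         "extending the lambda grid")
  attr(pool, "per_time") <- per_time
  pool
}

#' Sequential weighted stability selection across time points
#'
#' Processes time points chronologically on the pool-restricted data.
#' At the first time point all pool genes carry penalty weight 1; at
#' each later time point genes selected at the previous time point keep
#' weight 1 while the rest are penalized by \code{gamma} (> 1), biasing
#' selection towards genes that stay informative.  If a previous
#' selection is empty, all weights fall back to 1.
#'
#' @param x a preprocessed \linkS4class{TimeCourseSet}.
#' @param pool character vector of pool genes
#'   (\code{\link{buildGenePool}}).
#' @param control an \code{\link{ssControl}} list (master seed; per
#'   time point derived seeds).
#' @param gamma penalty multiplier for genes not in the previous gene
#'   list; must be > 1.
#' @return List with one element per time point: \code{t},
#'   \code{weights}, \code{sp} (per-pool-gene selection probability),
#'   \code{gene_list} (thresholded selection at \code{t}).
#' @export
sequentialWeightedSelection <- function(x, pool, control = ssControl(),
                                        gamma = 2) {
  if (gamma <= 1) stop("'gamma' must be > 1")
  if (!length(pool)) stop("empty gene pool")
  if (!all(pool %in% rownames(x))) stop("pool genes absent from dataset")
  y <- responseBinary(x)
  sub <- x[pool, ]
  gl_prev <- character(0)
  out <- vector("list", nTimePoints(x))
  names(out) <- timePoints(x)
  for (i in seq_along(timePoints(x))) {
    t <- timePoints(x)[i]
    w <- if (length(gl_prev)) ifelse(pool %in% gl_prev, 1, gamma)
         else rep(1, length(pool))
    prof <- runStabilitySelection(designMatrix(sub, t), y, control,
                                  weights = w,
                                  seed = .deriveSeed(control$seed, 2L, i))
    gl <- thresholdSelect(prof, control$theta_ss)
    out[[t]] <- list(t = t, weights = stats::setNames(w, pool),
                     sp = selProb(prof), gene_list = gl)
    gl_prev <- gl
  }
  out
}

#' Rank pool genes by the product of selection probabilities
#'
#' The consistency score of gene \eqn{j} is \eqn{\prod_t SP_{t,j}}, the
#' product of its per-time-point selection probabilities; a gene that
#' drops out at any single time point scores (near) zero.  Genes are
#' sorted in descending score order; ties keep the pool order (stable).
#'
#' @param selections output of \code{\link{sequentialWeightedSelection}}.
#' @return A \linkS4class{RankedGeneList}.
#' @export
rankBySPFinal <- function(selections) {
  if (!length(selections)) stop("no time-point selections supplied")
  sp <- vapply(selections, function(s) s$sp,
               numeric(length(selections[[1L]]$sp)))
  if (is.null(dim(sp))) sp <- matrix(sp, nrow = 1L,
                                     dimnames = list(names(selections[[1L]]$sp),
                                                     names(selections)))
  sp_final <- apply(sp, 1L, prod)
  ord <- order(-sp_final)  # stable: ties keep row (pool) order
  new("RankedGeneList", spTable = sp, spFinal = sp_final,
      ranking = rownames(sp)[ord],
      geneLists = lapply(selections, `[[`, "gene_list"))
}

#' Accessors for RankedGeneList
#'
#' \code{rankedGenes} returns the pool in descending score order,
#' \code{spFinal} the per-gene product score, \code{spTable} the
#' genes x time-points selection-probability matrix.
#'
#' @param x a \linkS4class{RankedGeneList}.
#' @name RankedGeneList-accessors
NULL

#' @rdname RankedGeneList-accessors
#' @export
setMethod("rankedGenes", "RankedGeneList", function(x) x@ranking)

#' @rdname RankedGeneList-accessors
#' @export
setMethod("spFinal", "RankedGeneList", function(x) x@spFinal)

#' @rdname RankedGeneList-accessors
#' @export
setMethod("spTable", "RankedGeneList", function(x) x@spTable)

setMethod("show", "RankedGeneList", function(object) {
  cat("RankedGeneList:", length(object@ranking), "pool genes over",
      ncol(object@spTable), "time points\n  top genes:",
      paste(utils::head(object@ranking, 5L), collapse = ", "), "\n")
})

#' Write a gene ranking as TSV
#'
#' Columns: gene, per-time-point selection probabilities, the product
#' score, and the rank.
#'
#' @param ranking a \linkS4class{RankedGeneList}.
#' @param path output file.
#' @export
writeRankedGenes <- function(ranking, path) {
  g <- rankedGenes(ranking)
  df <- data.frame(gene = g,
                   spTable(ranking)[g, , drop = FALSE],
                   sp_final = spFinal(ranking)[g],
                   rank = seq_along(g), check.names = FALSE)
  colnames(df)[2:(1 + ncol(spTable(ranking)))] <-
    paste0("SP_", colnames(spTable(ranking)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
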