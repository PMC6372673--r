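#' Construct a TimeCourseSet
#'
#' @param matrices named list of numeric matrices (genes x samples), one
#'   per time point, in chronological order; all matrices must share the
#'   same gene and sample names in the same order.
#' @param response per-sample responder label: a character/factor vector
#'   of \code{"good"} / \code{"poor"}, or a 0/1 vector (1 = good), named
#'   or in sample order.
#' @return A \linkS4class{TimeCourseSet}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' tcs <- TimeCourseSet(list(t1 = m, t2 = m + 1),
#'                      response = c("good", "good", "poor", "poor"))
#' timePoints(tcs)
#' @export
TimeCourseSet <- function(matrices, response) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("'matrices' must be a non-empty named list of matrices")
  if (is.null(names(matrices)) || any(names(matrices) == ""))
    stop("'matrices' must be named by time point")
  ref <- matrices[[1L]]
  for (t in names(matrices)) {
    m <- matrices[[t]]
    if (!is.matrix(m) || !identical(dimnames(m), dimnames(ref)))
      stop("all time-point matrices must share identical gene/sample names")
  }
  samples <- colnames(ref)
  resp <- .coerceResponse(response, samples)
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(lapply(matrices, as.matrix)),
    colData = S4Vectors::DataFrame(response = resp, row.names = samples))
  new("TimeCourseSet", se)
}

.coerceResponse <- function(response, samples) {
  if (!is.null(names(response))) {
    missing <- setdiff(samples, names(response))
    if (length(missing))
      stop("label missing for sample ", paste(missing, collapse = ", "))
    response <- response[samples]
  } else if (length(response) != length(samples)) {
    stop("'response' must have one label per sample")
  }
  if (is.numeric(response)) {
    if (!all(response %in% c(0, 1)))
      stop("numeric response must be 0/1 (1 = good responder)")
    response <- ifelse(response == 1, "good", "poor")
  }
  response <- as.character(response)
  bad <- setdiff(unique(response), c("good", "poor"))
  if (length(bad))
    stop("unknown label token: ", paste(bad, collapse = ", "))
  factor(response, levels = c("poor", "good"))
}

#' Accessors for TimeCourseSet
#'
#' \code{timePoints} returns the ordered time-point labels;
#' \code{responseLabels} the good/poor factor; \code{responseBinary} the
#' 0/1 encoding (1 = good responder); \code{exprMatrix} the genes x
#' samples matrix at time point \code{t}; \code{designMatrix} its
#' transpose (samples x genes), the orientation the solvers consume.
#'
#' @param x a \linkS4class{TimeCourseSet}.
#' @param t a time-point label.
#' @name TimeCourseSet-accessors
NULL

#' @rdname TimeCourseSet-accessors
#' @export
setMethod("timePoints", "TimeCourseSet", function(x) assayNames(x))

#' @rdname TimeCourseSet-accessors
#' @export
setMethod("nTimePoints", "TimeCourseSet", function(x) length(assays(x)))

#' @rdname TimeCourseSet-accessors
#' @export
setMethod("responseLabels", "TimeCourseSet",
          function(x) colData(x)$response)

#' @rdname TimeCourseSet-accessors
#' @export
setMethod("responseBinary", "TimeCourseSet",
          function(x) as.integer(colData(x)$response == "good"))

#' @rdname TimeCourseSet-accessors
#' @export
setMethod("exprMatrix", "TimeCourseSet", function(x, t) {
  if (!t %in% assayNames(x)) stop("unknown time point: ", t)
  assay(x, t)
})

#' @rdname TimeCourseSet-accessors
#' @export
setMethod("designMatrix", "TimeCourseSet", function(x, t) {
  t(exprMatrix(x, t))
})

setMethod("show", "TimeCourseSet", function(object) {
  resp <- responseLabels(object)
  cat("TimeCourseSet with", nrow(object), "genes,", ncol(object),
      "samples (", sum(resp == "good"), "good /", sum(resp == "poor"),
      "poor ) at", nTimePoints(object), "time points:",
      paste(timePoints(object), collapse = ", "), "\n")
})

#' Read a time-course dataset from per-time-point TSV matrices
#'
#' Each matrix file is tab-separated with gene identifiers in the first
#' column and one column per sample; the labels file is a two-column TSV
#' (sample id, label in \{good, poor\}) without a header.  Genes present
#' at only some time points are dropped with a warning; sample sets must
#' agree across files.
#'
#' @param matrix_paths named character vector of file paths, one per
#'   time point (names become the time-point labels, in the given
#'   order).
#' @param labels_path path of the labels TSV.
#' @return A \linkS4class{TimeCourseSet}.
#' @seealso \code{\link{writeTimeCourse}} for the inverse operation.
#' @export
readTimeCourse <- function(matrix_paths, labels_path) {
  if (is.null(names(matrix_paths)) || any(names(matrix_paths) == ""))
    stop("'matrix_paths' must be named by time point")
  mats <- lapply(matrix_paths, function(p) {
    d <- read.delim(p, row.names = 1L, check.names = FALSE)
    as.matrix(d)
  })
  samples <- colnames(mats[[1L]])
  for (t in names(mats)) {
    extra <- setdiff(colnames(mats[[t]]), samples)
    miss <- setdiff(samples, colnames(mats[[t]]))
    if (length(extra) || length(miss))
      stop("sample sets differ across time points (time point '", t,
           "'): ", paste(c(extra, miss), collapse = ", "))
  }
  genes <- Reduce(intersect, lapply(mats, rownames))
  dropped <- setdiff(unique(unlist(lapply(mats, rownames))), genes)
  if (length(dropped))
    warning(length(dropped),
            " gene(s) absent at some time points were dropped: ",
            paste(utils::head(dropped, 10L), collapse = ", "))
  if (!length(genes)) stop("no genes shared across all time points")
  mats <- lapply(mats, function(m) m[genes, samples, drop = FALSE])

  lab <- read.delim(labels_path, header = FALSE,
                    col.names = c("sample", "label"),
                    colClasses = "character")
  labels <- stats::setNames(lab$label, lab$sample)
  TimeCourseSet(mats, response = labels)
}

#' Write a time-course dataset as TSV matrices plus a labels file
#'
#' Writes one \code{<prefix>_<timepoint>.tsv} per time point (genes in
#' rows, full double precision so a read/write round trip is exact) and
#' \code{<prefix>_labels.tsv}.
#'
#' @param x a \linkS4class{TimeCourseSet}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of matrix paths plus the labels
#'   path (attribute \code{labels}).
#' @export
writeTimeCourse <- function(x, dir, prefix = "expr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (t in timePoints(x)) {
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, t))
    m <- exprMatrix(x, t)
    chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                  dimnames = dimnames(m))
    df <- data.frame(gene = rownames(chr), chr, check.names = FALSE)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[t] <- p
  }
  lp <- file.path(dir, sprintf("%s_labels.tsv", prefix))
  write.table(
    data.frame(sample = colnames(x),
               label = as.character(responseLabels(x))),
    lp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  attr(paths, "labels") <- lp
  invisible(paths)
}

#' Read a GEO series-matrix file into a TimeCourseSet
#'
#' Parses the \code{!Sample_} header block and the data table of a GEO
#' series-matrix file.  GEO encodes the sample-to-time-point design as
#' free text, so the mapping is supplied explicitly: \code{sample_info}
#' has one row per GSM column with the subject it belongs to, its time
#' point, and the subject's responder label.  Columns of the same
#' subject are aligned across time points; rows with missing values are
#' dropped with a warning.
#'
#' @param path series-matrix file path (uncompressed).
#' @param sample_info data.frame with columns \code{gsm},
#'   \code{subject}, \code{time}, \code{response}; alternatively a path
#'   to a JSON file holding these records.
#' @return A \linkS4class{TimeCourseSet} with subjects as samples.
#' @export
readGEOSeriesMatrix <- function(path, sample_info) {
  if (is.character(sample_info) && length(sample_info) == 1L)
    sample_info <- as.data.frame(jsonlite::fromJSON(sample_info))
  need <- c("gsm", "subject", "time", "response")
  if (!all(need %in% colnames(sample_info)))
    stop("'sample_info' needs columns: ", paste(need, collapse = ", "))

  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("no series-matrix data table found in ", path)
  tab <- read.delim(text = lines[(beg + 1L):(end - 1L)],
                    check.names = FALSE)
  gsm_cols <- colnames(tab)[-1L]
  expr <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(expr) <- as.character(tab[[1L]])

  sample_info$time <- as.character(sample_info$time)
  sample_info$subject <- as.character(sample_info$subject)
  known <- sample_info$gsm %in% gsm_cols
  if (!all(known))
    stop("sample_info lists GSMs absent from the table: ",
         paste(sample_info$gsm[!known], collapse = ", "))

  times <- unique(sample_info$time)
  subjects <- unique(sample_info$subject)
  mats <- list()
  for (tp in times) {
    sel <- sample_info[sample_info$time == tp, ]
    if (anyDuplicated(sel$subject))
      stop("subject measured twice at time point ", tp)
    miss <- setdiff(subjects, sel$subject)
    if (length(miss))
      stop("sample sets differ across time points (time point '", tp,
           "'): missing subject ", paste(miss, collapse = ", "))
    m <- expr[, sel$gsm, drop = FALSE]
    colnames(m) <- sel$subject
    mats[[tp]] <- m[, subjects, drop = FALSE]
  }
  keep <- Reduce(`&`, lapply(mats, function(m) apply(is.finite(m), 1L, all)))
  if (!all(keep)) {
    warning(sum(!keep), " gene(s) with missing values were dropped")
    mats <- lapply(mats, function(m) m[keep, , drop = FALSE])
  }
  resp <- sample_info$response[match(subjects, sample_info$subject)]
  TimeCourseSet(mats, response = stats::setNames(resp, subjects))
}
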