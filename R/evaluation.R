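#' Accuracy from confusion counts
#'
#' \eqn{ACC\,[\%] = 100\,(TP + TN) / (TP + FP + FN + TN)}.
#'
#' @param tp,fp,fn,tn non-negative integer counts; their sum must be
#'   positive.
#' @return Accuracy in percent.
#' @export
accuracyFromConfusion <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stop("confusion counts sum to zero")
  100 * (tp + tn) / total
}

#' Bootstrap evaluation of a gene group's cross-time accuracy
#'
#' Per replicate, samples are resampled with replacement (redrawn, up
#' to 100 attempts, if a single class results), a logistic model is fit
#' on the resampled rows at the construction time point, and accuracy
#' is scored at every other time point.  Scoring uses all original
#' samples by default; \code{scoring = "oob"} restricts it to the
#' out-of-bag samples of the replicate.
#'
#' @param x a preprocessed \linkS4class{TimeCourseSet}.
#' @param genes gene group.
#' @param t_build construction time point.
#' @param n_replicates bootstrap replicates (default 50).
#' @param seed RNG seed.
#' @param scoring \code{"all"} or \code{"oob"}.
#' @param ridge passed to \code{\link{fitPredictionModel}}.
#' @return List of class \code{bootstrapReport}: \code{acc} (replicates
#'   x other time points accuracy matrix), \code{cross_mean}
#'   (per-replicate mean over those time points), \code{mean} /
#'   \code{sd} (per time point), \code{overall_mean} /
#'   \code{overall_sd} (of \code{cross_mean}), \code{t_build},
#'   \code{n_replicates}.
#' @export
bootstrapEvaluate <- function(x, genes, t_build, n_replicates = 50L,
                              seed = 1L, scoring = c("all", "oob"),
                              ridge = 1e-4) {
  scoring <- match.arg(scoring)
  if (!length(genes)) stop("gene group must be non-empty")
  y <- responseBinary(x)
  n <- length(y)
  others <- setdiff(timePoints(x), t_build)
  if (!length(others)) stop("no time points other than 't_build' to score")
  Xb <- designMatrix(x, t_build)[, genes, drop = FALSE]
  Xd <- lapply(others, function(d)
    designMatrix(x, d)[, genes, drop = FALSE])
  names(Xd) <- others

  set.seed(seed)
  acc <- matrix(NA_real_, n_replicates, length(others),
                dimnames = list(NULL, others))
  for (b in seq_len(n_replicates)) {
    for (attempt in seq_len(100L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      if (attempt == 100L)
        stop("could not draw a two-class bootstrap sample in 100 attempts")
    }
    fit <- fitPredictionModel(Xb[idx, , drop = FALSE], y[idx], ridge)
    oob <- setdiff(seq_len(n), idx)
    for (d in others) {
      keep <- if (scoring == "oob") oob else seq_len(n)
      if (!length(keep)) next
      pred <- .classify(predict(fit, Xd[[d]][keep, , drop = FALSE]))
      acc[b, d] <- 100 * mean(pred == y[keep])
    }
  }
  cross_mean <- rowMeans(acc)
  sdv <- if (n_replicates > 1L) apply(acc, 2L, stats::sd) else {
    warning("single replicate: SD reported as 0")
    stats::setNames(rep(0, length(others)), others)
  }
  osd <- if (n_replicates > 1L) stats::sd(cross_mean) else 0
  structure(list(acc = acc, cross_mean = cross_mean,
                 mean = colMeans(acc), sd = sdv,
                 overall_mean = mean(cross_mean), overall_sd = osd,
                 t_build = t_build,
                 n_replicates = as.integer(n_replicates)),
            class = "bootstrapReport")
}

#' @export
print.bootstrapReport <- function(x, ...) {
  cat("Bootstrap evaluation (", x$n_replicates, "replicates, built at",
      x$t_build, ")\n  per-time-point mean (sd):",
      paste(sprintf("%s %.1f (%.1f)", names(x$mean), x$mean, x$sd),
            collapse = ", "),
      "\n  cross-time mean:", sprintf("%.1f", x$overall_mean), "\n")
  invisible(x)
}

#' Compare two bootstrap accuracy distributions
#'
#' Welch two-sample t-test (two-sided) between the replicate-level
#' cross-time mean accuracies of two bootstrap reports (or two numeric
#' vectors).
#'
#' @param a,b \code{bootstrapReport} objects or numeric vectors of
#'   replicate accuracies.
#' @return The \code{htest} object from \code{t.test}.
#' @export
compareBootstrap <- function(a, b) {
  va <- if (inherits(a, "bootstrapReport")) a$cross_mean else a
  vb <- if (inherits(b, "bootstrapReport")) b$cross_mean else b
  t.test(va, vb, var.equal = FALSE)
}

.aucRank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks on ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve, AUC and bootstrap confidence interval
#'
#' AUC via the rank (Mann-Whitney) formulation with midrank tie
#' correction; the 95\% confidence interval from stratified bootstrap
#' percentiles (resampling each class separately), or the DeLong
#' variance formula with a normal interval.
#'
#' @param scores per-sample predicted probabilities (or any monotone
#'   score).
#' @param labels binary labels (1 = good responder); both classes
#'   required.
#' @param n_boot bootstrap resamples for the percentile interval.
#' @param seed RNG seed.
#' @param method \code{"bootstrap"} (default) or \code{"delong"}.
#' @param conf confidence level.
#' @return List: \code{auc}, \code{ci} (length-2), \code{method},
#'   \code{roc} (data.frame of FPR/TPR points at every threshold).
#' @export
rocAucCi <- function(scores, labels, n_boot = 2000L, seed = 1L,
                     method = c("bootstrap", "delong"), conf = 0.95) {
  method <- match.arg(method)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  auc <- .aucRank(scores, labels)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(thr, function(s) mean(scores[labels == 0] >= s), 0),
    tpr = vapply(thr, function(s) mean(scores[labels == 1] >= s), 0))

  alpha <- 1 - conf
  if (method == "bootstrap") {
    pos <- which(labels == 1)
    neg <- which(labels == 0)
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- c(pos[sample.int(length(pos), replace = TRUE)],
             neg[sample.int(length(neg), replace = TRUE)])
      .aucRank(scores[i], labels[i])
    }, numeric(1))
    ci <- unname(quantile(bs, c(alpha / 2, 1 - alpha / 2)))
  } else {
    # DeLong structural components
    xs <- scores[labels == 1]
    ys <- scores[labels == 0]
    v10 <- vapply(xs, function(xi)
      mean((xi > ys) + 0.5 * (xi == ys)), numeric(1))
    v01 <- vapply(ys, function(yi)
      mean((xs > yi) + 0.5 * (xs == yi)), numeric(1))
    v <- stats::var(v10) / length(xs) + stats::var(v01) / length(ys)
    zq <- stats::qnorm(1 - alpha / 2)
    ci <- c(max(0, auc - zq * sqrt(v)), min(1, auc + zq * sqrt(v)))
  }
  list(auc = auc, ci = ci, method = method, roc = roc)
}

#' Per-gene responder-difference report
#'
#' For every gene and time point, a two-sided Wilcoxon rank-sum test
#' between good and poor responders (exact when sample sizes permit and
#' no ties, normal approximation otherwise), Benjamini-Hochberg
#' adjusted within each time point across the reported genes.  Each
#' gene gets a direction flag: \code{"good"} if the good-responder
#' median is higher at every time point, \code{"poor"} if lower at
#' every time point, otherwise \code{"inconsistent"}.
#'
#' @param x a \linkS4class{TimeCourseSet}.
#' @param genes genes to report on.
#' @return List of class \code{geneDifferenceReport}: \code{p_raw} and
#'   \code{p_adj} (genes x time points matrices), \code{direction}
#'   (named character).
#' @export
responderDifferenceReport <- function(x, genes) {
  if (!all(genes %in% rownames(x)))
    stop("gene(s) absent from dataset: ",
         paste(setdiff(genes, rownames(x)), collapse = ", "))
  resp <- responseLabels(x)
  tps <- timePoints(x)
  p_raw <- matrix(NA_real_, length(genes), length(tps),
                  dimnames = list(genes, tps))
  med_good <- med_poor <- p_raw
  for (t in tps) {
    m <- exprMatrix(x, t)[genes, , drop = FALSE]
    for (g in genes) {
      gv <- m[g, resp == "good"]
      pv <- m[g, resp == "poor"]
      p_raw[g, t] <- suppressWarnings(wilcox.test(gv, pv)$p.value)
      med_good[g, t] <- median(gv)
      med_poor[g, t] <- median(pv)
    }
  }
  p_adj <- apply(p_raw, 2L, p.adjust, method = "BH")
  if (is.null(dim(p_adj)))
    p_adj <- matrix(p_adj, 1L, length(tps), dimnames = list(genes, tps))
  direction <- vapply(genes, function(g) {
    if (all(med_good[g, ] > med_poor[g, ])) "good"
    else if (all(med_good[g, ] < med_poor[g, ])) "poor"
    else "inconsistent"
  }, character(1))
  structure(list(p_raw = p_raw, p_adj = p_adj, direction = direction),
            class = "geneDifferenceReport")
}

#' @export
print.geneDifferenceReport <- function(x, ...) {
  cat("Responder-difference report for", nrow(x$p_adj), "genes:\n")
  df <- data.frame(round(x$p_adj, 3), direction = x$direction)
  print(df)
  invisible(x)
}

#' Write a responder-difference report as TSV
#'
#' @param report a \code{geneDifferenceReport}.
#' @param path output file.
#' @export
writeDifferenceReport <- function(report, path) {
  df <- data.frame(gene = rownames(report$p_adj), report$p_adj,
                   direction = report$direction, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROC curve points as TSV
#'
#' @param roc result of \code{\link{rocAucCi}}.
#' @param path output file.
#' @export
writeRoc <- function(roc, path) {
  write.table(roc$roc, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
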