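#' Run the full time-course biomarker pipeline
#'
#' Executes, with one master seed driving every random stage:
#' gene-pool screening, sequential weighted stability selection,
#' consistency ranking, the prefix/time-point model search, and the
#' evaluation suite (bootstrap accuracy at the time points not used for
#' construction, ROC/AUC with confidence intervals per time point, and
#' the per-gene rank-sum report).  Optionally writes every stage
#' artifact as TSV/JSON into \code{out_dir}.
#'
#' @param x a preprocessed \linkS4class{TimeCourseSet} with at least
#'   two time points.
#' @param ss an \code{\link{ssControl}} list; its \code{seed} is
#'   overridden by \code{seed} when that is supplied.
#' @param gamma penalty multiplier of the sequential stage (> 1).
#' @param k_max largest ranking prefix searched (default min(pool, 30)).
#' @param n_bootstrap bootstrap replicates for the evaluation stage.
#' @param auc_boot bootstrap resamples for the AUC confidence interval.
#' @param seed master seed (defaults to \code{ss$seed}).
#' @param out_dir if non-NULL, directory for stage artifacts.
#' @return List of class \code{tcenetResult}: \code{pool},
#'   \code{selections}, \code{ranking} (\linkS4class{RankedGeneList}),
#'   \code{model} (\linkS4class{BestModel}), \code{bootstrap},
#'   \code{auc} (per time point), \code{gene_report}, \code{seed}.
#' @seealso \code{\link{runConventional}} for the single-time-point
#'   comparator.
#' @export
runProposed <- function(x, ss = ssControl(), gamma = 2, k_max = NULL,
                        n_bootstrap = 50L, auc_boot = 2000L,
                        seed = ss$seed, out_dir = NULL) {
  if (nTimePoints(x) < 2L)
    stop("time-course method requires at least two time points")
  ss$seed <- as.integer(seed)

  pool <- withStage("gene pool", buildGenePool(x, ss))
  selections <- withStage("sequential selection",
    sequentialWeightedSelection(x, pool, ss, gamma = gamma))
  ranking <- withStage("ranking", rankBySPFinal(selections))
  model <- withStage("model search",
    searchBestModel(x, ranking, k_max = k_max))

  boot <- withStage("bootstrap evaluation",
    bootstrapEvaluate(x, bestGenes(model), buildTimePoint(model),
                      n_replicates = n_bootstrap,
                      seed = .deriveSeed(seed, 3L)))
  auc <- withStage("ROC/AUC", {
    out <- list()
    for (i in seq_along(timePoints(x))) {
      t <- timePoints(x)[i]
      out[[t]] <- rocAucCi(predictResponse(model, x, t),
                           responseBinary(x), n_boot = auc_boot,
                           seed = .deriveSeed(seed, 4L, i))
    }
    out
  })
  report <- withStage("gene report",
    responderDifferenceReport(x, bestGenes(model)))

  res <- structure(list(pool = pool, selections = selections,
                        ranking = ranking, model = model,
                        bootstrap = boot, auc = auc,
                        gene_report = report, seed = seed),
                   class = "tcenetResult")
  if (!is.null(out_dir)) writeResultBundle(res, x, out_dir)
  res
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the single-time-point comparator
#'
#' Stability selection at a single time point ranks all genes by their
#' selection probability (no pool, no history weighting); the same
#' prefix/time-point model search then picks the best model.  The
#' history-weight parameter gamma plays no role here.
#'
#' @param x a preprocessed \linkS4class{TimeCourseSet}.
#' @param t_single the single time point whose data drive the ranking.
#' @param ss an \code{\link{ssControl}} list.
#' @param k_max largest ranking prefix searched (default 30).
#' @param n_bootstrap bootstrap replicates (evaluated at the chosen
#'   model's construction time point).
#' @param seed master seed.
#' @return List of class \code{tcenetResult} with elements
#'   \code{ranking} (character, all genes by selection probability),
#'   \code{sel_prob}, \code{model}, \code{bootstrap}, \code{t_single},
#'   \code{seed}.
#' @export
runConventional <- function(x, t_single, ss = ssControl(),
                            k_max = 30L, n_bootstrap = 50L,
                            seed = ss$seed) {
  if (!t_single %in% timePoints(x))
    stop("unknown time point: ", t_single)
  ss$seed <- as.integer(seed)
  prof <- withStage("stability selection",
    runStabilitySelection(designMatrix(x, t_single), responseBinary(x),
                          ss, seed = .deriveSeed(seed, 5L)))
  sp <- selProb(prof)
  ranking <- names(sp)[order(-sp)]  # stable: ties keep gene order
  model <- withStage("model search",
    searchBestModel(x, ranking, k_max = k_max))
  boot <- withStage("bootstrap evaluation",
    bootstrapEvaluate(x, bestGenes(model), buildTimePoint(model),
                      n_replicates = n_bootstrap,
                      seed = .deriveSeed(seed, 6L)))
  structure(list(ranking = ranking, sel_prob = sp, model = model,
                 bootstrap = boot, t_single = t_single, seed = seed),
            class = "tcenetResult")
}

#' @export
print.tcenetResult <- function(x, ...) {
  if (!is.null(x$t_single))
    cat("Single-time-point comparator run (ranking built at",
        x$t_single, ")\n")
  else cat("Time-course pipeline run (pool of", length(x$pool),
           "genes )\n")
  show(x$model)
  if (!is.null(x$bootstrap))
    cat("  bootstrap cross-time mean accuracy:",
        sprintf("%.1f", x$bootstrap$overall_mean), "%\n")
  invisible(x)
}

#' Write every stage artifact of a pipeline run
#'
#' Writes pool.tsv, ranking.tsv, candidate_grid.tsv, model.json,
#' bootstrap.tsv, auc.tsv, roc_<t>.tsv and gene_report.tsv.
#'
#' @param res a \code{tcenetResult} from \code{\link{runProposed}}.
#' @param x the dataset the run used.
#' @param dir output directory (created if needed).
#' @export
writeResultBundle <- function(res, x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$pool))
    write.table(data.frame(gene = res$pool), file.path(dir, "pool.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (is(res$ranking, "RankedGeneList"))
    writeRankedGenes(res$ranking, file.path(dir, "ranking.tsv"))
  writeCandidateGrid(res$model, file.path(dir, "candidate_grid.tsv"))
  jsonlite::write_json(
    list(genes = bestGenes(res$model),
         t_build = buildTimePoint(res$model),
         intercept = res$model@intercept,
         coefficients = as.list(res$model@coefficients),
         accuracy = as.list(accTable(res$model))),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (!is.null(res$bootstrap)) {
    b <- res$bootstrap
    write.table(
      data.frame(time_point = names(b$mean), mean = b$mean, sd = b$sd),
      file.path(dir, "bootstrap.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(res$auc)) {
    write.table(
      data.frame(time_point = names(res$auc),
                 auc = vapply(res$auc, `[[`, 0, "auc"),
                 ci_lo = vapply(res$auc, function(a) a$ci[1], 0),
                 ci_hi = vapply(res$auc, function(a) a$ci[2], 0)),
      file.path(dir, "auc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (t in names(res$auc))
      writeRoc(res$auc[[t]], file.path(dir, sprintf("roc_%s.tsv", t)))
  }
  if (!is.null(res$gene_report))
    writeDifferenceReport(res$gene_report,
                          file.path(dir, "gene_report.tsv"))
  invisible(dir)
}
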