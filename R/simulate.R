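#' Settings for the synthetic time-course generator
#'
#' The defaults emulate the study conditions of the motivating design:
#' 15 good and 9 poor responders, three time points, three genes with a
#' consistent between-class shift at every time point, three genes
#' shifted at exactly one time point each, one block of five genes
#' sharing pairwise correlation 0.9 (multicollinearity), and
#' independent-noise null genes up to \code{p = 100}.  The effect is a
#' standardized mean shift of 2.5 noise SDs.
#'
#' @param n_good,n_poor class sizes.
#' @param p total genes.
#' @param T_points number of time points.
#' @param n_consistent genes shifted between classes at every time
#'   point.
#' @param n_inconsistent genes shifted at exactly one time point each
#'   (active time points cycle over the series).
#' @param effect between-class mean shift in units of \code{noise_sd}.
#' @param effect_inconsistent mean shift of the inconsistent genes at
#'   their active time point (default: same as \code{effect}).  Setting
#'   it above \code{effect} emulates strongly but transiently
#'   predictive genes, the failure mode of single-time-point rankings.
#' @param n_blocks,block_size,rho correlated null-gene blocks: each
#'   block shares pairwise correlation \code{rho} via a latent factor.
#' @param noise_sd residual noise SD.
#' @param standardize return per-gene standardized matrices (the
#'   solver's expected input scale).
#' @return A list of class \code{simControl}.
#' @export
simControl <- function(n_good = 15L, n_poor = 9L, p = 100L,
                       T_points = 3L, n_consistent = 3L,
                       n_inconsistent = 3L, effect = 2.5,
                       effect_inconsistent = effect,
                       n_blocks = 1L, block_size = 5L, rho = 0.9,
                       noise_sd = 1, standardize = TRUE) {
  if (n_consistent + n_inconsistent + n_blocks * block_size > p)
    stop("planted and block genes exceed the total gene count 'p'")
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  if (effect < 0) stop("'effect' must be non-negative")
  if (T_points < 1L) stop("at least one time point is required")
  structure(list(n_good = as.integer(n_good),
                 n_poor = as.integer(n_poor), p = as.integer(p),
                 T_points = as.integer(T_points),
                 n_consistent = as.integer(n_consistent),
                 n_inconsistent = as.integer(n_inconsistent),
                 effect = effect,
                 effect_inconsistent = effect_inconsistent,
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size), rho = rho,
                 noise_sd = noise_sd, standardize = standardize),
            class = "simControl")
}

#' Simulate a labelled time-course expression dataset
#'
#' Samples are drawn from class-conditional normals per time point:
#' consistent genes carry a mean shift of \eqn{\pm effect/2} (good vs
#' poor) at every time point, inconsistent genes only at their active
#' time point, block genes share pairwise correlation \eqn{\rho}
#' through a latent factor (\eqn{x = \sqrt{\rho}\,z +
#' \sqrt{1-\rho}\,\epsilon}), and null genes are independent noise.
#' Fully reproducible from \code{seed}.
#'
#' @param control a \code{\link{simControl}} list.
#' @param seed RNG seed.
#' @return List with \code{dataset} (a \linkS4class{TimeCourseSet},
#'   standardized if requested) and \code{truth}: index sets
#'   \code{consistent}, \code{inconsistent} (with attribute
#'   \code{active_time} naming each gene's shifted time point),
#'   \code{blocks} (list per block), \code{null}.
#' @examples
#' sim <- simulateTimeCourse(simControl(p = 20, block_size = 2), seed = 7)
#' sim$dataset
#' sim$truth$consistent
#' @export
simulateTimeCourse <- function(control = simControl(), seed = 1L) {
  c_ <- control
  n <- c_$n_good + c_$n_poor
  genes <- sprintf("g%03d", seq_len(c_$p))
  samples <- sprintf("s%02d", seq_len(n))
  tps <- paste0("t", seq_len(c_$T_points))
  y <- c(rep(1L, c_$n_good), rep(0L, c_$n_poor))

  i_cons <- seq_len(c_$n_consistent)
  i_inc <- seq_len(c_$n_inconsistent) + c_$n_consistent
  blocks <- list()
  nb <- c_$n_blocks * c_$block_size
  if (nb > 0) {
    start <- c_$n_consistent + c_$n_inconsistent
    for (b in seq_len(c_$n_blocks))
      blocks[[b]] <- start + (b - 1L) * c_$block_size +
        seq_len(c_$block_size)
  }
  i_null <- setdiff(seq_len(c_$p), c(i_cons, i_inc, unlist(blocks)))
  active_time <- tps[((seq_len(c_$n_inconsistent) - 1L) %%
                        c_$T_points) + 1L]

  set.seed(seed)
  mats <- list()
  for (ti in seq_along(tps)) {
    shift <- rep(0, c_$p)
    shift[i_cons] <- c_$effect
    shift[i_inc[active_time == tps[ti]]] <- c_$effect_inconsistent
    # samples x genes noise
    m <- matrix(rnorm(n * c_$p, sd = c_$noise_sd), n, c_$p)
    for (b in blocks) {
      z <- rnorm(n, sd = c_$noise_sd)
      m[, b] <- sqrt(c_$rho) * z +
        sqrt(1 - c_$rho) * m[, b, drop = FALSE]
    }
    mu <- outer(ifelse(y == 1, 0.5, -0.5), shift * c_$noise_sd)
    m <- m + mu
    m <- t(m)  # genes x samples
    dimnames(m) <- list(genes, samples)
    if (c_$standardize) m <- zscoreGenes(m)
    mats[[tps[ti]]] <- m
  }
  truth <- list(consistent = genes[i_cons],
                inconsistent = stats::setNames(genes[i_inc],
                                               active_time),
                blocks = lapply(blocks, function(b) genes[b]),
                null = genes[i_null])
  attr(truth$inconsistent, "active_time") <- active_time
  list(dataset = TimeCourseSet(mats,
                               response = stats::setNames(
                                 ifelse(y == 1, "good", "poor"),
                                 samples)),
       truth = truth)
}

#' Write the planted ground truth as JSON
#'
#' @param truth the \code{truth} element of
#'   \code{\link{simulateTimeCourse}}'s result.
#' @param path output file.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(
    list(consistent = truth$consistent,
         inconsistent = as.list(stats::setNames(
           as.character(truth$inconsistent),
           attr(truth$inconsistent, "active_time"))),
         blocks = truth$blocks, null = truth$null),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
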