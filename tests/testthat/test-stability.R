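test_that("stratified subsamples respect class counts and the seed", {
  y <- rep(c(1, 0), c(15, 9))
  set.seed(1)
  idx <- stratifiedSubsample(y, 12, 8)
  expect_length(idx, 20)
  expect_identical(sum(y[idx] == 1), 12L)
  expect_identical(sum(y[idx] == 0), 8L)
  expect_false(anyDuplicated(idx) > 0)

  # exhausting a class always includes all of it
  set.seed(2)
  idx2 <- stratifiedSubsample(y, 9, 9)
  expect_setequal(idx2[y[idx2] == 0], which(y == 0))

  set.seed(42); a <- replicate(5, stratifiedSubsample(y, 12, 8))
  set.seed(42); b <- replicate(5, stratifiedSubsample(y, 12, 8))
  expect_identical(a, b)

  expect_error(stratifiedSubsample(y, 16, 8), "cannot supply")
})

test_that("selection frequencies are multiples of 1/B and sel_prob is the max over lambda", {
  tcs <- toy_tcs()
  X <- designMatrix(tcs, "t1")
  y <- responseBinary(tcs)
  ctl <- ssControl(n_iterations = 40L, n_good_sub = 9L, n_poor_sub = 6L,
                   lambda_grid = c(0.05, 0.2, 0.6), seed = 5L)
  prof <- runStabilitySelection(X, y, ctl)
  expect_true(all(abs(selFreq(prof) * 40 -
                        round(selFreq(prof) * 40)) < 1e-12))
  expect_equal(selProb(prof), apply(selFreq(prof), 1, max))

  # singleton grid: sel_prob equals that lambda's frequency column
  ctl1 <- ssControl(n_iterations = 40L, n_good_sub = 9L,
                    n_poor_sub = 6L, lambda_grid = 0.2, seed = 5L)
  prof1 <- runStabilitySelection(X, y, ctl1)
  expect_equal(selProb(prof1), selFreq(prof1)[, 1])

  # sel_prob invariant to the order of lambda values (same subsamples)
  ctl_rev <- ctl
  ctl_rev$lambda_grid <- rev(ctl$lambda_grid)
  prof_rev <- runStabilitySelection(X, y, ctl_rev)
  expect_equal(selProb(prof_rev), selProb(prof))
})

test_that("thresholding is inclusive and validates theta", {
  prof <- new("SelectionProfile",
              freq = matrix(c(0.9, 0.5, 0.2), 3, 1,
                            dimnames = list(c("g1", "g2", "g3"), NULL)),
              selProb = c(g1 = 0.9, g2 = 0.5, g3 = 0.2),
              lambda = 0.3, nIterations = 10L)
  expect_identical(thresholdSelect(prof, 0.5), c("g1", "g2"))
  expect_length(thresholdSelect(prof, 1.0), 0)
  expect_error(thresholdSelect(prof, 0), "0, 1")
  expect_error(ssControl(theta_ss = 0), "0, 1")
})

test_that("Monte-Carlo frequencies converge to exhaustive enumeration on a 6-sample design", {
  set.seed(33)
  n <- 6
  y <- rep(c(1, 0), each = 3)
  X <- stdcols(matrix(rnorm(n * 3), n, 3))
  X[, 1] <- stdcols(matrix(ifelse(y == 1, 1, -1) + rnorm(n, sd = 0.6)))
  colnames(X) <- paste0("g", 1:3)
  grid <- c(0.05, 0.15, 0.4)
  ctl_enet <- enetControl(tol = 1e-9)

  # oracle: enumerate all C(3,2)^2 = 9 equally likely stratified draws
  good_sets <- combn(which(y == 1), 2, simplify = FALSE)
  poor_sets <- combn(which(y == 0), 2, simplify = FALSE)
  exact <- matrix(0, 3, length(grid))
  n_draws <- 0
  for (gs in good_sets) for (ps in poor_sets) {
    idx <- c(gs, ps)
    fits <- fitEnetLogistic(X[idx, ], y[idx], grid, control = ctl_enet)
    act <- vapply(fits, function(f)
      seq_len(3) %in% activeSet(f), logical(3))
    exact <- exact + act
    n_draws <- n_draws + 1
  }
  exact <- exact / n_draws

  B <- 1500L
  prof <- runStabilitySelection(
    X, y, ssControl(n_iterations = B, n_good_sub = 2L, n_poor_sub = 2L,
                    lambda_grid = grid, seed = 77L, enet = ctl_enet))
  mc <- unname(selFreq(prof))
  se <- sqrt(exact * (1 - exact) / B)
  expect_true(all(abs(mc - exact) <= 3 * se + 1e-12))
})

test_that("raising a gene's penalty weight never increases its selection frequency", {
  # full-data "subsamples" keep the design orthogonal across draws
  set.seed(12)
  n <- 16
  y <- rep(c(1, 0), each = 8)
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  X <- stdcols(Q)
  colnames(X) <- paste0("g", 1:4)
  grid <- seq(0.02, 0.3, length.out = 8)
  ctl <- function(w1) {
    list(w = c(w1, 1, 1, 1),
         ss = ssControl(n_iterations = 5L, n_good_sub = 8L,
                        n_poor_sub = 8L, lambda_grid = grid, seed = 3L))
  }
  a <- ctl(1); b <- ctl(2.5)
  fa <- selFreq(runStabilitySelection(X, y, a$ss, weights = a$w))
  fb <- selFreq(runStabilitySelection(X, y, b$ss, weights = b$w))
  expect_true(all(fb["g1", ] <= fa["g1", ] + 1e-12))
})

test_that("a planted differential gene attains the top selection probability", {
  set.seed(21)
  n <- 20
  y <- rep(c(1, 0), each = 10)
  X <- matrix(rnorm(n * 30), n, 30)
  X[, 7] <- ifelse(y == 1, 1.5, -1.5) + rnorm(n, sd = 1)
  X <- stdcols(X)
  colnames(X) <- paste0("g", 1:30)
  prof <- runStabilitySelection(
    X, y, ssControl(n_iterations = 100L, n_good_sub = 7L,
                    n_poor_sub = 7L, lambda_grid = seq(0.1, 1, by = 0.1),
                    seed = 4L))
  expect_identical(unname(which.max(selProb(prof))), 7L)
})

test_that("pure-noise designs do not produce saturated selection probabilities", {
  set.seed(55)
  n <- 20
  y <- rep(c(1, 0), each = 10)
  X <- stdcols(matrix(rnorm(n * 30), n, 30))
  colnames(X) <- paste0("g", 1:30)
  grid <- seq(0.1, 1, by = 0.1)
  prof <- runStabilitySelection(
    X, y, ssControl(n_iterations = 100L, n_good_sub = 7L,
                    n_poor_sub = 7L, lambda_grid = grid, seed = 6L))
  # at the stronger penalties no gene is ever selected every time and
  # the typical gene is almost never selected
  high <- grid >= 0.5
  expect_lt(max(selFreq(prof)[, high]), 1.0)
  expect_lt(median(selFreq(prof)[, high]), 0.05)
})

test_that("selection profiles serialize to TSV", {
  tcs <- toy_tcs()
  prof <- runStabilitySelection(
    designMatrix(tcs, "t1"), responseBinary(tcs),
    ssControl(n_iterations = 20L, n_good_sub = 9L, n_poor_sub = 6L,
              lambda_grid = c(0.1, 0.4), seed = 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSelectionProfile(prof, path)
  tab <- read.delim(path)
  expect_identical(tab$gene, rownames(selFreq(prof)))
  expect_equal(tab$sel_prob, unname(selProb(prof)))
})
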