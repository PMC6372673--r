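test_that("confusion-count accuracy is exact", {
  expect_equal(accuracyFromConfusion(2, 0, 0, 2), 100)
  expect_equal(accuracyFromConfusion(3, 1, 2, 2), 62.5)
  expect_equal(accuracyFromConfusion(0, 1, 1, 0), 0)
  expect_error(accuracyFromConfusion(0, 0, 0, 0), "sum to zero")
  expect_error(accuracyFromConfusion(-1, 0, 0, 2), "non-negative")
  # exact rational path for large counts
  expect_identical(accuracyFromConfusion(3e5, 1e5, 1e5, 5e5),
                   100 * 8e5 / 1e6)
})

test_that("rank-formulation AUC equals the all-pairs oracle, with ties", {
  expect_equal(rocAucCi(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1),
                        n_boot = 50)$auc, 1.0)
  expect_equal(rocAucCi(rep(0.4, 8), rep(c(0, 1), 4),
                        n_boot = 50)$auc, 0.5)
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 1)  # force ties
    r <- rocAucCi(scores, labels, n_boot = 20)
    expect_equal(r$auc, auc_bruteforce(scores, labels))
  }
  expect_error(rocAucCi(1:4, rep(1, 4)), "both classes")
})

test_that("ROC points and confidence intervals are coherent", {
  set.seed(42)
  labels <- rep(c(0, 1), each = 10)
  scores <- plogis(labels + rnorm(20))
  r <- rocAucCi(scores, labels, n_boot = 500, seed = 2)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_lte(r$ci[1], r$ci[2])
  expect_true(r$ci[1] >= 0 && r$ci[2] <= 1)
  rd <- rocAucCi(scores, labels, method = "delong")
  expect_equal(rd$auc, r$auc)
  expect_true(rd$ci[1] < rd$auc && rd$auc < rd$ci[2])
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  expect_equal(bh_stepup(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(43)
  for (rep in 1:10) {
    p <- runif(sample(1:12, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup(p))
  }
  expect_equal(p.adjust(0.3, "BH"), 0.3)  # identity at m = 1
})

test_that("rank-sum p-values match exhaustive enumeration and direction flags follow medians", {
  expect_equal(ranksum_exact_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(suppressWarnings(
    wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value), 0.1)
  set.seed(44)
  for (rep in 1:5) {
    a <- rnorm(4)  # continuous, tie-free: the exact test applies
    b <- rnorm(4)
    expect_equal(wilcox.test(a, b, exact = TRUE)$p.value,
                 ranksum_exact_p(a, b), tolerance = 1e-12)
  }

  set.seed(45)
  n_good <- 8; n_poor <- 6
  n <- n_good + n_poor
  y <- rep(c(1, 0), c(n_good, n_poor))
  mk <- function(shift_by_t) {
    mats <- lapply(shift_by_t, function(s) {
      m <- t(matrix(rnorm(n * 3, sd = 0.2), n, 3) +
               outer(ifelse(y == 1, 1, -1), s / 2))
      dimnames(m) <- list(paste0("g", 1:3), paste0("s", 1:n))
      m
    })
    names(mats) <- paste0("t", seq_along(mats))
    TimeCourseSet(mats, response = ifelse(y == 1, "good", "poor"))
  }
  # g1 higher in good at both t; g2 higher in poor; g3 flips direction
  tcs <- mk(list(c(3, -3, 3), c(3, -3, -3)))
  rep_ <- responderDifferenceReport(tcs, c("g1", "g2", "g3"))
  expect_identical(unname(rep_$direction),
                   c("good", "poor", "inconsistent"))
  expect_true(all(rep_$p_adj >= rep_$p_raw - 1e-15))
  expect_true(all(rep_$p_adj > 0 & rep_$p_adj <= 1))
  # BH is applied within each time point across genes
  expect_equal(rep_$p_adj[, "t1"],
               bh_stepup(rep_$p_raw[, "t1"]), ignore_attr = TRUE)
})

test_that("bootstrap evaluation: perfect classifier, degenerate replicate count, stability", {
  tcs <- toy_tcs(T_points = 3, gap = 6)
  b <- bootstrapEvaluate(tcs, "g1", "t1", n_replicates = 25, seed = 1)
  expect_equal(unname(b$mean), c(100, 100))
  expect_equal(unname(b$sd), c(0, 0))
  expect_equal(b$overall_mean, 100)
  expect_identical(colnames(b$acc), c("t2", "t3"))

  expect_warning(b1 <- bootstrapEvaluate(tcs, "g1", "t1",
                                         n_replicates = 1, seed = 1),
                 "single replicate")
  expect_equal(unname(b1$sd), c(0, 0))

  # doubling replicates moves the mean by less than 2 Monte-Carlo SEs
  tcs2 <- toy_tcs(T_points = 2, gap = 1, seed = 7)
  b50 <- bootstrapEvaluate(tcs2, c("g1", "g2"), "t1",
                           n_replicates = 50, seed = 3)
  b100 <- bootstrapEvaluate(tcs2, c("g1", "g2"), "t1",
                            n_replicates = 100, seed = 4)
  se <- sqrt(stats::var(b50$cross_mean) / 50 +
               stats::var(b100$cross_mean) / 100)
  expect_lt(abs(b50$overall_mean - b100$overall_mean), 2 * se + 1)

  # out-of-bag scoring is supported and bounded like the default
  boob <- bootstrapEvaluate(tcs, "g1", "t1", n_replicates = 10,
                            seed = 5, scoring = "oob")
  expect_true(all(boob$acc >= 0 & boob$acc <= 100, na.rm = TRUE))

  expect_error(bootstrapEvaluate(tcs, character(0), "t1"), "non-empty")
})

test_that("Welch comparison of bootstrap reports returns a two-sided htest", {
  set.seed(46)
  a <- rnorm(30, 80, 4)
  b <- rnorm(30, 70, 6)
  ht <- compareBootstrap(a, b)
  expect_s3_class(ht, "htest")
  expect_match(ht$method, "Welch")
  expect_lt(ht$p.value, 0.01)
})
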