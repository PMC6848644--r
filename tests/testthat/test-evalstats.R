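test_that("dice matches the set formula, is symmetric, and handles emptiness", {
  mk <- function(v) array(v, c(2, 3, 1))
  a <- mk(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  b <- mk(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))   # |a|=4 |b|=5 |int|=3
  expect_equal(dice(a, b), 2 * 3 / (4 + 5))
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(mk(c(TRUE, rep(FALSE, 5))),
                    mk(c(FALSE, TRUE, rep(FALSE, 4)))), 0)
  expect_equal(dice(mk(rep(FALSE, 6)), mk(rep(FALSE, 6))), 1)
  expect_error(dice(a, array(TRUE, c(3, 3, 1))), "geometry mismatch")

  ## |a| = 4, |b| = 6, |intersection| = 3 -> 0.6
  a2 <- array(FALSE, c(3, 4, 1)); b2 <- array(FALSE, c(3, 4, 1))
  a2[1, 1:4, 1] <- TRUE
  b2[1, 1:3, 1] <- TRUE; b2[2, 1:3, 1] <- TRUE
  expect_equal(dice(a2, b2), 2 * 3 / (4 + 6))
})

test_that("dice on LabelMasks selects the requested structure", {
  lab1 <- array(0L, c(4, 4, 2)); lab2 <- array(0L, c(4, 4, 2))
  lab1[1:2, 1:2, 1] <- 1L; lab1[1, 1, 1] <- 2L
  lab2[1:2, 1:2, 1] <- 1L; lab2[1, 1:2, 1] <- 2L
  m1 <- labelMask(lab1); m2 <- labelMask(lab2)
  expect_equal(dice(m1, m2, "midbrain"), 1)
  expect_equal(dice(m1, m2, "snpc"), 2 * 1 / (1 + 2))
})

test_that("dice oracle equivalence on random mask pairs", {
  set.seed(404)
  for (i in 1:50) {
    a <- array(runif(60) < 0.4, c(4, 5, 3))
    b <- array(runif(60) < 0.4, c(4, 5, 3))
    expected <- if (sum(a) + sum(b) == 0) 1 else 2 * sum(a & b) / (sum(a) + sum(b))
    expect_equal(dice(a, b), expected)
  }
})

test_that("DSC rating bands match the printed scale exactly", {
  expect_identical(rateDSC(0.83), "high")
  expect_identical(rateDSC(0.79), "moderate")
  expect_identical(rateDSC(0.40), "moderate")
  expect_identical(rateDSC(0.39), "low")
  expect_identical(rateDSC(0.80), "high")
  expect_identical(rateDSC(c(0, 1)), c("low", "high"))
  expect_error(rateDSC(1.2), "\\[0, 1\\]")
  ## total function over a fine grid
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(rateDSC(grid) %in% c("low", "moderate", "high")))
})

test_that("ROC AUC equals the pair-counting oracle, with correct orientation", {
  expect_equal(rocAUC(c(1, 2, 3, 4), c("PD", "PD", "HC", "HC"),
                      "low_is_positive")$auc, 1.0)
  expect_equal(rocAUC(c(1, 3, 2, 4), c("PD", "PD", "HC", "HC"),
                      "low_is_positive")$auc, 0.75)
  expect_equal(rocAUC(rep(5, 6), c("PD", "PD", "PD", "HC", "HC", "HC"),
                      "low_is_positive")$auc, 0.5)
  set.seed(11)
  for (i in 1:40) {
    n <- sample(6:14, 1)
    scores <- sample(1:6, n, TRUE)          # heavy ties
    labels <- c("PD", "HC", sample(c("HC", "PD"), n - 2, TRUE))
    r <- rocAUC(scores, labels, "low_is_positive")
    expect_equal(r$auc, pairCountAUC(scores, labels))
    ## orientation flip mirrors the AUC
    r2 <- rocAUC(scores, labels, "high_is_positive")
    expect_equal(r2$auc, 1 - r$auc)
  }
})

test_that("ROC AUC agrees with pROC and the cutoff maximises Youden's J", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:10) {
    scores <- rnorm(30)
    labels <- sample(c("HC", "PD"), 30, TRUE)
    if (length(unique(labels)) < 2) next
    r <- rocAUC(scores, labels, "high_is_positive")
    pr <- pROC::roc(labels, scores, levels = c("HC", "PD"),
                    direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    ## no curve point has a larger J than the reported optimum
    expect_true(all(r$curve$sensitivity + r$curve$specificity - 1 <=
                    r$sensitivity + r$specificity - 1 + 1e-12))
  }
})

test_that("DeLong self-comparison and antisymmetry behave as defined", {
  scores <- c(1, 5, 2, 8, 3, 9, 4, 7)
  labels <- rep(c("PD", "HC"), 4)
  self <- delongTest(scores, scores, labels)
  expect_equal(self$z, 0); expect_equal(self$p, 1)

  other <- scores + c(0.5, -1, 2, 0, -0.3, 1, 0, 0.2)
  ab <- delongTest(scores, other, labels)
  ba <- delongTest(other, scores, labels)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_true(ab$p >= 0 && ab$p <= 1)
})

test_that("DeLong agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:8) {
    n <- 24
    labels <- rep(c("HC", "PD"), n / 2)
    base <- rnorm(n) + (labels == "PD")
    a <- base + rnorm(n, 0, 0.6)
    b <- base + rnorm(n, 0, 0.6)
    mine <- delongTest(a, b, labels, orientation = "high_is_positive")
    ra <- pROC::roc(labels, a, levels = c("HC", "PD"), direction = "<",
                    quiet = TRUE)
    rb <- pROC::roc(labels, b, levels = c("HC", "PD"), direction = "<",
                    quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("Spearman strength bands follow the five-level scale", {
  r1 <- spearmanStrength(1:10, (1:10)^2)
  expect_equal(r1$r, 1); expect_identical(r1$category, "very strong")
  set.seed(5)
  ## bands evaluated on |r|
  expect_identical(nmseg:::.spearmanBand(-0.65), "strong")
  expect_identical(nmseg:::.spearmanBand(-0.32), "weak")
  expect_identical(nmseg:::.spearmanBand(0.19), "very weak")
  expect_identical(nmseg:::.spearmanBand(0.45), "moderate")
  expect_identical(nmseg:::.spearmanBand(0.80), "very strong")
  expect_error(spearmanStrength(rep(1, 5), 1:5), "constant")
  expect_error(spearmanStrength(1:2, 1:2), "at least 3")
})

test_that("group comparison wrappers match their base definitions", {
  x <- c(1, 2, 3, 4, 5)
  t0 <- groupCompare(x, x, "t")
  expect_equal(t0$statistic, 0); expect_equal(t0$p, 1)

  mw <- groupCompare(x, x, "mann_whitney")
  expect_equal(mw$statistic, length(x)^2 / 2)   # U = n1*n2/2 under identity

  chi <- groupCompare(matrix(c(10, 0, 0, 10), 2), test = "chi2")
  expect_equal(chi$statistic, 20)               # sum (O-E)^2/E, no correction
  expect_error(groupCompare(matrix(c(5, 5, 0, 0), 2, byrow = TRUE),
                            test = "chi2"), "zero margin")
  expect_error(groupCompare(numeric(0), x, "t"), "empty")
})

test_that("dice table aggregates by structure and group", {
  p <- noiselessParams()
  subs <- generateCohortInMemory(p, 2, 2)
  masks <- lapply(subs, function(s) s@truth)
  groups <- vapply(subs, function(s) s@record$group, character(1))
  dt <- diceTable(masks, masks, groups)
  expect_true(all(dt$meanDSC == 1))
  expect_true(all(dt$rating == "high"))
  expect_setequal(unique(dt$group), c("All", "HC", "PD"))
  expect_setequal(unique(dt$structure), c("midbrain", "snpc"))
})
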