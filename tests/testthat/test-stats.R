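# Two-group statistics: normality gate, Hodges-Lehmann, Mann-Whitney,
# chi-square, Spearman, significance filter.

test_that("normality test rejects log-normal and accepts normal data", {
  set.seed(81)
  # power: strongly skewed samples are flagged essentially always
  rej <- mean(replicate(50, normalityTest(rlnorm(500, 0, 1)) < 0.05))
  expect_gte(rej, 0.99)
  # calibration at the null (normal data): rejection rate near 0.05
  rejNull <- mean(replicate(400, normalityTest(rnorm(100)) < 0.05))
  expect_lt(abs(rejNull - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  # degenerate constant sample
  p <- normalityTest(rep(1, 10))
  expect_equal(as.numeric(p), 0)
  expect_true(isTRUE(attr(p, "degenerate")))
  expect_error(normalityTest(c(1, 2)), "insufficient")
})

test_that("Hodges-Lehmann estimate equals the pairwise-difference median", {
  cmp <- compareFeature(hc = c(1, 2, 3, 9), mci = c(2, 3, 4, 10))
  expect_equal(cmp@hlEstimate, 1)

  set.seed(82)
  for (i in 1:40) {
    hc <- round(rnorm(sample(5:12, 1), 10, 3), 2)
    mci <- round(rnorm(sample(5:12, 1), 12, 3), 2)
    cmp <- compareFeature(hc, mci)
    expect_equal(cmp@hlEstimate, hlOracle(hc, mci), tolerance = 1e-8)
    diffs <- as.vector(outer(mci, hc, "-"))
    expect_gte(cmp@hlEstimate, min(diffs))
    expect_lte(cmp@hlEstimate, max(diffs))
    expect_lte(cmp@hlCI[1], cmp@hlEstimate)
    expect_gte(cmp@hlCI[2], cmp@hlEstimate)
  }
})

test_that("Hodges-Lehmann is shift-equivariant", {
  set.seed(83)
  hc <- rnorm(15); mci <- rnorm(15)
  base <- compareFeature(hc, mci)@hlEstimate
  shifted <- compareFeature(hc, mci + 2.5)@hlEstimate
  expect_equal(shifted, base + 2.5, tolerance = 1e-8)
})

test_that("identical samples give a null comparison", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.8)
  cmp <- compareFeature(x, x)
  expect_equal(cmp@hlEstimate, 0)
  expect_gt(cmp@pValue, 0.9)
  expect_false(cmp@significant)
})

test_that("the normality gate picks the test", {
  set.seed(84)
  cmpN <- compareFeature(rnorm(60), rnorm(60, 0.2))
  expect_equal(cmpN@testUsed, "t")
  cmpL <- compareFeature(rlnorm(60, 0, 1), rlnorm(60, 0.3, 1))
  expect_equal(cmpL@testUsed, "mann_whitney")
})

test_that("Mann-Whitney is invariant under monotone transforms", {
  set.seed(85)
  hc <- rlnorm(30, 0, 0.8); mci <- rlnorm(30, 0.5, 0.8)
  p1 <- compareFeature(hc, mci, test = "mann_whitney")
  p2 <- compareFeature(log(hc), log(mci), test = "mann_whitney")
  expect_equal(p1@pValue, p2@pValue, tolerance = 1e-10)
  expect_equal(p1@statistic, p2@statistic, tolerance = 1e-10)
})

test_that("exact small-sample Mann-Whitney agrees with enumeration", {
  set.seed(86)
  hc <- c(1.1, 2.3, 3.7, 5.2, 8.4)
  mci <- c(2.2, 4.9, 6.1, 7.3, 9.9)
  cmp <- compareFeature(hc, mci, test = "mann_whitney")
  # full permutation enumeration of the U statistic, 10 choose 5 splits
  pool <- c(hc, mci)
  splits <- combn(10, 5)
  uOf <- function(idx) sum(rank(pool)[idx]) - 5 * 6 / 2
  uObs <- uOf(6:10)
  uAll <- apply(splits, 2, uOf)
  pExact <- mean(abs(uAll - 12.5) >= abs(uObs - 12.5))
  expect_equal(cmp@pValue, pExact, tolerance = 1e-10)
})

test_that("significance filter preserves order and matches a brute scan", {
  p <- c(a = 0.03, b = 0.5, c = 0.0004, d = NA, e = 0.049)
  expect_identical(significantFeatures(p), c("a", "c", "e"))
  expect_identical(significantFeatures(setNames(rep(0.5, 4), letters[1:4])),
                   character(0))
  set.seed(87)
  pv <- setNames(runif(50), paste0("x", 1:50))
  expect_identical(significantFeatures(pv, 0.1),
                   names(pv)[which(pv < 0.1)])
})

test_that("printed p values parse, including censored entries", {
  expect_equal(parsePValue(c(".033", "<.001", "0.002", "", ".73")),
               c(0.033, 0.0005, 0.002, NA, 0.73))
})

test_that("chi-square matches hand computation", {
  prop <- matrix(c(20, 10, 40, 20), 2) # perfectly proportional
  r <- chiSquareTest(prop)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)

  diag2 <- matrix(c(10, 0, 0, 10), 2)
  r2 <- chiSquareTest(diag2)
  expect_equal(r2$statistic, 20)
  expect_equal(r2$df, 1)

  expect_error(chiSquareTest(matrix(c(5, 5, 0, 0), 2)), "expected")

  set.seed(88)
  rej <- mean(replicate(300, {
    tab <- matrix(rbinom(4, 30, 0.5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA)
    chiSquareTest(tab)$p < 0.05
  }), na.rm = TRUE)
  expect_lt(rej, 0.12) # calibrated near or below nominal
})

test_that("Spearman correlation handles ties and sign", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearmanCor(x, x)$rho, 1)
  expect_equal(spearmanCor(x, -x)$rho, -1)
  set.seed(89)
  a <- rnorm(30); b <- a + rnorm(30)
  r <- spearmanCor(a, b)
  expect_equal(r$rho, cor(rank(a), rank(b)), tolerance = 1e-10)
  expect_error(spearmanCor(x, rep(1, 6)), "constant")
})
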