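test_that("contingency tables are built under the named binning schemes", {
  se <- makeCallSet(list(
    control = c(rep(1, 10), rep(2, 60), rep(3, 20), rep(4, 6), rep(5, 3),
                rep(6, 1)),
    case = c(rep(0, 4), rep(1, 16), rep(2, 55), rep(3, 18), rep(4, 7))))

  tab <- buildContingency(se, "G1", scheme = "per_dcn")
  m <- tableCounts(tab)
  expect_identical(colnames(m), c("0", "1", "2", "3", "4-6"))
  expect_identical(unname(m["control", ]), c(0L, 10L, 60L, 20L, 10L))
  expect_identical(unname(m["case", ]), c(4L, 16L, 55L, 18L, 7L))

  tabN <- buildContingency(se, "G1", scheme = "null_vs_rest")
  expect_identical(unname(tableCounts(tabN)),
                   rbind(c(0L, 100L), c(4L, 96L)))
  tabL <- buildContingency(se, "G1", scheme = "low_vs_rest")
  expect_identical(unname(tableCounts(tabL)[, "1"]), c(10L, 16L))

  # an all-diploid cohort has a single informative category: refused
  mono <- makeCallSet(list(control = rep(2, 50), case = rep(2, 50)))
  expect_error(buildContingency(mono, "G1", scheme = "per_dcn"),
               "informative")
  expect_error(buildContingency(se, "nope"), "unknown gene")
})

test_that("Fisher exact reproduces published 2x2 p-values", {
  # agreement to one unit in the last printed digit
  expect_lt(abs(pValue(fisherExact(printedMatrix("IL12B"))) - 0.1183), 1e-4)
  expect_lt(abs(pValue(fisherExact(printedMatrix("TNIP1"))) - 0.2414), 1e-4)
  expect_lt(abs(pValue(fisherExact(printedMatrix("TNFAIP3"))) - 1.0), 1e-4)
  expect_lt(abs(pValue(fisherExact(printedMatrix("C4B_low"))) - 0.0331),
            1e-4)
  # proportional rows carry no association signal
  expect_equal(pValue(fisherExact(rbind(c(10, 20), c(20, 40)))), 1)
})

test_that("the three Fisher routes agree with each other and the oracle", {
  # 2x2: matches hypergeometric enumeration on random tables with N <= 60
  set.seed(5)
  for (i in 1:30) {
    m <- matrix(rpois(4, 6) + c(1, 0, 0, 1), 2)
    for (meth in c("network", "exact_enumeration"))
      expect_equal(pValue(fisherExact(m, method = meth)),
                   oracleFisher2x2(m), tolerance = 1e-10)
  }
  # 2x3 with small margins: full enumeration equals the independent
  # recursive oracle and the network route
  set.seed(6)
  for (i in 1:20) {
    m <- matrix(rpois(6, 3), 2)
    m[rowSums(m) == 0, 1] <- 1
    pN <- pValue(fisherExact(m, method = "network"))
    pE <- pValue(fisherExact(m, method = "exact_enumeration"))
    pO <- oracleFisher2xk(m)
    expect_equal(pE, pO, tolerance = 1e-10)
    expect_equal(pN, pO, tolerance = 1e-8)
  }
  # row and column permutation invariance
  m <- printedMatrix("C4A")
  p0 <- pValue(fisherExact(m, method = "exact_enumeration"))
  expect_equal(pValue(fisherExact(m[2:1, ], method = "exact_enumeration")),
               p0, tolerance = 1e-10)
  expect_equal(pValue(fisherExact(m[, 3:1], method = "exact_enumeration")),
               p0, tolerance = 1e-10)
})

test_that("Monte-Carlo Fisher agrees with the exact value within its SE", {
  m <- printedMatrix("C4B")
  exact <- pValue(fisherExact(m, method = "network"))
  mc <- fisherExact(m, method = "monte_carlo", B = 2e4, seed = 3)
  expect_lt(abs(pValue(mc) - exact), 3 * mc@mcSE)
  # deterministic given seed
  expect_identical(pValue(fisherExact(m, method = "monte_carlo", B = 5000,
                                      seed = 11)),
                   pValue(fisherExact(m, method = "monte_carlo", B = 5000,
                                      seed = 11)))
})

test_that("two-sided Fisher definitions are both available for 2x2", {
  m <- printedMatrix("C4B_low")
  pProb <- pValue(fisherExact(m))
  pDouble <- pValue(fisherExact(m, definition = "double_one_sided"))
  expect_true(pDouble >= pProb - 1e-12)
  expect_error(fisherExact(printedMatrix("C4A"),
                           definition = "double_one_sided"), "2 x 2")
})

test_that("chi-squared matches the closed-form 2x2 formula", {
  m <- printedMatrix("C4B_low")
  got <- chiSquared(m)
  a <- as.numeric(m[1, 1]); b <- as.numeric(m[1, 2])
  c <- as.numeric(m[2, 1]); d <- as.numeric(m[2, 2])
  N <- a + b + c + d
  stat <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(got@statistic, stat, tolerance = 1e-10)
  # proportional rows: statistic 0, p 1
  z <- chiSquared(rbind(c(10, 20), c(20, 40)))
  expect_equal(z@statistic, 0, tolerance = 1e-12)
  expect_equal(pValue(z), 1)
  # the 2x2 statistic is the k = 2 case of the general Pearson sum
  exp2 <- outer(rowSums(m), colSums(m)) / N
  pearson <- sum((m - exp2)^2 / exp2)
  expect_equal(got@statistic, pearson, tolerance = 1e-10)
  expect_error(chiSquared(rbind(c(0, 0), c(2, 3))), "margin")
  expect_match(paste(chiSquared(rbind(c(1, 30), c(2, 40)))@note,
                     collapse = " "), "expected count")
})

test_that("odds ratios follow the published zero-cell conventions", {
  # no zero cells: the point estimate with a Woolf interval
  o <- oddsRatio(printedMatrix("C4B_low"))
  expect_equal(orEstimate(o), 1.6051, tolerance = 1e-4)
  expect_false(isLowerBound(o))
  ci <- confint95(o)
  expect_length(ci, 2)
  expect_true(ci[1] < 1.6051 && 1.6051 < ci[2])
  # all policies agree without zero cells
  expect_equal(orEstimate(oddsRatio(printedMatrix("C4B_low"), "haldane")),
               1.6051, tolerance = 5e-3)

  # zero cell: substitute-one lower bound, CI suppressed
  o0 <- oddsRatio(printedMatrix("CCL3L3_null"))
  expect_equal(orEstimate(o0), 18.5355, tolerance = 1e-4)
  expect_true(isLowerBound(o0))
  expect_length(confint95(o0), 0)
  oh <- oddsRatio(printedMatrix("CCL3L3_null"), "haldane")
  expect_false(isLowerBound(oh))
  expect_gt(orEstimate(oh), 18.5355)
  expect_error(oddsRatio(printedMatrix("CCL3L3_null"), "error"),
               "zero cell")

  expect_equal(orEstimate(oddsRatio(rbind(c(5, 5), c(5, 5)))), 1.0)
})

test_that("rank-sum test matches enumeration and handles degenerate input", {
  got <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
  # full permutation enumeration: 2 of the C(6,3) = 20 assignments are as
  # extreme, two-sided p = 2/20 + 0 ... = 0.1
  expect_equal(pValue(got), 0.1, tolerance = 1e-12)
  expect_gte(pValue(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))), 0.99)
})

test_that("rank-sum type-I error is calibrated on equal cohorts", {
  rej <- withr::with_seed(17, {
    vapply(1:1000, function(i) {
      x <- sample(0:4, 60, replace = TRUE, prob = c(.1, .3, .4, .15, .05))
      y <- sample(0:4, 60, replace = TRUE, prob = c(.1, .3, .4, .15, .05))
      pValue(wilcoxonRankSum(x, y)) < 0.05
    }, logical(1))
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("Bonferroni uses the declared family size and caps at 1", {
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  expect_equal(bonferroni(0.0331, m = 11), 0.3641, tolerance = 1e-10)
  expect_equal(bonferroni(1e-5, m = 11), 1.1e-4, tolerance = 1e-12)
  expect_equal(bonferroni(c(0.001, 0.2), m = 5), c(0.005, 1.0))
  expect_error(bonferroni(c(0.1, 0.2, 0.3), m = 2), "family size")
  expect_error(bonferroni(0.1, m = 0), "positive integer")
})

test_that("clinical-variable screening tests null status per variable", {
  set.seed(23)
  status <- c(rep(TRUE, 20), rep(FALSE, 80))
  flags <- data.frame(
    mirror = status,                        # perfect association
    coin = as.logical(rbinom(100, 1, 0.5)), # independent
    always = rep(TRUE, 100))                # constant: skipped
  expect_warning(res <- clinicalAssociation(status, flags), "skipped")
  expect_identical(res$tested, c(TRUE, TRUE, FALSE))
  expect_lt(res$p[res$variable == "mirror"], 1e-10)
  expect_gt(res$p[res$variable == "coin"], 0.01)
  expect_true(is.na(res$p[res$variable == "always"]))
  # adjustment uses the declared family
  res11 <- suppressWarnings(clinicalAssociation(status, flags, m = 11))
  expect_equal(res11$pAdjusted[1], min(1, 11 * res11$p[1]))
})
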