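test_that("raw ratio combines target and control peak pairs correctly", {
  expect_equal(computeRawRatio(
    data.frame(g_T = 1, c_T = 1, g_I = 1, c_I = 1)), 1.0)
  expect_equal(computeRawRatio(
    data.frame(g_T = 0, c_T = 1, g_I = 1, c_I = 1)), 0.0)
  # two control pairs are averaged arithmetically: (0.9 + 1.1)/2 = 1
  expect_equal(computeRawRatio(
    data.frame(g_T = 2, c_T = 1, g_I = 0.9, c_I = 1, g_I2 = 1.1, c_I2 = 1)),
    2.0)
  expect_error(computeRawRatio(
    data.frame(g_T = 1, c_T = 0, g_I = 1, c_I = 1)), "competitor")
  expect_true(is.na(computeRawRatio(
    data.frame(g_T = NA, c_T = NA, g_I = NA, c_I = NA, failed = TRUE))))
})

test_that("standardization divides by half the median", {
  s <- standardizeCN(c(0.5, 1.0, 1.5))
  expect_equal(as.vector(s), c(1, 2, 3))
  expect_equal(attr(s, "divisor"), 0.5)
  expect_equal(as.vector(standardizeCN(rep(0.73, 5))), rep(2, 5))
  # median of the result is exactly the expected median CN
  set.seed(1)
  x <- rlnorm(101, log(2), 0.3)
  expect_equal(stats::median(standardizeCN(x)), 2, tolerance = 1e-12)
  expect_equal(stats::median(standardizeCN(x, expectedMedianCN = 1)), 1,
               tolerance = 1e-12)
  expect_error(standardizeCN(c(0, 0, 0)), "positive")
  # NA propagates without influencing the median
  s <- standardizeCN(c(0.5, NA, 1.0, 1.5))
  expect_true(is.na(s[2]))
  expect_equal(as.vector(s)[-2], c(1, 2, 3))
})

test_that("digitization uses half-open bins with x.5 edges", {
  expect_identical(digitizeCN(c(0.49, 0.5, 2.0)), c(0L, 1L, 2L))
  # closed-form oracle on a dense grid
  grid <- seq(0, 6.4, by = 0.1)
  expect_identical(digitizeCN(grid), as.integer(floor(grid + 0.5)))
  # monotone step function
  expect_true(all(diff(digitizeCN(seq(0, 6.4, 0.01))) >= 0))
  expect_warning(d <- digitizeCN(7.2), "clamped")
  expect_identical(d, 6L)
  expect_error(digitizeCN(-0.1), "non-negative")
  expect_identical(digitizeCN(c(1, NA)), c(1L, NA_integer_))
})

test_that("digitized calls are invariant to positive rescaling of raw data", {
  set.seed(42)
  raw <- rlnorm(201, log(2), 0.25)
  base <- digitizeCN(standardizeCN(raw))
  for (f in c(0.01, 0.37, 12)) {
    expect_identical(digitizeCN(standardizeCN(raw * f)), base)
  }
})

test_that("X-linked standardization treats the sexes as separate strata", {
  s <- standardizeXLinked(c(1, 1, 2), sexes = c("M", "M", "M"))
  expect_equal(as.vector(s), c(1, 1, 2))
  expect_identical(digitizeCN(s), c(1L, 1L, 2L))
  # all-female stratum identical to plain standardization
  raw <- c(0.5, 1.0, 1.5, 0.9)
  expect_equal(as.vector(standardizeXLinked(raw, rep("F", 4))),
               as.vector(standardizeCN(raw)))
  expect_error(standardizeXLinked(c(1, NA), c("M", NA)), "sex")
  # mixed cohort: male CN 1 and female CN 2 both standardize to their truth
  g <- GeneModel("xl", c(0.02, 0.98), inheritance = "x_linked")
  sexes <- rep(c("M", "F"), each = 150)
  geno <- sampleGenotypes(g, 300, sexes = sexes, seed = 21)
  co <- data.frame(id = sprintf("s%03d", 1:300), group = "control",
                   sex = sexes, gene = "xl", geno)
  pk <- simulateMrcpcrPeaks(co, noiseCV = 0.02, assayFailureRate = 0,
                            seed = 22)
  s <- standardizeXLinked(computeRawRatio(pk), sexes)
  acc <- mean(digitizeCN(s) == co$totalCN)
  expect_gte(acc, 0.99)
})

test_that("cohort calling returns a complete SummarizedExperiment", {
  g <- GeneModel("A", c(0.2, 0.5, 0.3))
  g2 <- GeneModel("X", c(0.05, 0.95), inheritance = "x_linked")
  spec <- CohortSpec(40, 40, list(g, g2), noiseCV = 0.02,
                     assayFailureRate = 0, seed = 5)
  co <- simulateCohort(spec)
  pk <- simulateMrcpcrPeaks(co, noiseCV = 0.02, assayFailureRate = 0,
                            seed = 6)
  si <- unique(co[, c("id", "group", "sex")])
  se <- callCopyNumbers(pk, sampleInfo = si,
                        inheritance = c(A = "autosomal", X = "x_linked"))
  expect_s4_class(se, "SummarizedExperiment")
  expect_setequal(SummarizedExperiment::assayNames(se),
                  c("rawRatio", "sCN", "dCN", "qcPass"))
  expect_identical(dim(se), c(2L, 80L))
  truth <- co[co$gene == "A", ]
  dcn <- SummarizedExperiment::assay(se, "dCN")["A", truth$id]
  expect_gte(mean(dcn == truth$totalCN), 0.99)
  # standardization constants are recorded
  expect_true(length(S4Vectors::metadata(se)$standardization) >= 2)
})

test_that("QC filter reproduces the cohort accounting and its ledger", {
  # 368 samples; 5 fail the DNA criterion; 36 of the remainder fail an
  # assay; 327 retained
  n <- 368
  ids <- sprintf("s%03d", 1:n)
  pk <- expand.grid(sample = ids, gene = sprintf("G%d", 1:7),
                    stringsAsFactors = FALSE)
  pk$g_T <- 1; pk$c_T <- 1; pk$g_I <- 1; pk$c_I <- 1; pk$failed <- FALSE
  dnaFail <- ids[1:5]
  assayFail <- ids[6:41]
  pk$failed[pk$sample %in% assayFail & pk$gene == "G3"] <- TRUE
  pk[pk$failed, c("g_T", "c_T", "g_I", "c_I")] <- NA
  si <- data.frame(id = ids, group = "case",
                   dnaPass = !(ids %in% dnaFail))
  se <- callCopyNumbers(pk, sampleInfo = si)
  res <- qcFilter(se)
  expect_identical(res$ledger$dna, 5L)
  expect_identical(res$ledger$assayFailure, 36L)
  expect_identical(res$ledger$retained, 327L)
  expect_identical(ncol(res$experiment), 327L)
  # order of exclusion: a sample failing both criteria counts under DNA
  si2 <- si; si2$dnaPass[si$id %in% assayFail[1]] <- FALSE
  res2 <- qcFilter(callCopyNumbers(pk, sampleInfo = si2))
  expect_identical(res2$ledger$dna, 6L)
  expect_identical(res2$ledger$assayFailure, 35L)

  # no failures: ledger zeros, cohort unchanged
  pkClean <- pk
  pkClean$failed <- FALSE
  pkClean[, c("g_T", "c_T", "g_I", "c_I")] <- 1
  siAll <- data.frame(id = ids, group = "case", dnaPass = TRUE)
  resC <- qcFilter(callCopyNumbers(pkClean, sampleInfo = siAll))
  expect_identical(resC$ledger$dna, 0L)
  expect_identical(resC$ledger$assayFailure, 0L)
  expect_identical(resC$ledger$retained, resC$ledger$nInput)
})

test_that("per-sample retention matches the independent-failure model", {
  # with per-assay failure f over 7 genes, retention ~ (1 - f)^7
  g <- lapply(sprintf("G%d", 1:7), function(n) GeneModel(n, c(0.2, 0.8)))
  spec <- CohortSpec(200, 200, g, assayFailureRate = 0.01, seed = 31)
  co <- simulateCohort(spec)
  pk <- simulateMrcpcrPeaks(co, noiseCV = 0.02, assayFailureRate = 0.01,
                            seed = 32)
  si <- unique(co[, c("id", "group", "sex")])
  res <- qcFilter(callCopyNumbers(pk, sampleInfo = si))
  pKeep <- (1 - 0.01)^7
  expect_lt(abs(res$ledger$retained / 400 - pKeep), 3 * binomSE(pKeep, 400))
})

test_that("end-to-end dCN recovery is near-perfect at low assay noise", {
  g <- GeneModel("g", c(0.3, 0.4, 0.3))  # totals 0..4, median 2
  spec <- CohortSpec(400, 400, list(g), noiseCV = 0.02,
                     assayFailureRate = 0, seed = 13)
  co <- simulateCohort(spec)
  pk <- simulateMrcpcrPeaks(co, noiseCV = 0.02, assayFailureRate = 0,
                            seed = 14)
  si <- unique(co[, c("id", "group", "sex")])
  se <- callCopyNumbers(pk, sampleInfo = si)
  dcn <- SummarizedExperiment::assay(se, "dCN")["g", co$id]
  for (cn in 0:4) {
    i <- co$totalCN == cn
    if (sum(i) >= 30)
      expect_gte(mean(dcn[i] == cn), 0.99)
  }
  expect_gte(mean(dcn == co$totalCN), 0.99)
})

test_that("calls and exclusion ledger serialize to CSV and JSON", {
  g <- GeneModel("g", c(0.2, 0.8))
  spec <- CohortSpec(10, 10, list(g), seed = 3)
  co <- simulateCohort(spec)
  pk <- simulateMrcpcrPeaks(co, noiseCV = 0.02, assayFailureRate = 0,
                            seed = 4)
  se <- callCopyNumbers(pk, sampleInfo = unique(co[, c("id", "group",
                                                       "sex")]))
  res <- qcFilter(se)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  writeCalls(se, csv, ledger = res$ledger, ledgerPath = js)
  back <- utils::read.csv(csv)
  expect_identical(nrow(back), 20L)
  led <- jsonlite::read_json(js)
  expect_identical(led$retained, 20L)
})
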