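test_that("genotype sampling follows the haplotype model", {
  # degenerate distribution: every haplotype is class 1, so every total is 2
  g <- GeneModel("fix2", c(0, 1))
  got <- sampleGenotypes(g, 10, seed = 1)
  expect_true(all(got$totalCN == 2L))
  expect_true(all(got$hap1 + got$hap2 == got$totalCN))

  # self-convolution: q = (.5, .5) gives totals (.25, .50, .25)
  g <- GeneModel("half", c(0.5, 0.5))
  got <- sampleGenotypes(g, 1e5, seed = 42)
  prop <- tabulate(got$totalCN + 1L, 3) / 1e5
  expected <- c(0.25, 0.5, 0.25)
  for (i in 1:3)
    expect_lt(abs(prop[i] - expected[i]), 3 * binomSE(expected[i], 1e5))

  # empirical haplotype-class frequencies converge to the model
  g3 <- GeneModel("tri", c(0.2, 0.5, 0.3))
  got <- sampleGenotypes(g3, 1e5, seed = 7)
  hapFreq <- tabulate(c(got$hap1, got$hap2) + 1L, 3) / (2e5)
  for (i in 1:3)
    expect_lt(abs(hapFreq[i] - alleleFreqs(g3)[i]),
              3 * binomSE(alleleFreqs(g3)[i], 2e5))
})

test_that("X-linked males carry a single haplotype", {
  g <- GeneModel("xl", c(0, 1), inheritance = "x_linked")
  sexes <- rep(c("M", "F"), c(6, 4))
  got <- sampleGenotypes(g, 10, sexes = sexes, seed = 3)
  expect_true(all(is.na(got$hap2[sexes == "M"])))
  expect_true(all(got$totalCN[sexes == "M"] == 1L))
  expect_true(all(got$totalCN[sexes == "F"] == 2L))
})

test_that("population total-CN distribution is the self-convolution", {
  q <- c(0.2, 0.5, 0.3)
  g <- GeneModel("tri", q)
  p <- totalCNDistribution(g)
  brute <- numeric(5)
  for (a in 0:2) for (b in 0:2)
    brute[a + b + 1] <- brute[a + b + 1] + q[a + 1] * q[b + 1]
  expect_equal(unname(p), brute, tolerance = 1e-14)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("case tilt multiplies the risk-category odds and renormalizes", {
  g <- GeneModel("g", c(sqrt(0.02), 1 - sqrt(0.02)))
  # population null probability is exactly 0.02 by construction
  pop <- totalCNDistribution(g)
  expect_equal(unname(pop["0"]), 0.02, tolerance = 1e-12)

  # odds transform oracle: odds' = 5 * p/(1-p); p' = odds'/(1+odds')
  tilted <- tiltedTotalDistribution(g, riskCategory = 0, oddsRatio = 5)
  odds <- 5 * (0.02 / 0.98)
  expect_equal(unname(tilted["0"]), odds / (1 + odds), tolerance = 1e-12)

  # identity at OR = 1; support preserved; sums to 1
  t1 <- tiltedTotalDistribution(g, 0, 1)
  expect_equal(t1, pop, tolerance = 1e-14)
  expect_equal(sum(tilted), 1, tolerance = 1e-12)
  expect_identical(names(tilted), names(pop))
  expect_true(all((tilted > 0) == (pop > 0)))

  # tilting onto an impossible category is refused
  g0 <- GeneModel("nonull", c(0, 1))
  expect_error(tiltedTotalDistribution(g0, 0, 5), "zero population mass")
})

test_that("tilted case sampling attains the target frequencies", {
  g <- GeneModel("g", c(0.15, 0.6, 0.25))
  tilted <- tiltedTotalDistribution(g, riskCategory = 0, oddsRatio = 8)
  got <- sampleCaseGenotypes(g, 0, 8, n = 4e4, seed = 11)
  prop0 <- mean(got$totalCN == 0)
  expect_lt(abs(prop0 - tilted["0"]), 3 * binomSE(tilted["0"], 4e4))
  expect_true(all(got$totalCN == got$hap1 + got$hap2))
})

test_that("stochastic generators are bit-reproducible given a seed", {
  g <- GeneModel("g", c(0.2, 0.5, 0.3))
  expect_identical(sampleGenotypes(g, 50, seed = 5),
                   sampleGenotypes(g, 50, seed = 5))
  expect_false(identical(sampleGenotypes(g, 50, seed = 5),
                         sampleGenotypes(g, 50, seed = 6)))
  spec <- CohortSpec(30, 30, list(g), seed = 9)
  expect_identical(simulateCohort(spec), simulateCohort(spec))
  co <- simulateCohort(spec)
  expect_identical(simulateMrcpcrPeaks(co, seed = 2),
                   simulateMrcpcrPeaks(co, seed = 2))
  d1 <- simulateDdpcrDroplets(2, seed = 4)
  expect_identical(d1, simulateDdpcrDroplets(2, seed = 4))
})

test_that("peak forward model has the stated signal and noise structure", {
  co <- data.frame(id = c("a", "b"), group = "control", sex = "F",
                   gene = "G", hap1 = c(1, 0), hap2 = c(1, 0),
                   totalCN = c(2L, 0L))
  pk <- simulateMrcpcrPeaks(co, noiseCV = 0, assayFailureRate = 0, seed = 1)
  r <- computeRawRatio(pk)
  expect_equal(r[1], 1.0, tolerance = 1e-12)  # diploid, noiseless
  expect_equal(r[2], 0.0, tolerance = 1e-12)  # null genotype: no target peak

  # ratio of four independent log-normal peaks: CV ~ 2 * noiseCV
  co <- data.frame(id = sprintf("s%d", 1:10000), group = "control",
                   sex = "F", gene = "G", hap1 = 1, hap2 = 1, totalCN = 2L)
  pk <- simulateMrcpcrPeaks(co, noiseCV = 0.05, assayFailureRate = 0,
                            seed = 8)
  r <- computeRawRatio(pk)
  cv <- stats::sd(r) / mean(r)
  sigma <- log1p(0.05)
  cvTheory <- sqrt(exp(4 * sigma^2) - 1)
  expect_lt(abs(cv - cvTheory) / cvTheory, 0.10)

  # failures are flagged and propagate missing peaks
  pk <- simulateMrcpcrPeaks(co, noiseCV = 0.05, assayFailureRate = 0.2,
                            seed = 3)
  expect_true(any(pk$failed))
  expect_true(all(is.na(pk$g_T[pk$failed])))
  expect_true(all(is.na(computeRawRatio(pk)[pk$failed])))
})

test_that("droplet generator reproduces Poisson occupancy and null patterns", {
  # no template, no homolog: nothing above the negative cluster
  d <- simulateDdpcrDroplets(0, homologCN = 0, c0 = 0.5, nDroplets = 5000,
                             seed = 1)
  ampT <- d$amplitude[d$channel == "target"]
  expect_equal(sum(ampT > 2000), 0L)

  # occupancy: CN 2 at c0 = 0.5 means lambda 1, positive fraction 1 - e^-1
  d <- simulateDdpcrDroplets(2, homologCN = 0, c0 = 0.5, nDroplets = 15000,
                             seed = 2)
  ampT <- d$amplitude[d$channel == "target"]
  frac <- mean(ampT > 5000)
  pExp <- 1 - exp(-1)
  expect_lt(abs(frac - pExp), 3 * binomSE(pExp, 15000))

  # null with cross-reacting homolog: a mid cluster exists, no true positives
  d <- simulateDdpcrDroplets(0, homologCN = 2, c0 = 0.5, nDroplets = 15000,
                             seed = 3)
  ampT <- d$amplitude[d$channel == "target"]
  expect_gt(sum(ampT > 2000 & ampT < 5000), 0)
  expect_equal(sum(ampT > 6500), 0L)

  # unordered cluster means are refused
  expect_error(
    simulateDdpcrDroplets(1, clusterMeans = c(negative = 1000, cross = 9000,
                                              positive = 8000)),
    "strictly ordered")
})

test_that("cohort truth and measurement tables round-trip through text files", {
  g <- GeneModel("g", c(0.2, 0.5, 0.3))
  spec <- CohortSpec(10, 10, list(g), seed = 2)
  co <- simulateCohort(spec)
  tmp <- tempfile(fileext = ".csv")
  writeCohortTruth(co, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(back$totalCN, co$totalCN)

  pk <- simulateMrcpcrPeaks(co, seed = 1)
  tsv <- tempfile(fileext = ".tsv")
  writePeakTable(pk, tsv)
  back <- readPeakTable(tsv)
  expect_equal(back$g_T, pk$g_T, tolerance = 1e-9)

  d <- simulateDdpcrDroplets(2, nDroplets = 200, seed = 1)
  csv <- tempfile(fileext = ".csv")
  writeDropletTable(d, csv)
  expect_equal(readDropletTable(csv)$amplitude, d$amplitude,
               tolerance = 1e-9)
})
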