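#' @include AllClasses.R utils.R
NULL

#' Construct a GeneModel
#'
#' @param name gene identifier.
#' @param alleleFreqs numeric vector of per-haplotype copy-class frequencies
#'   over classes \code{0..A_max} (in order); will be named \code{"0"},
#'   \code{"1"}, ... automatically.
#' @param inheritance \code{"autosomal"} (default) or \code{"x_linked"}.
#' @param label optional free-text description.
#' @return a [GeneModel-class].
#' @examples
#' GeneModel("CCL3L3", c(0.16, 0.60, 0.24))
#' @export
GeneModel <- function(name, alleleFreqs,
                      inheritance = c("autosomal", "x_linked"),
                      label = "") {
  inheritance <- match.arg(inheritance)
  q <- as.numeric(alleleFreqs)
  names(q) <- as.character(seq_along(q) - 1L)
  new("GeneModel", name = name, inheritance = inheritance,
      alleleFreqs = q, label = label)
}

#' Construct a CohortSpec
#'
#' Defaults emulate a female-predominant autoimmune case-control cohort:
#' 90% female, 1% independent per-assay failure (so roughly 7% of samples
#' fail at least one of seven genes), 5% multiplicative peak-height noise.
#'
#' @param nCases,nControls group sizes.
#' @param genes list of [GeneModel-class] objects.
#' @param caseOR named list (by gene) of
#'   \code{list(riskCategory =, oddsRatio =)} describing case enrichment.
#' @param femaleFraction probability a simulated individual is female.
#' @param assayFailureRate per sample-by-gene failure probability.
#' @param noiseCV coefficient of variation of each simulated peak height.
#' @param seed root seed.
#' @return a [CohortSpec-class].
#' @export
CohortSpec <- function(nCases, nControls, genes, caseOR = list(),
                       femaleFraction = 0.9, assayFailureRate = 0.01,
                       noiseCV = 0.05, seed = 1L) {
  names(genes) <- vapply(genes, geneName, character(1))
  new("CohortSpec", nCases = as.integer(nCases),
      nControls = as.integer(nControls), genes = genes, caseOR = caseOR,
      femaleFraction = femaleFraction, assayFailureRate = assayFailureRate,
      noiseCV = noiseCV, seed = as.integer(seed))
}

#' Population distribution of diploid total copy number
#'
#' Self-convolution of the haplotype copy-class frequencies: under
#' Hardy-Weinberg random mating, \eqn{P(total = k) = \sum_a q_a q_{k-a}}.
#' For X-linked males the total equals the single haplotype class.
#'
#' @param model a [GeneModel-class].
#' @param sex \code{"F"} (two haplotypes; also the autosomal case) or
#'   \code{"M"} for X-linked males (one haplotype).
#' @return named numeric vector of probabilities over totals
#'   \code{0..2*A_max} (or \code{0..A_max} for X-linked males).
#' @export
totalCNDistribution <- function(model, sex = "F") {
  q <- alleleFreqs(model)
  if (inheritanceMode(model) == "x_linked" && sex == "M") return(q)
  k <- 0:(2L * (length(q) - 1L))
  p <- vapply(k, function(kk) {
    a <- max(0L, kk - length(q) + 1L):min(length(q) - 1L, kk)
    sum(q[a + 1L] * q[kk - a + 1L])
  }, numeric(1))
  names(p) <- as.character(k)
  p
}

#' Sample Hardy-Weinberg copy-number genotypes
#'
#' Haplotype classes are drawn i.i.d. from the model's class frequencies;
#' autosomal individuals and X-linked females receive two, X-linked males
#' one (their second haplotype is \code{NA}).
#'
#' @param model a [GeneModel-class].
#' @param n number of individuals.
#' @param sexes character vector (\code{"M"}/\code{"F"}) of length \code{n};
#'   only consulted for X-linked genes. Default all-female.
#' @param seed integer seed; the call is bit-reproducible given
#'   \code{(seed, model, n, sexes)}.
#' @return data.frame with columns \code{hap1}, \code{hap2}, \code{totalCN}.
#' @examples
#' g <- GeneModel("toy", c(0.5, 0.5))
#' sampleGenotypes(g, 5, seed = 1)
#' @export
sampleGenotypes <- function(model, n, sexes = rep("F", n), seed = NULL) {
  stopifnot(isCount(n), n >= 1, length(sexes) == n)
  validObject(model)
  q <- alleleFreqs(model)
  classes <- seq_along(q) - 1L
  withSeed(seed, {
    hap1 <- sample(classes, n, replace = TRUE, prob = q)
    hap2 <- sample(classes, n, replace = TRUE, prob = q)
  })
  if (inheritanceMode(model) == "x_linked")
    hap2[sexes == "M"] <- NA_integer_
  total <- hap1 + ifelse(is.na(hap2), 0L, hap2)
  data.frame(hap1 = hap1, hap2 = hap2, totalCN = total)
}

#' Tilt a total-CN distribution to a target case odds ratio
#'
#' Retrospective case sampling: the population total-CN distribution is
#' re-weighted so that the odds of the risk category are multiplied by
#' \code{oddsRatio} and everything is renormalized, i.e. weight
#' \code{oddsRatio} on the risk category and 1 elsewhere. A case-control
#' comparison of the tilted vs the population distribution then has the
#' requested odds ratio exactly, in expectation.
#'
#' @param model a [GeneModel-class].
#' @param riskCategory total-CN value whose odds are inflated.
#' @param oddsRatio positive multiplier of the risk-category odds.
#' @param sex passed to [totalCNDistribution()].
#' @return named probability vector over totals.
#' @export
tiltedTotalDistribution <- function(model, riskCategory, oddsRatio,
                                    sex = "F") {
  stopifnot(oddsRatio > 0)
  p <- totalCNDistribution(model, sex = sex)
  key <- as.character(riskCategory)
  if (!key %in% names(p) || p[key] == 0)
    stop("risk category ", riskCategory,
         " has zero population mass; cannot tilt onto it", call. = FALSE)
  w <- rep(1, length(p))
  w[names(p) == key] <- oddsRatio
  out <- p * w
  out / sum(out)
}

#' Sample case genotypes enriched at a risk category
#'
#' Draws unordered haplotype pairs whose probabilities are the population
#' pair probabilities re-weighted by the total-CN tilt of
#' [tiltedTotalDistribution()], so the within-total pair composition is
#' untouched.
#'
#' @inheritParams sampleGenotypes
#' @param riskCategory,oddsRatio see [tiltedTotalDistribution()].
#' @return data.frame with columns \code{hap1}, \code{hap2}, \code{totalCN}.
#' @export
sampleCaseGenotypes <- function(model, riskCategory, oddsRatio, n,
                                sexes = rep("F", n), seed = NULL) {
  stopifnot(isCount(n), n >= 1, length(sexes) == n, oddsRatio > 0)
  validObject(model)
  q <- alleleFreqs(model)
  classes <- seq_along(q) - 1L
  xl <- inheritanceMode(model) == "x_linked"

  # ordered-pair probability grid, tilted on the total
  pairProb <- outer(q, q)
  totals <- outer(classes, classes, `+`)
  tilt <- tiltedTotalDistribution(model, riskCategory, oddsRatio)
  pop <- totalCNDistribution(model)
  ratio <- tilt / ifelse(pop > 0, pop, 1)
  wPair <- pairProb * matrix(ratio[as.character(totals)], nrow(totals))
  wPair <- wPair / sum(wPair)

  # single-haplotype tilt for X-linked males
  wMale <- NULL
  if (xl && any(sexes == "M")) {
    tiltM <- tiltedTotalDistribution(model, riskCategory, oddsRatio,
                                     sex = "M")
    wMale <- tiltM
  }

  withSeed(seed, {
    idx <- sample.int(length(wPair), n, replace = TRUE, prob = as.vector(wPair))
    hap1 <- classes[(idx - 1L) %% length(classes) + 1L]
    hap2 <- classes[(idx - 1L) %/% length(classes) + 1L]
    if (!is.null(wMale)) {
      m <- which(sexes == "M")
      hap1[m] <- sample(classes, length(m), replace = TRUE, prob = wMale)
      hap2[m] <- NA_integer_
    } else if (xl) {
      hap2[sexes == "M"] <- NA_integer_
    }
  })
  total <- hap1 + ifelse(is.na(hap2), 0L, hap2)
  data.frame(hap1 = hap1, hap2 = hap2, totalCN = total)
}

#' Simulate a full case-control cohort
#'
#' Draws sexes, then per-gene genotypes (controls from the population
#' distribution, cases from the tilted distribution for genes listed in the
#' spec's \code{caseOR}), in long format. All randomness derives from the
#' spec's root seed through named substreams, so the cohort is
#' bit-reproducible.
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame with columns \code{id}, \code{group}, \code{sex},
#'   \code{gene}, \code{hap1}, \code{hap2}, \code{totalCN}.
#' @export
simulateCohort <- function(spec) {
  validObject(spec)
  nC <- spec@nCases
  nK <- spec@nControls
  ids <- c(sprintf("ctrl%04d", seq_len(nK)), sprintf("case%04d", seq_len(nC)))
  group <- rep(c("control", "case"), c(nK, nC))
  sexes <- withSeed(deriveSeed(spec@seed, "sex"), {
    ifelse(stats::runif(nK + nC) < spec@femaleFraction, "F", "M")
  })
  out <- lapply(names(spec@genes), function(gn) {
    g <- spec@genes[[gn]]
    ctl <- sampleGenotypes(g, nK, sexes = sexes[seq_len(nK)],
                           seed = deriveSeed(spec@seed, paste0("ctl:", gn)))
    cse <- if (gn %in% names(spec@caseOR)) {
      tl <- spec@caseOR[[gn]]
      sampleCaseGenotypes(g, tl$riskCategory, tl$oddsRatio, nC,
                          sexes = sexes[nK + seq_len(nC)],
                          seed = deriveSeed(spec@seed, paste0("case:", gn)))
    } else {
      sampleGenotypes(g, nC, sexes = sexes[nK + seq_len(nC)],
                      seed = deriveSeed(spec@seed, paste0("case:", gn)))
    }
    geno <- rbind(ctl, cse)
    data.frame(id = ids, group = group, sex = sexes, gene = gn, geno)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate competitive-PCR peak heights for a cohort
#'
#' Forward model of the measurement: per sample and gene, the target genomic
#' peak is proportional to the true total copy number and the control-gene
#' genomic peak to 2 (a diploid reference such as IGF1), each peak carrying
#' independent multiplicative log-normal noise
#' \eqn{e^{\epsilon}, \epsilon \sim N(0, \sigma^2)} with
#' \eqn{\sigma = \log(1 + \mathrm{noiseCV})}. Competitor peaks are
#' proportional to the spiked amounts \code{kT}, \code{kI} (which cancel in
#' the later median standardization). A fraction \code{assayFailureRate} of
#' records is flagged failed with missing peaks. For X-linked genes the
#' reference ploidy of the control-gene peak stays 2 for both sexes.
#'
#' @param cohort long-format truth as from [simulateCohort()].
#' @param noiseCV per-peak coefficient of variation; the raw ratio of four
#'   independent peaks then has CV close to \code{2 * noiseCV}.
#' @param assayFailureRate per-record failure probability.
#' @param kT,kI competitor spike amounts (arbitrary units).
#' @param seed integer seed.
#' @return data.frame with columns \code{sample}, \code{gene}, \code{g_T},
#'   \code{c_T}, \code{g_I}, \code{c_I}, \code{failed}.
#' @export
simulateMrcpcrPeaks <- function(cohort, noiseCV = 0.05,
                                assayFailureRate = 0.01, kT = 1, kI = 1,
                                seed = NULL) {
  stopifnot(noiseCV >= 0, assayFailureRate >= 0, assayFailureRate < 1)
  n <- nrow(cohort)
  sigma <- log1p(noiseCV)
  withSeed(seed, {
    eps <- matrix(stats::rnorm(4L * n, 0, sigma), ncol = 4L)
    failed <- stats::runif(n) < assayFailureRate
  })
  gT <- cohort$totalCN * exp(eps[, 1L])
  cT <- kT * exp(eps[, 2L])
  gI <- 2 * exp(eps[, 3L])
  cI <- kI * exp(eps[, 4L])
  gT[failed] <- NA_real_; cT[failed] <- NA_real_
  gI[failed] <- NA_real_; cI[failed] <- NA_real_
  data.frame(sample = cohort$id, gene = cohort$gene,
             g_T = gT, c_T = cT, g_I = gI, c_I = cI, failed = failed)
}

#' Simulate droplet digital PCR amplitudes for one sample
#'
#' Droplets are Poisson-occupied: the target channel receives true-template
#' copies at rate \code{totalCN * c0} per droplet and cross-reactive homolog
#' copies at rate \code{homologCN * c0}; the reference channel (a diploid
#' housekeeping gene) at rate \code{2 * c0}. A droplet's amplitude is drawn
#' from the Gaussian cluster of its highest-amplitude occupant: negative <
#' cross-reactive-positive < true-positive, mirroring the weak cross-talk
#' clusters seen when two near-identical paralogs share PCR primers.
#'
#' @param totalCN true copy number of the target gene.
#' @param homologCN copy number of the cross-reacting homolog.
#' @param c0 base concentration in copies per droplet per template copy.
#' @param nDroplets number of droplets (>= 100).
#' @param clusterMeans named numeric: \code{negative}, \code{cross},
#'   \code{positive} mean amplitudes, strictly increasing.
#' @param clusterSDs matching cluster standard deviations.
#' @param refClusterMeans,refClusterSDs two-cluster (negative/positive)
#'   parameters for the reference channel.
#' @param seed integer seed.
#' @return data.frame with columns \code{droplet_id}, \code{channel}
#'   (\code{"target"}/\code{"reference"}), \code{amplitude}.
#' @export
simulateDdpcrDroplets <- function(totalCN, homologCN = 0, c0 = 0.5,
                                  nDroplets = 15000,
                                  clusterMeans = c(negative = 1000,
                                                   cross = 3500,
                                                   positive = 8000),
                                  clusterSDs = c(negative = 50, cross = 300,
                                                 positive = 300),
                                  refClusterMeans = c(negative = 1000,
                                                      positive = 6000),
                                  refClusterSDs = c(negative = 50,
                                                    positive = 300),
                                  seed = NULL) {
  stopifnot(nDroplets >= 100, c0 > 0, totalCN >= 0, homologCN >= 0)
  if (!(clusterMeans["negative"] < clusterMeans["cross"] &&
        clusterMeans["cross"] < clusterMeans["positive"]))
    stop("cluster means must be strictly ordered negative < cross < positive",
         call. = FALSE)
  withSeed(seed, {
    kTrue <- stats::rpois(nDroplets, totalCN * c0)
    kCross <- stats::rpois(nDroplets, homologCN * c0)
    kRef <- stats::rpois(nDroplets, 2 * c0)
    cls <- ifelse(kTrue > 0, "positive", ifelse(kCross > 0, "cross",
                                                "negative"))
    ampT <- stats::rnorm(nDroplets, clusterMeans[cls], clusterSDs[cls])
    clsR <- ifelse(kRef > 0, "positive", "negative")
    ampR <- stats::rnorm(nDroplets, refClusterMeans[clsR], refClusterSDs[clsR])
  })
  data.frame(
    droplet_id = rep(seq_len(nDroplets), 2L),
    channel = rep(c("target", "reference"), each = nDroplets),
    amplitude = c(ampT, ampR)
  )
}

#' Read or write the cohort text formats
#'
#' The simulator's external formats: cohort truth and droplet tables as CSV,
#' peak tables as TSV with header (mirroring a fragment-analysis peak-height
#' export).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return the file path (writers, invisibly) or a data.frame (readers).
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
writeCohortTruth <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cohort-io
#' @export
writePeakTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cohort-io
#' @export
readPeakTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname cohort-io
#' @export
writeDropletTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cohort-io
#' @export
readDropletTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
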