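#' @import methods
NULL

#' Per-gene population model for copy-number haplotypes
#'
#' A \code{GeneModel} holds what the population-genetic analyses assume about
#' one gene: its inheritance mode and the frequencies of the per-haplotype
#' copy-number classes \eqn{0, 1, \dots, A_{max}}. Under random mating the
#' diploid total copy-number distribution is the self-convolution of these
#' class frequencies (one class per haplotype; X-linked males carry a single
#' haplotype).
#'
#' @slot name single gene identifier.
#' @slot inheritance \code{"autosomal"} or \code{"x_linked"}.
#' @slot alleleFreqs numeric vector of per-haplotype copy-class frequencies,
#'   named \code{"0"}, \code{"1"}, ...; non-negative, summing to 1.
#' @slot label free-text description.
#'
#' @seealso [GeneModel()] for the constructor, [sampleGenotypes()],
#'   [totalCNDistribution()].
#' @aliases GeneModel-class
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    name = "character",
    inheritance = "character",
    alleleFreqs = "numeric",
    label = "character"
  ),
  prototype(inheritance = "autosomal", label = "")
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@inheritance) != 1L ||
      !object@inheritance %in% c("autosomal", "x_linked"))
    msg <- c(msg, "'inheritance' must be \"autosomal\" or \"x_linked\"")
  q <- object@alleleFreqs
  if (length(q) < 2L)
    msg <- c(msg, "'alleleFreqs' needs at least classes 0 and 1 (A_max >= 1)")
  if (any(is.na(q)) || any(q < 0))
    msg <- c(msg, "'alleleFreqs' must be non-negative and non-missing")
  else if (abs(sum(q) - 1) > 1e-12)
    msg <- c(msg, "'alleleFreqs' must sum to 1 (tolerance 1e-12)")
  if (!identical(names(q), as.character(seq_along(q) - 1L)))
    msg <- c(msg, "'alleleFreqs' must be named \"0\", \"1\", ... in order")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic case-control cohort
#'
#' Bundles everything the cohort simulator needs: group sizes, the per-gene
#' population models, which genes are enriched in cases (and at what odds
#' ratio), the demographic and assay-noise parameters, and the root seed.
#'
#' @slot nCases,nControls group sizes.
#' @slot genes named list of [GeneModel-class] objects.
#' @slot caseOR named list (by gene) of \code{list(riskCategory =, oddsRatio =)};
#'   genes absent from the list are sampled identically in cases and controls.
#' @slot femaleFraction probability that a simulated individual is female.
#' @slot assayFailureRate per sample-by-gene probability of assay failure.
#' @slot noiseCV coefficient of variation of each simulated peak height.
#' @slot seed root seed for all cohort randomness.
#'
#' @seealso [CohortSpec()], [simulateCohort()].
#' @aliases CohortSpec-class
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nCases = "integer",
    nControls = "integer",
    genes = "list",
    caseOR = "list",
    femaleFraction = "numeric",
    assayFailureRate = "numeric",
    noiseCV = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nCases < 1L || object@nControls < 1L)
    msg <- c(msg, "group sizes must be >= 1")
  if (!length(object@genes) ||
      !all(vapply(object@genes, is, logical(1), "GeneModel")))
    msg <- c(msg, "'genes' must be a non-empty list of GeneModel objects")
  gn <- unname(vapply(object@genes, function(g) g@name, character(1)))
  if (!identical(names(object@genes), gn))
    msg <- c(msg, "'genes' must be named by their GeneModel names")
  if (length(object@caseOR)) {
    if (!all(names(object@caseOR) %in% gn))
      msg <- c(msg, "'caseOR' refers to genes absent from 'genes'")
    ok <- vapply(object@caseOR, function(x) {
      is.list(x) && all(c("riskCategory", "oddsRatio") %in% names(x)) &&
        x$oddsRatio > 0
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "each 'caseOR' entry needs riskCategory and oddsRatio > 0")
  }
  for (p in c("femaleFraction", "assayFailureRate")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must be a probability", p))
  }
  if (length(object@noiseCV) != 1L || object@noiseCV < 0)
    msg <- c(msg, "'noiseCV' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Two-group contingency table of copy-number categories
#'
#' A 2 x k count matrix with the control group in row 1 and the case group in
#' row 2; columns are digitized copy-number categories or pooled bins (for
#' example \code{"4-6"}). The substrate of all categorical association tests.
#'
#' @slot counts integer matrix, 2 rows, k >= 2 columns, with dimnames.
#'
#' @seealso [ContingencyTable()], [buildContingency()], [fisherExact()],
#'   [chiSquared()], [oddsRatio()].
#' @aliases ContingencyTable-class
#' @exportClass ContingencyTable
setClass("ContingencyTable", representation(counts = "matrix"))

setValidity("ContingencyTable", function(object) {
  m <- object@counts
  msg <- character()
  if (nrow(m) != 2L) msg <- c(msg, "must have exactly 2 rows (control, case)")
  if (ncol(m) < 2L) msg <- c(msg, "must have k >= 2 columns")
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (nrow(m) == 2L && any(rowSums(m) <= 0))
    msg <- c(msg, "both row sums must be positive")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must carry row and column labels")
  if (length(msg)) msg else TRUE
})

#' Result of a categorical or rank association test
#'
#' Uniform container returned by [fisherExact()], [chiSquared()],
#' [oddsRatio()] and [wilcoxonRankSum()]. Slots not applicable to a given
#' test are length zero.
#'
#' @slot test one of \code{"fisher"}, \code{"chi2"}, \code{"wilcoxon"},
#'   \code{"odds_ratio"}.
#' @slot statistic test statistic, when the test has one.
#' @slot p two-sided p-value (empty for a pure odds-ratio computation).
#' @slot pAdjusted Bonferroni-adjusted p, when requested.
#' @slot mTests declared family size used for adjustment.
#' @slot oddsRatio odds-ratio estimate (2 x 2 tables).
#' @slot orIsLowerBound \code{TRUE} when a zero cell was substituted, so the
#'   estimate is a lower bound on an infinite odds ratio.
#' @slot ci95 length-2 Woolf 95% confidence interval for the odds ratio;
#'   suppressed (length 0) after zero-cell substitution.
#' @slot mcSE Monte-Carlo standard error, for simulated Fisher p-values.
#' @slot note free-text flags (for example expected-count warnings).
#'
#' @aliases AssociationResult-class
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(
    test = "character",
    statistic = "numeric",
    p = "numeric",
    pAdjusted = "numeric",
    mTests = "integer",
    oddsRatio = "numeric",
    orIsLowerBound = "logical",
    ci95 = "numeric",
    mcSE = "numeric",
    note = "character"
  ),
  prototype(statistic = numeric(0), p = numeric(0), pAdjusted = numeric(0),
            mTests = integer(0), oddsRatio = numeric(0),
            orIsLowerBound = FALSE, ci95 = numeric(0), mcSE = numeric(0),
            note = character(0))
)

setValidity("AssociationResult", function(object) {
  msg <- character()
  if (length(object@p) && (object@p < 0 || object@p > 1 + 1e-12))
    msg <- c(msg, "'p' must lie in [0, 1]")
  if (length(object@pAdjusted) &&
      (object@pAdjusted < 0 || object@pAdjusted > 1 + 1e-12))
    msg <- c(msg, "'pAdjusted' must lie in [0, 1]")
  if (length(object@ci95) && length(object@ci95) != 2L)
    msg <- c(msg, "'ci95' must have length 2 when present")
  if (length(msg)) msg else TRUE
})

#' EM-fitted haplotype copy-class frequency model
#'
#' Maximum-likelihood frequencies of the per-haplotype copy-number classes
#' \eqn{0..A_{max}} fitted from unphased diploid totals by EM, with the
#' log-likelihood trace kept for monotonicity checks.
#'
#' @slot q fitted class frequencies, named \code{"0"}..\code{A_max}.
#' @slot loglik multinomial log-likelihood of the self-convolved fit.
#' @slot trace per-iteration log-likelihood values.
#' @slot nIter iterations used.
#' @slot converged whether the parameter change fell below tolerance.
#' @slot AMax largest haplotype copy class.
#'
#' @seealso [emFit()], [expectedDiploid()], [hweChisq()].
#' @aliases AlleleFreqModel-class
#' @exportClass AlleleFreqModel
setClass("AlleleFreqModel",
  representation(
    q = "numeric",
    loglik = "numeric",
    trace = "numeric",
    nIter = "integer",
    converged = "logical",
    AMax = "integer"
  )
)

setValidity("AlleleFreqModel", function(object) {
  msg <- character()
  if (abs(sum(object@q) - 1) > 1e-10)
    msg <- c(msg, "'q' must sum to 1 (tolerance 1e-10)")
  if (any(object@q < -1e-12)) msg <- c(msg, "'q' must be non-negative")
  if (length(object@q) != object@AMax + 1L)
    msg <- c(msg, "'q' must have A_max + 1 entries")
  if (length(object@trace) > 1L &&
      any(diff(object@trace) < -1e-8))
    msg <- c(msg, "log-likelihood trace must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Hardy-Weinberg test result for copy-number data
#'
#' Pearson goodness-of-fit of an observed diploid total-CN histogram against
#' the self-convolution of EM-fitted haplotype class frequencies, with
#' optional parametric-bootstrap p-value.
#'
#' @slot chi2 Pearson statistic after pooling.
#' @slot df degrees of freedom (categories after pooling - 1 - A_max,
#'   clamped at 1).
#' @slot pAsymptotic upper-tail chi-squared p-value.
#' @slot pBootstrap parametric-bootstrap p-value, when computed.
#' @slot poolingApplied labels of the pooled categories actually used.
#' @slot expected expected counts on the pooled grid.
#' @slot observed observed counts on the pooled grid.
#' @slot model the fitted [AlleleFreqModel-class].
#' @slot saturated \code{TRUE} when pooling left too few categories for a
#'   proper test (p is reported as 1).
#'
#' @seealso [hweChisq()], [hweBootstrap()], [hweTest()].
#' @aliases HWEResult-class
#' @exportClass HWEResult
setClass("HWEResult",
  representation(
    chi2 = "numeric",
    df = "integer",
    pAsymptotic = "numeric",
    pBootstrap = "numeric",
    poolingApplied = "character",
    expected = "numeric",
    observed = "numeric",
    model = "AlleleFreqModel",
    saturated = "logical"
  ),
  prototype(pBootstrap = numeric(0), saturated = FALSE)
)

setValidity("HWEResult", function(object) {
  msg <- character()
  if (length(object@expected) &&
      abs(sum(object@expected) - sum(object@observed)) > 1e-8)
    msg <- c(msg, "expected counts must conserve the sample size")
  if (object@df < 0L) msg <- c(msg, "df must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Droplet digital PCR quantification result
#'
#' Positive-droplet counts gated per channel, Poisson concentration
#' estimates (copies per droplet) with 95% confidence intervals, and the
#' copy-number estimate relative to a diploid reference gene.
#'
#' @slot lambdaTarget,lambdaRef estimated copies per droplet.
#' @slot lambdaTargetCI,lambdaRefCI 95% confidence intervals (Wilson interval
#'   on the positive fraction propagated through \eqn{-\log(1-p)}).
#' @slot cnEstimate copy number, \code{referencePloidy * lambdaTarget/lambdaRef}.
#' @slot cnCI 95% confidence interval for the copy number.
#' @slot nPositiveTarget,nPositiveRef,nDroplets droplet counts.
#' @slot thresholds amplitude thresholds used for gating, named by channel.
#'
#' @seealso [quantifyDroplets()], [poissonConcentration()],
#'   [ddpcrCopyNumber()].
#' @aliases DdpcrQuant-class
#' @exportClass DdpcrQuant
setClass("DdpcrQuant",
  representation(
    lambdaTarget = "numeric",
    lambdaRef = "numeric",
    lambdaTargetCI = "numeric",
    lambdaRefCI = "numeric",
    cnEstimate = "numeric",
    cnCI = "numeric",
    nPositiveTarget = "integer",
    nPositiveRef = "integer",
    nDroplets = "integer",
    thresholds = "numeric"
  )
)

setValidity("DdpcrQuant", function(object) {
  msg <- character()
  if (object@lambdaTarget < 0 || object@lambdaRef < 0)
    msg <- c(msg, "concentrations must be >= 0")
  if (object@nPositiveTarget > object@nDroplets ||
      object@nPositiveRef > object@nDroplets)
    msg <- c(msg, "positive counts cannot exceed the droplet total")
  if (length(msg)) msg else TRUE
})

#' Pipeline report
#'
#' Everything one [runPipeline()] invocation produced: per-gene count tables,
#' association statistics, Hardy-Weinberg results per group, the QC exclusion
#' ledger, optional ddPCR concordance, and a provenance block (seed, config
#' hash, package version) so reruns are verifiable.
#'
#' @slot countTables named list of [ContingencyTable-class] objects.
#' @slot association data.frame of per-gene association statistics.
#' @slot hwe named list of [HWEResult-class] objects (gene x group).
#' @slot exclusionLedger named list of exclusion counts per reason.
#' @slot concordance named list with slope/intercept/r.squared/p/n, or empty.
#' @slot provenance named list (seed, configHash, package, version, date).
#'
#' @aliases CNVReport-class
#' @exportClass CNVReport
setClass("CNVReport",
  representation(
    countTables = "list",
    association = "data.frame",
    hwe = "list",
    exclusionLedger = "list",
    concordance = "list",
    provenance = "list"
  )
)

setValidity("CNVReport", function(object) {
  if (!length(object@provenance))
    "a provenance block is required" else TRUE
})
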