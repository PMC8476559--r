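#' @include AllClasses.R utils.R
NULL

#' Gate droplet amplitudes into a positive count
#'
#' With \code{policy = "valley"} (default), a smoothed histogram of the
#' amplitudes is scanned for well-separated modes (local maxima carrying at
#' least 0.5% of droplets; adjacent maxima merge unless the valley between
#' them dips below one fifth of the lower peak) and the threshold is placed
#' at the minimum-density valley between
#' the two highest-amplitude modes — the upper valley. When a
#' cross-reactive mid-amplitude cluster is present (a homologous sequence
#' weakly hit by the probe) that upper valley separates it from the true
#' positives, which are the droplets counted. \code{minThreshold} encodes
#' assay knowledge of the lowest amplitude a true-positive droplet can
#' have: a valley below this floor means the positive cluster is absent
#' (for example a null genotype whose only upper cluster is
#' cross-reactive), and the floor is used instead. When the distribution is
#' effectively unimodal the function falls back to the fixed threshold with
#' a warning. With \code{policy = "fixed"} the supplied threshold is used
#' directly.
#'
#' @param amplitudes numeric vector of droplet amplitudes (>= 100 droplets).
#' @param policy \code{"valley"} or \code{"fixed"}.
#' @param threshold fixed threshold (required for \code{"fixed"}; fallback
#'   for a unimodal \code{"valley"}).
#' @param bins histogram bin count for the valley search.
#' @param minThreshold optional amplitude floor for the valley threshold
#'   (see Details).
#' @return integer positive count, with the threshold used attached as
#'   attribute \code{"threshold"}.
#' @export
gateDroplets <- function(amplitudes, policy = c("valley", "fixed"),
                         threshold = NULL, bins = 256,
                         minThreshold = NULL) {
  policy <- match.arg(policy)
  if (length(amplitudes) < 100)
    stop("need at least 100 droplets to gate", call. = FALSE)
  if (policy == "fixed") {
    if (is.null(threshold)) stop("fixed gating needs a threshold",
                                 call. = FALSE)
    thr <- threshold
  } else {
    h <- graphics::hist(amplitudes, breaks = bins, plot = FALSE)
    sm <- stats::filter(h$counts, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- 0
    cand <- which(diff(sign(diff(c(-1, sm, -1)))) == -2)
    cand <- cand[sm[cand] > 0.005 * length(amplitudes)]
    # prominence merge: adjacent maxima whose connecting valley stays above
    # a fifth of the lower peak are wiggles of one cluster, not two modes
    modes <- sort(cand)
    repeat {
      if (length(modes) < 2L) break
      merged <- FALSE
      for (j in seq_len(length(modes) - 1L)) {
        lo <- modes[j]; hi <- modes[j + 1L]
        if (min(sm[lo:hi]) > 0.2 * min(sm[lo], sm[hi])) {
          modes <- modes[-(if (sm[lo] < sm[hi]) j else j + 1L)]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    if (length(modes) < 2L) {
      if (is.null(threshold))
        stop("amplitude distribution is unimodal and no fallback threshold ",
             "was given", call. = FALSE)
      warning("unimodal amplitude distribution: falling back to the fixed ",
              "threshold")
      thr <- threshold
    } else {
      m <- utils::tail(modes, 2L)  # the two highest-amplitude modes
      valley <- m[1L] + which.min(sm[m[1L]:m[2L]]) - 1L
      thr <- h$mids[valley]
      if (!is.null(minThreshold) && thr < minThreshold) thr <- minThreshold
    }
  }
  structure(sum(amplitudes > thr), threshold = thr)
}

#' Poisson concentration from a positive-droplet count
#'
#' Limiting-dilution estimate \eqn{\hat\lambda = -\log(1 - k/n)} copies per
#' droplet, with a 95% confidence interval obtained by propagating the
#' Wilson interval for the positive fraction through the same transform
#' (the Wilson interval behaves sensibly at k near 0).
#'
#' @param k positive droplets.
#' @param n total droplets.
#' @param conf confidence level.
#' @return list with \code{lambda}, \code{ci} (length 2), \code{k}, \code{n}.
#' @examples
#' poissonConcentration(0, 10000)$lambda        # 0
#' poissonConcentration(round(10000 * (1 - exp(-1))), 10000)$lambda  # ~1
#' @export
poissonConcentration <- function(k, n, conf = 0.95) {
  stopifnot(isCount(k), isCount(n), n >= 1)
  if (k >= n)
    stop("all droplets positive: saturated reaction, dilute the template",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  lo <- max(0, centre - half)
  hi <- min(1 - 1e-12, centre + half)
  list(lambda = -log1p(-p), ci = c(-log1p(-lo), -log1p(-hi)), k = k, n = n)
}

#' Copy number from target and reference concentrations
#'
#' \code{referencePloidy * lambdaTarget / lambdaRef}: the reference gene is
#' assumed diploid, so equal concentrations read out as copy number 2.
#'
#' @param lambdaTarget,lambdaRef copies per droplet.
#' @param referencePloidy copy number of the reference gene (default 2).
#' @return numeric copy-number estimate.
#' @export
ddpcrCopyNumber <- function(lambdaTarget, lambdaRef, referencePloidy = 2) {
  if (lambdaRef <= 0)
    stop("reference concentration must be positive", call. = FALSE)
  referencePloidy * lambdaTarget / lambdaRef
}

#' Quantify one sample's droplet table
#'
#' Gates the target and reference channels independently, estimates both
#' concentrations by Poisson statistics and returns the copy number relative
#' to the diploid reference. The copy-number confidence interval combines
#' the two Wilson-based lambda intervals on the log scale (independent
#' channels).
#'
#' @param droplets data.frame with columns \code{channel}
#'   (\code{"target"}/\code{"reference"}) and \code{amplitude}, as from
#'   [simulateDdpcrDroplets()] or [readDropletTable()].
#' @param policy,bins gating controls, see [gateDroplets()].
#' @param fallbackThreshold fixed threshold used when a channel is unimodal
#'   (for example a null sample with no positive cluster); also the
#'   target-channel amplitude floor separating true positives from
#'   cross-reactive droplets.
#' @param referencePloidy copy number of the reference gene.
#' @return a [DdpcrQuant-class].
#' @export
quantifyDroplets <- function(droplets, policy = "valley", bins = 256,
                             fallbackThreshold = 5000,
                             referencePloidy = 2) {
  ampT <- droplets$amplitude[droplets$channel == "target"]
  ampR <- droplets$amplitude[droplets$channel == "reference"]
  kT <- suppressWarnings(gateDroplets(ampT, policy = policy,
                                      threshold = fallbackThreshold,
                                      bins = bins,
                                      minThreshold = fallbackThreshold))
  kR <- suppressWarnings(gateDroplets(ampR, policy = policy,
                                      threshold = fallbackThreshold,
                                      bins = bins))
  pcT <- poissonConcentration(as.integer(kT), length(ampT))
  pcR <- poissonConcentration(as.integer(kR), length(ampR))
  cn <- ddpcrCopyNumber(pcT$lambda, pcR$lambda, referencePloidy)
  # log-scale combination of the two interval half-widths
  ciCN <- if (pcT$lambda > 0 && all(pcT$ci > 0)) {
    relT <- log(pcT$ci / pcT$lambda)
    relR <- log(pcR$ci / pcR$lambda)
    half <- sqrt(max(relT)^2 + max(relR)^2)
    cn * exp(c(-half, half))
  } else {
    # null target: lower bound 0, upper from the upper lambda bound
    c(0, referencePloidy * max(pcT$ci) / pcR$lambda)
  }
  new("DdpcrQuant",
      lambdaTarget = pcT$lambda, lambdaRef = pcR$lambda,
      lambdaTargetCI = pcT$ci, lambdaRefCI = pcR$ci,
      cnEstimate = cn, cnCI = sort(ciCN),
      nPositiveTarget = as.integer(kT), nPositiveRef = as.integer(kR),
      nDroplets = length(ampT),
      thresholds = c(target = attr(kT, "threshold"),
                     reference = attr(kR, "threshold")))
}

#' Concordance between two copy-number assays
#'
#' Ordinary least-squares regression of one assay on the other;
#' \eqn{R^2} is the squared Pearson correlation and the p-value comes from
#' the slope t-test.
#'
#' @param x,y equal-length numeric vectors (length >= 3), for example
#'   competitive-PCR sCN and ddPCR copy-number estimates.
#' @return list with \code{slope}, \code{intercept}, \code{r.squared},
#'   \code{p}, \code{n}.
#' @export
cnConcordance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0)
    stop("zero variance in x: regression undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r.squared = s$r.squared,
       p = unname(s$coefficients[2L, 4L]),
       n = length(x))
}
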