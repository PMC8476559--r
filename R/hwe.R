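#' @include AllClasses.R utils.R
NULL

# --- internal EM core -------------------------------------------------------
# The copy-number HWE model: a haplotype carries a copy class a in 0..AMax
# with frequency q_a; an individual's unphased total k is the sum of two
# i.i.d. classes, so P(k) = sum_{a+b=k} q_a q_b. Only the totals are
# observed; EM imputes the unordered pair (a, k-a) with posterior
# proportional to q_a q_{k-a} (x2 when a != k-a, handled by summing both
# ordered assignments).

# flat (k, a, b) index triples over all ordered haplotype pairs, plus an
# accumulation matrix turning per-pair weights into per-class haplotype
# counts; computed once per AMax and reused across EM runs
emContext <- function(AMax) {
  k <- a <- integer(0)
  for (kk in 0:(2L * AMax)) {
    aa <- max(0L, kk - AMax):min(AMax, kk)
    k <- c(k, rep.int(kk, length(aa)))
    a <- c(a, aa)
  }
  b <- k - a
  nPair <- length(k)
  acc <- matrix(0, AMax + 1L, nPair)
  acc[cbind(a + 1L, seq_len(nPair))] <- acc[cbind(a + 1L, seq_len(nPair))] + 1
  acc[cbind(b + 1L, seq_len(nPair))] <- acc[cbind(b + 1L, seq_len(nPair))] + 1
  conv <- matrix(0, 2L * AMax + 1L, nPair)
  conv[cbind(k + 1L, seq_len(nPair))] <- 1
  list(aI = a + 1L, bI = b + 1L, kI = k + 1L, acc = acc, conv = conv,
       AMax = AMax)
}

selfConvolve <- function(q, ctx = NULL) {
  if (is.null(ctx)) ctx <- emContext(length(q) - 1L)
  as.vector(ctx$conv %*% (q[ctx$aI] * q[ctx$bI]))
}

emLogLik <- function(nk, pk) {
  i <- which(nk > 0)
  if (any(pk[i] <= 0)) return(-Inf)
  sum(nk[i] * log(pk[i]))
}

momentInit <- function(nk, AMax) {
  # spread each total k over nearby haplotype classes around k/2, smoothed
  q <- rep(0.5, AMax + 1L)
  for (k in seq_along(nk) - 1L) {
    if (nk[k + 1L] == 0) next
    a <- 0:AMax
    w <- pmax(0, 1 - abs(k / 2 - a))
    if (sum(w) == 0) w <- rep(1, AMax + 1L)
    q <- q + nk[k + 1L] * w / sum(w)
  }
  q / sum(q)
}

emCore <- function(nk, AMax, tol = 1e-8, maxIter = 1000L,
                   init = c("moment", "uniform"), ctx = NULL,
                   keepTrace = TRUE) {
  init <- match.arg(init)
  if (is.null(ctx)) ctx <- emContext(AMax)
  nk <- c(nk, rep(0, 2L * AMax + 1L - length(nk)))
  n <- sum(nk)
  q <- if (init == "moment") momentInit(nk, AMax) else
    rep(1 / (AMax + 1L), AMax + 1L)
  trace <- if (keepTrace) numeric(maxIter) else numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    w <- q[ctx$aI] * q[ctx$bI]              # ordered-pair probabilities
    pk <- as.vector(ctx$conv %*% w)          # P(total = k)
    if (any(pk[nk > 0] <= 0))
      stop("EM reached a zero-probability observed category", call. = FALSE)
    wn <- (nk / ifelse(pk > 0, pk, 1))[ctx$kI] * w  # posterior pair counts
    qNew <- as.vector(ctx$acc %*% wn) / (2 * n)
    if (keepTrace) trace[it] <- emLogLik(nk, selfConvolve(qNew, ctx))
    delta <- max(abs(qNew - q))
    q <- qNew
    if (delta < tol) { converged <- TRUE; break }
  }
  list(q = q, loglik = emLogLik(nk, selfConvolve(q, ctx)),
       trace = if (keepTrace) trace[seq_len(it)] else trace,
       nIter = it, converged = converged)
}

# pool adjacent categories with expected < minExpected from both tails
# inward; returns pooled observed/expected and the category labels
poolTails <- function(obs, expd, labels, minExpected) {
  lo <- 1L; hi <- length(expd)
  while (lo < hi && expd[lo] < minExpected) {
    expd[lo + 1L] <- expd[lo + 1L] + expd[lo]
    obs[lo + 1L] <- obs[lo + 1L] + obs[lo]
    lo <- lo + 1L
  }
  while (hi > lo && expd[hi] < minExpected) {
    expd[hi - 1L] <- expd[hi - 1L] + expd[hi]
    obs[hi - 1L] <- obs[hi - 1L] + obs[hi]
    hi <- hi - 1L
  }
  lab <- labels[lo:hi]
  if (lo > 1L) lab[1L] <- paste0(labels[1L], "-", labels[lo])
  if (hi < length(labels)) lab[length(lab)] <-
      paste0(labels[hi], "-", labels[length(labels)])
  list(obs = obs[lo:hi], expected = expd[lo:hi], labels = lab)
}

normalizeHist <- function(counts) {
  if (is.data.frame(counts)) {
    k <- counts[[1L]]; n <- counts[[2L]]
    out <- numeric(max(k) + 1L)
    out[k + 1L] <- n
    return(out)
  }
  if (!is.null(names(counts))) {
    k <- as.integer(names(counts))
    out <- numeric(max(k) + 1L)
    out[k + 1L] <- counts
    return(out)
  }
  as.numeric(counts)
}

#' EM fit of haplotype copy-class frequencies from diploid totals
#'
#' Maximum-likelihood estimation of the per-haplotype copy-class
#' frequencies \eqn{q_0..q_{A_{max}}} from an observed histogram of unphased
#' diploid total copy numbers, assuming random mating (the diploid
#' distribution is the self-convolution of q). The E-step assigns each
#' individual with total k the posterior over unordered class pairs
#' \eqn{(a, k-a) \propto q_a q_{k-a}}; the M-step sets q to the mean
#' posterior haplotype counts over 2n haplotypes. The log-likelihood is
#' non-decreasing across iterations (kept in the trace and asserted by the
#' class validity).
#'
#' @param counts diploid total-CN histogram: a plain numeric vector indexed
#'   from total 0, a named vector (names = totals), or a two-column
#'   data.frame (k, count).
#' @param AMax largest haplotype copy class; default the smallest space
#'   consistent with the data, \code{ceiling(max observed k / 2)}.
#' @param tol convergence tolerance on \code{max |q change|}.
#' @param maxIter iteration cap; non-convergence returns the current fit
#'   with a warning and \code{hasConverged(fit) == FALSE}.
#' @param init \code{"moment"} (default: smoothed marginal around k/2) or
#'   \code{"uniform"}.
#' @return an [AlleleFreqModel-class].
#' @examples
#' emFit(c(25, 50, 25))  # exactly Hardy-Weinberg for q = (0.5, 0.5)
#' @export
emFit <- function(counts, AMax = NULL, tol = 1e-8, maxIter = 1000L,
                  init = c("moment", "uniform")) {
  nk <- normalizeHist(counts)
  if (sum(nk) <= 0) stop("empty histogram", call. = FALSE)
  kMax <- max(which(nk > 0)) - 1L
  minA <- as.integer(ceiling(kMax / 2))
  if (is.null(AMax)) AMax <- max(1L, minA)
  AMax <- as.integer(AMax)
  if (AMax < minA)
    stop("AMax = ", AMax, " cannot generate observed totals up to ", kMax,
         call. = FALSE)
  stopifnot(tol > 0)
  fit <- emCore(nk, AMax, tol = tol, maxIter = as.integer(maxIter),
                init = init)
  if (!fit$converged)
    warning("EM did not converge in ", maxIter, " iterations")
  q <- fit$q
  names(q) <- as.character(0:AMax)
  new("AlleleFreqModel", q = q, loglik = fit$loglik, trace = fit$trace,
      nIter = fit$nIter, converged = fit$converged, AMax = AMax)
}

#' Expected diploid total-CN counts under Hardy-Weinberg
#'
#' \eqn{E_k = n \sum_{a+b=k} q_a q_b}: the self-convolution of the fitted
#' haplotype class frequencies, scaled to the sample size. Conserves n.
#'
#' @param model an [AlleleFreqModel-class] (or a bare frequency vector).
#' @param n number of individuals.
#' @return named numeric vector of expected counts over totals
#'   \code{0..2*AMax}.
#' @export
expectedDiploid <- function(model, n) {
  q <- if (is(model, "AlleleFreqModel")) model@q else as.numeric(model)
  e <- n * selfConvolve(q)
  names(e) <- as.character(seq_along(e) - 1L)
  e
}

#' Hardy-Weinberg chi-squared test for copy-number histograms
#'
#' Pearson goodness-of-fit of the observed diploid total histogram against
#' the EM-fitted self-convolution expectation. Adjacent categories with
#' expected counts below \code{poolingMinExpected} are merged from both
#' tails inward before summing \eqn{(O-E)^2/E}. Degrees of freedom follow
#' \code{dfRule}: \code{"categories_minus_params"} (default) uses
#' (categories after pooling - 1) - AMax, clamped at 1 with a saturation
#' flag; \code{"categories_minus_one"} ignores the estimated parameters.
#'
#' @param counts observed histogram (see [emFit()] for accepted forms).
#' @param model optional pre-fitted [AlleleFreqModel-class]; fitted from
#'   \code{counts} when missing.
#' @param AMax,tol,maxIter,init passed to [emFit()] when fitting.
#' @param poolingMinExpected minimum expected count per category
#'   (default 1).
#' @param dfRule degrees-of-freedom convention, see Details.
#' @return an [HWEResult-class].
#' @export
hweChisq <- function(counts, model = NULL, AMax = NULL,
                     poolingMinExpected = 1,
                     dfRule = c("categories_minus_params",
                                "categories_minus_one"),
                     tol = 1e-8, maxIter = 1000L, init = "moment") {
  dfRule <- match.arg(dfRule)
  stopifnot(poolingMinExpected >= 0)
  nk <- normalizeHist(counts)
  if (is.null(model)) model <- emFit(nk, AMax = AMax, tol = tol,
                                     maxIter = maxIter, init = init)
  n <- sum(nk)
  expd <- expectedDiploid(model, n)
  obs <- c(nk, rep(0, length(expd) - length(nk)))
  pooled <- poolTails(obs, expd, names(expd), poolingMinExpected)
  nCat <- length(pooled$obs)
  if (nCat < 2L) {
    return(new("HWEResult", chi2 = 0, df = 0L, pAsymptotic = 1,
               poolingApplied = pooled$labels, expected = pooled$expected,
               observed = pooled$obs, model = model, saturated = TRUE))
  }
  chi2 <- sum((pooled$obs - pooled$expected)^2 / pooled$expected)
  dfRaw <- if (dfRule == "categories_minus_params")
    nCat - 1L - model@AMax else nCat - 1L
  saturated <- dfRaw < 1L
  df <- max(1L, dfRaw)
  new("HWEResult", chi2 = chi2, df = as.integer(df),
      pAsymptotic = stats::pchisq(chi2, df, lower.tail = FALSE),
      poolingApplied = pooled$labels, expected = pooled$expected,
      observed = pooled$obs, model = model, saturated = saturated)
}

#' Parametric-bootstrap Hardy-Weinberg p-value
#'
#' Guards against degrees-of-freedom convention ambiguity: B histograms of
#' the observed size are resampled from the fitted Hardy-Weinberg model,
#' the EM fit and Pearson statistic are recomputed on each, and the
#' p-value is the fraction of resampled statistics at or above the observed
#' one. Deterministic given the seed.
#'
#' @inheritParams hweChisq
#' @param B number of bootstrap resamples (>= 200).
#' @param seed integer seed.
#' @return the bootstrap p-value, with the observed [HWEResult-class]
#'   attached as attribute \code{"observedResult"}.
#' @export
hweBootstrap <- function(counts, AMax = NULL, B = 1000L, seed = NULL,
                         poolingMinExpected = 1,
                         dfRule = "categories_minus_params",
                         tol = 1e-8, maxIter = 1000L) {
  stopifnot(B >= 200)
  nk <- normalizeHist(counts)
  n <- sum(nk)
  obsRes <- hweChisq(nk, AMax = AMax, poolingMinExpected = poolingMinExpected,
                     dfRule = dfRule, tol = tol, maxIter = maxIter)
  fit <- obsRes@model
  AMaxUse <- fit@AMax
  probs <- selfConvolve(fit@q)
  ctx <- emContext(AMaxUse)
  chi2Of <- function(nkSim) {
    f <- emCore(nkSim, AMaxUse, tol = tol, maxIter = as.integer(maxIter),
                ctx = ctx, keepTrace = FALSE)
    expd <- n * selfConvolve(f$q, ctx)
    pooled <- poolTails(nkSim, expd, as.character(seq_along(expd) - 1L),
                        poolingMinExpected)
    if (length(pooled$obs) < 2L) return(0)
    sum((pooled$obs - pooled$expected)^2 / pooled$expected)
  }
  sims <- withSeed(seed, stats::rmultinom(B, n, probs))
  stat <- vapply(seq_len(B), function(b) chi2Of(sims[, b]), numeric(1))
  p <- mean(stat >= obsRes@chi2 - 1e-12)
  structure(p, observedResult = obsRes)
}

#' One-call Hardy-Weinberg test
#'
#' Convenience wrapper: EM fit, asymptotic chi-squared test, and (when
#' \code{B > 0}) the parametric-bootstrap p-value, returned in one
#' [HWEResult-class].
#'
#' @inheritParams hweBootstrap
#' @param B bootstrap resamples; 0 skips the bootstrap.
#' @return an [HWEResult-class].
#' @export
hweTest <- function(counts, AMax = NULL, B = 0L, seed = NULL,
                    poolingMinExpected = 1,
                    dfRule = "categories_minus_params") {
  res <- hweChisq(counts, AMax = AMax,
                  poolingMinExpected = poolingMinExpected, dfRule = dfRule)
  if (B > 0) {
    pb <- hweBootstrap(counts, AMax = AMax, B = B, seed = seed,
                       poolingMinExpected = poolingMinExpected,
                       dfRule = dfRule)
    res@pBootstrap <- as.numeric(pb)
  }
  res
}
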