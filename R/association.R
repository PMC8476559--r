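#' @include AllClasses.R utils.R
NULL

#' Construct a ContingencyTable
#'
#' @param counts 2 x k numeric matrix, control row first, case row second.
#' @param rowLabels,colLabels optional dimnames (defaults:
#'   \code{c("control", "case")} and the existing or index-based column
#'   names).
#' @return a [ContingencyTable-class].
#' @examples
#' ContingencyTable(rbind(c(43, 295), c(62, 265)),
#'                  colLabels = c("1", "2-4"))
#' @export
ContingencyTable <- function(counts, rowLabels = c("control", "case"),
                             colLabels = NULL) {
  m <- as.matrix(counts)
  storage.mode(m) <- "integer"
  rownames(m) <- rowLabels
  colnames(m) <- if (!is.null(colLabels)) colLabels else
    if (!is.null(colnames(counts))) colnames(counts) else
      as.character(seq_len(ncol(m)) - 1L)
  new("ContingencyTable", counts = m)
}

asCountMatrix <- function(table) {
  if (is(table, "ContingencyTable")) table@counts else {
    m <- as.matrix(table)
    if (is.null(rownames(m))) rownames(m) <- c("control", "case")
    if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
    m
  }
}

#' Build a contingency table from cohort calls
#'
#' Tabulates digitized copy numbers of one gene by group under a named
#' binning scheme:
#' \describe{
#'   \item{per_dcn}{one column per dCN value, with values in
#'     \code{pool[1]..pool[2]} pooled into one upper bin (default
#'     \code{"4-6"}); columns empty in both groups are dropped.}
#'   \item{null_vs_rest}{\code{"0"} vs \code{"1+"} (null-genotype status).}
#'   \item{low_vs_rest}{\code{"1"} vs \code{"2+"} (low-copy status).}
#'   \item{custom}{\code{customBins}, a named list of dCN vectors; empty
#'     bins are retained.}
#' }
#'
#' @param se \code{SummarizedExperiment} of calls with a \code{dCN} assay and
#'   a \code{group} colData column (\code{"control"}/\code{"case"}).
#' @param gene row name to tabulate.
#' @param scheme binning scheme, see Details.
#' @param pool length-2 integer range pooled by \code{per_dcn}.
#' @param customBins named list of dCN vectors for \code{scheme = "custom"}.
#' @param sexFilter optional \code{"M"}/\code{"F"} restriction (X-linked
#'   genes are analyzed per sex).
#' @return a [ContingencyTable-class].
#' @export
buildContingency <- function(se, gene,
                             scheme = c("per_dcn", "null_vs_rest",
                                        "low_vs_rest", "custom"),
                             pool = c(4L, 6L), customBins = NULL,
                             sexFilter = NULL) {
  scheme <- match.arg(scheme)
  if (!gene %in% rownames(se)) stop("unknown gene: ", gene, call. = FALSE)
  cd <- SummarizedExperiment::colData(se)
  if (!"group" %in% names(cd))
    stop("calls need a 'group' colData column", call. = FALSE)
  keep <- rep(TRUE, ncol(se))
  if (!is.null(sexFilter)) {
    if (!"sex" %in% names(cd))
      stop("sexFilter needs a 'sex' colData column", call. = FALSE)
    keep <- cd$sex == sexFilter
  }
  dcn <- SummarizedExperiment::assay(se, "dCN")[gene, keep]
  grp <- cd$group[keep]
  ok <- !is.na(dcn)
  dcn <- dcn[ok]; grp <- grp[ok]
  if (!length(dcn)) stop("no retained calls for gene ", gene, call. = FALSE)

  bins <- switch(scheme,
    per_dcn = {
      vals <- 0:6
      inPool <- vals >= pool[1L] & vals <= pool[2L]
      lab <- ifelse(inPool, paste0(pool[1L], "-", pool[2L]),
                    as.character(vals))
      split(vals, factor(lab, levels = unique(lab)))
    },
    null_vs_rest = list(`0` = 0L, `1+` = 1:6),
    low_vs_rest = list(`1` = 1L, `2+` = 2:6),
    custom = {
      if (is.null(customBins)) stop("custom scheme needs customBins",
                                    call. = FALSE)
      customBins
    })

  count1 <- function(g) vapply(bins, function(b)
    sum(dcn[grp == g] %in% b), integer(1))
  m <- rbind(control = count1("control"), case = count1("case"))
  if (scheme == "per_dcn") m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2L)
    stop("fewer than two informative categories for gene ", gene,
         call. = FALSE)
  ContingencyTable(m, rowLabels = rownames(m), colLabels = colnames(m))
}

# log point probability of a 2xk table under the fixed-margin null,
# as a function of its first row
logProbRow1 <- function(r1, colSums., n1) {
  sum(lchoose(colSums., r1)) - lchoose(sum(colSums.), n1)
}

# enumerate all first rows compatible with the margins (small tables only)
enumerateFirstRows <- function(rowSums., colSums.) {
  k <- length(colSums.)
  sz <- prod(pmin(colSums.[-k], rowSums.[1L]) + 1)
  if (sz > 5e6)
    stop("table too large for full enumeration; use method = \"monte_carlo\"",
         call. = FALSE)
  grid <- as.matrix(expand.grid(lapply(colSums.[-k], function(cj)
    0:min(cj, rowSums.[1L]))))
  last <- rowSums.[1L] - rowSums(grid)
  ok <- last >= 0 & last <= colSums.[k]
  cbind(grid[ok, , drop = FALSE], last[ok])
}

#' Fisher exact test for 2 x k tables
#'
#' Two-sided p-value under the multivariate hypergeometric null with fixed
#' margins, defined as the total probability of tables whose point
#' probability does not exceed the observed one (the Freeman-Halton
#' definition, which reduces to the usual two-sided Fisher test at k = 2).
#' Routes: \code{"network"} delegates to [stats::fisher.test()]'s network
#' algorithm; \code{"exact_enumeration"} sums over all compatible tables
#' directly (small tables; also the package's independent oracle);
#' \code{"monte_carlo"} samples B tables from the null via
#' [stats::r2dtable()] and reports the add-one estimator with its standard
#' error. \code{"auto"} tries the network algorithm and falls back to
#' Monte Carlo. All routes use the customary relative tolerance 1e-7 when
#' comparing point probabilities.
#'
#' @param table a [ContingencyTable-class] or 2 x k matrix.
#' @param method \code{"auto"}, \code{"exact_enumeration"},
#'   \code{"network"} or \code{"monte_carlo"}.
#' @param B Monte-Carlo draws.
#' @param seed seed for the Monte-Carlo route.
#' @param definition \code{"prob_le"} (default, as above) or
#'   \code{"double_one_sided"} (2 x 2 only: twice the smaller tail,
#'   capped at 1).
#' @return an [AssociationResult-class] with the p-value (and \code{mcSE}
#'   for the Monte-Carlo route).
#' @examples
#' fisherExact(rbind(c(0, 338), c(3, 324)))  # p ~ 0.1183
#' @export
fisherExact <- function(table,
                        method = c("auto", "exact_enumeration", "network",
                                   "monte_carlo"),
                        B = 1e5, seed = NULL,
                        definition = c("prob_le", "double_one_sided")) {
  method <- match.arg(method)
  definition <- match.arg(definition)
  m <- asCountMatrix(table)
  stopifnot(nrow(m) == 2L, ncol(m) >= 2L)
  note <- character(0)
  mcSE <- numeric(0)
  rs <- rowSums(m); cs <- colSums(m)

  if (definition == "double_one_sided") {
    if (ncol(m) != 2L)
      stop("double_one_sided is defined for 2 x 2 tables only",
           call. = FALSE)
    x <- m[1L, 1L]
    lower <- stats::phyper(x, cs[1L], cs[2L], rs[1L])
    upper <- stats::phyper(x - 1, cs[1L], cs[2L], rs[1L],
                           lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    return(new("AssociationResult", test = "fisher", p = p,
               note = "double_one_sided"))
  }

  relTol <- 1 + 1e-7
  runEnum <- function() {
    rows <- enumerateFirstRows(rs, cs)
    lp <- apply(rows, 1L, logProbRow1, colSums. = cs, n1 = rs[1L])
    lobs <- logProbRow1(m[1L, ], cs, rs[1L])
    sum(exp(lp[lp <= lobs + log(relTol)]))
  }
  runMC <- function() {
    lobs <- logProbRow1(m[1L, ], cs, rs[1L])
    hits <- withSeed(seed, {
      sims <- stats::r2dtable(B, rs, cs)
      lps <- vapply(sims, function(s) logProbRow1(s[1L, ], cs, rs[1L]),
                    numeric(1))
      sum(lps <= lobs + log(relTol))
    })
    p <- (hits + 1) / (B + 1)
    mcSE <<- sqrt(p * (1 - p) / B)
    note <<- c(note, sprintf("monte_carlo B=%g", B))
    p
  }

  p <- switch(method,
    exact_enumeration = runEnum(),
    network = stats::fisher.test(m, workspace = 2e7, hybrid = FALSE)$p.value,
    monte_carlo = runMC(),
    auto = tryCatch(
      stats::fisher.test(m, workspace = 2e7, hybrid = FALSE)$p.value,
      error = function(e) {
        note <<- c(note, "network route failed; Monte-Carlo fallback")
        runMC()
      })
  )
  new("AssociationResult", test = "fisher", p = min(1, p), mcSE = mcSE,
      note = note)
}

#' Pearson chi-squared test for 2 x k tables
#'
#' Pearson statistic with df = k - 1 and no continuity correction by
#' default (Yates available for 2 x 2). A note flags expected cells below
#' 5; the test is never silently swapped for another.
#'
#' @param table a [ContingencyTable-class] or 2 x k matrix.
#' @param correct apply the Yates correction (2 x 2 only).
#' @return an [AssociationResult-class] with statistic and p-value.
#' @export
chiSquared <- function(table, correct = FALSE) {
  m <- asCountMatrix(table)
  stopifnot(nrow(m) == 2L, ncol(m) >= 2L)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: chi-squared test undefined", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  note <- sprintf("df=%d", unname(ht$parameter))
  if (any(ht$expected < 5))
    note <- c(note, "expected count < 5 in at least one cell")
  new("AssociationResult", test = "chi2",
      statistic = unname(ht$statistic), p = unname(ht$p.value), note = note)
}

#' Odds ratio for a 2 x 2 table with zero-cell policies
#'
#' Layout: row 1 = control (exposed, unexposed), row 2 = case (exposed,
#' unexposed); OR = (case exposed x control unexposed) / (case unexposed x
#' control exposed). With a zero cell the raw odds ratio is infinite or
#' zero; \code{"substitute_one"} (default) replaces each zero cell by 1 and
#' flags the estimate as a lower bound, \code{"haldane"} adds 0.5 to every
#' cell, \code{"error"} refuses. The 95% CI is the Woolf log-normal
#' interval, suppressed after zero-cell substitution. For tables without
#' zero cells all policies agree.
#'
#' @param table a [ContingencyTable-class] or 2 x 2 matrix.
#' @param zeroCellPolicy \code{"substitute_one"}, \code{"haldane"} or
#'   \code{"error"}.
#' @return an [AssociationResult-class] carrying \code{oddsRatio},
#'   \code{orIsLowerBound} and (when defined) \code{ci95}.
#' @examples
#' orEstimate(oddsRatio(rbind(c(43, 295), c(62, 265))))  # 1.6051
#' @export
oddsRatio <- function(table, zeroCellPolicy = c("substitute_one", "haldane",
                                                "error")) {
  zeroCellPolicy <- match.arg(zeroCellPolicy)
  m <- asCountMatrix(table)
  stopifnot(nrow(m) == 2L, ncol(m) == 2L)
  hasZero <- any(m == 0)
  isBound <- FALSE
  work <- m
  if (hasZero) {
    if (zeroCellPolicy == "error")
      stop("zero cell in the 2 x 2 table (policy \"error\")", call. = FALSE)
    if (zeroCellPolicy == "substitute_one") {
      work[work == 0] <- 1
      isBound <- TRUE
    } else {
      work <- m + 0.5
    }
  }
  or <- (work[2L, 1L] * work[1L, 2L]) / (work[2L, 2L] * work[1L, 1L])
  ci <- numeric(0)
  if (!isBound) {
    se <- sqrt(sum(1 / work))
    ci <- or * exp(c(-1, 1) * stats::qnorm(0.975) * se)
  }
  new("AssociationResult", test = "odds_ratio", oddsRatio = or,
      orIsLowerBound = isBound, ci95 = ci,
      note = if (hasZero) paste0("zero cell handled by ", zeroCellPolicy)
             else character(0))
}

#' Wilcoxon rank-sum test on standardized copy numbers
#'
#' Two-sided comparison of two continuous samples. The exact null
#' distribution is used when both samples have at most 50 observations and
#' no ties; otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric vectors.
#' @return an [AssociationResult-class] with the rank-sum statistic and p.
#' @export
wilcoxonRankSum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  doExact <- length(x) <= 50 && length(y) <= 50 &&
    !anyDuplicated(c(x, y))
  ht <- stats::wilcox.test(x, y, exact = doExact, correct = !doExact)
  new("AssociationResult", test = "wilcoxon",
      statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Bonferroni correction with a declared family size
#'
#' \code{min(1, m * p)} per value. The family size m is declared, not
#' inferred, so correcting a subset of a larger testing family stays
#' honest.
#'
#' @param p numeric vector of p-values.
#' @param m declared number of tests (>= \code{length(p)}).
#' @return adjusted p-values.
#' @examples
#' bonferroni(0.0331, m = 11)  # 0.3641
#' @export
bonferroni <- function(p, m) {
  if (!isCount(m) || m < 1) stop("m must be a positive integer",
                                 call. = FALSE)
  if (m < length(p))
    stop("declared family size m is smaller than the number of p-values",
         call. = FALSE)
  pmin(1, m * p)
}

#' Association of null-genotype status with binary clinical variables
#'
#' For each clinical variable, a 2 x 2 Fisher exact test of null status
#' against the variable. Constant variables (or variables with fewer than
#' two informative observations) are skipped with a warning. An optional
#' declared-family Bonferroni adjustment is applied across the variables
#' actually tested.
#'
#' @param nullStatus logical vector (TRUE = null genotype) per sample.
#' @param clinicalFlags data.frame of logical/binary columns aligned with
#'   \code{nullStatus}.
#' @param m optional declared family size for Bonferroni adjustment
#'   (default: the number of variables tested).
#' @return data.frame with columns \code{variable}, \code{p},
#'   \code{pAdjusted}, \code{tested}.
#' @export
clinicalAssociation <- function(nullStatus, clinicalFlags, m = NULL) {
  stopifnot(is.logical(nullStatus), nrow(clinicalFlags) == length(nullStatus))
  res <- lapply(names(clinicalFlags), function(v) {
    f <- as.logical(clinicalFlags[[v]])
    ok <- !is.na(f) & !is.na(nullStatus)
    if (sum(ok) < 2L || length(unique(f[ok])) < 2L ||
        length(unique(nullStatus[ok])) < 2L) {
      warning("variable ", v, " skipped (constant or too few observations)")
      return(data.frame(variable = v, p = NA_real_, tested = FALSE))
    }
    tab <- rbind(c(sum(!nullStatus[ok] & f[ok]), sum(!nullStatus[ok] & !f[ok])),
                 c(sum(nullStatus[ok] & f[ok]), sum(nullStatus[ok] & !f[ok])))
    data.frame(variable = v, p = pValue(fisherExact(tab)), tested = TRUE)
  })
  out <- do.call(rbind, res)
  mUse <- if (is.null(m)) sum(out$tested) else m
  out$pAdjusted <- NA_real_
  if (any(out$tested))
    out$pAdjusted[out$tested] <- bonferroni(out$p[out$tested], mUse)
  out[, c("variable", "p", "pAdjusted", "tested")]
}
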