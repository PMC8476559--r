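#' @include AllClasses.R utils.R
NULL

#' Raw relative copy number from competitive-PCR peaks
#'
#' The target genomic/competitor peak ratio normalized by the control-gene
#' genomic/competitor ratio: \code{(g_T/c_T) / mean(g_I/c_I)}, where the mean
#' runs over one or two control-gene peak pairs (columns \code{g_I}/\code{c_I}
#' and optionally \code{g_I2}/\code{c_I2}). Since the control gene is
#' diploid, a diploid target sample scores 1 at equal spike amounts; a null
#' genotype scores exactly 0. Failed records propagate \code{NA}.
#'
#' @param peaks data.frame with columns \code{g_T}, \code{c_T}, \code{g_I},
#'   \code{c_I}, optionally \code{g_I2}, \code{c_I2} and \code{failed}.
#' @return numeric vector of raw relative copy numbers.
#' @examples
#' computeRawRatio(data.frame(g_T = 2, c_T = 1, g_I = 1, c_I = 1))
#' @export
computeRawRatio <- function(peaks) {
  need <- c("g_T", "c_T", "g_I", "c_I")
  if (!all(need %in% names(peaks)))
    stop("peak table must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  failed <- if ("failed" %in% names(peaks)) peaks$failed else
    rep(FALSE, nrow(peaks))
  live <- !failed & !is.na(peaks$c_T) & !is.na(peaks$c_I)
  if (any(live & (peaks$c_T <= 0 | peaks$c_I <= 0), na.rm = TRUE))
    stop("zero or negative competitor peak on a non-failed record",
         call. = FALSE)
  ctrl <- peaks$g_I / peaks$c_I
  if (all(c("g_I2", "c_I2") %in% names(peaks))) {
    ctrl2 <- peaks$g_I2 / peaks$c_I2
    ctrl <- ifelse(is.na(ctrl2), ctrl, (ctrl + ctrl2) / 2)
  }
  ratio <- (peaks$g_T / peaks$c_T) / ctrl
  ratio[failed] <- NA_real_
  ratio
}

#' Standardize raw copy-number ratios to sCN
#'
#' Divides each raw ratio by \code{median(raw) / expectedMedianCN}; with the
#' default \code{expectedMedianCN = 2} this is division by half the cohort
#' median, so the median individual scores exactly 2 (a single X-linked male
#' stratum uses 1). Missing values are ignored for the median and propagate
#' through the result. The divisor actually used is attached as attribute
#' \code{"divisor"}.
#'
#' @param raw numeric vector of raw relative copy numbers (NA allowed).
#' @param expectedMedianCN assumed copy number of the median individual
#'   (1 or 2).
#' @return numeric vector of sCN values with attribute \code{"divisor"}.
#' @examples
#' standardizeCN(c(0.5, 1.0, 1.5))  # 1, 2, 3
#' @export
standardizeCN <- function(raw, expectedMedianCN = 2) {
  stopifnot(expectedMedianCN %in% c(1, 2))
  obs <- raw[!is.na(raw)]
  if (!length(obs) || !any(obs > 0))
    stop("need at least one positive raw ratio to standardize", call. = FALSE)
  med <- stats::median(obs)
  if (med <= 0)
    stop("cohort median of raw ratios is zero; cannot standardize",
         call. = FALSE)
  divisor <- med / expectedMedianCN
  structure(raw / divisor, divisor = divisor)
}

#' Digitize sCN into integer copy-number bins
#'
#' Half-open bins with edges at x.5: \code{[0, 0.5) -> 0},
#' \code{[0.5, 1.5) -> 1}, ..., \code{[5.5, 6.5) -> 6}; equivalently
#' \code{floor(sCN + 0.5)} below 6.5. Values at or above 6.5 are clamped to
#' 6 with a warning (display tables pool the upper bins anyway). \code{NA}
#' propagates.
#'
#' @param sCN numeric vector of standardized copy numbers (>= 0).
#' @return integer vector of digitized copy numbers in \code{0..6}.
#' @examples
#' digitizeCN(c(0.49, 0.5, 2.0))  # 0 1 2
#' @export
digitizeCN <- function(sCN) {
  if (any(sCN < 0, na.rm = TRUE))
    stop("sCN must be non-negative", call. = FALSE)
  d <- as.integer(floor(sCN + 0.5))
  over <- !is.na(d) & d > 6L
  if (any(over)) {
    warning(sum(over), " sCN value(s) at or above 6.5 clamped to dCN 6")
    d[over] <- 6L
  }
  d
}

#' Standardize an X-linked gene per sex stratum
#'
#' Females are standardized with an expected median copy number of 2 and
#' males with 1, independently, so hemizygous males center on sCN 1.
#'
#' @param raw numeric vector of raw relative copy numbers.
#' @param sexes character vector (\code{"M"}/\code{"F"}) aligned with
#'   \code{raw}.
#' @return numeric vector of sCN values; attribute \code{"divisor"} is a
#'   named vector with the per-stratum divisors.
#' @export
standardizeXLinked <- function(raw, sexes) {
  stopifnot(length(raw) == length(sexes))
  if (any(is.na(sexes)))
    stop("sex must be known for every sample", call. = FALSE)
  out <- rep(NA_real_, length(raw))
  div <- c(F = NA_real_, M = NA_real_)
  for (s in intersect(c("F", "M"), unique(sexes))) {
    i <- sexes == s
    sc <- standardizeCN(raw[i], expectedMedianCN = if (s == "F") 2 else 1)
    out[i] <- sc
    div[s] <- attr(sc, "divisor")
  }
  structure(out, divisor = div)
}

#' Call copy numbers for a whole cohort
#'
#' Runs raw-ratio computation, per-gene median standardization (per sex
#' stratum for X-linked genes) and digitization over a long-format peak
#' table, returning a \link[SummarizedExperiment]{SummarizedExperiment} with
#' genes as rows, samples as columns and assays \code{rawRatio}, \code{sCN},
#' \code{dCN} and \code{qcPass}. Standardization divisors are recorded in
#' \code{metadata()$standardization}.
#'
#' @param peaks long-format peak table (see [simulateMrcpcrPeaks()] or
#'   [readPeakTable()]).
#' @param sampleInfo optional data.frame with column \code{id} and any of
#'   \code{group}, \code{sex}, \code{dnaPass}; becomes the colData.
#' @param inheritance named character vector mapping gene ->
#'   \code{"autosomal"}/\code{"x_linked"}; unlisted genes are autosomal.
#' @param perGroup when \code{TRUE}, medians are computed separately within
#'   each \code{group}; the default pools cases and controls so a
#'   case-control copy-number shift cannot be standardized away.
#' @return a \code{SummarizedExperiment}.
#' @export
callCopyNumbers <- function(peaks, sampleInfo = NULL, inheritance = NULL,
                            perGroup = FALSE) {
  genes <- unique(peaks$gene)
  samples <- unique(peaks$sample)
  cd <- S4Vectors::DataFrame(row.names = samples)
  if (!is.null(sampleInfo)) {
    m <- match(samples, sampleInfo$id)
    if (anyNA(m)) stop("sampleInfo is missing some samples", call. = FALSE)
    for (col in setdiff(names(sampleInfo), "id"))
      cd[[col]] <- sampleInfo[[col]][m]
  }
  if (perGroup && is.null(cd$group))
    stop("perGroup standardization needs a 'group' column", call. = FALSE)

  mk <- function() matrix(NA_real_, length(genes), length(samples),
                          dimnames = list(genes, samples))
  raw <- mk(); scn <- mk()
  divisors <- list()

  strata <- if (perGroup) cd$group else rep("all", length(samples))
  names(strata) <- samples

  for (g in genes) {
    pg <- peaks[peaks$gene == g, , drop = FALSE]
    r <- computeRawRatio(pg)
    idx <- match(pg$sample, samples)
    raw[g, idx] <- r
    xl <- !is.null(inheritance) && !is.na(inheritance[g]) &&
      identical(unname(inheritance[g]), "x_linked")
    if (xl && is.null(cd$sex))
      stop("X-linked gene ", g, " needs a 'sex' column in sampleInfo",
           call. = FALSE)
    for (st in unique(strata)) {
      sel <- idx[strata[pg$sample] == st]
      rawst <- raw[g, sel]
      sub <- which(strata[pg$sample] == st)
      sc <- if (xl) standardizeXLinked(rawst, cd$sex[sel]) else
        standardizeCN(rawst)
      scn[g, sel] <- sc
      divisors[[paste(g, st, sep = "/")]] <- attr(sc, "divisor")
    }
  }
  dcn <- suppressWarnings(
    matrix(digitizeCN(as.vector(scn)), nrow(scn), ncol(scn),
           dimnames = dimnames(scn)))
  qc <- !is.na(raw)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rawRatio = raw, sCN = scn, dCN = dcn, qcPass = qc),
    colData = cd,
    metadata = list(standardization = divisors, perGroup = perGroup)
  )
}

#' Cohort-level QC filtering with an exclusion ledger
#'
#' A sample is retained iff its DNA-quantity flag passes and every required
#' gene has a passing call, applied in that order: samples failing the DNA
#' criterion are counted under \code{dna} and never re-counted under
#' \code{assayFailure}.
#'
#' @param se a \code{SummarizedExperiment} from [callCopyNumbers()]; an
#'   optional logical colData column \code{dnaPass} marks the DNA criterion
#'   (missing column means all pass).
#' @param requiredGenes genes whose calls are required; defaults to all rows.
#' @return list with elements \code{experiment} (the retained columns) and
#'   \code{ledger} (named list: \code{nInput}, \code{dna},
#'   \code{assayFailure}, \code{retained}, and a per-group breakdown
#'   \code{byGroup} when a \code{group} column exists).
#' @export
qcFilter <- function(se, requiredGenes = rownames(se)) {
  stopifnot(length(requiredGenes) >= 1,
            all(requiredGenes %in% rownames(se)))
  cd <- SummarizedExperiment::colData(se)
  dna <- if ("dnaPass" %in% names(cd)) as.logical(cd$dnaPass) else
    rep(TRUE, ncol(se))
  qc <- SummarizedExperiment::assay(se, "qcPass")[requiredGenes, ,
                                                  drop = FALSE]
  allPass <- colSums(!qc) == 0L
  exclDNA <- !dna
  exclAssay <- dna & !allPass
  keep <- dna & allPass
  ledger <- list(nInput = ncol(se), dna = sum(exclDNA),
                 assayFailure = sum(exclAssay), retained = sum(keep))
  if ("group" %in% names(cd)) {
    ledger$byGroup <- data.frame(
      group = sort(unique(cd$group)),
      nInput = as.vector(table(cd$group)),
      dna = as.vector(tapply(exclDNA, cd$group, sum)),
      assayFailure = as.vector(tapply(exclAssay, cd$group, sum)),
      retained = as.vector(tapply(keep, cd$group, sum))
    )
  }
  list(experiment = se[, keep], ledger = ledger)
}

#' Write copy-number calls and the exclusion ledger
#'
#' Calls go to CSV in long format (sample, gene, rawRatio, sCN, dCN,
#' qcPass); the ledger to JSON.
#'
#' @param se a \code{SummarizedExperiment} of calls.
#' @param path output CSV path.
#' @param ledger,ledgerPath optional exclusion ledger and its JSON path.
#' @return \code{path}, invisibly.
#' @export
writeCalls <- function(se, path, ledger = NULL, ledgerPath = NULL) {
  long <- data.frame(
    sample = rep(colnames(se), each = nrow(se)),
    gene = rep(rownames(se), times = ncol(se)),
    rawRatio = as.vector(SummarizedExperiment::assay(se, "rawRatio")),
    sCN = as.vector(SummarizedExperiment::assay(se, "sCN")),
    dCN = as.vector(SummarizedExperiment::assay(se, "dCN")),
    qcPass = as.vector(SummarizedExperiment::assay(se, "qcPass"))
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (!is.null(ledger) && !is.null(ledgerPath))
    jsonlite::write_json(ledger, ledgerPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(path)
}
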