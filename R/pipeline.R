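#' @include AllClasses.R utils.R cn-calling.R association.R hwe.R
NULL

# tiny rolling string hash for the provenance block (hex)
fnv1a <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the simulate-call-associate-HWE pipeline
#'
#' Orchestrates one reproducible end-to-end run: cohort simulation,
#' peak simulation, copy-number calling, QC filtering, per-gene association
#' tests with Bonferroni adjustment, Hardy-Weinberg tests per group, and an
#' optional ddPCR concordance stage. All randomness flows from one root
#' seed through named substreams, so reruns with the same config are
#' identical.
#'
#' @param config a list (or YAML file path) with elements:
#'   \describe{
#'     \item{cohort}{a [CohortSpec-class].}
#'     \item{schemes}{named list per gene:
#'       \code{list(scheme =, test = "fisher"|"chisq", sexFilter = NULL)};
#'       genes without an entry get \code{per_dcn} + Fisher.}
#'     \item{m}{declared Bonferroni family size (default: number of tests
#'       run).}
#'     \item{hwe}{\code{list(genes =, B = 0, seed offset automatic)};
#'       default: HWE on every scheme gene, both groups, no bootstrap.}
#'     \item{ddpcr}{optional \code{list(gene =, nPerDcn = 3, c0 = 0.5,
#'       nDroplets = 15000)} enabling the concordance stage.}
#'     \item{dnaFailRate}{per-sample probability of failing the DNA-quantity
#'       criterion (default 0).}
#'     \item{requiredGenes}{genes required by QC (default: all).}
#'     \item{seed}{root seed (default: the cohort spec's).}
#'   }
#' @return a [CNVReport-class].
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  spec <- config$cohort
  stopifnot(is(spec, "CohortSpec"))
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else spec@seed

  cohort <- simulateCohort(spec)
  peaks <- simulateMrcpcrPeaks(cohort, noiseCV = spec@noiseCV,
                               assayFailureRate = spec@assayFailureRate,
                               seed = deriveSeed(seed, "peaks"))

  samples <- unique(cohort$id)
  si <- unique(cohort[, c("id", "group", "sex")])
  dnaFailRate <- if (is.null(config$dnaFailRate)) 0 else config$dnaFailRate
  si$dnaPass <- withSeed(deriveSeed(seed, "dna"),
                         stats::runif(nrow(si)) >= dnaFailRate)
  inh <- vapply(spec@genes, inheritanceMode, character(1))

  se <- callCopyNumbers(peaks, sampleInfo = si, inheritance = inh)
  requiredGenes <- if (is.null(config$requiredGenes)) rownames(se) else
    config$requiredGenes
  flt <- qcFilter(se, requiredGenes = requiredGenes)
  seQC <- flt$experiment

  schemes <- config$schemes
  if (is.null(schemes))
    schemes <- stats::setNames(rep(list(list(scheme = "per_dcn",
                                             test = "fisher")),
                                   length(spec@genes)), names(spec@genes))
  rows <- list()
  tables <- list()
  for (gn in names(schemes)) {
    sc <- schemes[[gn]]
    tab <- buildContingency(seQC, gn, scheme = sc$scheme,
                            sexFilter = sc$sexFilter)
    tables[[gn]] <- tab
    test <- if (is.null(sc$test)) "fisher" else sc$test
    res <- if (test == "chisq") chiSquared(tab) else
      fisherExact(tab, seed = deriveSeed(seed, paste0("fisher:", gn)))
    orRes <- if (ncol(tableCounts(tab)) == 2L) oddsRatio(tab) else NULL
    rows[[gn]] <- data.frame(
      gene = gn, scheme = sc$scheme, test = test, p = pValue(res),
      oddsRatio = if (!is.null(orRes)) orEstimate(orRes) else NA_real_,
      orIsLowerBound = if (!is.null(orRes)) isLowerBound(orRes) else NA,
      stringsAsFactors = FALSE)
  }
  assoc <- do.call(rbind, rows)
  mUse <- if (is.null(config$m)) nrow(assoc) else config$m
  assoc$pAdjusted <- bonferroni(assoc$p, mUse)
  assoc$mTests <- mUse
  rownames(assoc) <- NULL

  hweCfg <- config$hwe
  hweGenes <- if (!is.null(hweCfg$genes)) hweCfg$genes else names(schemes)
  hweB <- if (!is.null(hweCfg$B)) hweCfg$B else 0L
  dcn <- SummarizedExperiment::assay(seQC, "dCN")
  grp <- SummarizedExperiment::colData(seQC)$group
  hweRes <- list()
  for (gn in hweGenes) {
    if (inh[gn] == "x_linked") next  # hemizygotes break the diploid model
    for (g in c("control", "case")) {
      v <- dcn[gn, grp == g]
      h <- tabulate(v + 1L, nbins = max(v) + 1L)
      hweRes[[paste(gn, g, sep = ".")]] <-
        hweTest(h, B = hweB,
                seed = deriveSeed(seed, paste0("hwe:", gn, ":", g)))
    }
  }

  conc <- list()
  dd <- config$ddpcr
  if (!is.null(dd)) {
    gn <- dd$gene
    nPer <- if (is.null(dd$nPerDcn)) 3L else dd$nPerDcn
    c0 <- if (is.null(dd$c0)) 0.5 else dd$c0
    nDrop <- if (is.null(dd$nDroplets)) 15000L else dd$nDroplets
    truth <- cohort[cohort$gene == gn &
                      cohort$id %in% colnames(seQC), ]
    scn <- SummarizedExperiment::assay(seQC, "sCN")[gn, truth$id]
    picked <- integer(0)
    for (d in 0:4) {
      i <- which(truth$totalCN == d)
      if (length(i)) picked <- c(picked, utils::head(i, nPer))
    }
    if (length(picked) >= 3L) {
      est <- vapply(seq_along(picked), function(j) {
        i <- picked[j]
        drops <- simulateDdpcrDroplets(
          truth$totalCN[i], homologCN = 2, c0 = c0, nDroplets = nDrop,
          seed = deriveSeed(seed, paste0("ddpcr:", j)))
        cnEstimate(quantifyDroplets(drops))
      }, numeric(1))
      conc <- cnConcordance(scn[picked], est)
    }
  }

  cfgString <- paste(deparse(config[setdiff(names(config), "cohort")]),
                     collapse = "")
  new("CNVReport",
      countTables = tables, association = assoc, hwe = hweRes,
      exclusionLedger = flt$ledger, concordance = conc,
      provenance = list(
        seed = seed,
        configHash = fnv1a(paste0(cfgString, spec@seed, spec@nCases,
                                  spec@nControls)),
        package = "mrcCNV",
        version = as.character(utils::packageVersion("mrcCNV"))))
}

#' Read printed dCN count tables
#'
#' Long-format CSV with columns \code{table}, \code{gene}, \code{test},
#' \code{group}, \code{category}, \code{count}; one block per analysis
#' table, control and case rows. The package ships the published count
#' tables of a 338-control / 327-case SLE cohort as
#' \code{system.file("extdata", "sle_dcn_counts.csv", package = "mrcCNV")}.
#'
#' @param path CSV path.
#' @return named list of [ContingencyTable-class] objects, each with
#'   attribute \code{"test"} (the test the published p-value corresponds
#'   to) and \code{"gene"}.
#' @export
readCountTables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(category = "character"))
  out <- list()
  for (id in unique(df$table)) {
    d <- df[df$table == id, ]
    cats <- unique(d$category)
    m <- matrix(0L, 2L, length(cats),
                dimnames = list(c("control", "case"), cats))
    for (i in seq_len(nrow(d)))
      m[d$group[i], d$category[i]] <- d$count[i]
    tab <- ContingencyTable(m, rowLabels = rownames(m),
                            colLabels = colnames(m))
    attr(tab, "test") <- d$test[1L]
    attr(tab, "gene") <- d$gene[1L]
    out[[id]] <- tab
  }
  out
}

#' Recompute association statistics from printed count tables
#'
#' The regression entry point: bypasses simulation and recomputes Fisher
#' exact and Pearson chi-squared p-values, odds ratios (2 x 2 tables, with
#' the zero-cell substitute-one lower-bound policy), and Bonferroni
#' adjustments directly from published contingency tables.
#'
#' @param tables a CSV path for [readCountTables()] or its result.
#' @param m declared Bonferroni family size (default: number of tables).
#' @return data.frame with one row per table: \code{table}, \code{gene},
#'   \code{k}, \code{n}, \code{fisher_p}, \code{chisq_p}, \code{odds_ratio},
#'   \code{or_lower_bound}, \code{primary_test}, \code{primary_p},
#'   \code{p_adjusted}.
#' @export
regressCountTables <- function(tables, m = NULL) {
  if (is.character(tables)) tables <- readCountTables(tables)
  rows <- lapply(names(tables), function(id) {
    tab <- tables[[id]]
    cnt <- tableCounts(tab)
    fp <- pValue(fisherExact(tab))
    cp <- pValue(chiSquared(tab))
    orE <- NA_real_; orLB <- NA
    if (ncol(cnt) == 2L) {
      o <- oddsRatio(tab)
      orE <- orEstimate(o); orLB <- isLowerBound(o)
    }
    primary <- attr(tab, "test")
    pp <- switch(primary, fisher = fp, chisq = cp, NA_real_)
    data.frame(table = id, gene = attr(tab, "gene"), k = ncol(cnt),
               n = sum(cnt), fisher_p = fp, chisq_p = cp,
               odds_ratio = orE, or_lower_bound = orLB,
               primary_test = primary, primary_p = pp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mUse <- if (is.null(m)) sum(!is.na(out$primary_p)) else m
  out$p_adjusted <- ifelse(is.na(out$primary_p), NA,
                           bonferroni(ifelse(is.na(out$primary_p), 1,
                                             out$primary_p), mUse))
  rownames(out) <- NULL
  out
}

#' Write a pipeline report to disk
#'
#' Emits the association table as CSV, each count table as CSV with
#' percentages re-derived from the counts, and the full report (tests, HWE,
#' ledger, concordance, provenance) as JSON.
#'
#' @param report a [CNVReport-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@association,
                   file.path(dir, "association.csv"), row.names = FALSE)
  tabJson <- lapply(report@countTables, function(t) {
    cnt <- tableCounts(t)
    pct <- round(100 * sweep(cnt, 1, rowSums(cnt), "/"), 1)
    list(counts = as.data.frame(cnt), percent = as.data.frame(pct))
  })
  hweJson <- lapply(report@hwe, function(h) list(
    chi2 = h@chi2, df = h@df, p_asymptotic = h@pAsymptotic,
    p_bootstrap = if (length(h@pBootstrap)) h@pBootstrap else NULL,
    categories = h@poolingApplied, q = as.list(h@model@q),
    converged = h@model@converged))
  jsonlite::write_json(
    list(association = report@association, tables = tabJson,
         hwe = hweJson, exclusions = report@exclusionLedger,
         concordance = report@concordance, provenance = report@provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
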