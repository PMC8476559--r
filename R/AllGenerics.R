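#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family used across the package's S4 classes: slot access
#' stays behind functions, as usual for this class of software.
#'
#' @param object an S4 object from this package.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alleleFreqs", function(object) standardGeneric("alleleFreqs"))

#' @rdname accessors
#' @export
setGeneric("inheritanceMode",
           function(object) standardGeneric("inheritanceMode"))

#' @rdname accessors
#' @export
setGeneric("geneName", function(object) standardGeneric("geneName"))

#' @rdname accessors
#' @export
setGeneric("tableCounts", function(object) standardGeneric("tableCounts"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("orEstimate", function(object) standardGeneric("orEstimate"))

#' @rdname accessors
#' @export
setGeneric("isLowerBound", function(object) standardGeneric("isLowerBound"))

#' @rdname accessors
#' @export
setGeneric("confint95", function(object) standardGeneric("confint95"))

#' @rdname accessors
#' @export
setGeneric("emTrace", function(object) standardGeneric("emTrace"))

#' @rdname accessors
#' @export
setGeneric("hasConverged", function(object) standardGeneric("hasConverged"))

#' @rdname accessors
#' @export
setGeneric("cnEstimate", function(object) standardGeneric("cnEstimate"))

## -- GeneModel ---------------------------------------------------------------

#' @rdname accessors
setMethod("alleleFreqs", "GeneModel", function(object) object@alleleFreqs)

#' @rdname accessors
setMethod("inheritanceMode", "GeneModel", function(object) object@inheritance)

#' @rdname accessors
setMethod("geneName", "GeneModel", function(object) object@name)

#' @export
setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel \"%s\" (%s), haplotype classes 0..%d\n",
              object@name, object@inheritance,
              length(object@alleleFreqs) - 1L))
  print(round(object@alleleFreqs, 4))
  if (nzchar(object@label)) cat(" ", object@label, "\n")
  invisible(NULL)
})

## -- ContingencyTable --------------------------------------------------------

#' @rdname accessors
setMethod("tableCounts", "ContingencyTable", function(object) object@counts)

#' @export
setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable: 2 x %d (N = %d)\n",
              ncol(object@counts), sum(object@counts)))
  print(object@counts)
  invisible(NULL)
})

#' @export
setMethod("dim", "ContingencyTable", function(x) dim(x@counts))

## -- AssociationResult -------------------------------------------------------

#' @rdname accessors
setMethod("pValue", "AssociationResult", function(object) object@p)

#' @rdname accessors
setMethod("orEstimate", "AssociationResult", function(object) object@oddsRatio)

#' @rdname accessors
setMethod("isLowerBound", "AssociationResult",
          function(object) object@orIsLowerBound)

#' @rdname accessors
setMethod("confint95", "AssociationResult", function(object) object@ci95)

#' @export
setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult [%s]\n", object@test))
  if (length(object@statistic))
    cat(sprintf("  statistic = %.4g\n", object@statistic))
  if (length(object@p)) cat(sprintf("  p = %.4g", object@p))
  if (length(object@mcSE)) cat(sprintf(" (MC SE %.2g)", object@mcSE))
  if (length(object@p)) cat("\n")
  if (length(object@pAdjusted))
    cat(sprintf("  adjusted p = %.4g (m = %d)\n", object@pAdjusted,
                object@mTests))
  if (length(object@oddsRatio)) {
    cat(sprintf("  OR %s %.4f", if (object@orIsLowerBound) ">" else "=",
                object@oddsRatio))
    if (length(object@ci95) == 2L)
      cat(sprintf("  [95%% CI %.4f, %.4f]", object@ci95[1], object@ci95[2]))
    cat("\n")
  }
  if (length(object@note)) cat("  note:", paste(object@note, collapse = "; "),
                               "\n")
  invisible(NULL)
})

## -- AlleleFreqModel ---------------------------------------------------------

#' @rdname accessors
setMethod("alleleFreqs", "AlleleFreqModel", function(object) object@q)

#' @rdname accessors
setMethod("emTrace", "AlleleFreqModel", function(object) object@trace)

#' @rdname accessors
setMethod("hasConverged", "AlleleFreqModel", function(object) object@converged)

#' Log-likelihood of an EM haplotype-frequency fit
#' @param object an [AlleleFreqModel-class].
#' @param ... ignored.
#' @export
setMethod("logLik", "AlleleFreqModel", function(object, ...) {
  structure(object@loglik, df = object@AMax, class = "logLik")
})

#' @export
setMethod("show", "AlleleFreqModel", function(object) {
  cat(sprintf(
    "AlleleFreqModel: A_max = %d, logLik = %.4f, %d iterations (%s)\n",
    object@AMax, object@loglik, object@nIter,
    if (object@converged) "converged" else "NOT converged"))
  print(round(object@q, 5))
  invisible(NULL)
})

## -- HWEResult ---------------------------------------------------------------

#' @rdname accessors
setMethod("pValue", "HWEResult", function(object) object@pAsymptotic)

#' @export
setMethod("show", "HWEResult", function(object) {
  cat(sprintf("HWEResult: chi2 = %.4f, df = %d, asymptotic p = %.4g\n",
              object@chi2, object@df, object@pAsymptotic))
  if (length(object@pBootstrap))
    cat(sprintf("  bootstrap p = %.4g\n", object@pBootstrap))
  if (length(object@poolingApplied))
    cat("  categories:", paste(object@poolingApplied, collapse = ", "), "\n")
  if (object@saturated) cat("  [saturated fit: test uninformative]\n")
  invisible(NULL)
})

## -- DdpcrQuant --------------------------------------------------------------

#' @rdname accessors
setMethod("cnEstimate", "DdpcrQuant", function(object) object@cnEstimate)

#' @export
setMethod("show", "DdpcrQuant", function(object) {
  cat(sprintf(
    "DdpcrQuant: %d droplets; target %d+ (lambda %.4f), reference %d+ (lambda %.4f)\n",
    object@nDroplets, object@nPositiveTarget, object@lambdaTarget,
    object@nPositiveRef, object@lambdaRef))
  cat(sprintf("  CN estimate = %.3f [95%% CI %.3f, %.3f]\n",
              object@cnEstimate, object@cnCI[1], object@cnCI[2]))
  invisible(NULL)
})

## -- CNVReport ---------------------------------------------------------------

#' @export
setMethod("show", "CNVReport", function(object) {
  cat("CNVReport\n")
  cat(sprintf("  genes analyzed: %s\n",
              paste(names(object@countTables), collapse = ", ")))
  cat(sprintf("  association rows: %d; HWE results: %d\n",
              nrow(object@association), length(object@hwe)))
  scalars <- Filter(function(x) is.numeric(x) && length(x) == 1L,
                    object@exclusionLedger)
  cat(sprintf("  exclusions: %s\n",
              paste(sprintf("%s=%d", names(scalars),
                            unlist(scalars)),
                    collapse = ", ")))
  cat(sprintf("  seed %s, config %s\n", object@provenance$seed,
              object@provenance$configHash))
  invisible(NULL)
})
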