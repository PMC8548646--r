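#' @rdname PairedCohort-class
#' @param object,x a \linkS4class{PairedCohort} or \linkS4class{MatchScore}.
#' @export
setGeneric("recipientGeno", function(x) standardGeneric("recipientGeno"))

#' @rdname PairedCohort-class
#' @export
setGeneric("donorGeno", function(x) standardGeneric("donorGeno"))

#' @rdname PairedCohort-class
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname PairedCohort-class
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @rdname PairedCohort-class
#' @export
setGeneric("outcomeType", function(x) standardGeneric("outcomeType"))

#' @rdname PairedCohort-class
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname PairedCohort-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname PairedCohort-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname MatchScore-class
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname MatchScore-class
#' @export
setGeneric("scoreType", function(x) standardGeneric("scoreType"))

#' @exportMethod recipientGeno
setMethod("recipientGeno", "PairedCohort", function(x) x@recipient)

#' @exportMethod donorGeno
setMethod("donorGeno", "PairedCohort", function(x) x@donor)

#' @exportMethod covariates
setMethod("covariates", "PairedCohort", function(x) x@covariates)

#' @exportMethod outcome
setMethod("outcome", "PairedCohort", function(x) x@outcome)

#' @exportMethod outcomeType
setMethod("outcomeType", "PairedCohort", function(x) x@outcomeType)

#' @exportMethod nPairs
setMethod("nPairs", "PairedCohort", function(x) nrow(x@recipient))

#' @exportMethod nSnps
setMethod("nSnps", "PairedCohort", function(x) ncol(x@recipient))

#' @exportMethod snpInfo
setMethod("snpInfo", "PairedCohort", function(x) x@snpInfo)

#' @exportMethod scoreValues
setMethod("scoreValues", "MatchScore", function(x) x@z)

#' @exportMethod scoreType
setMethod("scoreType", "MatchScore", function(x) x@scoreType)

setMethod("show", "PairedCohort", function(object) {
  cat(sprintf("PairedCohort: %d D/R pairs, %d SNPs, %d covariate(s), %s outcome\n",
              nPairs(object), nSnps(object), ncol(object@covariates),
              object@outcomeType))
  if (object@outcomeType == "binary")
    cat(sprintf("  cases: %d (prevalence %.3f)\n", sum(object@outcome),
                mean(object@outcome)))
  invisible(NULL)
})

setMethod("show", "MatchScore", function(object) {
  cat(sprintf("MatchScore (%s%s): %d pairs over %d SNPs; mean %.3f, range [%g, %g]\n",
              object@scoreType, if (object@weighted) ", weighted" else "",
              length(object@z), length(object@snpIds), mean(object@z),
              min(object@z), max(object@z)))
  invisible(NULL)
})

setMethod("show", "JSTResult", function(object) {
  cat("Joint score test (recipient SNPs + D/R matching score)\n")
  cat(sprintf("  score type: %s;  SNPs used: %d%s\n", object@scoreType,
              object@nSnpsUsed,
              if (length(object@droppedSnps))
                sprintf(" (%d monomorphic dropped)", length(object@droppedSnps))
              else ""))
  cat(sprintf("  s = %d PCs (%.0f%% variance), statistic = %.4f, df = %d, p = %.4g\n",
              object@s, 100 * object@thresholdUsed, object@statistic,
              object@df, object@pValue))
  invisible(NULL)
})
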