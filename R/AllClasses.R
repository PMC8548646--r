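#' @import methods
NULL

.SCORE_TYPES <- c("IBS", "INCOMP", "AMS", "MM")

.checkGenoMatrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    return(sprintf("'%s' must be a numeric matrix", what))
  ok <- x[!is.na(x)]
  if (length(ok) && !all(ok %in% c(0, 1, 2)))
    return(sprintf("'%s' must contain minor-allele counts in {0,1,2}", what))
  NULL
}

#' PairedCohort: genotypes, covariates and outcome for n donor/recipient pairs
#'
#' The central container of the package. Row \eqn{i} of every slot refers to
#' the same donor/recipient (D/R) pair: \code{recipient} and \code{donor}
#' hold minor-allele counts (0/1/2) for the same \eqn{m} SNPs, \code{covariates}
#' holds \eqn{K} adjustment covariates (possibly zero columns), and
#' \code{outcome} is the transplant phenotype, binary 0/1 (e.g. acute
#' rejection) or continuous.
#'
#' @slot recipient n x m numeric matrix of recipient genotypes.
#' @slot donor n x m numeric matrix of donor genotypes, same SNP order.
#' @slot covariates n x K numeric matrix (K may be 0).
#' @slot outcome length-n numeric vector.
#' @slot outcomeType "binary" or "continuous".
#' @slot snpInfo data.frame of per-SNP metadata (id, chrom, pos, ref, alt as
#'   available); zero rows when not supplied.
#'
#' @name PairedCohort-class
#' @rdname PairedCohort-class
#' @exportClass PairedCohort
setClass("PairedCohort",
  slots = c(
    recipient   = "matrix",
    donor       = "matrix",
    covariates  = "matrix",
    outcome     = "numeric",
    outcomeType = "character",
    snpInfo     = "data.frame"
  )
)

setValidity("PairedCohort", function(object) {
  msgs <- character(0)
  for (w in c("recipient", "donor")) {
    m <- .checkGenoMatrix(slot(object, w), w)
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  n <- nrow(object@recipient)
  if (!identical(dim(object@recipient), dim(object@donor)))
    msgs <- c(msgs, "recipient and donor matrices must have identical dimensions")
  if (nrow(object@covariates) != n)
    msgs <- c(msgs, "covariates must have one row per pair")
  if (length(object@outcome) != n)
    msgs <- c(msgs, "outcome must have one value per pair")
  if (!(length(object@outcomeType) == 1L &&
        object@outcomeType %in% c("binary", "continuous")))
    msgs <- c(msgs, "outcomeType must be 'binary' or 'continuous'")
  else if (object@outcomeType == "binary") {
    y <- object@outcome
    if (!all(y %in% c(0, 1)))
      msgs <- c(msgs, "binary outcome must be coded 0/1")
    else if (length(unique(y)) < 2L)
      msgs <- c(msgs, "binary outcome must contain both classes")
  }
  if (anyNA(object@outcome) || anyNA(object@covariates))
    msgs <- c(msgs, "outcome and covariates must be complete")
  if (n < ncol(object@covariates) + 2L)
    msgs <- c(msgs, "need n >= K + 2 pairs")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PairedCohort
#'
#' @param recipient,donor n x m genotype matrices (minor-allele counts 0/1/2).
#' @param outcome length-n phenotype vector.
#' @param covariates optional n x K matrix or data.frame of covariates.
#' @param outcomeType "binary" or "continuous".
#' @param snpInfo optional data.frame of per-SNP metadata with one row per SNP.
#' @return A \linkS4class{PairedCohort}.
#' @examples
#' set.seed(1)
#' xr <- matrix(rbinom(40, 2, 0.3), 20, 2)
#' xd <- matrix(rbinom(40, 2, 0.3), 20, 2)
#' y <- rbinom(20, 1, 0.4)
#' PairedCohort(xr, xd, y, outcomeType = "binary")
#' @export
PairedCohort <- function(recipient, donor, outcome, covariates = NULL,
                         outcomeType = c("binary", "continuous"),
                         snpInfo = NULL) {
  outcomeType <- match.arg(outcomeType)
  recipient <- as.matrix(recipient)
  donor <- as.matrix(donor)
  storage.mode(recipient) <- "double"
  storage.mode(donor) <- "double"
  n <- nrow(recipient)
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
  }
  if (is.null(snpInfo))
    snpInfo <- data.frame(id = colnames(recipient) %||%
                            paste0("snp", seq_len(ncol(recipient))))
  new("PairedCohort", recipient = recipient, donor = donor,
      covariates = covariates, outcome = as.numeric(outcome),
      outcomeType = outcomeType, snpInfo = snpInfo)
}

#' MatchScore: a gene-based donor/recipient matching score
#'
#' Holds the per-pair gene-based matching score \eqn{Z_i}, i.e. the sum (or
#' weight-normalised sum) over a gene's SNPs of a per-SNP D/R distance.
#'
#' @slot z length-n numeric score vector, all values >= 0.
#' @slot scoreType one of "IBS", "INCOMP", "AMS", "MM".
#' @slot snpIds identifiers of the SNPs aggregated.
#' @slot weighted whether inverse-MAF (or user) weights were applied.
#' @slot weights per-SNP positive weights (length 0 when unweighted).
#'
#' @name MatchScore-class
#' @rdname MatchScore-class
#' @exportClass MatchScore
setClass("MatchScore",
  slots = c(z = "numeric", scoreType = "character", snpIds = "character",
            weighted = "logical", weights = "numeric")
)

setValidity("MatchScore", function(object) {
  msgs <- character(0)
  if (!(length(object@scoreType) == 1L && object@scoreType %in% .SCORE_TYPES))
    msgs <- c(msgs, "scoreType must be one of IBS, INCOMP, AMS, MM")
  if (any(object@z < -1e-12, na.rm = TRUE))
    msgs <- c(msgs, "score values must be non-negative")
  if (object@weighted) {
    if (length(object@weights) != length(object@snpIds))
      msgs <- c(msgs, "need one weight per SNP")
    if (any(object@weights <= 0))
      msgs <- c(msgs, "weights must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' JSTResult: result of one Joint Score Test
#'
#' @slot statistic the chi-squared test statistic.
#' @slot s number of retained principal components of the recipient-SNP
#'   score covariance.
#' @slot df degrees of freedom (s + 1, or s when the matching score is
#'   degenerate and the test falls back to the recipient-only statistic).
#' @slot pValue upper-tail chi-squared p-value.
#' @slot thresholdUsed variance-explained fraction used to choose s.
#' @slot scoreType matching-score type tested.
#' @slot nSnpsUsed number of SNP columns entering the test after
#'   monomorphic-column removal.
#' @slot droppedSnps identifiers of SNP columns dropped as monomorphic.
#'
#' @name JSTResult-class
#' @rdname JSTResult-class
#' @exportClass JSTResult
setClass("JSTResult",
  slots = c(statistic = "numeric", s = "integer", df = "integer",
            pValue = "numeric", thresholdUsed = "numeric",
            scoreType = "character", nSnpsUsed = "integer",
            droppedSnps = "character")
)

setValidity("JSTResult", function(object) {
  msgs <- character(0)
  if (object@statistic < -1e-8) msgs <- c(msgs, "statistic must be >= 0")
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (object@df < 1L) msgs <- c(msgs, "df must be >= 1")
  if (length(msgs)) msgs else TRUE
})
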