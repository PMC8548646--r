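## Per-SNP donor/recipient distance functions and gene-based matching scores.
##
## Genotypes are minor-allele counts in {0,1,2} at diallelic SNPs. A genotype
## g corresponds to the allele multiset {g copies of the minor allele,
## 2-g copies of the major allele}.

.checkGenoVec <- function(x, what) {
  ok <- x[!is.na(x)]
  if (!all(ok %in% c(0, 1, 2)))
    stop(sprintf("'%s' must contain genotype codes in {0,1,2}", what),
         call. = FALSE)
}

#' Per-SNP donor/recipient distance functions
#'
#' The four single-SNP distances underlying the gene-based matching scores:
#' \describe{
#'   \item{\code{dIbs}}{identity-by-state mismatch, \eqn{|x_D - x_R|}: the
#'     number of allele copies by which the genotypes differ.}
#'   \item{\code{dIncomp}}{incompatibility, the indicator \eqn{x_D \neq x_R}.}
#'   \item{\code{dAms}}{allogenomics mismatch: the number of donor allele
#'     copies whose allele type is absent from the recipient genotype. This
#'     counts alleles the recipient immune system could see as non-self; it
#'     is directional (donor vs recipient).}
#'   \item{\code{dMm}}{binary mismatch, the indicator that the donor carries
#'     any allele type absent from the recipient (\code{dAms > 0}).}
#' }
#' All are vectorized; \code{NA} inputs propagate.
#'
#' @param xDonor,xRecipient minor-allele counts in \{0,1,2\} (equal length).
#' @return Integer vector of distances: \code{dIbs} in \{0,1,2\},
#'   \code{dIncomp} in \{0,1\}, \code{dAms} in \{0,1,2\}, \code{dMm} in \{0,1\}.
#' @examples
#' dIbs(2, 0)      # 2
#' dAms(c(2, 1, 0), c(0, 1, 2))  # 2 0 0
#' @export
dIbs <- function(xDonor, xRecipient) {
  .checkGenoVec(xDonor, "xDonor"); .checkGenoVec(xRecipient, "xRecipient")
  as.integer(abs(xDonor - xRecipient))
}

#' @rdname dIbs
#' @export
dIncomp <- function(xDonor, xRecipient) {
  .checkGenoVec(xDonor, "xDonor"); .checkGenoVec(xRecipient, "xRecipient")
  as.integer(xDonor != xRecipient)
}

#' @rdname dIbs
#' @export
dAms <- function(xDonor, xRecipient) {
  .checkGenoVec(xDonor, "xDonor"); .checkGenoVec(xRecipient, "xRecipient")
  ## heterozygous recipient carries both allele types -> 0 mismatches;
  ## recipient 0 lacks the minor allele (xDonor copies mismatch);
  ## recipient 2 lacks the major allele (2 - xDonor copies mismatch)
  out <- ifelse(xRecipient == 1, 0,
                ifelse(xRecipient == 0, xDonor, 2 - xDonor))
  as.integer(out)
}

#' @rdname dIbs
#' @export
dMm <- function(xDonor, xRecipient) {
  as.integer(dAms(xDonor, xRecipient) > 0)
}

#' Evaluate a per-SNP distance by score type
#'
#' @inheritParams dIbs
#' @param scoreType one of "IBS", "INCOMP", "AMS", "MM".
#' @return Integer vector of per-SNP distances.
#' @export
snpDistance <- function(xDonor, xRecipient,
                        scoreType = c("IBS", "INCOMP", "AMS", "MM")) {
  scoreType <- match.arg(scoreType)
  switch(scoreType,
         IBS = dIbs(xDonor, xRecipient),
         INCOMP = dIncomp(xDonor, xRecipient),
         AMS = dAms(xDonor, xRecipient),
         MM = dMm(xDonor, xRecipient))
}

#' Inverse-MAF weights for a weighted matching score
#'
#' Weights \eqn{w_j = 1 / MAF_j}, computed by default on the pooled
#' donor + recipient sample, upweight rarer SNPs in the weighted gene score.
#'
#' @inheritParams pooledMaf
#' @param maf optional pre-computed per-SNP MAF vector (overrides pooling).
#' @return Positive weight vector, one per SNP.
#' @export
mafWeights <- function(recipient, donor, maf = NULL) {
  maf <- maf %||% pooledMaf(recipient, donor)
  if (any(maf <= 0))
    stop("cannot form 1/MAF weights for monomorphic SNPs", call. = FALSE)
  1 / maf
}

#' Gene-based donor/recipient matching score
#'
#' Aggregates a per-SNP D/R distance over the SNPs of a gene:
#' unweighted, \eqn{Z_i = \sum_j D(x_{ij}^D, x_{ij}^R)}; weighted,
#' \eqn{Z_i = \sum_j w_j D_j / \sum_j w_j} (e.g. \eqn{w_j = 1/MAF_j} from
#' \code{\link{mafWeights}}).
#'
#' Missing genotypes are handled at the distance level: with
#' \code{naAction = "impute"} a pair missing at SNP j contributes the mean
#' distance of complete pairs at j, keeping n constant per gene;
#' \code{naAction = "fail"} errors instead.
#'
#' @param donor,recipient n x m genotype matrices in the same SNP order.
#' @param scoreType one of "IBS", "INCOMP", "AMS", "MM".
#' @param weights optional positive per-SNP weights.
#' @param naAction "impute" (default) or "fail".
#' @return A \linkS4class{MatchScore}.
#' @examples
#' xd <- matrix(c(2, 1, 0), 1, 3)
#' xr <- matrix(0, 1, 3)
#' scoreValues(matchingScore(xd, xr, "IBS"))  # 3
#' @export
matchingScore <- function(donor, recipient,
                          scoreType = c("IBS", "INCOMP", "AMS", "MM"),
                          weights = NULL, naAction = c("impute", "fail")) {
  scoreType <- match.arg(scoreType)
  naAction <- match.arg(naAction)
  donor <- as.matrix(donor); recipient <- as.matrix(recipient)
  if (!identical(dim(donor), dim(recipient)))
    stop("donor and recipient matrices must have identical dimensions",
         call. = FALSE)
  if (!is.null(weights)) {
    if (length(weights) != ncol(donor))
      stop("need one weight per SNP", call. = FALSE)
    if (any(weights <= 0))
      stop("weights must be positive", call. = FALSE)
  }
  D <- matrix(snpDistance(donor, recipient, scoreType),
              nrow = nrow(donor), ncol = ncol(donor))
  if (anyNA(D)) {
    if (naAction == "fail")
      stop("missing genotypes present and naAction = 'fail'", call. = FALSE)
    for (j in which(colSums(is.na(D)) > 0)) {
      cj <- D[, j]
      if (all(is.na(cj)))
        stop(sprintf("SNP column %d has no complete pairs", j), call. = FALSE)
      D[is.na(cj), j] <- mean(cj, na.rm = TRUE)
    }
  }
  z <- if (is.null(weights)) rowSums(D)
       else drop(D %*% weights) / sum(weights)
  ids <- colnames(donor) %||% paste0("snp", seq_len(ncol(donor)))
  new("MatchScore", z = as.numeric(z), scoreType = scoreType,
      snpIds = as.character(ids), weighted = !is.null(weights),
      weights = as.numeric(weights %||% numeric(0)))
}

#' Write per-gene matching scores to a TSV file
#'
#' @param scores named list of \linkS4class{MatchScore} objects (names are
#'   gene ids).
#' @param pairIds pair identifiers, recycled across genes.
#' @param file output path.
#' @return Invisibly, the data.frame written.
#' @export
writeScoreTable <- function(scores, pairIds, file) {
  stopifnot(length(names(scores)) == length(scores))
  tabs <- lapply(names(scores), function(g) {
    ms <- scores[[g]]
    data.frame(pair_id = pairIds, gene_id = g, score_type = ms@scoreType,
               z = ms@z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
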