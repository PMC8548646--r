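## Gene-by-gene analysis driver: harmonized loading of paired genotype
## files (VCF or TSV), MAF filtering, BED region grouping via GenomicRanges,
## per-gene JST (optionally with comparators) and Benjamini-Hochberg FDR.

.readGenoVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    a <- strsplit(g, "[/|]")[[1]]
    if (length(a) != 2L || any(!a %in% c("0", "1")))
      return(NA_real_)
    sum(a == "1")
  })
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- data.frame(id = fx$ID, chrom = fx$CHROM, pos = as.integer(fx$POS),
                     ref = fx$REF, alt = fx$ALT, stringsAsFactors = FALSE)
  multi <- grepl(",", info$alt) | nchar(info$ref) != 1L |
    nchar(info$alt) != 1L
  list(geno = t(counts)[, !multi, drop = FALSE], info = info[!multi, ],
       nMultiDropped = sum(multi))
}

.readGenoTsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(tab[[1]])
  geno <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(geno) <- "double"
  rownames(geno) <- ids
  list(geno = geno,
       info = data.frame(id = colnames(geno), chrom = NA_character_,
                         pos = NA_integer_, ref = NA_character_,
                         alt = NA_character_, stringsAsFactors = FALSE),
       nMultiDropped = 0L)
}

.readGeno <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) .readGenoVcf(path)
  else .readGenoTsv(path)
}

#' Load and harmonize paired donor/recipient data
#'
#' Reads recipient and donor genotypes (VCF with diploid GT, or TSV with a
#' pair-id first column and one column per SNP), covariates and phenotype
#' tables (TSV with a pair-id first column), aligns everything on pair ids,
#' harmonizes donor/recipient allele coding (a donor SNP whose REF/ALT are
#' swapped relative to the recipient file is flipped, with a log record),
#' recodes to minor-allele counts on the pooled sample, imputes residual
#' missing genotypes to the SNP mean and filters SNPs with pooled
#' MAF < \code{mafMin}.
#'
#' @param genoR,genoD paths to the recipient and donor genotype files.
#' @param covar optional path to a covariate TSV (NULL for none).
#' @param pheno path to a phenotype TSV; the first non-id column is the
#'   outcome.
#' @param outcomeType "binary" or "continuous".
#' @param mafMin minimum pooled minor allele frequency (default 0.05).
#' @return A \linkS4class{PairedCohort}; the filtering/flipping log is in
#'   \code{attr(x, "log")}.
#' @export
loadPairedData <- function(genoR, genoD, pheno, covar = NULL,
                           outcomeType = c("binary", "continuous"),
                           mafMin = 0.05) {
  outcomeType <- match.arg(outcomeType)
  log <- character(0)
  R <- .readGeno(genoR)
  D <- .readGeno(genoD)
  if (R$nMultiDropped || D$nMultiDropped)
    log <- c(log, sprintf("multi-allelic/non-SNP records dropped: %d (R), %d (D)",
                          R$nMultiDropped, D$nMultiDropped))
  common <- intersect(R$info$id, D$info$id)
  if (!length(common)) stop("no shared SNP ids between files", call. = FALSE)
  iR <- match(common, R$info$id); iD <- match(common, D$info$id)
  XR <- R$geno[, iR, drop = FALSE]
  XD <- D$geno[, iD, drop = FALSE]
  info <- R$info[iR, ]
  ## allele harmonization between files
  if (!anyNA(R$info$ref)) {
    refR <- R$info$ref[iR]; altR <- R$info$alt[iR]
    refD <- D$info$ref[iD]; altD <- D$info$alt[iD]
    swapped <- which(refR == altD & altR == refD)
    if (length(swapped)) {
      XD[, swapped] <- 2 - XD[, swapped]
      log <- c(log, sprintf("REF/ALT swapped in donor file, flipped: %s",
                            paste(common[swapped], collapse = ",")))
    }
    conflict <- which(!(refR == refD & altR == altD) &
                        !(refR == altD & altR == refD))
    if (length(conflict))
      stop("allele-coding conflict between donor and recipient files for: ",
           paste(common[conflict], collapse = ", "), call. = FALSE)
  }
  ## align pairs
  ph <- utils::read.delim(pheno, check.names = FALSE)
  pairIds <- as.character(ph[[1]])
  for (nm in c("recipient", "donor")) {
    G <- if (nm == "recipient") XR else XD
    missing <- setdiff(pairIds, rownames(G))
    if (length(missing))
      stop(sprintf("%s genotypes missing for pair(s): %s", nm,
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  XR <- XR[pairIds, , drop = FALSE]
  XD <- XD[pairIds, , drop = FALSE]
  Y <- as.numeric(ph[[2]])
  W <- NULL
  if (!is.null(covar)) {
    cv <- utils::read.delim(covar, check.names = FALSE)
    cvIds <- as.character(cv[[1]])
    missing <- setdiff(pairIds, cvIds)
    if (length(missing))
      stop("covariates missing for pair(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    W <- as.matrix(cv[match(pairIds, cvIds), -1, drop = FALSE])
    storage.mode(W) <- "double"
  }
  ## minor-allele recoding on the pooled sample
  pAlt <- colMeans(rbind(XR, XD), na.rm = TRUE) / 2
  flip <- which(pAlt > 0.5)
  if (length(flip)) {
    XR[, flip] <- 2 - XR[, flip]
    XD[, flip] <- 2 - XD[, flip]
    log <- c(log, sprintf("recoded to minor-allele counts: %d SNP(s)",
                          length(flip)))
  }
  ## residual missing genotypes: SNP-mean imputation
  nNA <- sum(is.na(XR)) + sum(is.na(XD))
  if (nNA) {
    imp <- function(G) {
      for (j in which(colSums(is.na(G)) > 0))
        G[is.na(G[, j]), j] <- mean(G[, j], na.rm = TRUE)
      G
    }
    XR <- imp(XR); XD <- imp(XD)
    log <- c(log, sprintf("mean-imputed %d missing genotype call(s)", nNA))
  }
  maf <- pooledMaf(XR, XD)
  keep <- maf >= mafMin
  log <- c(log, sprintf("MAF filter (>= %g): kept %d of %d SNPs", mafMin,
                        sum(keep), length(keep)))
  cohort <- PairedCohort(XR[, keep, drop = FALSE], XD[, keep, drop = FALSE],
                         Y, covariates = W, outcomeType = outcomeType,
                         snpInfo = info[keep, ])
  attr(cohort, "log") <- log
  cohort
}

#' Group SNPs into gene regions
#'
#' Reads BED regions (0-based half-open on disk, converted to 1-based
#' inclusive coordinates) and assigns every SNP to every overlapping region;
#' a SNP at the inclusive end position of a region is included. Regions with
#' no SNPs are skipped and counted.
#'
#' @param snpInfo data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}.
#' @param regions path to a BED file (chrom, start, end, name), or a
#'   data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id} already in 1-based inclusive coordinates.
#' @param flank symmetric flank in bp added around each region (default 0).
#' @return Named list of gene regions, each a list with \code{geneId},
#'   \code{chrom}, \code{start}, \code{end}, \code{snpIndices} (row indices
#'   into \code{snpInfo}); the number of empty regions is in
#'   \code{attr(x, "nEmpty")}.
#' @export
assignGenes <- function(snpInfo, regions, flank = 0L) {
  if (is.character(regions)) {
    bed <- utils::read.table(regions, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 4L) stop("BED file needs chrom,start,end,name columns",
                             call. = FALSE)
    regions <- data.frame(chrom = as.character(bed[[1]]),
                          start = as.integer(bed[[2]]) + 1L,
                          end = as.integer(bed[[3]]),
                          gene_id = as.character(bed[[4]]),
                          stringsAsFactors = FALSE)
  }
  if (any(regions$start > regions$end))
    stop("malformed region: start > end", call. = FALSE)
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(pmax(regions$start - flank, 1L),
                                                regions$end + flank))
  snps <- GenomicRanges::GRanges(snpInfo$chrom,
                                 IRanges::IRanges(snpInfo$pos, snpInfo$pos))
  hits <- GenomicRanges::findOverlaps(gr, snps)
  out <- list()
  nEmpty <- 0L
  for (g in seq_along(gr)) {
    idx <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == g]
    if (!length(idx)) { nEmpty <- nEmpty + 1L; next }
    out[[regions$gene_id[g]]] <-
      list(geneId = regions$gene_id[g], chrom = regions$chrom[g],
           start = regions$start[g], end = regions$end[g],
           snpIndices = sort(idx))
  }
  attr(out, "nEmpty") <- nEmpty
  out
}

#' Gene-by-gene joint score test scan
#'
#' Runs the JST for every gene region and requested score type, optionally
#' alongside the SKAT-style IBS-kernel comparator, and applies
#' Benjamini-Hochberg FDR adjustment across genes within each score type
#' (set \code{bhPooled = TRUE} to pool all score types into one BH family).
#' Per-gene failures are recorded and the scan continues.
#'
#' @param cohort a \linkS4class{PairedCohort} (e.g. from
#'   \code{\link{loadPairedData}}).
#' @param regions gene regions from \code{\link{assignGenes}}.
#' @param scoreRegions optional second region set (same gene ids) giving the
#'   SNPs the matching score is computed from; by default the score uses the
#'   tested gene's SNPs, but the two sets need not coincide.
#' @param scoreTypes character vector of score types to fit.
#' @param threshold variance-explained fraction for s (default 0.85).
#' @param comparators also run the SKAT-style IBS-kernel quadratic test.
#' @param bhPooled pool score types into a single BH adjustment.
#' @return data.frame with one row per gene x score type: \code{gene_id},
#'   \code{n_snps_used}, \code{score_type}, \code{s}, \code{df},
#'   \code{statistic}, \code{p_value}, \code{fdr_q} (plus
#'   \code{skat_ibs_p} when \code{comparators}); failures carry NA
#'   statistics and an \code{error} message column entry.
#' @export
runGenomeScan <- function(cohort, regions, scoreRegions = NULL,
                          scoreTypes = c("IBS", "INCOMP", "AMS", "MM"),
                          threshold = 0.85, comparators = FALSE,
                          bhPooled = FALSE) {
  stopifnot(is(cohort, "PairedCohort"), length(regions) >= 1L)
  W <- if (ncol(covariates(cohort))) covariates(cohort) else NULL
  rows <- list()
  for (g in names(regions)) {
    idx <- regions[[g]]$snpIndices
    scoreIdx <- if (!is.null(scoreRegions) && !is.null(scoreRegions[[g]]))
      scoreRegions[[g]]$snpIndices else idx
    XR <- recipientGeno(cohort)[, idx, drop = FALSE]
    XD <- donorGeno(cohort)[, idx, drop = FALSE]
    XRs <- recipientGeno(cohort)[, scoreIdx, drop = FALSE]
    XDs <- donorGeno(cohort)[, scoreIdx, drop = FALSE]
    sub <- PairedCohort(XR, XD, outcome(cohort), covariates = W,
                        outcomeType = outcomeType(cohort),
                        snpInfo = snpInfo(cohort)[idx, , drop = FALSE])
    skatP <- NA_real_
    if (comparators) {
      skatP <- tryCatch({
        z <- scoreValues(matchingScore(XDs, XRs, "IBS"))
        K <- buildKernel(cbind(XR, score = z), "ibs")
        quadTest(outcome(cohort), W, K, outcomeType(cohort))$pValue
      }, error = function(e) NA_real_)
    }
    for (st in scoreTypes) {
      res <- tryCatch(jstTest(sub, matchingScore(XDs, XRs, st),
                              threshold = threshold),
                      error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
        data.frame(gene_id = g, n_snps_used = NA_integer_, score_type = st,
                   s = NA_integer_, df = NA_integer_,
                   statistic = NA_real_, p_value = NA_real_,
                   skat_ibs_p = skatP, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(gene_id = g, n_snps_used = res@nSnpsUsed,
                   score_type = st, s = res@s, df = res@df,
                   statistic = res@statistic, p_value = res@pValue,
                   skat_ibs_p = skatP, error = NA_character_,
                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_q <- NA_real_
  if (bhPooled) {
    ok <- !is.na(out$p_value)
    out$fdr_q[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  } else {
    for (st in unique(out$score_type)) {
      sel <- out$score_type == st & !is.na(out$p_value)
      out$fdr_q[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
    }
  }
  if (!comparators) out$skat_ibs_p <- NULL
  attr(out, "meta") <- list(threshold = threshold, scoreTypes = scoreTypes,
                            bhPooled = bhPooled,
                            package = as.character(utils::packageVersion("JointScoreTest")))
  out
}
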