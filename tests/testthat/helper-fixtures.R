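# Programmatic VCF / TSV fixtures for pipeline tests.

# Write a minimal diploid VCF for `geno` (pairs x SNPs, alt-allele counts).
writeToyVcf <- function(geno, info, file) {
  samples <- rownames(geno)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gtOf <- function(g) {
    if (is.na(g)) return("./.")
    c("0/0", "0/1", "1/1")[g + 1]
  }
  rows <- vapply(seq_len(ncol(geno)), function(j) {
    paste(c(info$chrom[j], info$pos[j], info$id[j], info$ref[j], info$alt[j],
            ".", "PASS", ".", "GT",
            vapply(geno[, j], gtOf, "")), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), file)
  file
}

# A small paired dataset: nPairs x 5 SNPs, SNP "rare1" below the MAF filter.
makePipelineFixture <- function(dir = tempfile("pipe"), nPairs = 20,
                                swapSnp = NULL, dropDonorPair = NULL,
                                seed = 77) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(nPairs))
  m <- 5
  info <- data.frame(id = paste0("rs", 1:m), chrom = "1",
                     pos = c(150, 250, 260, 400, 520),
                     ref = rep("A", m), alt = rep("G", m),
                     stringsAsFactors = FALSE)
  freq <- c(0.3, 0.4, 0.25, 0.35, 0.0)
  XR <- sapply(freq, function(p) rbinom(nPairs, 2, p))
  XD <- sapply(freq, function(p) rbinom(nPairs, 2, p))
  # make SNP 5 rare: a single alt allele across the pooled sample
  XR[, 5] <- 0; XD[, 5] <- 0; XR[1, 5] <- 1
  rownames(XR) <- rownames(XD) <- ids
  colnames(XR) <- colnames(XD) <- info$id
  infoD <- info
  if (!is.null(swapSnp)) {  # swap REF/ALT in the donor file for one SNP
    j <- match(swapSnp, info$id)
    infoD$ref[j] <- info$alt[j]; infoD$alt[j] <- info$ref[j]
    XD[, j] <- 2 - XD[, j]
  }
  XDout <- XD
  if (!is.null(dropDonorPair)) XDout <- XD[ids != dropDonorPair, ,
                                           drop = FALSE]
  files <- list(
    genoR = writeToyVcf(XR, info, file.path(dir, "recipient.vcf")),
    genoD = writeToyVcf(XDout, infoD, file.path(dir, "donor.vcf")),
    pheno = file.path(dir, "pheno.tsv"),
    covar = file.path(dir, "covar.tsv"),
    bed = file.path(dir, "genes.bed"))
  y <- rbinom(nPairs, 1, 0.4)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  write.table(data.frame(pair_id = ids, y = y), files$pheno, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(pair_id = ids, age = round(rnorm(nPairs, 50, 8)),
                         sex = rbinom(nPairs, 1, 0.5)),
              files$covar, sep = "\t", quote = FALSE, row.names = FALSE)
  # BED is 0-based half-open: geneA covers pos 101..260 inclusive
  writeLines(c("1\t100\t260\tgeneA", "1\t250\t600\tgeneB",
               "2\t0\t1000\tgeneEmpty"), files$bed)
  c(files, list(XR = XR, XD = XD, info = info, y = y, ids = ids))
}
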