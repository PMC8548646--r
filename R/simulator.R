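## Synthetic paired-cohort generator and simulation-study driver.
##
## Genotypes come from a latent-Gaussian threshold haplotype model: each
## haplotype is a vector of allele indicators obtained by thresholding a
## multivariate normal with block-equicorrelation structure at the
## per-SNP quantile of the minor allele frequency; a genotype is the sum of
## two independent haplotypes, so SNPs are in marginal Hardy-Weinberg
## equilibrium and within-block LD is controlled by the latent correlation.

#' Describe a synthetic gene: SNP count, MAFs and block LD structure
#'
#' @param m number of SNPs.
#' @param maf per-SNP minor allele frequencies in [0.05, 0.5] (recycled).
#' @param blockSize number of consecutive SNPs per LD block (last block may
#'   be smaller).
#' @param rho within-block latent haplotype correlation in [0, 1): around
#'   0.8 for high LD, 0.1 for low LD.
#' @return List of class \code{genotypeModel} with elements \code{m},
#'   \code{maf}, \code{blocks} (list of index vectors), \code{rho}.
#' @export
genotypeModel <- function(m, maf, blockSize = 5L, rho = 0.8) {
  maf <- rep_len(maf, m)
  if (any(maf < 0.05 - 1e-9 | maf > 0.5))
    stop("MAFs must lie in [0.05, 0.5]", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  blocks <- split(seq_len(m), (seq_len(m) - 1L) %/% blockSize)
  structure(list(m = as.integer(m), maf = maf, blocks = unname(blocks),
                 rho = rho),
            class = "genotypeModel")
}

#' Bundled gene archetypes for simulation studies
#'
#' Three synthetic gene presets spanning small, medium and large SNP counts
#' (m = 15, 40, 80) with blocks of five SNPs. MAFs are drawn once per preset
#' from Uniform(0.05, 0.5) under a fixed internal seed, so each preset
#' behaves like a fixed gene across sessions. The m values and LD layout are
#' package choices, not estimates of the real genes the names allude to.
#'
#' @param name "NAT2" (m = 15), "CHI3L2" (m = 40) or "ASAH1" (m = 80).
#' @param ld "high" (rho = 0.8) or "low" (rho = 0.1).
#' @return A \code{\link{genotypeModel}}.
#' @export
genePreset <- function(name = c("NAT2", "CHI3L2", "ASAH1"),
                       ld = c("high", "low")) {
  name <- match.arg(name)
  ld <- match.arg(ld)
  m <- switch(name, NAT2 = 15L, CHI3L2 = 40L, ASAH1 = 80L)
  presetSeed <- switch(name, NAT2 = 190801L, CHI3L2 = 190802L,
                       ASAH1 = 190803L)
  maf <- .withLocalSeed(presetSeed, round(stats::runif(m, 0.05, 0.5), 3))
  genotypeModel(m, maf, blockSize = 5L,
                rho = if (ld == "high") 0.8 else 0.1)
}

#' Simulate genotypes under the latent-Gaussian haplotype model
#'
#' @param model a \code{\link{genotypeModel}}.
#' @param n number of individuals.
#' @return n x m matrix of minor-allele counts. Uses the current RNG state;
#'   seed externally for reproducibility.
#' @export
simulateGenotypes <- function(model, n) {
  stopifnot(inherits(model, "genotypeModel"))
  thr <- stats::qnorm(model$maf)
  hap <- function() {
    Z <- matrix(0, n, model$m)
    for (idx in model$blocks) {
      shared <- stats::rnorm(n)
      E <- matrix(stats::rnorm(n * length(idx)), n)
      Z[, idx] <- sqrt(model$rho) * shared + sqrt(1 - model$rho) * E
    }
    sweep(Z, 2, thr, "<") + 0
  }
  G <- hap() + hap()
  colnames(G) <- paste0("snp", seq_len(model$m))
  G
}

#' Simulate paired donor/recipient genotype matrices
#'
#' Draws 2n independent individuals and pairs them: the first n are
#' recipients, the second n donors, so pairs are unrelated by construction.
#'
#' @param model a \code{\link{genotypeModel}}.
#' @param nPairs number of D/R pairs.
#' @return List with matrices \code{recipient} and \code{donor}.
#' @export
simulatePairs <- function(model, nPairs) {
  G <- simulateGenotypes(model, 2L * nPairs)
  list(recipient = G[seq_len(nPairs), , drop = FALSE],
       donor = G[nPairs + seq_len(nPairs), , drop = FALSE])
}

#' Solve the model intercept for a target outcome prevalence
#'
#' Finds \eqn{\alpha_0} such that the sample mean of
#' \eqn{expit(\alpha_0 + lp_i)} equals the target prevalence, by monotone
#' root finding to 1e-6.
#'
#' @param linearPredictor sample of linear-predictor values (without
#'   intercept).
#' @param target prevalence in (0, 1).
#' @return The intercept \eqn{\alpha_0}.
#' @examples
#' solveIntercept(rep(0, 10), 0.10)  # qlogis(0.10)
#' @export
solveIntercept <- function(linearPredictor, target) {
  if (target <= 0 || target >= 1) stop("target must lie in (0,1)",
                                       call. = FALSE)
  f <- function(a) mean(stats::plogis(a + linearPredictor)) - target
  stats::uniroot(f, c(-40, 40), tol = 1e-6)$root
}

## indices of associated SNPs: high LD takes consecutive SNPs walking
## through the blocks in order (so they share blocks); low LD takes one SNP
## per block, cycling
.associatedSnps <- function(model, propAssociated) {
  k <- max(1L, round(propAssociated * model$m))
  if (model$rho >= 0.5) {
    unlist(model$blocks)[seq_len(k)]
  } else {
    maxLen <- max(lengths(model$blocks))
    ord <- unlist(lapply(seq_len(maxLen), function(j) {
      has <- lengths(model$blocks) >= j
      vapply(model$blocks[has], `[`, integer(1), j)
    }))
    ord[seq_len(k)]
  }
}

#' Configuration of one simulation cell
#'
#' @param scenario "null", "recipient_effect" or "score_effect".
#' @param model a \code{\link{genotypeModel}} (default: NAT2-like preset).
#' @param nPairs number of D/R pairs (500 or 1000 in the study design).
#' @param outcomeType "binary" or "continuous".
#' @param prevalence binary-outcome prevalence (0.05-0.20 in the design).
#' @param effectSize per-SNP log odds ratio beta (recipient_effect) or
#'   score coefficient gamma (score_effect); design grid 0.14, 0.41, 0.69.
#' @param propAssociated fraction of the gene's SNPs truly associated
#'   (recipient_effect: 0.05/0.15/0.25; score_effect: 0.05-1).
#' @param scoreType matching-score type used to generate a score effect.
#' @param replicates Monte Carlo replicates.
#' @param alpha nominal test level.
#' @param seed base seed; replicate r uses \code{seedSequence(seed, r)}.
#' @return List of class \code{simStudyConfig}.
#' @export
simStudyConfig <- function(scenario = c("null", "recipient_effect",
                                        "score_effect"),
                           model = genePreset("NAT2"), nPairs = 500L,
                           outcomeType = c("binary", "continuous"),
                           prevalence = 0.10, effectSize = 0,
                           propAssociated = 0.25, scoreType = "IBS",
                           replicates = 2000L, alpha = 0.05, seed = 1L) {
  scenario <- match.arg(scenario)
  outcomeType <- match.arg(outcomeType)
  if (scenario != "null" && effectSize < 0)
    stop("effectSize must be non-negative", call. = FALSE)
  structure(list(scenario = scenario, model = model,
                 nPairs = as.integer(nPairs), outcomeType = outcomeType,
                 prevalence = prevalence, effectSize = effectSize,
                 propAssociated = propAssociated, scoreType = scoreType,
                 replicates = as.integer(replicates), alpha = alpha,
                 seed = as.integer(seed)),
            class = "simStudyConfig")
}

#' Simulate covariates and phenotype for one replicate
#'
#' Covariates are W1 ~ Bernoulli(0.5) and W2 ~ N(0,1). The null linear
#' predictor is 0.5 W1 + 0.5 W2; under "recipient_effect" the associated
#' SNPs add \eqn{X\beta}; under "score_effect" the matching score built
#' from only the associated SNP subset adds \eqn{Z\gamma} (the full-gene
#' score is still what gets tested). For binary outcomes the intercept is
#' solved so the realized prevalence matches the target including any
#' effect terms; continuous outcomes add standard normal noise.
#'
#' @param pairs list with \code{recipient}, \code{donor} matrices.
#' @param config a \code{\link{simStudyConfig}}.
#' @return List with \code{Y}, \code{W}, \code{assoc} (indices of associated
#'   SNPs, if any). Uses the current RNG state.
#' @export
simulatePhenotype <- function(pairs, config) {
  n <- nrow(pairs$recipient)
  W1 <- stats::rbinom(n, 1, 0.5)
  W2 <- stats::rnorm(n)
  W <- cbind(W1 = W1, W2 = W2)
  lp <- 0.5 * W1 + 0.5 * W2
  assoc <- integer(0)
  if (config$scenario != "null" && config$effectSize > 0) {
    assoc <- .associatedSnps(config$model, config$propAssociated)
    if (!length(assoc)) stop("no associated SNPs selected", call. = FALSE)
    if (config$scenario == "recipient_effect") {
      lp <- lp + drop(pairs$recipient[, assoc, drop = FALSE] %*%
                        rep(config$effectSize, length(assoc)))
    } else {
      zGen <- scoreValues(matchingScore(pairs$donor[, assoc, drop = FALSE],
                                        pairs$recipient[, assoc, drop = FALSE],
                                        config$scoreType))
      lp <- lp + config$effectSize * zGen
    }
  }
  if (config$outcomeType == "binary") {
    a0 <- solveIntercept(lp, config$prevalence)
    Y <- stats::rbinom(n, 1, stats::plogis(a0 + lp))
  } else {
    Y <- lp + stats::rnorm(n)
  }
  list(Y = Y, W = W, assoc = assoc)
}

## Evaluate a list of method specifications on one replicate; returns a
## named vector of p-values (NA for counted failures). Method specs:
##   list(method="jst",  score="IBS", threshold=0.65)
##   list(method="skat", score="IBS", kernel="linear"|"ibs", scale01=FALSE)
##   list(method="glm",  score="IBS", variant="lrt"|"score")
.methodLabel <- function(sp) {
  switch(sp$method,
         jst = sprintf("jst_%s_%02.0f", tolower(sp$score),
                       100 * sp$threshold),
         skat = sprintf("skat_%s_%s%s", sp$kernel, tolower(sp$score),
                        if (identical(sp$pmethod, "imhof")) "_imhof" else ""),
         glm = sprintf("glm_%s_%s", sp$variant, tolower(sp$score)))
}

.evalMethods <- function(pairs, pheno, outcomeType, methods) {
  XR <- pairs$recipient
  v <- apply(XR, 2, stats::var)
  XR <- XR[, v > 0, drop = FALSE]
  XD <- pairs$donor[, v > 0, drop = FALSE]
  out <- stats::setNames(rep(NA_real_, length(methods)),
                         vapply(methods, .methodLabel, ""))
  if (ncol(XR) < 1L) return(out)
  fit <- tryCatch(fitNullModel(pheno$Y, pheno$W, outcomeType),
                  error = function(e) NULL)
  if (is.null(fit)) return(out)
  scoreTypes <- unique(vapply(methods, function(sp) sp$score, ""))
  Zs <- lapply(stats::setNames(scoreTypes, scoreTypes), function(st)
    scoreValues(matchingScore(XD, XR, st)))
  needJst <- any(vapply(methods, function(sp) sp$method == "jst", TRUE))
  comps <- list()
  if (needJst) {
    for (st in scoreTypes) {
      B <- cbind(XR, score = Zs[[st]])
      Bres <- residualizeDesign(B, pheno$W, fit$weights)
      comps[[st]] <- scoreComponents(pheno$Y, fit, Bres)
    }
  }
  for (i in seq_along(methods)) {
    sp <- methods[[i]]
    p <- tryCatch({
      if (sp$method == "jst") {
        comp <- comps[[sp$score]]
        red <- eigenReduce(comp$VR, sp$threshold)
        jstStatistic(comp, red)@pValue
      } else if (sp$method == "skat") {
        B <- cbind(XR, score = Zs[[sp$score]])
        K <- buildKernel(B, sp$kernel,
                         scaleScores01 = isTRUE(sp$scale01))
        quadTest(pheno$Y, pheno$W, K, outcomeType,
                 method = sp$pmethod %||% "liu", nullFit = fit)$pValue
      } else {
        B <- cbind(XR, score = Zs[[sp$score]])
        suppressWarnings(glmJointTest(pheno$Y, pheno$W, B, outcomeType,
                                      variant = sp$variant)$pValue)
      }
    }, error = function(e) NA_real_)
    out[i] <- p
  }
  out
}

#' Simulate one null paired cohort as a PairedCohort object
#'
#' Convenience wrapper drawing genotypes, covariates (W1 ~ Bernoulli(0.5),
#' W2 ~ N(0,1)) and a null phenotype at the requested prevalence (binary)
#' or with unit-variance noise (continuous).
#'
#' @param model a \code{\link{genotypeModel}}.
#' @param nPairs number of D/R pairs.
#' @param prevalence binary-outcome prevalence.
#' @param outcomeType "binary" or "continuous".
#' @param seed integer seed.
#' @return A \linkS4class{PairedCohort}.
#' @export
simulateNullCohort <- function(model, nPairs, prevalence = 0.1,
                               outcomeType = c("binary", "continuous"),
                               seed = 1L) {
  outcomeType <- match.arg(outcomeType)
  cfg <- simStudyConfig("null", model = model, nPairs = nPairs,
                        outcomeType = outcomeType, prevalence = prevalence,
                        replicates = 1L, seed = seed)
  set.seed(seedSequence(seed, 1L))
  pairs <- simulatePairs(model, nPairs)
  pheno <- simulatePhenotype(pairs, cfg)
  PairedCohort(pairs$recipient, pairs$donor, pheno$Y,
               covariates = pheno$W, outcomeType = outcomeType)
}

#' Run a type-I error / power simulation study cell
#'
#' Per replicate: simulate a paired cohort and phenotype under the
#' configured scenario, run every requested method, and record p-values.
#' Replicate r is seeded with \code{seedSequence(config$seed, r)}, so any
#' cell is independently reproducible. Method failures (e.g. GLM
#' non-convergence) are counted per method, not silently dropped.
#'
#' @param config a \code{\link{simStudyConfig}}.
#' @param methods list of method specifications, each a list with element
#'   \code{method} ("jst", "skat", "glm"), \code{score} (score type) and
#'   method-specific fields \code{threshold} (jst), \code{kernel} with
#'   optional \code{scale01} and \code{pmethod} ("liu" default or "imhof")
#'   (skat), \code{variant} (glm).
#' @return List of class \code{simStudyResult}: \code{pvalues} (replicates x
#'   methods matrix), \code{rejection} (rate at \code{config$alpha}),
#'   \code{mcse} (binomial Monte-Carlo standard errors), \code{failures},
#'   \code{config}.
#' @examples
#' cfg <- simStudyConfig("null", nPairs = 100, replicates = 20, seed = 3)
#' res <- runSimStudy(cfg, list(list(method = "jst", score = "IBS",
#'                                   threshold = 0.65)))
#' res$rejection
#' @export
runSimStudy <- function(config, methods) {
  stopifnot(inherits(config, "simStudyConfig"), length(methods) >= 1L)
  labels <- vapply(methods, .methodLabel, "")
  P <- matrix(NA_real_, config$replicates, length(methods),
              dimnames = list(NULL, labels))
  for (r in seq_len(config$replicates)) {
    set.seed(seedSequence(config$seed, r))
    pairs <- simulatePairs(config$model, config$nPairs)
    pheno <- simulatePhenotype(pairs, config)
    P[r, ] <- .evalMethods(pairs, pheno, config$outcomeType, methods)
  }
  ok <- colSums(!is.na(P))
  rej <- colMeans(P < config$alpha, na.rm = TRUE)
  structure(list(pvalues = P,
                 rejection = rej,
                 mcse = sqrt(rej * (1 - rej) / pmax(ok, 1)),
                 failures = nrow(P) - ok,
                 config = config),
            class = "simStudyResult")
}
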