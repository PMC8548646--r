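## Core of the joint score test: null covariate-only fit, weighted
## residualization of (X, Z) on the covariates, joint score vector and its
## empirical covariance, eigen reduction of the recipient-SNP block, and the
## chi-squared statistic with s + 1 degrees of freedom.

#' Fit the covariate-only null model
#'
#' Binary outcome: logistic regression of Y on an intercept and the
#' covariates by iteratively reweighted least squares (tolerance 1e-8, at
#' most 100 iterations); returns fitted probabilities \eqn{\hat p_1(W_i)} and
#' the score-test weights \eqn{\hat p_1(1-\hat p_1)}. Continuous outcome:
#' ordinary least squares; unit weights and residual variance
#' RSS / (n - K - 1).
#'
#' @param Y outcome vector.
#' @param W n x K covariate matrix (NULL or zero columns for intercept-only).
#' @param outcomeType "binary" or "continuous".
#' @return A list of class \code{jstNullFit} with elements
#'   \code{fittedMean}, \code{weights}, \code{coefficients},
#'   \code{residualVariance} (continuous only) and \code{outcomeType}.
#' @export
fitNullModel <- function(Y, W = NULL, outcomeType = c("binary", "continuous")) {
  outcomeType <- match.arg(outcomeType)
  Y <- as.numeric(Y)
  n <- length(Y)
  W <- if (is.null(W)) matrix(numeric(0), n, 0) else as.matrix(W)
  D <- cbind(`(Intercept)` = 1, W)
  if (qr(D)$rank < ncol(D))
    stop("covariate matrix is singular (with intercept)", call. = FALSE)
  if (outcomeType == "binary") {
    if (!all(Y %in% c(0, 1)) || length(unique(Y)) < 2L)
      stop("binary outcome must be 0/1 with both classes present",
           call. = FALSE)
    fit <- stats::glm.fit(D, Y, family = stats::binomial(),
                          control = stats::glm.control(epsilon = 1e-8,
                                                       maxit = 100))
    if (!fit$converged)
      stop("logistic null fit did not converge", call. = FALSE)
    mu <- fit$fitted.values
    if (any(mu < 1e-10 | mu > 1 - 1e-10))
      stop("(quasi-)separation in the null logistic fit: fitted probabilities at 0/1",
           call. = FALSE)
    out <- list(fittedMean = mu, weights = mu * (1 - mu),
                coefficients = fit$coefficients,
                residualVariance = NULL, outcomeType = "binary")
  } else {
    fit <- stats::lm.fit(D, Y)
    rss <- sum(fit$residuals^2)
    out <- list(fittedMean = as.numeric(fit$fitted.values),
                weights = rep(1, n),
                coefficients = fit$coefficients,
                residualVariance = rss / (n - ncol(D)),
                outcomeType = "continuous")
  }
  class(out) <- "jstNullFit"
  out
}

#' Residualize genotype and score columns on the covariates
#'
#' Each column of B (the m recipient SNP columns plus the matching-score
#' column) is replaced by its residual from a weighted linear regression on
#' (1, W), with weights \eqn{\hat p_1(1-\hat p_1)} for a binary outcome and
#' unit weights for a continuous one. Every residual column is
#' weight-orthogonal to the intercept and covariates.
#'
#' @param B n x (m+1) matrix of recipient genotypes with the matching score
#'   appended as the last column (any column layout is accepted).
#' @param W n x K covariate matrix (NULL for none).
#' @param weights positive regression weights from the null fit.
#' @return n x ncol(B) matrix of residuals.
#' @export
residualizeDesign <- function(B, W = NULL, weights) {
  B <- as.matrix(B)
  n <- nrow(B)
  W <- if (is.null(W)) matrix(numeric(0), n, 0) else as.matrix(W)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  D <- cbind(1, W)
  sw <- sqrt(weights)
  qrD <- qr(D * sw)
  if (qrD$rank < ncol(D))
    stop("(1, W) is rank deficient", call. = FALSE)
  coef <- qr.coef(qrD, B * sw)
  B - D %*% coef
}

#' Joint score vector and empirical covariance
#'
#' Per-pair score contributions \eqn{Q_{ic} = B^{res}_{ic} (Y_i - \hat\mu_i)},
#' score vector \eqn{U = \sum_i Q_i} (m recipient-SNP components plus one
#' matching-score component) and empirical covariance \eqn{\hat V = Q'Q},
#' with the blocks \eqn{V_R} (SNPs), \eqn{C_{RS}} (SNP-score) and \eqn{V_S}
#' (score) extracted by position.
#'
#' @param Y outcome vector.
#' @param nullFit result of \code{\link{fitNullModel}}.
#' @param Bres residualized design from \code{\link{residualizeDesign}}.
#' @return List of class \code{jstScoreComponents}: \code{U}, \code{Q},
#'   \code{V}, \code{VR}, \code{CRS}, \code{VS}, \code{m}.
#' @export
scoreComponents <- function(Y, nullFit, Bres) {
  stopifnot(inherits(nullFit, "jstNullFit"))
  Bres <- as.matrix(Bres)
  r <- as.numeric(Y) - nullFit$fittedMean
  Q <- Bres * r
  U <- colSums(Q)
  V <- crossprod(Q)
  m <- ncol(Bres) - 1L
  out <- list(U = U, Q = Q, V = V,
              VR = V[seq_len(m), seq_len(m), drop = FALSE],
              CRS = V[seq_len(m), m + 1L],
              VS = V[m + 1L, m + 1L], m = m)
  class(out) <- "jstScoreComponents"
  out
}

#' Eigen reduction of the recipient-SNP score covariance
#'
#' Eigen-decomposes the m x m block \eqn{\hat V_R}, clips numerically
#' negative eigenvalues at zero, discards eigenvalues below 1e-10 times the
#' largest, and retains the smallest s leading components whose cumulative
#' eigenvalue fraction reaches \code{threshold}.
#'
#' @param VR symmetric positive semi-definite matrix.
#' @param threshold fraction of total variance to explain, in (0, 1].
#' @return List of class \code{jstEigenReduction}: \code{As} (m x s
#'   eigenvector matrix), \code{lambdas} (s retained eigenvalues, decreasing),
#'   \code{s}, \code{threshold}, \code{allLambdas}.
#' @export
eigenReduce <- function(VR, threshold) {
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]", call. = FALSE)
  VR <- as.matrix(VR)
  e <- eigen((VR + t(VR)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (lam[1] <= 0)
    stop("V_R has no positive eigenvalues; nothing to decompose",
         call. = FALSE)
  keep <- lam > 1e-10 * lam[1]
  lam <- lam[keep]
  A <- e$vectors[, keep, drop = FALSE]
  cumfrac <- cumsum(lam) / sum(lam)
  s <- which(cumfrac >= threshold - 1e-12)[1]
  out <- list(As = A[, seq_len(s), drop = FALSE], lambdas = lam[seq_len(s)],
              s = as.integer(s), threshold = threshold, allLambdas = lam)
  class(out) <- "jstEigenReduction"
  out
}

#' Joint score test statistic from components and reduction
#'
#' Projects the recipient-SNP score vector onto the retained eigenvectors,
#' \eqn{U^R_{P,l} = a_l' U^R / \sqrt{\lambda_l}} (so each component has unit
#' null variance and the upper-left block of the middle matrix is the
#' identity), appends the matching-score component \eqn{U_S}, and forms
#' \deqn{T = U_P' M^{-1} U_P, \quad
#'       M = [I_s, c; c', \hat{Var}(U_S)], \quad
#'       c_l = a_l' \hat C_{RS} / \sqrt{\lambda_l},}
#' which is chi-squared with s + 1 degrees of freedom under the joint null
#' of no recipient-SNP and no matching-score effect.
#'
#' \code{lambdaScaling = "lambda"} applies the alternative scaling
#' \eqn{a_l' U^R / \lambda_l} (kept for diagnostic comparison; the identity
#' middle block is only correct under the sqrt scaling, which is the
#' default). If the matching score is degenerate after residualization
#' (\eqn{\hat{Var}(U_S) \approx 0}) the test falls back to the
#' recipient-only statistic with s degrees of freedom, with a message.
#'
#' @param components from \code{\link{scoreComponents}}.
#' @param reduction from \code{\link{eigenReduce}}.
#' @param lambdaScaling "sqrt" (default) or "lambda".
#' @param scoreType,nSnpsUsed,droppedSnps metadata carried into the result.
#' @return A \linkS4class{JSTResult}.
#' @export
jstStatistic <- function(components, reduction,
                         lambdaScaling = c("sqrt", "lambda"),
                         scoreType = "IBS", nSnpsUsed = components$m,
                         droppedSnps = character(0)) {
  lambdaScaling <- match.arg(lambdaScaling)
  stopifnot(inherits(components, "jstScoreComponents"),
            inherits(reduction, "jstEigenReduction"))
  m <- components$m
  s <- reduction$s
  sc <- switch(lambdaScaling, sqrt = sqrt(reduction$lambdas),
               lambda = reduction$lambdas)
  UPR <- drop(crossprod(reduction$As, components$U[seq_len(m)])) / sc
  VS <- components$VS
  degenerate <- VS <= .Machine$double.eps^0.5 * max(diag(components$V))
  if (degenerate) {
    message("matching score degenerate after residualization; ",
            "falling back to recipient-only statistic with df = s")
    Tstat <- sum(UPR^2)
    df <- s
  } else {
    cvec <- drop(crossprod(reduction$As, components$CRS)) / sc
    M <- rbind(cbind(diag(s), cvec), c(cvec, VS))
    UP <- c(UPR, components$U[m + 1L])
    sol <- tryCatch(solve(M, UP), error = function(e)
      stop("middle matrix is singular: the matching score is collinear ",
           "with the retained genotype components", call. = FALSE))
    Tstat <- drop(crossprod(UP, sol))
    df <- s + 1L
  }
  new("JSTResult", statistic = as.numeric(Tstat), s = as.integer(s),
      df = as.integer(df),
      pValue = stats::pchisq(Tstat, df = df, lower.tail = FALSE),
      thresholdUsed = reduction$threshold, scoreType = scoreType,
      nSnpsUsed = as.integer(nSnpsUsed),
      droppedSnps = as.character(droppedSnps))
}

#' Joint score test of recipient SNP effects and a D/R matching-score effect
#'
#' End-to-end test of the joint null hypothesis that neither the recipient
#' genotypes of a gene nor the gene-based donor/recipient matching score are
#' associated with the outcome, adjusting for covariates. Monomorphic SNP
#' columns are dropped (and recorded on the result) before testing.
#'
#' @param cohort a \linkS4class{PairedCohort}.
#' @param score a \linkS4class{MatchScore}, or a score-type string
#'   ("IBS", "INCOMP", "AMS", "MM") in which case the unweighted score is
#'   computed from the cohort's donor/recipient genotypes.
#' @param threshold variance-explained fraction for choosing s (default 0.85).
#' @param lambdaScaling see \code{\link{jstStatistic}}.
#' @return A \linkS4class{JSTResult}.
#' @examples
#' model <- genePreset("NAT2")
#' coh <- simulateNullCohort(model, nPairs = 200, prevalence = 0.2, seed = 7)
#' jstTest(coh, "IBS", threshold = 0.65)
#' @export
jstTest <- function(cohort, score = "IBS", threshold = 0.85,
                    lambdaScaling = c("sqrt", "lambda")) {
  stopifnot(is(cohort, "PairedCohort"))
  lambdaScaling <- match.arg(lambdaScaling)
  X <- recipientGeno(cohort)
  if (is.character(score))
    score <- matchingScore(donorGeno(cohort), X, score)
  stopifnot(is(score, "MatchScore"))
  ids <- colnames(X) %||% paste0("snp", seq_len(ncol(X)))
  v <- apply(X, 2, stats::var)
  dropped <- ids[v <= 0]
  if (length(dropped)) X <- X[, v > 0, drop = FALSE]
  if (ncol(X) < 1L)
    stop("no polymorphic SNPs available for testing", call. = FALSE)
  W <- if (ncol(covariates(cohort))) covariates(cohort) else NULL
  fit <- fitNullModel(outcome(cohort), W, outcomeType(cohort))
  B <- cbind(X, score = scoreValues(score))
  Bres <- residualizeDesign(B, W, fit$weights)
  comp <- scoreComponents(outcome(cohort), fit, Bres)
  red <- eigenReduce(comp$VR, threshold)
  jstStatistic(comp, red, lambdaScaling, scoreType = scoreType(score),
               nSnpsUsed = ncol(X), droppedSnps = dropped)
}
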