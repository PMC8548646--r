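## Comparator tests: joint GLM likelihood-ratio / Rao score tests and
## SKAT-style quadratic-form tests with unweighted linear and IBS kernels,
## all taking the same n x (m+1) matrix of recipient genotypes plus the
## gene-based matching score.

.minMaxScale <- function(x, lo, hi) {
  r <- range(x)
  if (diff(r) <= 0) return(rep(lo, length(x)))
  lo + (hi - lo) * (x - r[1]) / diff(r)
}

#' Build a kernel matrix for the quadratic-form test
#'
#' \code{kind = "linear"}: \eqn{K = BB'}; with \code{scaleScores01 = TRUE}
#' the matching-score column is min-max scaled to [0, 1] first (this scaling
#' improves power when the score drives the association). The returned
#' matrix carries the factor B as an attribute so the null distribution can
#' be computed in the low-rank form.
#'
#' \code{kind = "ibs"}: average identity-by-state similarity
#' \eqn{K_{ii'} = \sum_c (2 - |B_{ic} - B_{i'c}|) / (2(m+1))}; non-genotype
#' columns (given by \code{scoreCol}) are min-max scaled to [0, 2] so they
#' enter on the genotype scale. Set \code{scoreCol = NULL} to exclude no
#' column from rescaling, or \code{dropScore = TRUE} to exclude the score
#' column from the kernel entirely.
#'
#' @param B n x (m+1) numeric matrix (recipient genotypes + score column).
#' @param kind "linear" or "ibs".
#' @param scaleScores01 linear kernel only: min-max scale the score column.
#' @param scoreCol index of the matching-score column (default: last).
#' @param dropScore ibs kernel only: drop the score column instead of
#'   rescaling it.
#' @return n x n symmetric PSD kernel matrix.
#' @export
buildKernel <- function(B, kind = c("linear", "ibs"), scaleScores01 = FALSE,
                        scoreCol = ncol(B), dropScore = FALSE) {
  kind <- match.arg(kind)
  B <- as.matrix(B)
  if (any(!is.finite(B))) stop("non-finite entries in B", call. = FALSE)
  if (kind == "linear") {
    if (scaleScores01 && !is.null(scoreCol))
      B[, scoreCol] <- .minMaxScale(B[, scoreCol], 0, 1)
    K <- tcrossprod(B)
    attr(K, "factor") <- B
  } else {
    if (dropScore && !is.null(scoreCol)) {
      B <- B[, -scoreCol, drop = FALSE]
    } else if (!is.null(scoreCol)) {
      B[, scoreCol] <- .minMaxScale(B[, scoreCol], 0, 2)
    }
    p <- ncol(B)
    S <- matrix(0, nrow(B), nrow(B))
    for (c in seq_len(p))
      S <- S + 2 - abs(outer(B[, c], B[, c], "-"))
    K <- S / (2 * p)
  }
  K
}

## Liu et al. moment-matching approximation to P(sum lambda_k chisq1 > q)
.liuPvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    delta <- 0
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  tstar <- (q - muQ) / sigmaQ
  muX <- l + delta; sigmaX <- sqrt(2) * a
  stats::pchisq(tstar * sigmaX + muX, df = l, ncp = delta,
                lower.tail = FALSE)
}

## Imhof-type numerical inversion for the chi-square mixture upper tail
.imhofPvalue <- function(q, lambda) {
  integrand <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(th) / (u * rho)
  }
  val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                          subdivisions = 2000L, stop.on.error = FALSE)$value
  min(max(0.5 + val / pi, 0), 1)
}

#' SKAT-style quadratic-form test
#'
#' Tests the same joint null as the JST with the variance-component
#' statistic \eqn{Q = (Y - \hat\mu)' K (Y - \hat\mu)}, where \eqn{\hat\mu}
#' is the covariate-only null fit. Under the null Q is distributed as a
#' mixture \eqn{\sum_k \lambda_k \chi^2_1}, with \eqn{\lambda_k} the nonzero
#' eigenvalues of the kernel pre- and post-multiplied by the square root of
#' the null residual variance-covariance (projection-adjusted for the
#' estimated covariate coefficients). The p-value is computed by Liu-type
#' moment matching (default, fast) or by Imhof-type numerical inversion of
#' the characteristic function (\code{method = "imhof"}).
#'
#' @param Y outcome vector.
#' @param W covariate matrix (NULL for intercept only).
#' @param K kernel matrix from \code{\link{buildKernel}} (a low-rank factor
#'   attribute, if present, is used for speed).
#' @param outcomeType "binary" or "continuous".
#' @param method "liu" or "imhof".
#' @param nullFit optional pre-computed \code{\link{fitNullModel}} result.
#' @return List of class \code{quadTestResult}: \code{qStat}, \code{pValue},
#'   \code{lambda}, \code{method}.
#' @export
quadTest <- function(Y, W = NULL, K, outcomeType = c("binary", "continuous"),
                     method = c("liu", "imhof"), nullFit = NULL) {
  outcomeType <- match.arg(outcomeType)
  method <- match.arg(method)
  fit <- nullFit %||% fitNullModel(Y, W, outcomeType)
  n <- length(Y)
  r <- as.numeric(Y) - fit$fittedMean
  v <- if (outcomeType == "binary") fit$weights
       else rep(fit$residualVariance, n)
  D <- cbind(1, if (is.null(W)) NULL else as.matrix(W))
  Dt <- D * sqrt(v)
  qrD <- qr(Dt)
  Fac <- attr(K, "factor")
  if (!is.null(Fac)) {
    qStat <- sum(drop(crossprod(Fac, r))^2)
    Vf <- Fac * sqrt(v)
    G <- Vf - Dt %*% qr.coef(qrD, Vf)
    lam <- eigen(crossprod(G), symmetric = TRUE, only.values = TRUE)$values
  } else {
    qStat <- drop(crossprod(r, K %*% r))
    sv <- sqrt(v)
    M0 <- K * tcrossprod(sv)
    HM <- Dt %*% qr.coef(qrD, M0)
    M1 <- M0 - HM - t(HM) + Dt %*% qr.coef(qrD, t(HM))
    lam <- eigen((M1 + t(M1)) / 2, symmetric = TRUE,
                 only.values = TRUE)$values
  }
  lam <- lam[lam > 1e-10 * max(lam, 0)]
  if (!length(lam)) stop("kernel has no variance under the null model",
                         call. = FALSE)
  ## a numerically perfect null fit (residuals ~ 0) carries no evidence
  degenerate <- sum(r^2) <= 1e-16 * max(sum((Y - mean(Y))^2),
                                        .Machine$double.eps)
  p <- if (qStat <= 0 || degenerate) 1
       else switch(method, liu = .liuPvalue(qStat, lam),
                   imhof = .imhofPvalue(qStat, lam))
  structure(list(qStat = qStat, pValue = p, lambda = lam, method = method),
            class = "quadTestResult")
}

#' Joint GLM likelihood-ratio or Rao score test
#'
#' Fits the covariate-only null model and the alternative model with all m
#' recipient SNP columns plus the matching score added, and tests the m + 1
#' added coefficients jointly against a chi-squared distribution with m + 1
#' degrees of freedom, either by the likelihood ratio or by the Rao score
#' statistic evaluated at the null fit.
#'
#' @param Y outcome vector.
#' @param W covariate matrix (NULL for intercept only).
#' @param B n x (m+1) matrix of recipient genotypes plus score column.
#' @param outcomeType "binary" or "continuous".
#' @param variant "lrt" or "score".
#' @return List of class \code{glmJointResult}: \code{statistic}, \code{df},
#'   \code{pValue}, \code{variant}. Rank-deficient alternative designs and
#'   non-convergent fits raise an error of class \code{jstGlmFailure} so
#'   simulation drivers can count failures.
#' @export
glmJointTest <- function(Y, W = NULL, B,
                         outcomeType = c("binary", "continuous"),
                         variant = c("lrt", "score")) {
  outcomeType <- match.arg(outcomeType)
  variant <- match.arg(variant)
  Y <- as.numeric(Y)
  n <- length(Y)
  B <- as.matrix(B)
  W <- if (is.null(W)) matrix(numeric(0), n, 0) else as.matrix(W)
  D0 <- cbind(1, W)
  D1 <- cbind(D0, B)
  .fail <- function(msg) stop(structure(class = c("jstGlmFailure", "error",
                                                  "condition"),
                                        list(message = msg, call = NULL)))
  if (qr(D1)$rank < ncol(D1))
    .fail("alternative design (1, W, B) is rank deficient")
  df <- ncol(B)
  if (outcomeType == "binary" && min(sum(Y == 1), sum(Y == 0)) < ncol(D1))
    warning("few cases relative to the number of fitted coefficients; ",
            "the chi-squared reference may be unreliable", call. = FALSE)
  fam <- if (outcomeType == "binary") stats::binomial() else stats::gaussian()
  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  f0 <- stats::glm.fit(D0, Y, family = fam, control = ctl)
  if (variant == "lrt") {
    f1 <- tryCatch(stats::glm.fit(D1, Y, family = fam, control = ctl),
                   error = function(e) .fail(conditionMessage(e)),
                   warning = function(w) {
                     f <- suppressWarnings(stats::glm.fit(D1, Y, family = fam,
                                                          control = ctl))
                     f
                   })
    if (outcomeType == "binary" && !f1$converged)
      .fail("alternative logistic fit did not converge")
    stat <- if (outcomeType == "binary") f0$deviance - f1$deviance
            else n * log(sum((Y - f0$fitted.values)^2) /
                         sum((Y - f1$fitted.values)^2))
    stat <- max(stat, 0)
  } else {
    mu0 <- f0$fitted.values
    r0 <- Y - mu0
    w0 <- if (outcomeType == "binary") mu0 * (1 - mu0) else rep(1, n)
    U <- drop(crossprod(D1, r0))
    I1 <- crossprod(D1 * sqrt(w0))
    stat <- drop(crossprod(U, solve(I1, U)))
    if (outcomeType == "continuous")
      stat <- stat / (sum(r0^2) / n)
  }
  structure(list(statistic = stat, df = df,
                 pValue = stats::pchisq(stat, df, lower.tail = FALSE),
                 variant = variant),
            class = "glmJointResult")
}
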