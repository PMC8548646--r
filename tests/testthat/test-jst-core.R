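test_that("intercept-only null fits reduce to sample summaries", {
  set.seed(21)
  y <- rbinom(60, 1, 0.4)
  fit <- fitNullModel(y, NULL, "binary")
  expect_equal(unname(fit$fittedMean), rep(mean(y), 60), tolerance = 1e-8)
  expect_true(all(fit$weights > 0 & fit$weights <= 0.25))

  yc <- rnorm(60)
  fitc <- fitNullModel(yc, NULL, "continuous")
  expect_equal(unname(fitc$fittedMean), rep(mean(yc), 60))
  expect_equal(fitc$residualVariance, var(yc))
  expect_equal(fitc$weights, rep(1, 60))
})

test_that("a known intercept recovers the target probability at large n", {
  set.seed(22)
  n <- 20000
  y <- rbinom(n, 1, plogis(qlogis(0.10)))
  fit <- fitNullModel(y, NULL, "binary")
  expect_lt(abs(fit$fittedMean[1] - 0.10), 0.01)
})

test_that("null fit fails informatively on separation and singular W", {
  y <- c(rep(0, 20), rep(1, 20))
  w <- as.numeric(y)  # perfectly separating covariate
  expect_error(fitNullModel(y, cbind(w), "binary"), "separation|converge")
  expect_error(fitNullModel(y, cbind(1, 1)[rep(1, 40), ], "binary"),
               "singular")
})

test_that("residualization matches the brute-force normal-equations solve", {
  set.seed(23)
  n <- 80
  W <- cbind(rbinom(n, 1, 0.5), rnorm(n))
  B <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4), rnorm(n))
  w <- runif(n, 0.05, 0.25)
  got <- residualizeDesign(B, W, w)
  D <- cbind(1, W)
  coef <- solve(t(D) %*% (w * D), t(D) %*% (w * B))
  expect_equal(got, B - D %*% coef, tolerance = 1e-10)
  # weighted orthogonality to (1, W)
  expect_equal(max(abs(t(D) %*% (w * got))), 0, tolerance = 1e-8)
  # intercept-only, unit weights: centering
  expect_equal(residualizeDesign(B, NULL, rep(1, n)),
               scale(B, scale = FALSE), ignore_attr = TRUE)
  # constant column residualizes to zero
  expect_equal(unname(residualizeDesign(cbind(rep(2, n)), W, w)[, 1]),
               rep(0, n), tolerance = 1e-10)
})

test_that("score components reproduce the classic single-SNP score numerator", {
  # 6-pair toy table, no covariates, binary outcome
  x <- c(0, 1, 2, 0, 1, 2)
  y <- c(0, 0, 1, 0, 1, 1)
  z <- c(1, 0, 2, 1, 0, 2)
  fit <- fitNullModel(y, NULL, "binary")
  Bres <- residualizeDesign(cbind(x, z), NULL, fit$weights)
  comp <- scoreComponents(y, fit, Bres)
  expect_equal(comp$U[["x"]], sum((x - mean(x)) * (y - mean(y))))
  expect_equal(comp$U[["z"]], sum((z - mean(z)) * (y - mean(y))))
  expect_equal(comp$V, crossprod(Bres * (y - mean(y))))
  expect_equal(comp$VS, sum(((z - mean(z)) * (y - mean(y)))^2))
})

test_that("a perfect null fit yields zero scores and covariance", {
  n <- 40
  W <- cbind(rnorm(n))
  y <- 2 + 3 * W[, 1]  # exactly linear: continuous residuals are zero
  fit <- fitNullModel(y, W, "continuous")
  Bres <- residualizeDesign(cbind(rbinom(n, 2, 0.3), rnorm(n)), W,
                            fit$weights)
  comp <- scoreComponents(y, fit, Bres)
  expect_equal(max(abs(comp$U)), 0, tolerance = 1e-10)
  expect_equal(max(abs(comp$V)), 0, tolerance = 1e-10)
})

test_that("eigen reduction selects s by cumulative variance", {
  r <- eigenReduce(diag(4), 0.65)
  expect_equal(r$s, 3L)  # equal eigenvalues: 3/4 = 0.75 >= 0.65
  expect_equal(eigenReduce(diag(c(9, 1)), 0.85)$s, 1L)  # 0.90 >= 0.85
  expect_equal(eigenReduce(diag(c(9, 1)), 0.95)$s, 2L)
  # eigenvalues sorted and diagonalization holds
  set.seed(24)
  Q <- matrix(rnorm(200), 40)
  V <- crossprod(Q)
  rr <- eigenReduce(V, 1)
  expect_true(all(diff(rr$lambdas) <= 1e-8))
  expect_equal(t(rr$As) %*% V %*% rr$As, diag(rr$lambdas),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(eigenReduce(matrix(0, 3, 3), 0.65), "eigenvalue")
  expect_error(eigenReduce(diag(3), 1.2), "threshold")
})

test_that("zero score vector gives zero statistic and p-value one", {
  set.seed(25)
  Q <- scale(matrix(rnorm(100), 20), scale = FALSE)  # columns sum to zero
  comp <- structure(list(U = colSums(Q), Q = Q, V = crossprod(Q),
                         VR = crossprod(Q)[1:4, 1:4],
                         CRS = crossprod(Q)[1:4, 5],
                         VS = crossprod(Q)[5, 5], m = 4L),
                    class = "jstScoreComponents")
  res <- jstStatistic(comp, eigenReduce(comp$VR, 0.8))
  expect_equal(res@statistic, 0, tolerance = 1e-12)
  expect_equal(res@pValue, 1)
})

test_that("block-diagonal case splits into recipient and score terms", {
  set.seed(26)
  m <- 4
  Q <- matrix(rnorm(300 * (m + 1)), 300)
  # orthogonalize the score column against the SNP columns so C_RS = 0
  Q[, m + 1] <- residuals(lm(Q[, m + 1] ~ Q[, 1:m] - 1))
  comp <- structure(list(U = colSums(Q) + c(rnorm(m), 1), Q = Q,
                         V = crossprod(Q)), class = "jstScoreComponents")
  comp$VR <- comp$V[1:m, 1:m]; comp$CRS <- comp$V[1:m, m + 1]
  comp$VS <- comp$V[m + 1, m + 1]; comp$m <- m
  res <- jstStatistic(comp, eigenReduce(comp$VR, 1))
  oracle <- drop(t(comp$U[1:m]) %*% solve(comp$VR, comp$U[1:m])) +
    comp$U[m + 1]^2 / comp$VS
  expect_equal(res@statistic, oracle, tolerance = 1e-6)
})

test_that("full-rank JST equals the Hotelling statistic against a direct inverse", {
  for (seed in c(31, 32, 33, 34, 35)) {
    coh <- makeToyCohort(n = 150, m = 6, seed = seed)
    fit <- fitNullModel(outcome(coh), covariates(coh), "binary")
    z <- scoreValues(matchingScore(donorGeno(coh), recipientGeno(coh), "IBS"))
    B <- cbind(recipientGeno(coh), z)
    Bres <- residualizeDesign(B, covariates(coh), fit$weights)
    comp <- scoreComponents(outcome(coh), fit, Bres)
    hotelling <- drop(t(comp$U) %*% solve(comp$V, comp$U))
    res <- jstStatistic(comp, eigenReduce(comp$VR, 1))
    expect_equal(res@statistic, hotelling, tolerance = 1e-8)
    expect_equal(res@df, comp$m + 1L)
  }
})

test_that("statistic is invariant to rescaling a column at full rank", {
  coh <- makeToyCohort(n = 120, m = 5, seed = 36)
  fit <- fitNullModel(outcome(coh), covariates(coh), "binary")
  z <- scoreValues(matchingScore(donorGeno(coh), recipientGeno(coh), "AMS"))
  B <- cbind(recipientGeno(coh), z)
  run <- function(B) {
    Bres <- residualizeDesign(B, covariates(coh), fit$weights)
    comp <- scoreComponents(outcome(coh), fit, Bres)
    jstStatistic(comp, eigenReduce(comp$VR, 1))@statistic
  }
  B2 <- B; B2[, 2] <- B2[, 2] * 7.3
  expect_equal(run(B), run(B2), tolerance = 1e-8)
})

test_that("continuous intercept-only scores reduce to centered cross-products", {
  coh <- makeToyCohort(n = 100, m = 4, outcomeType = "continuous", seed = 37)
  y <- outcome(coh)
  X <- recipientGeno(coh)
  fit <- fitNullModel(y, NULL, "continuous")
  z <- scoreValues(matchingScore(donorGeno(coh), X, "IBS"))
  Bres <- residualizeDesign(cbind(X, z), NULL, fit$weights)
  comp <- scoreComponents(y, fit, Bres)
  for (j in 1:4)
    expect_equal(unname(comp$U[j]),
                 sum((X[, j] - mean(X[, j])) * (y - mean(y))),
                 tolerance = 1e-10)
})

test_that("end-to-end jstTest is deterministic, drops monomorphic SNPs, and is stable under duplication", {
  coh <- makeToyCohort(n = 200, m = 6, seed = 38)
  r1 <- jstTest(coh, "IBS", 0.85)
  r2 <- jstTest(coh, "IBS", 0.85)
  expect_equal(r1@statistic, r2@statistic)
  expect_equal(r1@pValue, r2@pValue)

  # add a monomorphic SNP: dropped and recorded, result unchanged
  XR <- cbind(recipientGeno(coh), mono = 0)
  XD <- cbind(donorGeno(coh), mono = 0)
  coh2 <- PairedCohort(XR, XD, outcome(coh), covariates(coh), "binary")
  r3 <- jstTest(coh2, "IBS", 0.85)
  expect_equal(r3@droppedSnps, "mono")
  expect_equal(r3@statistic, r1@statistic, tolerance = 1e-10)

  # duplicating every pair leaves the null fit and score direction unchanged
  dup <- PairedCohort(rbind(recipientGeno(coh), recipientGeno(coh)),
                      rbind(donorGeno(coh), donorGeno(coh)),
                      rep(outcome(coh), 2),
                      rbind(covariates(coh), covariates(coh)), "binary")
  fit1 <- fitNullModel(outcome(coh), covariates(coh), "binary")
  fit2 <- fitNullModel(outcome(dup), covariates(dup), "binary")
  expect_equal(fit2$fittedMean[1:200], fit1$fittedMean, tolerance = 1e-6)
})

test_that("a degenerate matching score falls back to the recipient-only statistic", {
  coh <- makeToyCohort(n = 150, m = 5, seed = 39)
  z <- new("MatchScore", z = rep(1, 150), scoreType = "IBS",
           snpIds = "s", weighted = FALSE, weights = numeric(0))
  expect_message(res <- jstTest(coh, z, 0.85), "degenerate")
  expect_equal(res@df, res@s)
})
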