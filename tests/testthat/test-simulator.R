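test_that("genotype model and presets validate their inputs", {
  expect_error(genotypeModel(4, maf = 0.01), "MAF")
  expect_error(genotypeModel(4, maf = 0.2, rho = 1), "rho")
  m <- genePreset("NAT2")
  expect_equal(m$m, 15L)
  expect_equal(lengths(m$blocks), rep(5L, 3))
  expect_equal(genePreset("CHI3L2")$m, 40L)
  expect_equal(genePreset("ASAH1", ld = "low")$rho, 0.1)
  # preset MAFs are fixed across calls and unaffected by the caller's RNG
  set.seed(1); a <- genePreset("NAT2")$maf
  set.seed(999); b <- genePreset("NAT2")$maf
  expect_identical(a, b)
  expect_true(all(a >= 0.05 & a <= 0.5))
})

test_that("simulated genotypes have the right margins and LD", {
  model <- genotypeModel(6, maf = 0.3, blockSize = 2L, rho = 0)
  set.seed(61)
  G <- simulateGenotypes(model, 20000)
  expect_true(all(G %in% 0:2))
  # mean genotype is 2*MAF
  expect_equal(unname(colMeans(G)), rep(0.6, 6), tolerance = 0.02)
  # Hardy-Weinberg heterozygosity 2p(1-p)
  expect_equal(mean(G[, 1] == 1), 2 * 0.3 * 0.7, tolerance = 0.02)
  # rho = 0: no correlation, within or between blocks
  cc <- cor(G)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.03)
})

test_that("block correlation matches the bivariate-normal orthant oracle", {
  maf <- 0.3; rho <- 0.8
  model <- genotypeModel(2, maf = maf, blockSize = 2L, rho = rho)
  set.seed(62)
  G <- simulateGenotypes(model, 40000)
  t0 <- qnorm(maf)
  # P(Z1 <= t0, Z2 <= t0) for correlation rho by numerical integration
  p11 <- integrate(function(z)
    dnorm(z) * pnorm((t0 - rho * z) / sqrt(1 - rho^2)),
    -Inf, t0)$value
  oracleCor <- (p11 - maf^2) / (maf * (1 - maf))
  expect_equal(cor(G[, 1], G[, 2]), oracleCor, tolerance = 0.02)
})

test_that("donor/recipient pairs are independent and reproducible", {
  model <- genePreset("NAT2")
  set.seed(63)
  p1 <- simulatePairs(model, 500)
  expect_equal(dim(p1$recipient), c(500, 15))
  expect_equal(dim(p1$donor), c(500, 15))
  cors <- mapply(function(j) cor(p1$recipient[, j], p1$donor[, j]), 1:15)
  expect_lt(max(abs(cors)), 0.12)
  set.seed(63)
  p2 <- simulatePairs(model, 500)
  expect_identical(p1, p2)
})

test_that("the intercept solver hits the target prevalence", {
  expect_equal(solveIntercept(rep(0, 10), 0.5), 0, tolerance = 1e-6)
  expect_equal(solveIntercept(rep(0, 10), 0.10), qlogis(0.10),
               tolerance = 1e-5)
  set.seed(64)
  lp <- 0.5 * rbinom(1e5, 1, 0.5) + 0.5 * rnorm(1e5)
  a0 <- solveIntercept(lp, 0.10)
  y <- rbinom(1e5, 1, plogis(a0 + lp))
  expect_equal(mean(y), 0.10, tolerance = 0.005)
  expect_error(solveIntercept(lp, 1.5), "target")
})

test_that("zero effect size reduces the alternative generators to the null", {
  model <- genePreset("NAT2")
  cfgs <- list(simStudyConfig("null", model = model, nPairs = 100, seed = 9),
               simStudyConfig("recipient_effect", model = model, nPairs = 100,
                              effectSize = 0, seed = 9),
               simStudyConfig("score_effect", model = model, nPairs = 100,
                              effectSize = 0, seed = 9))
  ys <- lapply(cfgs, function(cfg) {
    set.seed(1234)
    pairs <- simulatePairs(model, 100)
    simulatePhenotype(pairs, cfg)$Y
  })
  expect_identical(ys[[1]], ys[[2]])
  expect_identical(ys[[1]], ys[[3]])
})

test_that("associated SNP selection follows the LD design", {
  high <- genePreset("NAT2", ld = "high")
  low <- genePreset("NAT2", ld = "low")
  ih <- JointScoreTest:::.associatedSnps(high, 0.25)  # 4 SNPs
  expect_true(all(ih %in% high$blocks[[1]]))
  il <- JointScoreTest:::.associatedSnps(low, 0.2)    # 3 SNPs
  expect_equal(length(il), 3)
  blockOf <- function(i) which(vapply(low$blocks, function(b) i %in% b, TRUE))
  expect_equal(length(unique(vapply(il, blockOf, 1L))), 3)
})

test_that("the study driver is deterministic and handles single replicates", {
  cfg <- simStudyConfig("null", model = genePreset("NAT2"), nPairs = 80,
                        replicates = 3, seed = 17)
  methods <- list(list(method = "jst", score = "IBS", threshold = 0.65))
  r1 <- runSimStudy(cfg, methods)
  r2 <- runSimStudy(cfg, methods)
  expect_identical(r1$pvalues, r2$pvalues)
  cfg1 <- simStudyConfig("null", model = genePreset("NAT2"), nPairs = 80,
                         replicates = 1, seed = 18)
  r3 <- runSimStudy(cfg1, methods)
  expect_true(r3$rejection %in% c(0, 1))
  expect_equal(unname(r3$mcse), 0)
})
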