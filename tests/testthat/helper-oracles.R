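# Independent brute-force oracles used across test files.

# allele multiset of a diallelic genotype coded as minor-allele count
alleleMultiset <- function(g) c(rep("minor", g), rep("major", 2 - g))

# set/multiset-based distance definitions, evaluated literally
oracleDistance <- function(xd, xr, type) {
  Sd <- alleleMultiset(xd)
  Sr <- alleleMultiset(xr)
  switch(type,
    IBS    = abs(xd - xr),
    INCOMP = as.integer(xd != xr),
    AMS    = sum(vapply(Sd, function(a) !(a %in% Sr), logical(1))),
    MM     = as.integer(any(!Sd %in% Sr))
  )
}

# 3x3 distance table, donor rows 0/1/2 x recipient cols 0/1/2
oracleTable <- function(type) {
  outer(0:2, 0:2, Vectorize(function(d, r) oracleDistance(d, r, type)))
}

# Benjamini-Hochberg step-up computed literally from the definition
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  adj <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest down
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  q[o] <- pmin(adj, 1)
  q
}

# small simulated cohort for core tests
makeToyCohort <- function(n = 150, m = 6, rho = 0.3, prevalence = 0.3,
                          outcomeType = "binary", seed = 42) {
  model <- genotypeModel(m, maf = seq(0.15, 0.45, length.out = m),
                         blockSize = 3L, rho = rho)
  simulateNullCohort(model, n, prevalence, outcomeType, seed = seed)
}
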