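`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic child seed for a replicate
#'
#' Maps a base seed and a replicate index to an integer seed below 2^31,
#' so any replicate of a simulation study can be regenerated in isolation.
#'
#' @param seed integer base seed.
#' @param index non-negative replicate index.
#' @return A single integer seed.
#' @export
seedSequence <- function(seed, index) {
  ## Weyl-style mixing in double arithmetic; exact for these magnitudes
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  v <- (s * 48271 + as.numeric(index) * 16807 + 12345) %% m
  as.integer(v) + 1L
}

## run expr with a private RNG stream, restoring the caller's state
.withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pooled minor allele frequencies for a donor/recipient SNP panel
#'
#' MAF is computed from the pooled donor + recipient allele counts so that the
#' same allele is "minor" in both members of a pair.
#'
#' @param recipient,donor genotype matrices (minor/alt-allele counts 0/1/2).
#' @return Numeric vector of per-SNP minor allele frequencies in [0, 0.5].
#' @export
pooledMaf <- function(recipient, donor) {
  p <- colMeans(rbind(recipient, donor), na.rm = TRUE) / 2
  pmin(p, 1 - p)
}
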