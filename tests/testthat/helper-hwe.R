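# Exhaustive enumeration oracle for the biallelic Hardy-Weinberg exact test:
# all genotype tables consistent with the observed allele counts, conditional
# probabilities in closed form.
hwe_enum_biallelic <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  mA <- 2L * nAA + nAB
  if (mA == 0L || mA == 2L * n) return(1)
  habs <- seq(mA %% 2L, min(mA, 2L * n - mA), by = 2L)
  logp <- vapply(habs, function(h) {
    aa <- (mA - h) / 2; bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(mA) + lfactorial(2 * n - mA) - lfactorial(2 * n)
  }, 0)
  p <- exp(logp)
  stopifnot(abs(sum(p) - 1) < 1e-9)
  obs <- p[match(nAB, habs)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# genotype matrix for given biallelic counts
geno_from_counts <- function(nAA, nAB, nBB, alleles = c("A*01:01", "A*02:01")) {
  rbind(
    matrix(rep(alleles[1], 2 * nAA), ncol = 2),
    matrix(rep(alleles, nAB), ncol = 2, byrow = TRUE),
    matrix(rep(alleles[2], 2 * nBB), ncol = 2))
}
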