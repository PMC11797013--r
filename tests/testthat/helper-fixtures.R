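# shared fixtures built in code

# two- and three-allele sets used across the operation tests
two_alleles <- function(c = 1) {
  allele_set(labels = c("drive", "wild"), susceptibility = c(0, c))
}
three_alleles <- function(c = 1, r = 0) {
  allele_set(susceptibility = c(0, c, r))
}

# split symmetric genotype matrix from homozygote masses and the full
# heterozygote mass of the (1,2) pair, written out by hand so the genotype
# construction is independent of form_zygotes()
G2 <- function(g11, het, g22) {
  matrix(c(g11, het / 2, het / 2, g22), 2, 2)
}

# heavyweight Monte Carlo batches reused by several acceptance checks;
# computed once per test run
.mc_cache <- new.env(parent = emptyenv())

acceptance_batch <- function(timing) {
  if (is.null(.mc_cache[[timing]]))
    .mc_cache[[timing]] <- run_monte_carlo(5000, timing, seed = 20240601)
  .mc_cache[[timing]]
}

acceptance_balanced <- function() {
  if (is.null(.mc_cache$balanced))
    .mc_cache$balanced <- balanced_sample(2000, "prezygotic",
                                          seed = 20240602,
                                          max_attempts = 1e6)
  .mc_cache$balanced
}

# percentage tolerance: 3 binomial standard errors at n draws around rate p
# (percent scale)
three_se_pct <- function(p_pct, n) 3 * sqrt(p_pct / 100 * (1 - p_pct / 100) / n) * 100
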