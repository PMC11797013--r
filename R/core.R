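## Per-generation life-cycle operations.
##
## The genotype state G is the K x K outer-product matrix: each unordered
## heterozygote's mass is split across the two symmetric off-diagonal cells,
## so sum(G) == 1, the full heterozygote frequency of pair (i, j) is
## 2 * G[i, j], and collapsing back to allele frequencies is rowSums(G).
##
## Arithmetic and RNG call order here mirror src/sim.cpp cell for cell, so
## that the "r" and "cpp" engines of simulate_drive() produce identical
## trajectories from identical seeds.

#' Form diploid zygote frequencies from allele frequencies
#'
#' Random union of gametes under Hardy-Weinberg proportions, allowing an
#' inbreeding excess of homozygosity: homozygote mass
#' \eqn{G_{ii} = p_i^2 + F p_i (1 - p_i)} and full heterozygote mass
#' \eqn{2 (1 - F) p_i p_j}. For two alleles this is the textbook
#' \eqn{p^2 + Fpq, \; 2pq(1-F), \; q^2 + Fpq}; the homozygote excess
#' \eqn{F p_i (1 - p_i)} is the standard multi-allele generalization.
#'
#' @param p Numeric vector of allele frequencies (must sum to 1).
#' @param inbreeding Inbreeding coefficient `F` in \[0, 1\].
#' @return A symmetric genotype matrix `G` with `sum(G) == 1`; each unordered
#'   heterozygote's mass is split across its two symmetric cells.
#' @examples
#' form_zygotes(c(0.5, 0.5), inbreeding = 0)
#' form_zygotes(c(0.5, 0.5), inbreeding = 1)   # no heterozygotes
#' @export
form_zygotes <- function(p, inbreeding = 0) {
  check_freqs(p)
  if (!is.numeric(inbreeding) || length(inbreeding) != 1 ||
      !is.finite(inbreeding) || inbreeding < 0 || inbreeding > 1)
    stop("`inbreeding` must be a single number in [0, 1]", call. = FALSE)
  G <- (1 - inbreeding) * outer(p, p)
  diag(G) <- p^2 + inbreeding * p * (1 - p)
  G
}

#' Homing conversion of susceptible alleles in drive heterozygotes
#'
#' In each genotype pairing the drive allele with a susceptible allele `j`
#' (full heterozygote frequency `H`), a mass
#' \eqn{\Delta G = x / n, \; x \sim \mathrm{Binomial}(n, c_j H)} is converted
#' to drive homozygotes (stochastic mode; the draw is clamped to the
#' available heterozygote mass). Deterministic mode propagates the
#' expectation \eqn{\Delta G = c_j H}. Genotypes without a drive allele are
#' untouched; total genotype mass is conserved.
#'
#' Stochastic draws consume the R random number stream; call [set.seed()]
#' beforehand for reproducibility.
#'
#' @param G Genotype matrix as returned by [form_zygotes()].
#' @param alleles An [allele_set()] giving per-allele susceptibilities.
#' @param pop_size Population size `n` used as the binomial trial count.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return The genotype matrix after conversion.
#' @examples
#' G <- form_zygotes(c(0.3, 0.7), inbreeding = 0)
#' a <- allele_set(labels = c("drive", "wild"), susceptibility = c(0, 1))
#' convert_heterozygotes(G, a, pop_size = 1e6, mode = "deterministic")
#' @export
convert_heterozygotes <- function(G, alleles, pop_size = 1e6,
                                  mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  check_genotypes(G)
  stopifnot(inherits(alleles, "allele_set"),
            nrow(G) == length(alleles$labels))
  if (!is.numeric(pop_size) || length(pop_size) != 1 || pop_size < 1)
    stop("`pop_size` must be >= 1", call. = FALSE)
  stochastic <- mode == "stochastic"
  n <- pop_size
  d <- alleles$drive
  susc <- alleles$susceptibility
  for (j in setdiff(seq_len(nrow(G)), d)) {
    cj <- susc[[j]]
    h <- 2 * G[d, j]
    if (cj > 0 && h > 0) {
      prob <- cj * h
      dH <- if (stochastic) rbinom(1, n, prob) / n else prob
      if (dH > h) dH <- h
      half <- dH / 2
      G[d, j] <- G[d, j] - half
      G[j, d] <- G[j, d] - half
      G[d, d] <- G[d, d] + dH
    }
  }
  G
}

# mass removed from one drive-carrying genotype class of frequency g
# (full heterozygote frequency for heterozygotes)
selection_removed <- function(g, d_eff, fitness_cost, exposure, n, stochastic) {
  if (stochastic) {
    trials <- round(exposure * g * n)
    prob <- d_eff * fitness_cost
    if (trials >= 1 && prob > 0) rbinom(1, trials, prob) / n else 0
  } else {
    exposure * g * d_eff * fitness_cost
  }
}

#' Selection against drive-carrying genotypes
#'
#' Genotypes carrying no drive allele have fitness 1 and are untouched. For a
#' drive-carrying genotype of frequency `G` the exposed trial count is
#' `round(e * G * n)` and the killed mass is
#' \eqn{x / n, \; x \sim \mathrm{Binomial}(\mathrm{round}(e G n),
#' d_{\mathrm{eff}} s)}, where the effective dominance weight
#' \eqn{d_{\mathrm{eff}}} is `d` for any genotype heterozygous for the drive
#' (including drive/resistant) and 1 for the drive homozygote. Deterministic
#' mode removes the expectation \eqn{e G d_{\mathrm{eff}} s}. After removal,
#' all genotype frequencies are rescaled to sum to 1.
#'
#' Drawing the killed mass with probability \eqn{d_{\mathrm{eff}} s} is
#' distributionally identical to drawing survivors with probability
#' \eqn{1 - d_{\mathrm{eff}} s} and subtracting the complement.
#'
#' @inheritParams convert_heterozygotes
#' @param fitness_cost Selection coefficient `s` in \[0, 1\].
#' @param exposure Exposed fraction `e` in \[0, 1\].
#' @param dominance Dominance `d` in \[0, 1\] of the cost in heterozygotes.
#' @return The rescaled genotype matrix after selection.
#' @examples
#' a <- allele_set(labels = c("drive", "wild"), susceptibility = c(0, 0.9))
#' G <- form_zygotes(c(0.3, 0.7), inbreeding = 0)
#' # recessive lethal: only drive homozygotes are removed
#' apply_selection(G, a, fitness_cost = 1, exposure = 1, dominance = 0,
#'                 mode = "deterministic")
#' @export
apply_selection <- function(G, alleles, fitness_cost, exposure, dominance,
                            pop_size = 1e6,
                            mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  check_genotypes(G)
  stopifnot(inherits(alleles, "allele_set"),
            nrow(G) == length(alleles$labels))
  for (nm in c("fitness_cost", "exposure", "dominance")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
      stop("`", nm, "` must be a single number in [0, 1]", call. = FALSE)
  }
  stochastic <- mode == "stochastic"
  n <- pop_size
  d <- alleles$drive
  g <- G[d, d]
  rem <- selection_removed(g, 1, fitness_cost, exposure, n, stochastic)
  if (rem > g) rem <- g
  G[d, d] <- g - rem
  for (j in setdiff(seq_len(nrow(G)), d)) {
    h <- 2 * G[d, j]
    if (h > 0) {
      remh <- selection_removed(h, dominance, fitness_cost, exposure, n,
                                stochastic)
      if (remh > h) remh <- h
      half <- remh / 2
      G[d, j] <- G[d, j] - half
      G[j, d] <- G[j, d] - half
    }
  }
  G / sum(G)
}

#' Collapse genotype frequencies to allele frequencies
#'
#' The marginal frequency of allele `i` is its homozygote mass plus half of
#' every heterozygote mass involving it; with the split symmetric storage
#' used here this is simply the row sum of the genotype matrix.
#'
#' @param G Genotype matrix as returned by [form_zygotes()].
#' @return Numeric vector of allele frequencies summing to 1.
#' @examples
#' genotypes_to_alleles(form_zygotes(c(0.5, 0.5), 0))
#' @export
genotypes_to_alleles <- function(G) {
  check_genotypes(G)
  rowSums(G)
}

#' Wright-Fisher genetic drift on the gamete pool
#'
#' Stochastic mode resamples each allele independently as
#' \eqn{p_i' = x_i / 2n, \; x_i \sim \mathrm{Binomial}(2n, p_i)} and then
#' renormalizes the vector to sum to 1 (the independent draws do not sum to 1
#' by themselves); with `method = "multinomial"` a single multinomial draw of
#' the `2n` gametes is used instead, which sums to `2n` by construction.
#' Alleles at frequency exactly 0 or 1 are not resampled (they are absorbing
#' states). Deterministic mode is the identity.
#'
#' @param p Numeric vector of allele frequencies (sums to 1).
#' @param pop_size Diploid population size `n`; `2n` gametes are sampled.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param method `"binomial"` (per-allele draws, renormalized) or
#'   `"multinomial"`.
#' @param renormalize If `FALSE` (binomial method only), return the raw
#'   `x / 2n` draws without renormalization; useful for checking the
#'   binomial moments \eqn{E[p'] = p}, \eqn{Var[p'] = p(1-p)/2n}.
#' @return Post-drift allele frequency vector.
#' @examples
#' set.seed(1)
#' apply_drift(c(0.5, 0.5), pop_size = 1e6)
#' @export
apply_drift <- function(p, pop_size = 1e6,
                        mode = c("stochastic", "deterministic"),
                        method = c("binomial", "multinomial"),
                        renormalize = TRUE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  check_freqs(p)
  if (!is.numeric(pop_size) || length(pop_size) != 1 || pop_size < 1)
    stop("`pop_size` must be >= 1", call. = FALSE)
  if (mode == "deterministic") return(p)
  n <- pop_size
  K <- length(p)
  if (method == "multinomial") {
    x <- rmultinom(1, 2 * n, p)[, 1]
    pp <- x / (2 * n)
  } else {
    x <- numeric(K)
    for (i in seq_len(K))
      x[i] <- if (p[i] > 0 && p[i] < 1) rbinom(1, 2 * n, p[i]) else p[i] * (2 * n)
    pp <- x / (2 * n)
    if (!renormalize) return(pp)
  }
  tot <- sum(pp)
  if (tot > 0) pp / tot else p
}

#' Advance one generation of the gene drive life cycle
#'
#' Executes, in order: zygote formation, (post-zygotic: homing conversion),
#' selection, (prezygotic: homing conversion), collapse to allele
#' frequencies, genetic drift. In a prezygotic drive homing happens during
#' gametogenesis, i.e. after selection has acted on the parents; in a
#' post-zygotic drive the newly formed zygotes are converted before selection
#' acts on them, so surviving drive carriers are homozygous.
#'
#' @param p Allele frequency vector `(drive, wild, resistant)` (or matching
#'   the scenario's allele set).
#' @param scenario A [drive_scenario()].
#' @return The next generation's allele frequency vector.
#' @examples
#' sc <- drive_scenario(conversion = 1, mode = "deterministic")
#' step_generation(c(0.001, 0.999, 0), sc)  # drive frequency 2p - p^2
#' @export
step_generation <- function(p, scenario) {
  stopifnot(inherits(scenario, "drive_scenario"))
  check_freqs(p)
  G <- form_zygotes(p, scenario$inbreeding)
  if (scenario$timing == "postzygotic")
    G <- convert_heterozygotes(G, scenario$alleles, scenario$pop_size,
                               scenario$mode)
  G <- apply_selection(G, scenario$alleles, scenario$fitness_cost,
                       scenario$exposure, scenario$dominance,
                       scenario$pop_size, scenario$mode)
  if (scenario$timing == "prezygotic")
    G <- convert_heterozygotes(G, scenario$alleles, scenario$pop_size,
                               scenario$mode)
  p <- genotypes_to_alleles(G)
  apply_drift(p, scenario$pop_size, scenario$mode, scenario$drift_method)
}
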