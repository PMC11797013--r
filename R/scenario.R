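#' Specify a gene drive release scenario
#'
#' A scenario bundles the seven design variables of the homing drive model
#' with the run settings. All rates are per generation and unitless.
#'
#' @param conversion Conversion efficiency `c` in \[0, 1\]: probability that
#'   the drive converts a wild-type allele in a drive/wild heterozygote.
#' @param resistance_level Conversion rate `R` of the drive acting on the
#'   resistant allele, in \[0, `conversion`\]; `0` means the resistant allele
#'   is fully immune to homing.
#' @param resistance_frequency Initial frequency of the resistant allele, in
#'   \[0, 0.4\] (resistant alleles are modelled as minor standing variants).
#' @param fitness_cost Selection coefficient `s` in \[0, 1\] acting against
#'   genotypes carrying the drive allele (0 neutral, 1 lethal).
#' @param exposure Fraction `e` in \[0, 1\] of the population exposed to the
#'   selective pressure each generation.
#' @param dominance Dominance `d` in \[0, 1\] of the drive's fitness cost in
#'   heterozygotes (0 recessive, 0.5 additive, 1 dominant). Drive homozygotes
#'   always bear the full cost.
#' @param inbreeding Inbreeding coefficient `F` in \[0, 1\]: excess
#'   homozygosity relative to Hardy-Weinberg at zygote formation.
#' @param pop_size Constant diploid population size `n` (default 1e6).
#' @param generations Number of generations to simulate (default 500).
#' @param initial_drive_frequency Release frequency of the drive allele,
#'   in (0, 1) (default 0.001).
#' @param timing `"prezygotic"` (homing during gametogenesis, i.e. after
#'   selection on the parents) or `"postzygotic"` (homing in the new zygote,
#'   before selection acts on it).
#' @param mode `"stochastic"` (binomial sampling at population size `n`) or
#'   `"deterministic"` (expectation propagation).
#' @param seed Optional integer seed; if set, [simulate_drive()] seeds the RNG
#'   so the trajectory is reproducible.
#' @param drift_method `"binomial"` (independent per-allele binomial draws,
#'   renormalized) or `"multinomial"` (one multinomial draw of the `2n`
#'   gametes).
#'
#' @return An object of class `drive_scenario` (a validated list), carrying
#'   an `alleles` element built with [allele_set()].
#' @examples
#' sc <- drive_scenario(conversion = 0.9, fitness_cost = 0.3, exposure = 1,
#'                      dominance = 0.5, mode = "deterministic")
#' sc
#' @seealso [simulate_drive()], [drive_preset()], [sample_scenario()]
#' @export
drive_scenario <- function(conversion,
                           resistance_level = 0,
                           resistance_frequency = 0,
                           fitness_cost = 0,
                           exposure = 1,
                           dominance = 0.5,
                           inbreeding = 0,
                           pop_size = 1e6,
                           generations = 500,
                           initial_drive_frequency = 0.001,
                           timing = c("prezygotic", "postzygotic"),
                           mode = c("stochastic", "deterministic"),
                           seed = NULL,
                           drift_method = c("binomial", "multinomial")) {
  timing <- match.arg(timing)
  mode <- match.arg(mode)
  drift_method <- match.arg(drift_method)

  chk01 <- function(x, name, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi)
      stop("`", name, "` must be a single number in [", lo, ", ", hi, "]",
           call. = FALSE)
    as.numeric(x)
  }
  conversion <- chk01(conversion, "conversion")
  resistance_level <- chk01(resistance_level, "resistance_level")
  resistance_frequency <- chk01(resistance_frequency, "resistance_frequency",
                                0, 0.4)
  fitness_cost <- chk01(fitness_cost, "fitness_cost")
  exposure <- chk01(exposure, "exposure")
  dominance <- chk01(dominance, "dominance")
  inbreeding <- chk01(inbreeding, "inbreeding")
  if (resistance_level > conversion)
    stop("`resistance_level` cannot exceed `conversion`: homing is at most ",
         "as efficient on resistant alleles as on wild-type", call. = FALSE)
  if (!is.numeric(pop_size) || length(pop_size) != 1 || pop_size < 1 ||
      pop_size != round(pop_size))
    stop("`pop_size` must be a positive integer", call. = FALSE)
  if (!is.numeric(generations) || length(generations) != 1 ||
      generations < 1 || generations != round(generations))
    stop("`generations` must be a positive integer", call. = FALSE)
  if (!is.numeric(initial_drive_frequency) ||
      length(initial_drive_frequency) != 1 ||
      initial_drive_frequency <= 0 || initial_drive_frequency >= 1)
    stop("`initial_drive_frequency` must lie in (0, 1)", call. = FALSE)
  if (initial_drive_frequency + resistance_frequency >= 1)
    stop("`initial_drive_frequency` + `resistance_frequency` must be < 1 ",
         "(the wild-type allele must have positive frequency)", call. = FALSE)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
      stop("`seed` must be a single integer", call. = FALSE)
    seed <- as.integer(seed)
  }

  structure(list(
    conversion = conversion,
    resistance_level = resistance_level,
    resistance_frequency = resistance_frequency,
    fitness_cost = fitness_cost,
    exposure = exposure,
    dominance = dominance,
    inbreeding = inbreeding,
    pop_size = as.numeric(pop_size),
    generations = as.integer(generations),
    initial_drive_frequency = initial_drive_frequency,
    timing = timing,
    mode = mode,
    seed = seed,
    drift_method = drift_method,
    alleles = allele_set(susceptibility = c(0, conversion, resistance_level))
  ), class = "drive_scenario")
}

#' @export
print.drive_scenario <- function(x, ...) {
  cat("Gene drive scenario (", x$timing, ", ", x$mode, ")\n", sep = "")
  cat(sprintf("  conversion %.3g | resistance level %.3g (freq %.3g)\n",
              x$conversion, x$resistance_level, x$resistance_frequency))
  cat(sprintf("  fitness cost %.3g x exposure %.3g (dominance %.3g), F = %.3g\n",
              x$fitness_cost, x$exposure, x$dominance, x$inbreeding))
  cat(sprintf("  n = %s, %d generations, release frequency %.4g",
              format(x$pop_size, big.mark = ",", scientific = FALSE),
              x$generations,
              x$initial_drive_frequency))
  if (!is.null(x$seed)) cat(", seed ", x$seed, sep = "")
  cat("\n")
  invisible(x)
}

# initial allele-frequency state (drive, wild, resistant) of a scenario
scenario_p0 <- function(scenario) {
  c(scenario$initial_drive_frequency,
    1 - scenario$initial_drive_frequency - scenario$resistance_frequency,
    scenario$resistance_frequency)
}
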