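#' Reference scenario presets
#'
#' Named parameter sets used throughout the package's examples and tests as
#' anchors in the design space:
#' \describe{
#'   \item{`"equilibrium"`}{A prezygotic drive that plateaus at intermediate
#'     frequency: conversion 0.95, fitness cost 0.8, exposure 0.5, resistance
#'     level 0.1, resistance frequency 0.1, recessive cost (dominance 0), no
#'     inbreeding.}
#'   \item{`"temporary"`}{Same drive but with a fully immune resistant allele
#'     (resistance level 0) and additive cost (dominance 0.5): the drive
#'     peaks and then crashes as immune alleles accumulate.}
#'   \item{`"dominance-sweep"`}{A post-zygotic drive (resistance level 0.3,
#'     dominance left at 0 as the free variable): sweeping dominance from 0
#'     to 1 walks the outcome from equilibrium toward temporary/loss.}
#' }
#'
#' @param name Preset name; unknown names raise an error listing the
#'   available presets.
#' @param ... Overrides passed to [drive_scenario()] (e.g. `mode`, `seed`,
#'   or `dominance` for the sweep preset).
#' @return A [drive_scenario()].
#' @examples
#' drive_preset("equilibrium", mode = "deterministic")
#' @export
drive_preset <- function(name, ...) {
  presets <- drive_presets()
  if (length(name) != 1 || !name %in% names(presets))
    stop("unknown preset '", paste(name, collapse = ","), "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  args <- modifyList(presets[[name]], list(...))
  do.call(drive_scenario, args)
}

# preset parameter lists (shared with the CLI `presets` subcommand)
drive_presets <- function() {
  base <- list(conversion = 0.95, fitness_cost = 0.8, exposure = 0.5,
               resistance_frequency = 0.1, inbreeding = 0)
  list(
    equilibrium = c(base, list(resistance_level = 0.1, dominance = 0,
                               timing = "prezygotic")),
    temporary = c(base, list(resistance_level = 0, dominance = 0.5,
                             timing = "prezygotic")),
    `dominance-sweep` = c(base, list(resistance_level = 0.3, dominance = 0,
                                     timing = "postzygotic"))
  )
}
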