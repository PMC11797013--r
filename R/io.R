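## Result serialization and run configuration files.

# serialize doubles at full (round-trip) precision: shortest of %.15g/%.17g
# that reparses to the same IEEE double
fmt_num <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

write_precise_csv <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write Monte Carlo records to CSV
#'
#' One row per simulation, fixed column order (design variables, derived
#' selection pressure, timing, per-simulation seed, summary statistics,
#' outcome), numeric columns at full precision.
#'
#' @param records A `drive_mc` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mc_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  write_precise_csv(records, path)
}

#' Write a simulated trajectory to CSV
#'
#' Columns: `generation`, `drive_frequency`, and one frequency column per
#' remaining allele, at full precision.
#'
#' @param sim A `drive_sim` object from [simulate_drive()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  stopifnot(inherits(sim, "drive_sim"))
  df <- as.data.frame(sim)
  names(df) <- c("generation", paste0(colnames(sim$allele_frequencies),
                                      "_frequency"))
  write_precise_csv(df, path)
}

#' Read a trajectory CSV back as a drive frequency series
#'
#' @param path A CSV written by [write_trajectory()] (or any CSV with a
#'   `drive_frequency` column).
#' @return Numeric vector of drive allele frequencies.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  if (!"drive_frequency" %in% names(df))
    stop("'", path, "' has no `drive_frequency` column", call. = FALSE)
  df$drive_frequency
}

## run configuration files ----------------------------------------------------

config_keys <- c("conversion", "resistance_level", "resistance_frequency",
                 "fitness_cost", "exposure", "dominance", "inbreeding",
                 "timing", "mode", "generations", "pop_size",
                 "initial_drive_frequency", "seed", "drift_method",
                 "n_sims", "n_per_outcome", "max_attempts", "out")

#' Read a run configuration file
#'
#' A flat YAML key-value file whose keys mirror the design variable names
#' (`conversion`, `resistance_level`, ..., `inbreeding`) plus run settings
#' (`timing`, `mode`, `generations`, `pop_size`, `initial_drive_frequency`,
#' `seed`, `drift_method`) and batch settings (`n_sims`, `n_per_outcome`,
#' `max_attempts`, `out`). Unknown keys are rejected.
#'
#' @param path Path to the configuration file.
#' @return A named list of settings.
#' @seealso [write_run_config()]
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s) in '", path, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg
}

#' Write a run configuration file
#'
#' Writes settings as flat `key: value` YAML in canonical key order with
#' doubles at full precision, so write -> read -> write is byte-identical.
#'
#' @param config Named list of settings (subset of the keys documented in
#'   [read_run_config()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keys <- intersect(config_keys, names(config))
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    val <- if (is.character(v)) v else fmt_num(as.numeric(v))
    paste0(k, ": ", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
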