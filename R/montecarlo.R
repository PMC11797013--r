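## Monte Carlo sensitivity framework.
##
## Each simulation index i is fully determined by (root seed, i): the RNG is
## seeded with child_seed(seed, i), the seven design variables are drawn, and
## the simulation consumes the stream from there. Batches are therefore
## reproducible and order-independent, and the balanced sampler draws records
## identical to those of a plain batch with the same root seed.

# draw the seven design variables from their sampling distributions:
# conversion, resistance ratio, dominance, inbreeding ~ U(0,1);
# resistance frequency ~ U(0, 0.4); resistance level = ratio x conversion
draw_variables <- function() {
  conversion <- runif(1)
  ratio <- runif(1)
  resistance_frequency <- runif(1, 0, 0.4)
  exposure <- runif(1)
  fitness_cost <- runif(1)
  dominance <- runif(1)
  inbreeding <- runif(1)
  list(conversion = conversion,
       resistance_ratio = ratio,
       resistance_level = ratio * conversion,
       resistance_frequency = resistance_frequency,
       exposure = exposure,
       fitness_cost = fitness_cost,
       dominance = dominance,
       inbreeding = inbreeding)
}

#' Draw a random gene drive scenario from the design distributions
#'
#' Samples the seven design variables from their Monte Carlo distributions:
#' conversion efficiency, resistance ratio, exposure rate, fitness cost,
#' dominance and inbreeding uniform on \[0, 1\]; resistance frequency uniform
#' on \[0, 0.4\] (resistant alleles are minor standing variants); resistance
#' level = ratio x conversion, so it never exceeds the conversion efficiency.
#' Run settings are fixed at the study conditions: population size 1e6, 500
#' generations, release frequency 0.001, stochastic mode.
#'
#' Draws consume the R random number stream; call [set.seed()] first for
#' reproducibility.
#'
#' @param timing `"prezygotic"` or `"postzygotic"`.
#' @return A [drive_scenario()].
#' @examples
#' set.seed(1)
#' sample_scenario()
#' @export
sample_scenario <- function(timing = c("prezygotic", "postzygotic")) {
  timing <- match.arg(timing)
  v <- draw_variables()
  drive_scenario(conversion = v$conversion,
                 resistance_level = v$resistance_level,
                 resistance_frequency = v$resistance_frequency,
                 fitness_cost = v$fitness_cost,
                 exposure = v$exposure,
                 dominance = v$dominance,
                 inbreeding = v$inbreeding,
                 timing = timing)
}

# run and summarize simulation index i of a batch; returns a named numeric
# row of variables + summary statistics, with the outcome as attribute
mc_one <- function(i, seed, timing, pop_size, generations,
                   initial_drive_frequency) {
  set.seed(child_seed(seed, i))
  v <- draw_variables()
  traj <- cpp_simulate_drive(
    c(initial_drive_frequency,
      1 - initial_drive_frequency - v$resistance_frequency,
      v$resistance_frequency),
    c(0, v$conversion, v$resistance_level),
    v$fitness_cost, v$exposure, v$dominance, v$inbreeding,
    pop_size, generations, timing == "postzygotic", TRUE, FALSE)
  dd <- traj[, 1L]
  L <- length(dd)
  mx <- max(dd)
  fin <- dd[L]
  grad <- (dd[L] - dd[L - 20L]) / 20
  structure(c(conversion = v$conversion,
              resistance_level = v$resistance_level,
              resistance_ratio = v$resistance_ratio,
              resistance_frequency = v$resistance_frequency,
              fitness_cost = v$fitness_cost,
              exposure = v$exposure,
              dominance = v$dominance,
              inbreeding = v$inbreeding,
              selection_pressure = v$fitness_cost * v$exposure,
              seed = child_seed(seed, i),
              max_frequency = mx,
              time_to_max = which.max(dd) - 1L,
              final_frequency = fin,
              gradient = grad),
            outcome = classify_values(mx, fin, grad))
}

mc_record_frame <- function(rows, outcomes, timing) {
  df <- as.data.frame(do.call(rbind, rows))
  df$timing <- timing
  df$outcome <- outcomes
  df$sim <- seq_len(nrow(df))
  df <- df[, c("sim", "conversion", "resistance_level", "resistance_ratio",
               "resistance_frequency", "fitness_cost", "exposure", "dominance",
               "inbreeding", "selection_pressure", "timing", "seed",
               "max_frequency", "time_to_max", "final_frequency", "gradient",
               "outcome")]
  class(df) <- c("drive_mc", "data.frame")
  df
}

#' Run a Monte Carlo batch of gene drive simulations
#'
#' Draws `n_sims` independent scenarios from the design distributions (see
#' [sample_scenario()]), simulates each stochastically, and records the
#' variables, summary statistics and categorical outcome. Simulation `i` is
#' seeded with `seed + i`, so records are reproducible and independent of
#' batch size and ordering.
#'
#' @param n_sims Number of simulations.
#' @param timing `"prezygotic"` or `"postzygotic"`.
#' @param seed Root integer seed.
#' @param pop_size,generations,initial_drive_frequency Run settings; defaults
#'   are the study conditions (1e6, 500, 0.001).
#' @return A data frame of class `drive_mc`, one row per simulation, with the
#'   seven design variables, the derived `selection_pressure`
#'   (`fitness_cost * exposure`), the per-simulation seed, the trajectory
#'   summary statistics and the `outcome`.
#' @examples
#' rec <- run_monte_carlo(50, "prezygotic", seed = 1)
#' outcome_frequencies(rec)
#' @seealso [outcome_frequencies()], [balanced_sample()],
#'   [regress_within_outcome()]
#' @export
run_monte_carlo <- function(n_sims, timing = c("prezygotic", "postzygotic"),
                            seed, pop_size = 1e6, generations = 500,
                            initial_drive_frequency = 0.001) {
  timing <- match.arg(timing)
  if (!is.numeric(n_sims) || length(n_sims) != 1 || n_sims < 1)
    stop("`n_sims` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for reproducible batches",
                          call. = FALSE)
  n_sims <- as.integer(n_sims)
  rows <- vector("list", n_sims)
  outcomes <- character(n_sims)
  for (i in seq_len(n_sims)) {
    r <- mc_one(i, seed, timing, pop_size, generations,
                initial_drive_frequency)
    outcomes[i] <- attr(r, "outcome")
    attributes(r) <- list(names = names(r))
    rows[[i]] <- r
  }
  mc_record_frame(rows, outcomes, timing)
}

#' Tabulate outcome frequencies of a Monte Carlo batch
#'
#' Percentage of simulations classified as loss, fixation, temporary and
#' equilibrium, on the 0-100 scale, with unclassified simulations retained in
#' the denominator; `total` is the sum of the four classified percentages.
#'
#' @param records A `drive_mc` data frame from [run_monte_carlo()].
#' @return An object of class `outcome_table`: a data frame with one row per
#'   outcome (Loss, Fixation, Temporary, Equilibrium, Total) and columns
#'   `count` and `percent`, plus attribute `n` (batch size).
#' @export
outcome_frequencies <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("`records` must be a nonempty data frame of simulation records",
         call. = FALSE)
  n <- nrow(records)
  counts <- vapply(c("loss", "fixation", "temporary", "equilibrium"),
                   function(o) sum(records$outcome == o), integer(1))
  pct <- 100 * counts / n
  out <- data.frame(outcome = c("Loss", "Fixation", "Temporary",
                                "Equilibrium", "Total"),
                    count = c(counts, sum(counts)),
                    percent = c(pct, sum(pct)))
  attr(out, "n") <- n
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("Outcome frequencies (", attr(x, "n"), " simulations)\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %6d  %6.2f %%\n", x$outcome[i], x$count[i],
                x$percent[i]))
  invisible(x)
}

#' Sample simulations until each outcome reaches a quota
#'
#' Keeps drawing scenarios from the design distributions (exactly as
#' [run_monte_carlo()] does, with the same per-index seeding) until
#' `n_per_outcome` simulations of each of the four classified outcomes have
#' been observed; unclassified simulations are discarded. Because equilibrium
#' is by far the rarest outcome (about 1.3% of prezygotic draws), expect on
#' the order of `n_per_outcome / 0.013` attempts to fill its quota.
#'
#' @inheritParams run_monte_carlo
#' @param n_per_outcome Target number of records per outcome.
#' @param max_attempts Attempt budget; if any quota is still unfilled after
#'   this many draws an error names the lagging outcome(s).
#' @return A `drive_mc` data frame with exactly `4 * n_per_outcome` rows,
#'   `n_per_outcome` per outcome, in attempt order; the `sim` column is the
#'   attempt index, so rows coincide with the same-seed plain batch.
#' @examples
#' bal <- balanced_sample(5, "prezygotic", seed = 1, max_attempts = 5000)
#' table(bal$outcome)
#' @export
balanced_sample <- function(n_per_outcome,
                            timing = c("prezygotic", "postzygotic"),
                            seed, max_attempts = 1000 * n_per_outcome,
                            pop_size = 1e6, generations = 500,
                            initial_drive_frequency = 0.001) {
  timing <- match.arg(timing)
  if (!is.numeric(n_per_outcome) || length(n_per_outcome) != 1 ||
      n_per_outcome < 1)
    stop("`n_per_outcome` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for reproducible batches",
                          call. = FALSE)
  quota <- c(loss = 0L, fixation = 0L, temporary = 0L, equilibrium = 0L)
  rows <- vector("list", 4L * n_per_outcome)
  outcomes <- character(4L * n_per_outcome)
  sims <- integer(4L * n_per_outcome)
  kept <- 0L
  for (i in seq_len(max_attempts)) {
    r <- mc_one(i, seed, timing, pop_size, generations,
                initial_drive_frequency)
    o <- attr(r, "outcome")
    if (o != "unclassified" && quota[[o]] < n_per_outcome) {
      quota[[o]] <- quota[[o]] + 1L
      kept <- kept + 1L
      attributes(r) <- list(names = names(r))
      rows[[kept]] <- r
      outcomes[kept] <- o
      sims[kept] <- i
      if (all(quota == n_per_outcome)) {
        df <- mc_record_frame(rows, outcomes, timing)
        df$sim <- sims
        return(df)
      }
    }
  }
  lag <- names(quota)[quota < n_per_outcome]
  stop("attempt budget (", max_attempts, ") exhausted before filling the ",
       "quota for outcome(s): ", paste(lag, collapse = ", "),
       " (", paste(quota[lag], collapse = ", "), " of ", n_per_outcome,
       " found)", call. = FALSE)
}
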