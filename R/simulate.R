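#' Simulate a gene drive trajectory
#'
#' Runs [step_generation()] for `scenario$generations` generations from the
#' initial state (drive allele at its release frequency, resistant allele at
#' its initial frequency, wild-type at the remainder), recording the allele
#' frequencies after each generation. Drive frequencies exactly 0 and exactly
#' 1 are absorbing (no mutation can re-create a lost drive and a fixed drive
#' cannot be displaced), so the remainder of the trajectory is frozen as soon
#' as either boundary is hit.
#'
#' @param scenario A [drive_scenario()].
#' @param engine `"cpp"` (compiled generation loop, the default) or `"r"`
#'   (pure-R loop composed from the exported per-operation functions). The
#'   two engines perform identical arithmetic and RNG calls and return
#'   identical trajectories from identical seeds.
#' @return An object of class `drive_sim`: a list with elements
#'   `drive_frequency` (length `generations + 1`, entry 1 = generation 0),
#'   `allele_frequencies` (matrix, one column per allele), and `scenario`.
#' @examples
#' sc <- drive_preset("equilibrium")
#' sc$mode <- "deterministic"
#' sim <- simulate_drive(sc)
#' summary(sim)
#' @seealso [summary.drive_sim()], [classify_outcome()], [drive_preset()]
#' @export
simulate_drive <- function(scenario, engine = c("cpp", "r")) {
  stopifnot(inherits(scenario, "drive_scenario"))
  engine <- match.arg(engine)
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  p0 <- scenario_p0(scenario)
  if (engine == "cpp") {
    traj <- cpp_simulate_drive(
      p0, unname(scenario$alleles$susceptibility),
      scenario$fitness_cost, scenario$exposure, scenario$dominance,
      scenario$inbreeding, scenario$pop_size, scenario$generations,
      scenario$timing == "postzygotic", scenario$mode == "stochastic",
      scenario$drift_method == "multinomial")
  } else {
    traj <- matrix(0, scenario$generations + 1L, length(p0))
    traj[1L, ] <- p <- p0
    for (t in seq_len(scenario$generations)) {
      p <- step_generation(p, scenario)
      traj[t + 1L, ] <- p
      if (p[1L] == 0 || p[1L] == 1) {
        if (t < scenario$generations)
          traj[(t + 2L):(scenario$generations + 1L), ] <-
            matrix(p, scenario$generations - t, length(p), byrow = TRUE)
        break
      }
    }
  }
  colnames(traj) <- scenario$alleles$labels
  structure(list(drive_frequency = traj[, scenario$alleles$drive],
                 allele_frequencies = traj,
                 scenario = scenario,
                 engine = engine),
            class = "drive_sim")
}

#' Simulate replicate trajectories from a scenario
#'
#' Method for [stats::simulate()]: runs `nsim` independent replicates of a
#' scenario. Replicate `i` is seeded with `seed + i`, so any single replicate
#' can be re-derived from the root seed and its index.
#'
#' @param object A [drive_scenario()].
#' @param nsim Number of replicate simulations.
#' @param seed Root integer seed (required for `nsim > 1`).
#' @param ... Passed to [simulate_drive()] (e.g. `engine`).
#' @return A single `drive_sim` if `nsim == 1`, otherwise a list of them.
#' @examples
#' reps <- simulate(drive_preset("equilibrium"), nsim = 3, seed = 1)
#' sapply(reps, function(s) summary(s)$outcome)
#' @export
simulate.drive_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed) && nsim > 1 && is.null(object$seed))
    stop("supply `seed` to simulate multiple replicates reproducibly",
         call. = FALSE)
  if (nsim == 1 && is.null(seed)) return(simulate_drive(object, ...))
  root <- if (is.null(seed)) object$seed else seed
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    sc <- object
    sc$seed <- child_seed(root, i)
    out[[i]] <- simulate_drive(sc, ...)
  }
  if (nsim == 1) out[[1]] else out
}

# deterministic child seed for replicate/simulation index i (kept < 2^31)
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + i) %% 2147483647)
}

#' @export
print.drive_sim <- function(x, ...) {
  s <- summary(x)
  cat("Gene drive simulation (", x$scenario$timing, ", ", x$scenario$mode,
      ", ", x$scenario$generations, " generations)\n", sep = "")
  cat(sprintf("  outcome: %s\n", s$outcome))
  cat(sprintf("  max frequency %.4f at generation %d; final frequency %.4f\n",
              s$max_frequency, s$time_to_max, s$final_frequency))
  invisible(x)
}

#' Summary statistics and outcome of a simulated trajectory
#'
#' Computes the trajectory summary via [summarize_trajectory()] and attaches
#' the categorical outcome from [classify_outcome()].
#'
#' @param object A `drive_sim` object from [simulate_drive()].
#' @param ... Passed to [summarize_trajectory()] (e.g. `gradient_method`).
#' @return A `drive_summary` list: `max_frequency`, `time_to_max`,
#'   `final_frequency`, `gradient`, `outcome`.
#' @export
summary.drive_sim <- function(object, ...) {
  s <- summarize_trajectory(object$drive_frequency, ...)
  s$outcome <- classify_outcome(s)
  class(s) <- "drive_summary"
  s
}

#' @export
print.drive_summary <- function(x, ...) {
  cat("Trajectory summary\n")
  cat(sprintf("  max frequency:   %.6f (generation %d)\n",
              x$max_frequency, x$time_to_max))
  cat(sprintf("  final frequency: %.6f\n", x$final_frequency))
  cat(sprintf("  gradient:        %.3g per generation (last %d generations)\n",
              x$gradient, x$window))
  cat(sprintf("  outcome:         %s\n", x$outcome))
  invisible(x)
}

#' @export
as.data.frame.drive_sim <- function(x, ...) {
  data.frame(generation = seq_len(nrow(x$allele_frequencies)) - 1L,
             x$allele_frequencies, check.names = FALSE)
}

#' Plot allele frequency trajectories
#'
#' @param x A `drive_sim` object.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.drive_sim <- function(x, ...) {
  traj <- x$allele_frequencies
  matplot(seq_len(nrow(traj)) - 1L, traj, type = "l", lty = 1,
          col = c("firebrick", "grey40", "steelblue")[seq_len(ncol(traj))],
          xlab = "Generation", ylab = "Allele frequency", ylim = c(0, 1), ...)
  legend("topleft", legend = colnames(traj), lty = 1, bty = "n",
         col = c("firebrick", "grey40", "steelblue")[seq_len(ncol(traj))])
  invisible(x)
}
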