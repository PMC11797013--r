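#' Regress a dynamics metric on the design variables within one outcome
#'
#' Ordinary least-squares multiple regression (main effects plus intercept)
#' of a trajectory dynamics metric on the seven design variables, restricted
#' to the records of one outcome. Variables are left on their raw sampling
#' scales (rates in \[0, 1\], time in generations), so a coefficient is the
#' change in the response per unit change of the variable.
#'
#' @param records A `drive_mc` data frame, typically from
#'   [balanced_sample()] so that each outcome has equal power.
#' @param outcome One of `"loss"`, `"fixation"`, `"temporary"`,
#'   `"equilibrium"`; at least 100 records of it are required.
#' @param response One of `"time_to_max"`, `"final_frequency"`,
#'   `"max_frequency"`.
#' @return An object of class `drive_ols`: a list with the coefficient table
#'   (`term`, `estimate`, `std_error`, `p_value`), the fitted [stats::lm()]
#'   object (`model`), `outcome`, `response`, and `n`.
#' @examples
#' bal <- balanced_sample(50, "prezygotic", seed = 1, max_attempts = 2e4)
#' \dontrun{regress_within_outcome(bal, "temporary", "max_frequency")}
#' @export
regress_within_outcome <- function(records,
                                   outcome = c("loss", "fixation",
                                               "temporary", "equilibrium"),
                                   response = c("time_to_max",
                                                "final_frequency",
                                                "max_frequency")) {
  outcome <- match.arg(outcome)
  response <- match.arg(response)
  if (!is.data.frame(records))
    stop("`records` must be a data frame of simulation records", call. = FALSE)
  vars <- c("conversion", "resistance_level", "resistance_frequency",
            "fitness_cost", "exposure", "dominance", "inbreeding")
  missing_cols <- setdiff(c(vars, response, "outcome"), names(records))
  if (length(missing_cols))
    stop("`records` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  sub <- records[records$outcome == outcome, , drop = FALSE]
  if (nrow(sub) < 100)
    stop("need at least 100 '", outcome, "' records, got ", nrow(sub),
         call. = FALSE)
  fit <- lm(reformulate(vars, response), data = sub)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("design matrix is rank deficient; collinear variable(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(sm),
                              estimate = sm[, "Estimate"],
                              std_error = sm[, "Std. Error"],
                              p_value = sm[, "Pr(>|t|)"],
                              row.names = NULL),
    model = fit,
    outcome = outcome,
    response = response,
    n = nrow(sub)), class = "drive_ols")
}

#' @export
print.drive_ols <- function(x, digits = 4, ...) {
  cat("Within-outcome OLS: ", x$response, " ~ design variables (",
      x$outcome, ", n = ", x$n, ")\n", sep = "")
  cf <- x$coefficients
  cf$estimate <- signif(cf$estimate, digits)
  cf$std_error <- signif(cf$std_error, digits)
  cf$p_value <- format.pval(cf$p_value, digits = 3)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' @export
coef.drive_ols <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
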