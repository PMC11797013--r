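test_that("scenario sampling respects the design distributions", {
  set.seed(81)
  draws <- replicate(2000, {
    sc <- sample_scenario()
    c(sc$conversion, sc$resistance_level, sc$resistance_frequency,
      sc$fitness_cost, sc$exposure, sc$dominance, sc$inbreeding)
  })
  expect_true(all(draws >= 0 & draws <= 1))
  expect_true(all(draws[3, ] <= 0.4))
  expect_true(all(draws[2, ] <= draws[1, ] + 1e-12))
  # resistance frequency ~ U(0, 0.4): mean 0.2 within 3 SE
  se <- (0.4 / sqrt(12)) / sqrt(2000)
  expect_lt(abs(mean(draws[3, ]) - 0.2), 3 * se)
  expect_lt(max(draws[3, ]), 0.4)
  # determinism under a fixed seed
  set.seed(82)
  a <- sample_scenario("postzygotic")
  set.seed(82)
  b <- sample_scenario("postzygotic")
  expect_identical(a, b)
})

test_that("Monte Carlo batches are reproducible and order-independent", {
  r1 <- run_monte_carlo(60, "prezygotic", seed = 301)
  r2 <- run_monte_carlo(60, "prezygotic", seed = 301)
  expect_identical(r1, r2)
  # records are fixed by (seed, index): a shorter batch is a prefix
  r3 <- run_monte_carlo(30, "prezygotic", seed = 301)
  expect_equal(as.data.frame(r3), as.data.frame(r1[1:30, ]))
  expect_equal(r1$selection_pressure, r1$fitness_cost * r1$exposure)
  expect_true(all(r1$outcome %in% c("loss", "fixation", "temporary",
                                    "equilibrium", "unclassified")))
})

test_that("outcome frequency tables count and percentage correctly", {
  rec <- data.frame(outcome = c("loss", "loss", "loss", "fixation",
                                "unclassified"))
  tab <- outcome_frequencies(rec)
  expect_equal(tab$percent[tab$outcome == "Loss"], 60)
  expect_equal(tab$percent[tab$outcome == "Fixation"], 20)
  expect_equal(tab$percent[tab$outcome == "Total"], 80)
  expect_equal(tab$count[tab$outcome == "Total"], 4)

  all_fix <- data.frame(outcome = rep("fixation", 10))
  expect_equal(outcome_frequencies(all_fix)$percent, c(0, 100, 0, 0, 100))
  expect_error(outcome_frequencies(data.frame()), "nonempty")
})

test_that("balanced sampling fills exact per-outcome quotas reproducibly", {
  bal <- balanced_sample(5, "prezygotic", seed = 83, max_attempts = 5000)
  expect_equal(nrow(bal), 20)
  expect_equal(unname(table(bal$outcome)[c("loss", "fixation", "temporary",
                                           "equilibrium")]),
               rep(5L, 4), ignore_attr = TRUE)
  expect_false(any(bal$outcome == "unclassified"))
  bal2 <- balanced_sample(5, "prezygotic", seed = 83, max_attempts = 5000)
  expect_identical(bal, bal2)
})

test_that("balanced sampling coincides with quota-filtered plain sampling", {
  # same (seed, index) scheme: the balanced records must be exactly the rows
  # of a plain batch at the same attempt indices
  bal <- balanced_sample(4, "prezygotic", seed = 84, max_attempts = 4000)
  plain <- run_monte_carlo(max(bal$sim), "prezygotic", seed = 84)
  merged <- plain[bal$sim, ]
  rownames(merged) <- NULL
  rb <- bal
  rownames(rb) <- NULL
  expect_equal(as.data.frame(rb), as.data.frame(merged))
})

test_that("an unreachable quota raises a budget error naming the laggard", {
  expect_error(balanced_sample(5, "prezygotic", seed = 85, max_attempts = 12),
               "budget.*exhausted|exhausted")
  err <- tryCatch(balanced_sample(300, "prezygotic", seed = 85,
                                  max_attempts = 60),
                  error = conditionMessage)
  expect_match(err, "equilibrium")
})

test_that("within-outcome regression recovers known coefficients", {
  set.seed(91)
  n <- 600
  vars <- c("conversion", "resistance_level", "resistance_frequency",
            "fitness_cost", "exposure", "dominance", "inbreeding")
  X <- as.data.frame(matrix(runif(n * 7), n, 7,
                            dimnames = list(NULL, vars)))
  beta <- c(conversion = -200, resistance_level = 120,
            resistance_frequency = 150, fitness_cost = -70, exposure = -75,
            dominance = 210, inbreeding = 250)
  X$time_to_max <- 100 + as.matrix(X[vars]) %*% beta + rnorm(n, sd = 20)
  X$outcome <- "equilibrium"
  fit <- regress_within_outcome(X, "equilibrium", "time_to_max")
  cf <- fit$coefficients
  for (v in vars) {
    row <- cf[cf$term == v, ]
    expect_lt(abs(row$estimate - beta[[v]]), 3 * row$std_error)
  }
})

test_that("regression demands sample size and full rank", {
  set.seed(92)
  small <- run_monte_carlo(40, "prezygotic", seed = 93)
  expect_error(regress_within_outcome(small, "loss", "time_to_max"),
               "at least 100")
  n <- 200
  X <- as.data.frame(matrix(runif(n * 7), n, 7,
                            dimnames = list(NULL,
                                            c("conversion", "resistance_level",
                                              "resistance_frequency",
                                              "fitness_cost", "exposure",
                                              "dominance", "inbreeding"))))
  X$exposure <- X$fitness_cost          # exact collinearity
  X$time_to_max <- runif(n)
  X$outcome <- "loss"
  expect_error(regress_within_outcome(X, "loss", "time_to_max"),
               "collinear.*exposure")
})
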