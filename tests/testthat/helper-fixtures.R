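# Shared fixtures, built in code.

# hand-built LMS table with round numbers (both sexes, 24-72 months)
hand_lms <- function() {
  grid <- seq(24, 72, by = 12)
  df <- rbind(
    data.frame(sex = "male", age = grid, L = -1.6, M = 15.0 + 0.1 * seq_along(grid),
               S = 0.08, stringsAsFactors = FALSE),
    data.frame(sex = "female", age = grid, L = -1.4, M = 14.8 + 0.1 * seq_along(grid),
               S = 0.09, stringsAsFactors = FALSE)
  )
  gwgmediate:::as_lms_table(df)
}

# simple analysis rows drawn directly from the two generating models
toy_rows <- function(n = 500, seed = 1, beta = c(-1, 0.05),
                     theta = c(0, 0.04, 0.3, -0.01), sigma = 0.8) {
  set.seed(seed)
  A <- runif(n, 19, 40)
  M <- rbinom(n, 1, plogis(beta[1] + beta[2] * A))
  Y <- theta[1] + theta[2] * A + theta[3] * M + theta[4] * A * M +
    rnorm(n, 0, sigma)
  data.frame(bmi = A, gwg_excessive = M, zbmi4 = Y)
}

# random coefficient sets for the oracle-equivalence battery
rand_coef_set <- function(seed) {
  set.seed(seed)
  mfit <- mediator_coefs(runif(1, -3, 0), runif(1, 0.01, 0.12),
                         c(c1 = runif(1, -0.4, 0.4), c2 = runif(1, -0.4, 0.4)))
  ofit <- outcome_coefs(runif(1, -1, 0.5), runif(1, -0.05, 0.08),
                        runif(1, -0.5, 1), runif(1, -0.04, 0.03),
                        c(c1 = runif(1, -0.3, 0.3), c2 = runif(1, -0.3, 0.3)),
                        sigma = 0.9)
  list(mfit = mfit, ofit = ofit,
       cvals = c(c1 = runif(1), c2 = runif(1)),
       a = runif(1, 28, 36), a_star = runif(1, 19, 25))
}

# small clean cohort (no corruption) for integration tests
small_cohort <- function(n = 250, seed = 11, ...) {
  simulate_cohort(cohort_config(
    n_pairs = n, glitch_rate = 0, missing_rate = c(race = 0),
    gap_gt7_rate = 0, window_miss_rate = 0, seed = seed, ...
  ))
}

cohort_rows <- function(coh) {
  derive_pairs(coh$mothers, coh$growth, synthetic_lms_table())
}
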