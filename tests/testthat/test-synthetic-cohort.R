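test_that("generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_pairs = 100, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$mothers, b$mothers)
  expect_identical(a$growth, b$growth)
  expect_identical(a$latent, b$latent)
  expect_identical(a$corruptions, b$corruptions)
})

test_that("null generating model implies zero true effects", {
  cfg <- cohort_config(n_pairs = 10, seed = 3)
  cfg$theta$exposure <- 0
  cfg$theta$mediator <- 0
  cfg$theta$interaction <- 0
  cfg$theta$covariates[] <- 0
  tr <- gwgmediate:::cohort_truth(cfg)$effects
  expect_equal(tr$cde, 0)
  expect_equal(tr$nde, 0)
  expect_equal(tr$nie, 0)
})

test_that("true total effect is exactly NDE + NIE", {
  for (seed in 1:5) {
    cfg <- cohort_config(n_pairs = 10, seed = seed)
    cfg$theta$mediator <- runif(1, -1, 1)
    tr <- gwgmediate:::cohort_truth(cfg)$effects
    expect_identical(tr$te, tr$nde + tr$nie)
  }
})

test_that("invalid configurations name the offending field", {
  expect_error(cohort_config(n_pairs = 0), "n_pairs")
  expect_error(cohort_config(sigma_y = -1), "sigma_y")
  expect_error(cohort_config(glitch_rate = 1.4), "rates/probabilities")
  expect_error(
    cohort_config(bmi_mixture = list(weights = c(0.6, 0.6),
                                     means = c(22, 30), sds = c(2, 2))),
    "weights")
  expect_error(cohort_config(growth_schedule = c(50, 40)), "growth_schedule")
})

test_that("growth series hit the target z exactly at the age-4 record", {
  lms <- synthetic_lms_table()
  # target z = 0: age-4 BMI equals the interpolated median
  g0 <- generate_growth_series(0, "male", c(24, 36, 48, 58), lms, seed = 2)
  last <- g0[nrow(g0), ]
  par <- lookup_lms(lms, "male", last$age)
  expect_equal(compute_bmi(last$weight, last$height), par$M, tolerance = 1e-9)
  # target z = 1: analytic LMS inversion M (1 + L S)^(1/L)
  g1 <- generate_growth_series(1, "female", c(30, 44, 52), lms, seed = 2)
  last <- g1[g1$age == 52, ]
  par <- lookup_lms(lms, "female", 52)
  expect_equal(compute_bmi(last$weight, last$height),
               par$M * (1 + par$L * par$S)^(1 / par$L), tolerance = 1e-9)
  expect_equal(lms_zscore(compute_bmi(last$weight, last$height),
                          par$L, par$M, par$S), 1, tolerance = 1e-6)
})

test_that("growth series respect schedule preconditions and monotone heights", {
  lms <- synthetic_lms_table()
  one <- generate_growth_series(0.4, "male", 50, lms, seed = 1)
  expect_equal(nrow(one), 1)
  expect_gt(one$height, 0)
  expect_error(generate_growth_series(0, "male", c(10, 48), lms), "range")
  expect_error(generate_growth_series(0, "male", c(48, 40), lms), "ascending")
  set.seed(8)
  for (i in 1:10) {
    g <- generate_growth_series(rnorm(1), "female", c(24, 30, 36, 45, 51, 58),
                                lms)
    expect_true(all(diff(g$height) > 0))
    expect_true(all(g$weight > 0))
  }
})

test_that("error injection with zero rates is the identity", {
  coh <- small_cohort(n = 80, seed = 5)
  cfg0 <- coh$config
  out <- inject_errors(coh, cfg0)
  expect_identical(out$growth, coh$growth)
  expect_identical(out$mothers, coh$mothers)
  expect_equal(nrow(out$corruptions), 0)
})

test_that("forced corruption of a child is detected by the cleaner", {
  coh <- small_cohort(n = 5, seed = 2)
  cfg <- coh$config
  cfg$glitch_rate <- 1
  out <- inject_errors(coh, cfg)
  g <- out$growth[out$growth$id == out$growth$id[1], ]
  expect_gt(sum(flag_nonmonotone(g$height)), 0)
})

test_that("corrupted-record fraction respects binomial bounds at rate 0.1", {
  cfg <- cohort_config(n_pairs = 1000, glitch_rate = 0.1,
                       missing_rate = c(race = 0), gap_gt7_rate = 0,
                       window_miss_rate = 0, seed = 17)
  coh <- simulate_cohort(cfg)
  # eligible records: all but the first visit of each child
  n_eligible <- nrow(coh$growth) - length(unique(coh$growth$id))
  frac <- nrow(coh$corruptions) / n_eligible
  half_width <- qnorm(0.995) * sqrt(0.1 * 0.9 / n_eligible)
  expect_gt(frac, 0.1 - half_width)
  expect_lt(frac, 0.1 + half_width)
})

test_that("refitting recovers generating coefficients at large n", {
  cfg <- cohort_config(n_pairs = 50000, glitch_rate = 0,
                       missing_rate = c(race = 0), gap_gt7_rate = 0,
                       window_miss_rate = 0, seed = 42)
  cfg$beta$exposure <- 0.1
  cfg$theta$exposure <- 0.03
  cfg$theta$mediator <- 0.2
  cfg$theta$interaction <- 0
  coh <- simulate_cohort(cfg)
  rows <- data.frame(bmi = coh$mothers$bmi,
                     gwg_excessive = coh$latent$m_true,
                     zbmi4 = coh$latent$y_true,
                     coh$mothers[c("race", "education", "smoking", "gdm",
                                   "cohort")])
  covs <- gwg_covariates("minimal")
  mf <- fit_mediator_model(rows, covs)
  of <- fit_outcome_model(rows, covs, interaction = FALSE)
  expect_lt(abs(mf$beta1 - 0.1) / sqrt(mf$vcov["bmi", "bmi"]), 3)
  expect_lt(abs(mf$beta0 - cfg$beta$intercept) /
              sqrt(mf$vcov["(Intercept)", "(Intercept)"]), 3)
  expect_lt(abs(of$theta1 - 0.03) / sqrt(of$vcov["bmi", "bmi"]), 3)
  expect_lt(abs(of$theta2 - 0.2) /
              sqrt(of$vcov["gwg_excessive", "gwg_excessive"]), 3)
  for (v in names(cfg$beta$covariates)) {
    expect_lt(abs(mf$beta2[v] - cfg$beta$covariates[v]) /
                sqrt(mf$vcov[v, v]), 4)
  }
})

test_that("default cohorts mimic the intended marginal structure", {
  ovob <- exc <- numeric(40)
  for (s in seq_len(40)) {
    coh <- simulate_cohort(cohort_config(seed = 100 + s))
    rows <- cohort_rows(coh)
    ovob[s] <- mean(rows$child_category %in% c("overweight", "obese"))
    exc[s] <- mean(rows$gwg_excessive, na.rm = TRUE)
  }
  expect_gt(mean(ovob), 0.18); expect_lt(mean(ovob), 0.30)
  expect_gt(mean(exc), 0.45); expect_lt(mean(exc), 0.65)
})

test_that("derived mediator and outcome equal the generating values", {
  coh <- small_cohort(n = 200, seed = 23)
  rows <- cohort_rows(coh)
  i <- match(rows$id, coh$latent$id)
  expect_equal(rows$gwg_excessive, coh$latent$m_true[i])
  expect_equal(rows$zbmi4, coh$latent$y_true[i], tolerance = 1e-9)
  ex <- attr(rows, "exclusions")
  expect_identical(unname(ex["rows_in"]),
                   unname(ex["rows_analyzed"] + ex["underweight_mother"] +
                            ex["no_window_visit"]))
})
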