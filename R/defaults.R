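# Default synthetic-cohort configuration.
#
# The defaults emulate the marginal structure of a prenatal-care birth
# cohort of 766 mother-child pairs: a maternal pre-pregnancy BMI mixture
# with roughly 44% normal-weight / 25% overweight / 31% obese mothers
# (underweight excluded), about 55-57% excessive gestational weight gain,
# and about a quarter of children overweight or obese at age four.
# The outcome-model coefficients are chosen so that the implied closed-form
# decomposition at the default contrast (BMI 30 vs 22, covariates at their
# expected indicator means) has CDE 0.322, NDE 0.235 and NIE 0.020 on the
# child BMI z-score scale.

race_levels <- c("black", "white", "hispanic", "other")
education_levels <- c("less_hs", "hs", "some_college", "college")
parity_levels <- c("0", "1", "2", "3+")

default_covariate_dist <- function() {
  list(
    race = c(black = 0.47, white = 0.32, hispanic = 0.17, other = 0.04),
    education = c(less_hs = 0.22, hs = 0.22, some_college = 0.23,
                  college = 0.33),
    smoking = 0.21,
    gdm = 0.064,
    cohort = 0.50,
    parity = c(`0` = 0.29, `1` = 0.37, `2` = 0.20, `3+` = 0.14),
    male = 0.53,
    cesarean = 0.37,
    mat_age = c(mean = 28.7, sd = 6.2),
    gest_age_days = c(mean = 270, sd = 16),
    birth_weight_g = c(mean = 3183, sd = 650)
  )
}

default_beta_covariates <- function() {
  c(racewhite = -0.10, racehispanic = -0.15, raceother = -0.10,
    educationhs = 0.00, educationsome_college = -0.05,
    educationcollege = -0.15, gdm = 0.25, smoking = 0.10, cohort = 0.00)
}

default_theta_covariates <- function() {
  c(racewhite = -0.05, racehispanic = 0.10, raceother = -0.05,
    educationhs = -0.03, educationsome_college = -0.05,
    educationcollege = -0.12, gdm = 0.05, smoking = 0.08, cohort = 0.00)
}

# expected value of the indicator-coded covariate vector under the
# generating distribution (reference levels: black, less_hs)
expected_covariate_means <- function(dist = default_covariate_dist()) {
  c(racewhite = unname(dist$race["white"]),
    racehispanic = unname(dist$race["hispanic"]),
    raceother = unname(dist$race["other"]),
    educationhs = unname(dist$education["hs"]),
    educationsome_college = unname(dist$education["some_college"]),
    educationcollege = unname(dist$education["college"]),
    gdm = dist$gdm, smoking = dist$smoking, cohort = dist$cohort)
}

# calibration constants (frozen; see the methods vignette)
CAL <- list(
  beta0 = -1.333568,       # mediator-model intercept
  beta1 = 0.06,            # mediator-model exposure slope (per BMI unit)
  theta0 = -0.803981,      # outcome-model intercept
  theta1 = 0.0402500,      # exposure slope: CDE 0.322 over an 8-unit contrast
  theta2 = 0.8547631,      # mediator main effect
  theta3 = -0.0228825,     # exposure x mediator interaction
  sigma_y = 0.90,
  mix_w = c(0.46, 0.22, 0.32),
  mix_mean = c(22.0, 27.3, 35.5),
  mix_sd = c(1.8, 1.4, 4.0)
)

#' Synthetic-cohort generator configuration
#'
#' Assembles (and validates) the configuration for [simulate_cohort()]:
#' the generating mediator/outcome coefficients, maternal BMI mixture,
#' covariate distribution, growth visit schedule, and corruption and
#' missingness rates. Defaults are calibrated to the marginal structure
#' described in the package vignette (roughly a quarter of children
#' overweight/obese, 25%/31% overweight/obese mothers, 55-57% excessive
#' gain) with outcome coefficients implying CDE 0.322, NDE 0.235 and
#' NIE 0.020 at the default BMI 30 vs 22 contrast.
#'
#' @param n_pairs number of mother-child pairs.
#' @param beta mediator-model coefficients: list with `intercept`,
#'   `exposure` and a named `covariates` vector (log-odds scale).
#' @param theta outcome-model coefficients: list with `intercept`,
#'   `exposure`, `mediator`, `interaction` and named `covariates` (BMI-z
#'   scale).
#' @param sigma_y outcome residual SD (> 0).
#' @param bmi_mixture list `weights`, `means`, `sds` for the 3-component
#'   maternal pre-pregnancy BMI normal mixture, truncated at 18.5 kg/m^2
#'   (the analysis excludes underweight mothers).
#' @param covariate_dist category probabilities and moments for the
#'   covariates (see `default_covariate_dist()`).
#' @param growth_schedule child visit ages in months (ascending).
#' @param glitch_rate probability that a (non-first) height record is
#'   corrupted downward by [inject_errors()].
#' @param missing_rate named per-variable missingness probabilities
#'   (variables of the maternal table).
#' @param mar_slope log-odds change in missingness per BMI unit (makes
#'   missingness MAR given the always-observed exposure).
#' @param gap_gt7_rate probability the last weight predates delivery by
#'   more than 7 days (GWG then set missing downstream).
#' @param window_miss_rate probability a child has no visit in the 48-59
#'   month outcome window (excluded downstream).
#' @param z_jitter_sd SD of the visit-level jitter around the child's
#'   generating z-score (the selected age-4 record is exact).
#' @param confounding if `TRUE`, maternal BMI is shifted by covariates
#'   (induces exposure-covariate confounding; off by default so tests can
#'   isolate adjustment behaviour).
#' @param seed RNG seed; the cohort is fully reproducible given the
#'   configuration.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 766,
                          beta = list(intercept = CAL$beta0,
                                      exposure = CAL$beta1,
                                      covariates = default_beta_covariates()),
                          theta = list(intercept = CAL$theta0,
                                       exposure = CAL$theta1,
                                       mediator = CAL$theta2,
                                       interaction = CAL$theta3,
                                       covariates = default_theta_covariates()),
                          sigma_y = CAL$sigma_y,
                          bmi_mixture = list(weights = CAL$mix_w,
                                             means = CAL$mix_mean,
                                             sds = CAL$mix_sd),
                          covariate_dist = default_covariate_dist(),
                          growth_schedule = c(24, 33, 42, 51, 58),
                          glitch_rate = 0.03,
                          missing_rate = c(race = 0.05, education = 0.06,
                                           smoking = 0.03, gdm = 0.03),
                          mar_slope = 0.05,
                          gap_gt7_rate = 0.02,
                          window_miss_rate = 0.02,
                          z_jitter_sd = 0.20,
                          confounding = FALSE,
                          seed = 1L) {
  if (!is.numeric(n_pairs) || n_pairs < 1) stop_field("n_pairs", "must be >= 1")
  if (sigma_y <= 0) stop_field("sigma_y", "must be > 0")
  w <- bmi_mixture$weights
  if (abs(sum(w) - 1) > 1e-8) stop_field("bmi_mixture$weights", "must sum to 1")
  if (any(w < 0)) stop_field("bmi_mixture$weights", "must be >= 0")
  if (length(w) != length(bmi_mixture$means) ||
      length(w) != length(bmi_mixture$sds)) {
    stop_field("bmi_mixture", "weights, means, sds must have equal length")
  }
  if (any(bmi_mixture$sds <= 0)) stop_field("bmi_mixture$sds", "must be > 0")
  probs <- c(glitch_rate, missing_rate, gap_gt7_rate, window_miss_rate,
             covariate_dist$smoking, covariate_dist$gdm, covariate_dist$cohort,
             covariate_dist$race, covariate_dist$education)
  if (any(probs < 0 | probs > 1)) {
    stop_field("rates/probabilities", "must lie in [0, 1]")
  }
  if (abs(sum(covariate_dist$race) - 1) > 1e-8) {
    stop_field("covariate_dist$race", "probabilities must sum to 1")
  }
  if (abs(sum(covariate_dist$education) - 1) > 1e-8) {
    stop_field("covariate_dist$education", "probabilities must sum to 1")
  }
  if (length(growth_schedule) < 1 ||
      (length(growth_schedule) > 1 && any(diff(growth_schedule) <= 0))) {
    stop_field("growth_schedule", "ages must be ascending and non-empty")
  }
  structure(list(
    n_pairs = as.integer(n_pairs), beta = beta, theta = theta,
    sigma_y = sigma_y, bmi_mixture = bmi_mixture,
    covariate_dist = covariate_dist, growth_schedule = growth_schedule,
    glitch_rate = glitch_rate, missing_rate = missing_rate,
    mar_slope = mar_slope, gap_gt7_rate = gap_gt7_rate,
    window_miss_rate = window_miss_rate, z_jitter_sd = z_jitter_sd,
    confounding = isTRUE(confounding), seed = as.integer(seed)
  ), class = "cohort_config")
}
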