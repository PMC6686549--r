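#' Simulate a mother-child cohort with known causal structure
#'
#' Generates maternal pre-pregnancy BMI from a truncated normal mixture,
#' covariates from the configured categorical distributions, the binary
#' mediator (excessive gestational weight gain) from the logistic mediator
#' model, and the child age-4 BMI z-score from the linear outcome model
#' with exposure-mediator interaction. The z-score is then realised as a
#' longitudinal growth series (heights strictly increasing, the last
#' record in the 48-59 month window reproducing the z-score exactly), and
#' raw maternal weights are constructed so that re-deriving GWG and its
#' IOM category recovers the generated mediator. When the configured
#' glitch or missingness rates are positive, [inject_errors()] is applied
#' before returning.
#'
#' The returned `truth` element carries the generating coefficients and
#' the implied closed-form effect decomposition at the default contrast
#' (BMI 30 vs 22, covariates at their expected indicator means), which
#' satisfies `te == nde + nie` exactly.
#'
#' @param config a [cohort_config()].
#' @param lms LMS reference used to realise growth series (default
#'   [synthetic_lms_table()]).
#' @return list of class `synthetic_cohort`: `mothers`, `growth`,
#'   `latent` (per-pair generating mediator/outcome), `truth`,
#'   `corruptions`, `missing`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            lms = synthetic_lms_table()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  dist <- config$covariate_dist

  mothers <- data.frame(
    id = sprintf("m%05d", seq_len(n)),
    race = factor(sample(race_levels, n, TRUE, prob = dist$race),
                  levels = race_levels),
    education = factor(sample(education_levels, n, TRUE,
                              prob = dist$education),
                       levels = education_levels),
    smoking = stats::rbinom(n, 1, dist$smoking),
    gdm = stats::rbinom(n, 1, dist$gdm),
    cohort = stats::rbinom(n, 1, dist$cohort),
    parity = factor(sample(parity_levels, n, TRUE, prob = dist$parity),
                    levels = parity_levels),
    mat_age = pmax(18, stats::rnorm(n, dist$mat_age["mean"],
                                    dist$mat_age["sd"])),
    cesarean = stats::rbinom(n, 1, dist$cesarean),
    gest_age_days = stats::rnorm(n, dist$gest_age_days["mean"],
                                 dist$gest_age_days["sd"]),
    birth_weight_g = stats::rnorm(n, dist$birth_weight_g["mean"],
                                  dist$birth_weight_g["sd"]),
    stringsAsFactors = FALSE
  )

  # maternal pre-pregnancy BMI: truncated mixture (underweight excluded)
  mix <- config$bmi_mixture
  comp <- sample.int(length(mix$weights), n, TRUE, prob = mix$weights)
  bmi <- stats::rnorm(n, mix$means[comp], mix$sds[comp])
  for (it in 1:100) {
    low <- bmi < 18.5
    if (!any(low)) break
    bmi[low] <- stats::rnorm(sum(low), mix$means[comp[low]], mix$sds[comp[low]])
  }
  bmi[bmi < 18.5] <- 18.5
  if (config$confounding) {
    bmi <- bmi + 1.2 * (mothers$race == "black") -
      1.2 * (mothers$education == "college")
  }
  mothers$bmi <- bmi

  Xc <- covariate_matrix(mothers, names(default_beta_covariates_cols()))
  bcov <- config$beta$covariates
  tcov <- config$theta$covariates
  lp_m <- config$beta$intercept + config$beta$exposure * bmi +
    drop(Xc[, names(bcov), drop = FALSE] %*% bcov)
  m_true <- stats::rbinom(n, 1, stats::plogis(lp_m))
  y_true <- config$theta$intercept + config$theta$exposure * bmi +
    config$theta$mediator * m_true + config$theta$interaction * bmi * m_true +
    drop(Xc[, names(tcov), drop = FALSE] %*% tcov) +
    stats::rnorm(n, 0, config$sigma_y)
  y_true <- pmin(pmax(y_true, -4.5), 4.5)  # keep the LMS inverse defined

  # raw maternal weights consistent with the generated mediator
  mat_cat <- as.character(classify_maternal_bmi(bmi))
  gwg <- draw_gwg(mat_cat, m_true)
  mothers$height_cm <- stats::rnorm(n, 163.2, 6.4)
  mothers$weight_pre <- bmi * (mothers$height_cm / 100)^2
  mothers$weight_lmp <- mothers$weight_pre + stats::rnorm(n, 0, 0.8)
  mothers$weight_delivery <- mothers$weight_lmp + gwg * KG_PER_LB
  gap <- sample(0:5, n, TRUE, prob = c(0.35, 0.25, 0.15, 0.1, 0.08, 0.07))
  late <- stats::runif(n) < config$gap_gt7_rate
  gap[late] <- sample(8:14, sum(late), TRUE)
  mothers$delivery_gap_days <- gap

  sex <- ifelse(stats::rbinom(n, 1, dist$male) == 1, "male", "female")
  mothers$male <- as.integer(sex == "male")
  no_window <- stats::runif(n) < config$window_miss_rate
  growth <- build_growth(mothers$id, sex, y_true, config$growth_schedule,
                         lms, config$z_jitter_sd, no_window)

  truth <- cohort_truth(config)
  out <- structure(list(
    mothers = mothers, growth = growth,
    latent = data.frame(id = mothers$id, m_true = m_true, y_true = y_true,
                        gwg_true = gwg, no_window = no_window,
                        stringsAsFactors = FALSE),
    truth = truth,
    corruptions = empty_corruptions(), missing = empty_missing(),
    config = config
  ), class = "synthetic_cohort")
  if (config$glitch_rate > 0 || any(config$missing_rate > 0)) {
    out <- inject_errors(out, config)
  }
  out
}

default_beta_covariates_cols <- function() {
  c(race = NA, education = NA, smoking = NA, gdm = NA, cohort = NA)
}

# true decomposition implied by a configuration (closed form)
cohort_truth <- function(config, a = 30, a_star = 22, m_cde = 0) {
  cvals <- expected_covariate_means(config$covariate_dist)
  mfit <- mediator_coefs(config$beta$intercept, config$beta$exposure,
                         config$beta$covariates)
  ofit <- outcome_coefs(config$theta$intercept, config$theta$exposure,
                        config$theta$mediator, config$theta$interaction,
                        config$theta$covariates, sigma = config$sigma_y)
  eff <- decompose_effects(ofit, mfit, a = a, a_star = a_star, m_cde = m_cde,
                           cvals = cvals)
  list(beta = config$beta, theta = config$theta, sigma_y = config$sigma_y,
       cvals = cvals, effects = eff)
}

# GWG (lbs) draw consistent with mediator status and the IOM ranges
draw_gwg <- function(mat_cat, excessive, p_inadequate = 0.47) {
  ranges <- iom_gwg_ranges()
  i <- match(mat_cat, ranges$category)
  lo <- ranges$lower[i]; hi <- ranges$upper[i]
  n <- length(mat_cat)
  gwg <- numeric(n)
  exc <- excessive == 1
  gwg[exc] <- hi[exc] + stats::rgamma(sum(exc), shape = 1.8, scale = 6)
  nexc <- which(!exc)
  inad <- stats::runif(length(nexc)) < p_inadequate
  lo_n <- lo[nexc]; hi_n <- hi[nexc]
  gwg[nexc[inad]] <- lo_n[inad] - stats::rgamma(sum(inad), shape = 1.5, scale = 4)
  gwg[nexc[!inad]] <- stats::runif(sum(!inad), lo_n[!inad], hi_n[!inad])
  gwg
}

# realise all children's growth series (common visit schedule)
build_growth <- function(ids, sex, target_z, schedule, lms, jitter_sd,
                         no_window, window = c(48, 59)) {
  n <- length(ids)
  k <- length(schedule)
  rng <- range(lms$age)
  if (min(schedule) < rng[1] || max(schedule) > rng[2]) {
    stop(sprintf("growth schedule outside LMS range [%g, %g] months",
                 rng[1], rng[2]), call. = FALSE)
  }
  in_win <- schedule >= window[1] & schedule <= window[2]
  sel_col <- if (any(in_win)) max(which(in_win)) else NA_integer_

  # strictly increasing heights: base at first visit plus positive increments
  h <- matrix(0, n, k)
  h[, 1] <- stats::rnorm(n, 87, 3.2) + 0.55 * (schedule[1] - 24)
  if (k > 1) {
    for (j in 2:k) {
      gap <- schedule[j] - schedule[j - 1]
      inc <- pmax(0.08 * gap, 0.55 * gap + stats::rnorm(n, 0, 0.6))
      h[, j] <- h[, j - 1] + inc
    }
  }

  z <- matrix(stats::rnorm(n * k, 0, jitter_sd), n, k) + target_z
  if (!is.na(sel_col)) z[, sel_col] <- target_z  # outcome record is exact
  z <- pmin(pmax(z, -4.8), 4.8)

  long <- data.frame(
    id = rep(ids, each = k),
    sex = rep(sex, each = k),
    age = rep(as.numeric(schedule), n),
    height = as.vector(t(h)),
    z = as.vector(t(z)),
    stringsAsFactors = FALSE
  )
  par <- lookup_lms(lms, long$sex, long$age)
  bmi <- lms_inverse(long$z, par$L, par$M, par$S)
  long$weight <- bmi * (long$height / 100)^2
  long$z <- NULL
  if (any(no_window)) {
    drop <- long$id %in% ids[no_window] & long$age >= window[1]
    long <- long[!drop, , drop = FALSE]
  }
  rownames(long) <- NULL
  long
}

#' Realise one child's growth series from a target age-4 z-score
#'
#' Builds a longitudinal (age, height, weight) series along a constant-z
#' BMI trajectory with per-visit jitter, such that heights are strictly
#' increasing and the last record with age in the 48-59 month window has a
#' BMI whose LMS z-score equals `target_z` to within numerical precision.
#'
#' @param target_z the child's age-4 BMI z-score.
#' @param sex "male" or "female".
#' @param schedule visit ages in months, ascending, within the LMS range.
#' @param lms an `lms_table`.
#' @param jitter_sd SD of visit-level z jitter (default 0.2).
#' @param seed optional RNG seed.
#' @return data.frame with columns `id`, `sex`, `age`, `height`, `weight`.
#' @export
generate_growth_series <- function(target_z, sex, schedule,
                                   lms = synthetic_lms_table(),
                                   jitter_sd = 0.2, seed = NULL) {
  if (length(schedule) < 1) stop("schedule must be non-empty", call. = FALSE)
  if (length(schedule) > 1 && any(diff(schedule) <= 0)) {
    stop("schedule ages must be strictly ascending", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  build_growth("child1", sex, target_z, schedule, lms, jitter_sd,
               no_window = FALSE)
}

empty_corruptions <- function() {
  data.frame(id = character(0), age = numeric(0), old = numeric(0),
             new = numeric(0), stringsAsFactors = FALSE)
}
empty_missing <- function() {
  data.frame(id = character(0), variable = character(0),
             stringsAsFactors = FALSE)
}

#' Inject growth glitches and covariate missingness
#'
#' Corrupts each eligible height record independently with probability
#' `glitch_rate` by subtracting a positive offset large enough to undercut
#' the previous visit's height, so the series departs from monotonicity at
#' that record (first visits are ineligible: a drop there is undetectable
#' under the running-maximum rule). Sets maternal variables missing with
#' their configured per-variable rates; the missingness log-odds shift
#' linearly with the (always observed) maternal BMI, making the mechanism
#' MAR. All corruption and missingness positions are recorded in the
#' returned object so tests can assert against them.
#'
#' @param cohort a `synthetic_cohort`.
#' @param config a [cohort_config()] supplying `glitch_rate`,
#'   `missing_rate` and `mar_slope`.
#' @return the cohort with corrupted `growth`, `mothers` with `NA`s, and
#'   populated `corruptions` / `missing` records.
#' @export
inject_errors <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  g <- cohort$growth
  g <- g[order(g$id, g$age), , drop = FALSE]
  first <- !duplicated(g$id)
  eligible <- which(!first)
  hit <- eligible[stats::runif(length(eligible)) < config$glitch_rate]
  if (length(hit)) {
    prev <- hit - 1
    offset <- (g$height[hit] - g$height[prev]) + stats::runif(length(hit), 0.5, 8)
    old <- g$height[hit]
    g$height[hit] <- g$height[hit] - offset
    cohort$corruptions <- rbind(cohort$corruptions,
                                data.frame(id = g$id[hit], age = g$age[hit],
                                           old = old, new = g$height[hit],
                                           stringsAsFactors = FALSE))
  }
  cohort$growth <- g

  mr <- config$missing_rate
  if (length(mr)) {
    bmi_c <- cohort$mothers$bmi - mean(cohort$mothers$bmi)
    for (v in names(mr)) {
      if (mr[[v]] <= 0) next
      if (!v %in% names(cohort$mothers)) next
      p <- stats::plogis(stats::qlogis(mr[[v]]) + config$mar_slope * bmi_c)
      miss <- stats::runif(nrow(cohort$mothers)) < p
      if (any(miss)) {
        cohort$mothers[[v]][miss] <- NA
        cohort$missing <- rbind(cohort$missing,
                                data.frame(id = cohort$mothers$id[miss],
                                           variable = v,
                                           stringsAsFactors = FALSE))
      }
    }
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic mother-child cohort: %d pairs, %d growth records\n",
              nrow(x$mothers), nrow(x$growth)))
  eff <- x$truth$effects
  cat(sprintf("  true effects (a = %g vs %g): CDE %.3f, NDE %.3f, NIE %.3f, TE %.3f\n",
              eff$a, eff$a_star, eff$cde, eff$nde, eff$nie, eff$te))
  if (nrow(x$corruptions)) {
    cat(sprintf("  %d corrupted height records\n", nrow(x$corruptions)))
  }
  if (nrow(x$missing)) {
    cat(sprintf("  %d missing cells across %d variables\n", nrow(x$missing),
                length(unique(x$missing$variable))))
  }
  invisible(x)
}
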