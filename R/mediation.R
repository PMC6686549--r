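#' Closed-form counterfactual effect decomposition
#'
#' For a linear outcome model with binary mediator and exposure-mediator
#' interaction,
#' \deqn{E[Y | a, m, c] = \theta_0 + \theta_1 a + \theta_2 m + \theta_3 a m
#'   + \theta_4' c}
#' and a logistic mediator model with \eqn{p(a) = \mathrm{expit}(\beta_0 +
#' \beta_1 a + \beta_2' c)}, the product-method decomposition at the
#' exposure contrast `a` vs `a_star`, conditional on covariate values `c`,
#' is
#' \deqn{CDE = (\theta_1 + \theta_3 m)\,(a - a^*)}
#' \deqn{NDE = (\theta_1 + \theta_3 p(a^*))\,(a - a^*)}
#' \deqn{NIE = (\theta_2 + \theta_3 a)\,(p(a) - p(a^*))}
#' with total effect `TE = NDE + NIE` (exact by construction) and
#' proportion mediated `NIE/TE` (undefined, `NA`, when `TE = 0`).
#'
#' @param ofit outcome-model coefficients, a `gwg_ofit`
#'   ([fit_outcome_model()] or [outcome_coefs()]).
#' @param mfit mediator-model coefficients, a `gwg_mfit`.
#' @param a,a_star exposed / unexposed exposure values (default BMI 30
#'   vs 22).
#' @param m_cde mediator level the controlled direct effect fixes for
#'   everyone (default 0, i.e. gain not excessive).
#' @param cvals named covariate values at which to condition (indicator-
#'   coded scale, e.g. column means of the design); may be `NULL` when the
#'   models have no covariates.
#' @param cmat optional covariate design matrix: when supplied the
#'   decomposition is averaged over its rows (marginal version) instead of
#'   conditioning on `cvals`.
#' @return list of class `gwg_effects` with elements `cde`, `nde`, `nie`,
#'   `te`, `pm` and the contrast.
#' @export
decompose_effects <- function(ofit, mfit, a = 30, a_star = 22, m_cde = 0,
                              cvals = NULL, cmat = NULL) {
  stopifnot(inherits(ofit, "gwg_ofit"), inherits(mfit, "gwg_mfit"))
  if (!isTRUE(mfit$converged)) {
    stop("decompose_effects: mediator fit did not converge", call. = FALSE)
  }
  d <- a - a_star
  lc <- mediator_covariate_lp(mfit, cvals, cmat)
  p_a <- stats::plogis(mfit$beta0 + mfit$beta1 * a + lc)
  p_astar <- stats::plogis(mfit$beta0 + mfit$beta1 * a_star + lc)
  cde <- (ofit$theta1 + ofit$theta3 * m_cde) * d
  nde <- mean((ofit$theta1 + ofit$theta3 * p_astar) * d)
  nie <- mean((ofit$theta2 + ofit$theta3 * a) * (p_a - p_astar))
  te <- nde + nie
  pm <- if (te == 0) NA_real_ else nie / te
  structure(list(cde = unname(cde), nde = unname(nde), nie = unname(nie),
                 te = unname(te), pm = unname(pm),
                 a = a, a_star = a_star, m_cde = m_cde),
            class = "gwg_effects")
}

mediator_covariate_lp <- function(mfit, cvals, cmat) {
  if (!is.null(cmat)) {
    if (length(mfit$beta2) == 0) return(rep(0, nrow(cmat)))
    return(drop(cmat[, names(mfit$beta2), drop = FALSE] %*% mfit$beta2))
  }
  if (length(mfit$beta2) == 0) return(0)
  if (is.null(cvals)) {
    stop("decompose_effects: covariate values required (cvals or cmat)",
         call. = FALSE)
  }
  sum(mfit$beta2 * cvals[names(mfit$beta2)])
}

#' Monte-Carlo potential-outcomes oracle
#'
#' Realises the counterfactual definitions of the natural effects directly
#' by simulation: draws `M(a) ~ Bernoulli(p(a))` (coupled across exposure
#' levels through a shared uniform) and evaluates the structural outcome
#' `Y(a, m)`, returning
#' `NDE = mean(Y(a, M(a*))) - mean(Y(a*, M(a*)))` and
#' `NIE = mean(Y(a, M(a))) - mean(Y(a, M(a*)))` with Monte-Carlo standard
#' errors. Serves as the brute-force cross-check for
#' [decompose_effects()]; residual outcome noise can optionally be drawn
#' to confirm it cancels in expectation.
#'
#' @inheritParams decompose_effects
#' @param covariate_sample optional covariate design matrix sampled from
#'   (with replacement) per Monte-Carlo draw; `NULL` conditions on `cvals`.
#' @param n_mc Monte-Carlo draws (>= 1).
#' @param seed RNG seed.
#' @param include_noise draw the outcome residual (tests that it cancels).
#' @return list with `nde`, `nie`, `te`, `se_nde`, `se_nie`, `n_mc`.
#' @export
mc_counterfactual_oracle <- function(ofit, mfit, a = 30, a_star = 22,
                                     cvals = NULL, covariate_sample = NULL,
                                     n_mc = 1e6, seed = 1,
                                     include_noise = FALSE) {
  stopifnot(n_mc >= 1)
  set.seed(seed)
  n_mc <- as.integer(n_mc)
  if (!is.null(covariate_sample)) {
    idx <- sample.int(nrow(covariate_sample), n_mc, replace = TRUE)
    lc <- mediator_covariate_lp(mfit, NULL, covariate_sample)[idx]
  } else {
    lc <- mediator_covariate_lp(mfit, cvals, NULL)
  }
  p_a <- stats::plogis(mfit$beta0 + mfit$beta1 * a + lc)
  p_astar <- stats::plogis(mfit$beta0 + mfit$beta1 * a_star + lc)
  u <- stats::runif(n_mc)
  m_a <- as.numeric(u < p_a)
  m_astar <- as.numeric(u < p_astar)
  noise <- function() {
    if (include_noise) stats::rnorm(n_mc, 0, ofit$sigma) else 0
  }
  y <- function(aa, mm) {
    ofit$theta0 + ofit$theta1 * aa + ofit$theta2 * mm + ofit$theta3 * aa * mm +
      noise()
  }
  d_nde <- y(a, m_astar) - y(a_star, m_astar)
  d_nie <- y(a, m_a) - y(a, m_astar)
  list(nde = mean(d_nde), nie = mean(d_nie),
       te = mean(d_nde) + mean(d_nie),
       se_nde = stats::sd(d_nde) / sqrt(n_mc),
       se_nie = stats::sd(d_nie) / sqrt(n_mc),
       n_mc = n_mc)
}

# one resample -> effect vector (cde, nde, nie, te, pm); NULL on fit failure
boot_one <- function(idx, A, M, Y, Xc, interaction, a, a_star, m_cde,
                     conditional) {
  Ab <- A[idx]; Mb <- M[idx]; Yb <- Y[idx]
  Xcb <- Xc[idx, , drop = FALSE]
  Xm <- cbind(1, Ab, Xcb)
  Xo <- cbind(1, Ab, Mb, if (interaction) Ab * Mb, Xcb)
  res <- tryCatch({
    mf <- suppressWarnings(logit_irls(Xm, Mb))
    of <- stats::lm.fit(Xo, Yb)
    if (of$rank < ncol(Xo)) stop("rank-deficient resample")
    list(mf = mf, of = of)
  }, error = function(e) NULL)
  if (is.null(res)) return(NULL)
  mf <- res$mf
  of <- res$of
  k <- ncol(Xc)
  beta2 <- if (k) mf$coef[-(1:2)] else numeric(0)
  th <- of$coefficients
  lc <- if (k) drop(Xcb %*% beta2) else 0
  if (conditional == "means") lc <- mean(lc)
  p_a <- stats::plogis(mf$coef[1] + mf$coef[2] * a + lc)
  p_astar <- stats::plogis(mf$coef[1] + mf$coef[2] * a_star + lc)
  th3 <- if (interaction) th[4] else 0
  d <- a - a_star
  cde <- (th[2] + th3 * m_cde) * d
  nde <- mean((th[2] + th3 * p_astar) * d)
  nie <- mean((th[3] + th3 * a) * (p_a - p_astar))
  te <- nde + nie
  c(cde = unname(cde), nde = unname(nde), nie = unname(nie), te = unname(te),
    pm = if (te == 0) NA_real_ else unname(nie / te))
}

#' Nonparametric bootstrap of the effect decomposition
#'
#' Resamples analysis rows with replacement, refits both models and
#' recomputes the decomposition per resample; 95% percentile intervals.
#' Resamples whose fits fail (e.g. separation) are dropped and counted;
#' more than 10% failures is an error. Proportion-mediated intervals use
#' the bootstrap distribution of NIE/TE with replicates whose total effect
#' changes sign (relative to the full-data estimate) dropped and counted.
#'
#' @inheritParams gwg_mediate
#' @param B number of bootstrap resamples.
#' @return list: `replicates` (B x 5 matrix), `ci` (5 x 2), `n_fail`,
#'   `n_pm_dropped`.
#' @export
bootstrap_decomposition <- function(data, covariates = character(0),
                                    exposure = "bmi",
                                    mediator = "gwg_excessive",
                                    outcome = "zbmi4",
                                    a = 30, a_star = 22, m_cde = 0,
                                    interaction = TRUE,
                                    conditional = c("means", "marginal"),
                                    B = 1000, seed = NULL) {
  conditional <- match.arg(conditional)
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  A <- data[[exposure]]; M <- data[[mediator]]; Y <- data[[outcome]]
  Xc <- covariate_matrix(data, covariates)
  n <- length(Y)
  point <- boot_one(seq_len(n), A, M, Y, Xc, interaction, a, a_star, m_cde,
                    conditional)
  if (is.null(point)) stop("bootstrap: full-data fit failed", call. = FALSE)
  reps <- matrix(NA_real_, B, 5,
                 dimnames = list(NULL, c("cde", "nde", "nie", "te", "pm")))
  n_fail <- 0L
  for (b in seq_len(B)) {
    r <- boot_one(sample.int(n, n, replace = TRUE), A, M, Y, Xc, interaction,
                  a, a_star, m_cde, conditional)
    if (is.null(r)) n_fail <- n_fail + 1L else reps[b, ] <- r
  }
  if (n_fail > 0.10 * B) {
    stop(sprintf(
      "bootstrap: %d of %d resamples failed to fit (>10%%); a larger sample is advised",
      n_fail, B), call. = FALSE)
  }
  reps <- reps[stats::complete.cases(reps[, 1:4]), , drop = FALSE]
  sgn <- sign(point["te"])
  pm_keep <- sign(reps[, "te"]) == sgn & reps[, "te"] != 0
  n_pm_dropped <- sum(!pm_keep)
  ci <- t(apply(reps[, 1:4, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE))
  pm_ci <- if (any(pm_keep)) {
    stats::quantile(reps[pm_keep, "pm"], probs = c(0.025, 0.975), names = FALSE)
  } else c(NA_real_, NA_real_)
  ci <- rbind(ci, pm = pm_ci)
  dimnames(ci) <- list(c("cde", "nde", "nie", "te", "pm"), c("2.5%", "97.5%"))
  list(replicates = reps, ci = ci, n_fail = n_fail,
       n_pm_dropped = n_pm_dropped)
}

#' Fit a counterfactual mediation analysis
#'
#' The package's central fitting function. Fits the logistic mediator model
#' and the linear outcome model (with exposure-mediator interaction by
#' default), computes the controlled direct, natural direct and natural
#' indirect effects at the exposure contrast `a` vs `a_star` by the
#' closed-form product-method decomposition ([decompose_effects()]), and
#' bootstraps 95% percentile confidence intervals.
#'
#' Rows with missing values in any used column are dropped (complete-case);
#' use [gwg_mediate_mi()] for multiply-imputed analyses.
#'
#' @param data data.frame of analysis rows (see [derive_pairs()]).
#' @param covariates covariate column names; [gwg_covariates()] gives the
#'   standard minimal and extended adjustment sets.
#' @param exposure,mediator,outcome column names of the continuous
#'   exposure, binary mediator and continuous outcome.
#' @param a,a_star exposure contrast (default BMI 30 vs 22).
#' @param m_cde mediator level fixed by the CDE (default 0).
#' @param interaction include exposure x mediator in the outcome model.
#' @param conditional `"means"` conditions the decomposition on covariate
#'   column means; `"marginal"` averages it over the empirical covariate
#'   rows.
#' @param boot bootstrap resamples (0 skips interval estimation).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `gwg_mediation`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_pairs = 300, seed = 1))
#' rows <- derive_pairs(coh$mothers, coh$growth, synthetic_lms_table())
#' fit <- gwg_mediate(rows, boot = 50, seed = 1)
#' fit
#' @export
gwg_mediate <- function(data, covariates = gwg_covariates("minimal"),
                        exposure = "bmi", mediator = "gwg_excessive",
                        outcome = "zbmi4", a = 30, a_star = 22, m_cde = 0,
                        interaction = TRUE,
                        conditional = c("means", "marginal"),
                        boot = 1000, seed = NULL) {
  conditional <- match.arg(conditional)
  used <- c(exposure, mediator, outcome, covariates)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop(sprintf("gwg_mediate: column(s) not in data: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cc <- stats::complete.cases(data[used])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]

  mfit <- fit_mediator_model(data, covariates, exposure, mediator)
  ofit <- fit_outcome_model(data, covariates, exposure, mediator, outcome,
                            interaction)
  Xc <- covariate_matrix(data, covariates)
  cvals <- if (ncol(Xc)) colMeans(Xc) else NULL
  effects <- decompose_effects(
    ofit, mfit, a = a, a_star = a_star, m_cde = m_cde,
    cvals = if (conditional == "means") cvals else NULL,
    cmat = if (conditional == "marginal") Xc else NULL
  )
  bt <- NULL
  if (boot > 0) {
    bt <- bootstrap_decomposition(
      data, covariates, exposure, mediator, outcome,
      a = a, a_star = a_star, m_cde = m_cde, interaction = interaction,
      conditional = conditional, B = boot, seed = seed
    )
  }
  structure(list(
    effects = effects,
    ci = if (is.null(bt)) NULL else bt$ci,
    boot = if (is.null(bt)) NULL else
      list(B = boot, n_fail = bt$n_fail, n_pm_dropped = bt$n_pm_dropped,
           replicates = bt$replicates),
    mediator_fit = mfit, outcome_fit = ofit,
    contrast = list(a = a, a_star = a_star, m_cde = m_cde),
    conditional = conditional, cvals = cvals,
    covariates = covariates,
    vars = c(exposure = exposure, mediator = mediator, outcome = outcome),
    n = nrow(data), n_dropped = n_dropped,
    call = match.call()
  ), class = "gwg_mediation")
}

#' Standard covariate adjustment sets
#'
#' `"minimal"` is the minimal sufficient adjustment set (race, education as
#' SES proxy, gestational diabetes, smoking in pregnancy, enrolment
#' period); `"extended"` adds parturition and maternal clinical variables
#' for the sensitivity analysis.
#'
#' @param set `"minimal"` or `"extended"`.
#' @return character vector of column names.
#' @export
gwg_covariates <- function(set = c("minimal", "extended")) {
  set <- match.arg(set)
  minimal <- c("race", "education", "gdm", "smoking", "cohort")
  if (set == "minimal") return(minimal)
  c(minimal, "mat_age", "cesarean", "gest_age_days", "male",
    "birth_weight_g", "parity")
}

#' @export
coef.gwg_mediation <- function(object, ...) {
  with(object$effects, c(cde = cde, nde = nde, nie = nie, te = te, pm = pm))
}

#' @export
confint.gwg_mediation <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$ci)) stop("no bootstrap intervals (boot = 0)", call. = FALSE)
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.gwg_mediation <- function(x, digits = 3, ...) {
  cat("Counterfactual mediation analysis\n")
  v <- x$vars
  cat(sprintf("  exposure %s -> mediator %s -> outcome %s (n = %d",
              v["exposure"], v["mediator"], v["outcome"], x$n))
  if (x$n_dropped > 0) cat(sprintf(", %d incomplete rows dropped", x$n_dropped))
  cat(")\n")
  ct <- x$contrast
  cat(sprintf("  contrast: a = %g vs a* = %g; CDE at m = %g; %s covariates\n\n",
              ct$a, ct$a_star, ct$m_cde,
              if (length(x$covariates)) "adjusted for" else "no"))
  eff <- coef(x)
  tab <- data.frame(Estimate = eff[1:4])
  if (!is.null(x$ci)) {
    tab$`2.5%` <- x$ci[1:4, 1]
    tab$`97.5%` <- x$ci[1:4, 2]
  }
  rownames(tab) <- c("CDE", "NDE", "NIE", "Total effect")
  print(round(tab, digits))
  if (!is.na(eff["pm"])) {
    cat(sprintf("\nProportion mediated: %.2f%%", 100 * eff["pm"]))
    if (!is.null(x$ci)) {
      cat(sprintf(" (95%% CI %.2f%%, %.2f%%)",
                  100 * x$ci["pm", 1], 100 * x$ci["pm", 2]))
    }
    cat("\n")
  } else {
    cat("\nProportion mediated: undefined (total effect = 0)\n")
  }
  invisible(x)
}

#' @export
summary.gwg_mediation <- function(object, ...) {
  mf <- object$mediator_fit; of <- object$outcome_fit
  mco <- c(`(Intercept)` = mf$beta0, exposure = mf$beta1, mf$beta2)
  oco <- c(`(Intercept)` = of$theta0, exposure = of$theta1,
           mediator = of$theta2, `exposure:mediator` = of$theta3, of$theta4)
  structure(list(fit = object,
                 mediator_coef = mco, mediator_se = sqrt(diag(mf$vcov)),
                 outcome_coef = oco, sigma = of$sigma,
                 outcome_se = sqrt(diag(of$vcov))),
            class = "summary.gwg_mediation")
}

#' @export
print.summary.gwg_mediation <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nMediator model (logistic, log-odds scale):\n")
  print(round(x$mediator_coef, digits))
  cat("\nOutcome model (linear, BMI-z scale); residual SD",
      format(round(x$sigma, digits)), "\n")
  print(round(x$outcome_coef, digits))
  invisible(x)
}

#' Plot the effect decomposition
#'
#' Point estimates with bootstrap intervals for CDE, NDE, NIE and the total
#' effect, on the child BMI z-score scale.
#'
#' @param x a `gwg_mediation`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gwg_mediation <- function(x, ...) {
  eff <- coef(x)[1:4]
  labs <- c("CDE", "NDE", "NIE", "TE")
  lo <- hi <- eff
  if (!is.null(x$ci)) { lo <- x$ci[1:4, 1]; hi <- x$ci[1:4, 2] }
  graphics::plot(eff, seq_along(eff), xlim = range(0, lo, hi), yaxt = "n",
                 xlab = "Effect on child BMI z-score", ylab = "",
                 pch = 19, ...)
  graphics::axis(2, at = seq_along(eff), labels = labs, las = 1)
  graphics::segments(lo, seq_along(eff), hi, seq_along(eff))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}
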