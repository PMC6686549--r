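# Low-level model fitting for the two mediation regressions.
#
# The mediator model is a maximum-likelihood logistic regression of the
# binary mediator (excessive GWG) on the continuous exposure (pre-pregnancy
# BMI) and covariates; the outcome model is an OLS regression of the child
# age-4 BMI z-score on exposure, mediator, their interaction and covariates.

# covariate design matrix (indicator-coded, no intercept column)
covariate_matrix <- function(data, covariates) {
  if (length(covariates) == 0) {
    return(matrix(numeric(0), nrow(data), 0))
  }
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols)) {
    stop(sprintf("covariate column(s) not in data: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- data[covariates]
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  X <- stats::model.matrix(~ ., df)
  X[, -1, drop = FALSE]
}

logit_irls <- function(X, y, maxit = 50L, tol = 1e-9) {
  # IRLS with an iteration cap and a separation check
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = list(maxit = maxit, epsilon = tol))
  mu <- fit$fitted.values
  eta <- fit$linear.predictors
  separated <- any(abs(eta) > 20 & (mu < 1e-8 | mu > 1 - 1e-8)) &&
    max(abs(fit$coefficients), na.rm = TRUE) > 15
  if (separated) {
    stop("mediator model: (quasi-)complete separation detected", call. = FALSE)
  }
  if (!fit$converged) {
    stop("mediator model: IRLS failed to converge within iteration budget",
         call. = FALSE)
  }
  w <- mu * (1 - mu)
  xtwx <- crossprod(X * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) {
    stop("mediator model: information matrix not positive definite",
         call. = FALSE)
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coef = fit$coefficients, vcov = vcov, converged = fit$converged)
}

#' Mediator-model coefficients as a decomposable object
#'
#' Packages logistic-model coefficients (log-odds scale) so that
#' [decompose_effects()] and [mc_counterfactual_oracle()] can be used with
#' known "true" coefficients as well as fitted ones.
#'
#' @param beta0 intercept.
#' @param beta1 exposure slope (per BMI unit).
#' @param beta2 named covariate coefficients (may be empty).
#' @param vcov,n,converged optional fit metadata.
#' @return object of class `gwg_mfit`.
#' @export
mediator_coefs <- function(beta0, beta1, beta2 = numeric(0), vcov = NULL,
                           n = NA_integer_, converged = TRUE) {
  structure(list(beta0 = unname(beta0), beta1 = unname(beta1), beta2 = beta2,
                 vcov = vcov, n = n, converged = converged),
            class = "gwg_mfit")
}

#' Outcome-model coefficients as a decomposable object
#'
#' @param theta0 intercept (BMI-z scale).
#' @param theta1 exposure slope.
#' @param theta2 mediator main effect.
#' @param theta3 exposure-by-mediator interaction (0 for a no-interaction
#'   model).
#' @param theta4 named covariate coefficients (may be empty).
#' @param sigma residual SD.
#' @param vcov,n optional fit metadata.
#' @return object of class `gwg_ofit`.
#' @export
outcome_coefs <- function(theta0, theta1, theta2, theta3 = 0,
                          theta4 = numeric(0), sigma = NA_real_, vcov = NULL,
                          n = NA_integer_) {
  structure(list(theta0 = unname(theta0), theta1 = unname(theta1),
                 theta2 = unname(theta2), theta3 = unname(theta3),
                 theta4 = theta4, sigma = sigma, vcov = vcov, n = n),
            class = "gwg_ofit")
}

#' Fit the mediator model (logistic regression)
#'
#' @param data data.frame of analysis rows (no missing values in the used
#'   columns).
#' @param covariates character vector of covariate column names.
#' @param exposure,mediator column names (defaults `bmi`, `gwg_excessive`).
#' @return a `gwg_mfit` (see [mediator_coefs()]).
#' @export
fit_mediator_model <- function(data, covariates = character(0),
                               exposure = "bmi", mediator = "gwg_excessive") {
  y <- data[[mediator]]
  if (anyNA(y) || anyNA(data[[exposure]])) {
    stop("fit_mediator_model: missing values in exposure/mediator", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("fit_mediator_model: mediator is constant", call. = FALSE)
  }
  Xc <- covariate_matrix(data, covariates)
  X <- cbind(`(Intercept)` = 1, exposure = data[[exposure]], Xc)
  colnames(X)[2] <- exposure
  f <- logit_irls(X, y)
  b <- f$coef
  mediator_coefs(beta0 = b[1], beta1 = b[2],
                 beta2 = if (ncol(Xc)) b[-(1:2)] else numeric(0),
                 vcov = f$vcov, n = length(y), converged = TRUE)
}

#' Fit the outcome model (linear regression)
#'
#' OLS of the outcome on exposure, mediator, (optionally) their interaction
#' and covariates, with closed-form coefficients and covariance.
#'
#' @inheritParams fit_mediator_model
#' @param outcome outcome column name (default `zbmi4`).
#' @param interaction include the exposure-by-mediator product term
#'   (default `TRUE`).
#' @return a `gwg_ofit` (see [outcome_coefs()]).
#' @export
fit_outcome_model <- function(data, covariates = character(0),
                              exposure = "bmi", mediator = "gwg_excessive",
                              outcome = "zbmi4", interaction = TRUE) {
  y <- data[[outcome]]
  a <- data[[exposure]]
  m <- data[[mediator]]
  if (anyNA(y) || anyNA(a) || anyNA(m)) {
    stop("fit_outcome_model: missing values in used columns", call. = FALSE)
  }
  Xc <- covariate_matrix(data, covariates)
  X <- cbind(1, a, m, if (interaction) a * m, Xc)
  colnames(X) <- c("(Intercept)", exposure, mediator,
                   if (interaction) paste0(exposure, ":", mediator),
                   colnames(Xc))
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    stop(sprintf("outcome model design is rank deficient (collinear: %s)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  p <- ncol(X); n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma <- sqrt(rss / max(n - p, 1))
  xtx_inv <- chol2inv(qr.R(fit$qr))
  vcov <- sigma^2 * xtx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  b <- fit$coefficients
  k <- if (interaction) 4 else 3
  outcome_coefs(theta0 = b[1], theta1 = b[2], theta2 = b[3],
                theta3 = if (interaction) b[4] else 0,
                theta4 = if (ncol(Xc)) b[-seq_len(k)] else numeric(0),
                sigma = sigma, vcov = vcov, n = n)
}
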