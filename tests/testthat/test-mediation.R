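# independent Newton-Raphson logistic fit (oracle for the IRLS path)
logit_oracle <- function(X, y, iter = 60) {
  b <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    p <- plogis(drop(X %*% b))
    W <- p * (1 - p)
    step <- solve(crossprod(X, X * W), crossprod(X, y - p))
    b <- b + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  b
}

test_that("outcome model: degenerate and exact-fit cases", {
  d <- data.frame(bmi = c(20, 25, 30, 35), gwg_excessive = c(0, 1, 0, 1),
                  zbmi4 = rep(1.3, 4))
  f <- fit_outcome_model(d, interaction = FALSE)
  expect_equal(f$theta0, 1.3)
  expect_equal(f$theta1, 0)
  expect_equal(f$theta2, 0)
  d$zbmi4 <- 1 + 0.5 * d$bmi
  f <- fit_outcome_model(d, interaction = FALSE)
  expect_equal(f$theta0, 1)
  expect_equal(f$theta1, 0.5)
  expect_equal(f$sigma, 0, tolerance = 1e-10)
})

test_that("outcome model equals the normal-equations solution", {
  d <- toy_rows(n = 120, seed = 14)
  d$c1 <- rnorm(120)
  f <- fit_outcome_model(d, covariates = "c1")
  X <- cbind(1, d$bmi, d$gwg_excessive, d$bmi * d$gwg_excessive, d$c1)
  bh <- solve(t(X) %*% X, t(X) %*% d$zbmi4)
  expect_equal(unname(c(f$theta0, f$theta1, f$theta2, f$theta3, f$theta4)),
               drop(bh), tolerance = 1e-10)
})

test_that("outcome model reports collinear columns", {
  d <- toy_rows(n = 60, seed = 2)
  d$dup <- d$bmi
  expect_error(fit_outcome_model(d, covariates = "dup"), "rank deficient")
})

test_that("mediator model: symmetry, oracle agreement, error conditions", {
  # perfectly balanced 2x2: no exposure effect
  d <- data.frame(bmi = rep(c(0, 1), each = 4),
                  gwg_excessive = rep(c(0, 1), 4))
  f <- fit_mediator_model(d)
  expect_equal(f$beta1, 0, tolerance = 1e-9)
  # agreement with an independent Newton fit
  d <- toy_rows(n = 400, seed = 8)
  d$c1 <- rnorm(400)
  f <- fit_mediator_model(d, covariates = "c1")
  X <- cbind(1, d$bmi, d$c1)
  expect_equal(unname(c(f$beta0, f$beta1, f$beta2)),
               logit_oracle(X, d$gwg_excessive), tolerance = 1e-6)
  expect_error(fit_mediator_model(
    data.frame(bmi = 1:10, gwg_excessive = rep(1L, 10))), "constant")
  sep <- data.frame(bmi = c(1:5, 11:15),
                    gwg_excessive = rep(c(0L, 1L), each = 5))
  expect_error(suppressWarnings(fit_mediator_model(sep)), "separation")
})

test_that("a null exposure-mediator association is estimated as null", {
  set.seed(77)
  n <- 20000
  A <- runif(n, 19, 40)
  M <- rbinom(n, 1, 0.5)           # independent of A
  f <- fit_mediator_model(data.frame(bmi = A, gwg_excessive = M))
  expect_lt(abs(f$beta1) / sqrt(f$vcov["bmi", "bmi"]), 3)
})

test_that("null contrast and no-interaction identities", {
  s <- rand_coef_set(101)
  eff0 <- decompose_effects(s$ofit, s$mfit, a = 25, a_star = 25,
                            cvals = s$cvals)
  expect_equal(eff0$cde, 0); expect_equal(eff0$nde, 0); expect_equal(eff0$nie, 0)
  # theta3 = 0: CDE equals NDE for any m, NIE = theta2 * (p(a) - p(a*))
  o2 <- s$ofit; o2$theta3 <- 0
  for (m in c(0, 0.4, 1)) {
    e <- decompose_effects(o2, s$mfit, a = 30, a_star = 22, m_cde = m,
                           cvals = s$cvals)
    expect_equal(e$cde, e$nde)
  }
  e <- decompose_effects(o2, s$mfit, a = 30, a_star = 22, cvals = s$cvals)
  lc <- sum(s$mfit$beta2 * s$cvals)
  dp <- plogis(s$mfit$beta0 + 30 * s$mfit$beta1 + lc) -
    plogis(s$mfit$beta0 + 22 * s$mfit$beta1 + lc)
  expect_equal(e$nie, o2$theta2 * dp)
})

test_that("cross-world identity: CDE at m = p(a*) equals NDE", {
  s <- rand_coef_set(55)
  lc <- sum(s$mfit$beta2 * s$cvals)
  p_astar <- plogis(s$mfit$beta0 + s$mfit$beta1 * s$a_star + lc)
  e <- decompose_effects(s$ofit, s$mfit, a = s$a, a_star = s$a_star,
                         m_cde = p_astar, cvals = s$cvals)
  expect_equal(e$cde, e$nde, tolerance = 1e-12)
})

test_that("additivity holds exactly for every decomposition", {
  for (seed in 1:20) {
    s <- rand_coef_set(seed)
    e <- decompose_effects(s$ofit, s$mfit, a = s$a, a_star = s$a_star,
                           cvals = s$cvals)
    expect_identical(e$te, e$nde + e$nie)
  }
})

test_that("closed form agrees with the Monte-Carlo counterfactual oracle", {
  for (seed in c(3, 17, 29)) {
    s <- rand_coef_set(seed)
    e <- decompose_effects(s$ofit, s$mfit, a = s$a, a_star = s$a_star,
                           cvals = s$cvals)
    mc <- mc_counterfactual_oracle(s$ofit, s$mfit, a = s$a, a_star = s$a_star,
                                   cvals = s$cvals, n_mc = 2e5,
                                   seed = seed + 1)
    expect_lt(abs(e$nde - mc$nde), 4 * max(mc$se_nde, 1e-12))
    expect_lt(abs(e$nie - mc$nie), 4 * max(mc$se_nie, 1e-12))
  }
})

test_that("the oracle is deterministic and residual noise cancels", {
  s <- rand_coef_set(5)
  m1 <- mc_counterfactual_oracle(s$ofit, s$mfit, cvals = s$cvals,
                                 n_mc = 1e4, seed = 9)
  m2 <- mc_counterfactual_oracle(s$ofit, s$mfit, cvals = s$cvals,
                                 n_mc = 1e4, seed = 9)
  expect_identical(m1, m2)
  # theta2 = theta3 = 0 -> the mediator cannot move the outcome
  o0 <- s$ofit; o0$theta2 <- 0; o0$theta3 <- 0
  m0 <- mc_counterfactual_oracle(o0, s$mfit, cvals = s$cvals, n_mc = 1e4,
                                 seed = 2)
  expect_identical(m0$nie, 0)
  # with noise included the estimates stay within Monte-Carlo error
  sn <- mc_counterfactual_oracle(s$ofit, s$mfit, cvals = s$cvals,
                                 n_mc = 2e5, seed = 4, include_noise = TRUE)
  e <- decompose_effects(s$ofit, s$mfit, cvals = s$cvals)
  expect_lt(abs(sn$nde - e$nde), 4 * sn$se_nde)
})

test_that("bootstrap: determinism, additivity of replicates, PM bookkeeping", {
  d <- toy_rows(n = 300, seed = 12)
  b1 <- bootstrap_decomposition(d, B = 60, seed = 99)
  b2 <- bootstrap_decomposition(d, B = 60, seed = 99)
  expect_identical(b1, b2)
  reps <- b1$replicates
  expect_equal(reps[, "te"], reps[, "nde"] + reps[, "nie"])
  expect_true(all(b1$ci[, 1] <= b1$ci[, 2]))
  expect_equal(b1$n_fail, 0)
})

test_that("zero outcome variance gives zero-width intervals", {
  set.seed(3)
  d <- data.frame(bmi = runif(80, 19, 40), gwg_excessive = rep(0:1, 40),
                  zbmi4 = 2)
  b <- bootstrap_decomposition(d, B = 40, seed = 5)
  expect_equal(unname(b$ci[1:4, 1]), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(b$ci[1:4, 2]), rep(0, 4), tolerance = 1e-12)
})

test_that("gwg_mediate returns a coherent fitted object", {
  coh <- small_cohort(n = 350, seed = 19)
  rows <- cohort_rows(coh)
  fit <- gwg_mediate(rows, boot = 60, seed = 4)
  expect_s3_class(fit, "gwg_mediation")
  eff <- coef(fit)
  expect_identical(unname(eff["te"]), unname(eff["nde"] + eff["nie"]))
  ci <- confint(fit)
  expect_true(all(ci[1:4, 1] <= coef(fit)[1:4] + 1e-12))
  expect_true(all(ci[1:4, 2] >= coef(fit)[1:4] - 1e-12))
  expect_output(print(fit), "Proportion mediated")
  expect_output(print(summary(fit)), "Mediator model")
  # conditional-on-means and marginal versions agree closely here
  f2 <- gwg_mediate(rows, conditional = "marginal", boot = 0)
  expect_equal(coef(f2)[["nie"]], eff[["nie"]], tolerance = 0.01)
  expect_error(gwg_mediate(rows, covariates = "nonexistent"), "not in data")
})

test_that("proportion mediated is undefined (not an error) at zero total effect", {
  s <- rand_coef_set(7)
  o <- s$ofit
  o$theta1 <- 0; o$theta2 <- 0; o$theta3 <- 0
  e <- decompose_effects(o, s$mfit, cvals = s$cvals)
  expect_true(is.na(e$pm))
  expect_equal(e$te, 0)
})
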