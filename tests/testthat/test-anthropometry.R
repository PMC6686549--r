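test_that("BMI arithmetic and domain checks", {
  expect_equal(compute_bmi(16, 100), 16)
  # 30 kg at 122 cm, checked against high-precision arithmetic
  expect_equal(compute_bmi(30, 122), 20.1558720773985, tolerance = 1e-12)
  expect_error(compute_bmi(0, 100), "positive")
  expect_error(compute_bmi(20, -5), "positive")
})

test_that("LMS z-score identities and frozen value", {
  # median maps to zero for any L, S
  for (L in c(-2.5, -1e-9, 0, 0.5)) {
    expect_equal(lms_zscore(15.7, L, 15.7, 0.085), 0)
  }
  # log-limit branch: x = M * exp(S) -> z = 1
  expect_equal(lms_zscore(15.7 * exp(0.085), 0, 15.7, 0.085), 1)
  # frozen independent evaluation of the power branch
  expect_equal(lms_zscore(18, -1.6, 15.7, 0.085), 1.44461412588448,
               tolerance = 1e-12)
  expect_error(lms_zscore(-1, -1.6, 15.7, 0.085), "positive")
})

test_that("the two LMS branches agree at the L -> 0 boundary", {
  x <- c(13, 15.7, 18.4)
  z_limit <- lms_zscore(x, 0, 15.7, 0.085)
  z_power <- lms_zscore(x, 1e-8 * 1.0000001, 15.7, 0.085)
  expect_equal(z_power, z_limit, tolerance = 1e-6)
})

test_that("lms_zscore is strictly increasing in the measurement", {
  for (L in c(-2.2, -0.5, 0, 0.8)) {
    x <- seq(10, 25, length.out = 60)
    z <- lms_zscore(x, L, 15.5, 0.08)
    expect_true(all(diff(z) > 0))
  }
})

test_that("lms_inverse round-trips the z-score", {
  lms <- synthetic_lms_table()
  par <- lookup_lms(lms, "female", 50)
  z <- c(-2, -0.3, 0, 1.2, 3)
  x <- lms_inverse(z, par$L, par$M, par$S)
  expect_equal(lms_zscore(x, par$L, par$M, par$S), z, tolerance = 1e-10)
})

test_that("LMS lookup: exact rows, midpoint interpolation, range errors", {
  tab <- gwgmediate:::as_lms_table(data.frame(
    sex = "male", age = c(48, 50), L = c(-1.5, -1.7), M = c(15.0, 15.4),
    S = c(0.08, 0.10)))
  exact <- lookup_lms(tab, "male", 48)
  expect_equal(unlist(exact), c(L = -1.5, M = 15.0, S = 0.08))
  mid <- lookup_lms(tab, "male", 49)
  expect_equal(mid$M, 15.2)
  expect_equal(mid$L, -1.6)
  expect_equal(mid$S, 0.09)
  expect_error(lookup_lms(tab, "male", 55), "range")
  expect_error(lookup_lms(tab, "female", 49), "no rows")
})

test_that("interpolated z-scores are continuous in age", {
  lms <- synthetic_lms_table()
  ages <- seq(30.01, 70, length.out = 200)
  par <- lookup_lms(lms, "male", ages)
  z <- lms_zscore(16.2, par$L, par$M, par$S)
  eps <- 1e-4
  par2 <- lookup_lms(lms, "male", ages + eps)
  z2 <- lms_zscore(16.2, par2$L, par2$M, par2$S)
  expect_lt(max(abs(z2 - z)), 1e-4)
})

test_that("read_lms handles the CDC CSV dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sex,Agemos,L,M,S",
               "1,48,-1.5,15.0,0.08",
               "1,60,-1.6,15.2,0.09",
               "2,48,-1.4,14.9,0.08"), path)
  tab <- read_lms(path)
  expect_s3_class(tab, "lms_table")
  expect_setequal(unique(tab$sex), c("male", "female"))
  expect_equal(lookup_lms(tab, "male", 54)$M, 15.1)
  # the shipped synthetic reference round-trips through the reader
  shipped <- read_lms(system.file("extdata", "lms_synthetic.csv",
                                  package = "gwgmediate"))
  expect_equal(shipped$M, synthetic_lms_table()$M, tolerance = 1e-12)
})

test_that("child BMI categories partition the z line with inclusive upper bounds", {
  expect_equal(as.character(classify_child_bmi(0)), "normal")
  expect_equal(as.character(classify_child_bmi(1.70)), "obese")
  q85 <- qnorm(0.85)
  expect_equal(as.character(classify_child_bmi(q85)), "overweight")
  expect_equal(as.character(classify_child_bmi(qnorm(0.95))), "obese")
  expect_equal(as.character(classify_child_bmi(-3)), "underweight")
  z <- seq(-4, 4, length.out = 400)
  cats <- classify_child_bmi(z)
  expect_false(anyNA(cats))            # exactly one category per finite z
  expect_error(classify_child_bmi(NaN), "finite")
})

test_that("maternal BMI categories and underweight exclusion signal", {
  expect_equal(as.character(classify_maternal_bmi(22)), "normal")
  expect_equal(as.character(classify_maternal_bmi(24.99)), "normal")
  expect_equal(as.character(classify_maternal_bmi(25)), "overweight")
  expect_equal(as.character(classify_maternal_bmi(30)), "obese")
  expect_true(is.na(classify_maternal_bmi(17)))  # excluded upstream
  bmi <- seq(18.5, 60, length.out = 300)
  expect_false(anyNA(classify_maternal_bmi(bmi)))
})

test_that("GWG computation, unit conversion and the delivery-gap rule", {
  expect_equal(compute_gwg(60, 70, 2), 22.0462262184878, tolerance = 1e-12)
  expect_equal(compute_gwg(65, 65, 0), 0)
  expect_true(is.na(compute_gwg(60, 70, 10)))     # too far before delivery
  expect_equal(compute_gwg(60, 70, 7), 22.0462262184878, tolerance = 1e-12)
  expect_lt(compute_gwg(70, 65, 1), 0)            # weight loss allowed
  expect_error(compute_gwg(-1, 70, 1), "positive")
})

test_that("IOM categorisation with closed adequate intervals", {
  r <- classify_gwg(25, "obese")
  expect_equal(as.character(r$gwg_category), "excessive")
  expect_equal(r$excessive, 1L)
  r <- classify_gwg(20, "overweight")
  expect_equal(as.character(r$gwg_category), "adequate")
  expect_equal(r$excessive, 0L)
  r <- classify_gwg(10, "normal")
  expect_equal(as.character(r$gwg_category), "inadequate")
  expect_equal(r$excessive, 0L)
  # closed endpoints are adequate
  expect_equal(as.character(classify_gwg(c(25, 35), "normal")$gwg_category),
               c("adequate", "adequate"))
  expect_equal(as.character(classify_gwg(c(11, 20), "obese")$gwg_category),
               c("adequate", "adequate"))
  expect_true(is.na(classify_gwg(NA, "normal")$excessive))
  expect_error(classify_gwg(20, "plump"), "unknown maternal category")
})

test_that("gain drawn inside the adequacy interval classifies as adequate", {
  set.seed(4)
  ranges <- iom_gwg_ranges()
  ranges <- ranges[ranges$category != "underweight", ]
  for (i in seq_len(nrow(ranges))) {
    g <- runif(50, ranges$lower[i], ranges$upper[i])
    expect_true(all(classify_gwg(g, ranges$category[i])$gwg_category == "adequate"))
  }
})

test_that("age-4 outcome selection takes the last usable record in window", {
  rec <- data.frame(age = c(50, 55, 58), height = c(100, 104, 106),
                    weight = c(16, 17, 18))
  expect_equal(select_age4_measurement(rec)$age, 58)
  expect_null(select_age4_measurement(
    data.frame(age = c(40, 62), height = c(95, 110), weight = c(14, 19))))
  one <- data.frame(age = 48, height = 100, weight = 16)
  expect_equal(select_age4_measurement(one)$age, 48)
  # record with missing weight is skipped
  rec$weight[3] <- NA
  expect_equal(select_age4_measurement(rec)$age, 55)
})
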