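#' LMS growth-reference z-scores
#'
#' The LMS method summarises a growth reference at each age and sex by a
#' Box-Cox power `L`, a median `M` and a coefficient of variation `S`.
#' A measurement `x` (here BMI in kg/m^2) is standardised as
#' \deqn{z = \frac{(x/M)^L - 1}{L \, S}}
#' with the analytic limit \eqn{z = \log(x/M)/S} as \eqn{L \to 0}.
#'
#' @param x positive measurement (BMI, kg/m^2); vectorised.
#' @param l,m,s LMS parameters, recycled against `x`. `m > 0`, `s > 0`.
#' @return z-score(s).
#' @examples
#' lms_zscore(15.7, -1.6, 15.7, 0.085)  # median -> 0
#' @export
lms_zscore <- function(x, l, m, s) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("lms_zscore: measurement must be positive and finite", call. = FALSE)
  }
  if (any(m <= 0) || any(s <= 0)) {
    stop("lms_zscore: M and S must be positive", call. = FALSE)
  }
  n <- max(length(x), length(l), length(m), length(s))
  x <- rep_len(x, n); l <- rep_len(l, n); m <- rep_len(m, n); s <- rep_len(s, n)
  z <- numeric(n)
  small <- abs(l) <= 1e-8
  z[small] <- log(x[small] / m[small]) / s[small]
  z[!small] <- ((x[!small] / m[!small])^l[!small] - 1) / (l[!small] * s[!small])
  z
}

#' Invert the LMS transform: measurement at a given z-score
#'
#' @inheritParams lms_zscore
#' @param z z-score(s).
#' @return measurement `x` such that `lms_zscore(x, l, m, s) == z`.
#' @export
lms_inverse <- function(z, l, m, s) {
  n <- max(length(z), length(l), length(m), length(s))
  z <- rep_len(z, n); l <- rep_len(l, n); m <- rep_len(m, n); s <- rep_len(s, n)
  x <- numeric(n)
  small <- abs(l) <= 1e-8
  x[small] <- m[small] * exp(z[small] * s[small])
  x[!small] <- m[!small] * (1 + l[!small] * s[!small] * z[!small])^(1 / l[!small])
  x
}

#' Read an LMS reference table
#'
#' Accepts the CDC growth-chart CSV dialect: columns `Sex` (1 = male,
#' 2 = female, or the strings "male"/"female"), `Agemos`, `L`, `M`, `S`
#' (header case-insensitive; `sex`/`agemos` synonyms accepted).
#'
#' @param path CSV file path.
#' @return a `data.frame` of class `lms_table` with columns
#'   `sex` ("male"/"female"), `age` (months), `L`, `M`, `S`, sorted by sex
#'   then age.
#' @export
read_lms <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(raw))
  pick <- function(keys) {
    i <- match(keys, nm)
    i <- i[!is.na(i)][1]
    if (is.na(i)) stop(sprintf("LMS file lacks a column among: %s",
                               paste(keys, collapse = ", ")), call. = FALSE)
    raw[[i]]
  }
  sex <- pick(c("sex"))
  if (is.numeric(sex)) sex <- c("male", "female")[sex]
  sex <- tolower(as.character(sex))
  out <- data.frame(
    sex = sex,
    age = as.numeric(pick(c("agemos", "age", "age_months"))),
    L = as.numeric(pick("l")),
    M = as.numeric(pick("m")),
    S = as.numeric(pick("s")),
    stringsAsFactors = FALSE
  )
  as_lms_table(out)
}

as_lms_table <- function(df) {
  stopifnot(all(c("sex", "age", "L", "M", "S") %in% names(df)))
  if (any(df$M <= 0) || any(df$S <= 0)) {
    stop("LMS table: M and S must be positive", call. = FALSE)
  }
  df <- df[order(df$sex, df$age), , drop = FALSE]
  for (sx in unique(df$sex)) {
    a <- df$age[df$sex == sx]
    if (anyDuplicated(a)) stop("LMS table: duplicate (sex, age) rows", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("lms_table", "data.frame")
  df
}

#' Look up (and linearly interpolate) LMS parameters
#'
#' Exact rows are returned as stored; ages between two reference rows get
#' linear interpolation of each of L, M, S between the bracketing ages.
#'
#' @param table an `lms_table` (see [read_lms()], [synthetic_lms_table()]).
#' @param sex "male" or "female", recycled against `age`.
#' @param age age in months; must lie within the table's range for that sex.
#' @return data.frame with columns `L`, `M`, `S`, one row per queried age.
#' @export
lookup_lms <- function(table, sex, age) {
  stopifnot(inherits(table, "lms_table"))
  n <- max(length(sex), length(age))
  sex <- rep_len(tolower(as.character(sex)), n)
  age <- rep_len(as.numeric(age), n)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "M", "S")))
  for (sx in unique(sex)) {
    sub <- table[table$sex == sx, , drop = FALSE]
    if (nrow(sub) == 0) stop(sprintf("LMS table has no rows for sex '%s'", sx),
                             call. = FALSE)
    i <- which(sex == sx)
    rng <- range(sub$age)
    bad <- age[i] < rng[1] | age[i] > rng[2]
    if (any(bad)) {
      stop(sprintf("age %s outside LMS reference range [%g, %g] months for sex '%s'",
                   paste(unique(age[i][bad]), collapse = ", "), rng[1], rng[2], sx),
           call. = FALSE)
    }
    for (p in c("L", "M", "S")) {
      out[i, p] <- stats::approx(sub$age, sub[[p]], xout = age[i],
                                 method = "linear", ties = "ordered")$y
    }
  }
  as.data.frame(out)
}

#' Smooth synthetic LMS reference table (BMI-for-age, 24-72 months)
#'
#' A fully synthetic, smooth stand-in for a BMI-for-age growth reference,
#' used by the test-suite and the cohort generator so that no external
#' reference download is required. Medians dip around age five and the
#' skewness (L) and spread (S) drift slowly with age, qualitatively like
#' pediatric BMI references; the numbers are NOT a real reference.
#'
#' @param ages integer months covered (default 24:72).
#' @return an `lms_table`.
#' @export
synthetic_lms_table <- function(ages = 24:72) {
  mk <- function(sx, m0, mq, l0, lsl, s0, ssl) {
    data.frame(
      sex = sx, age = as.numeric(ages),
      L = l0 + lsl * (ages - 24),
      M = m0 + mq * (ages - 60)^2,
      S = s0 + ssl * (ages - 24),
      stringsAsFactors = FALSE
    )
  }
  as_lms_table(rbind(
    mk("male",   15.30, 7.0e-4, -2.20, 0.008, 0.075, 3.0e-4),
    mk("female", 15.15, 7.5e-4, -2.00, 0.007, 0.080, 2.8e-4)
  ))
}
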