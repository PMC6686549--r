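#' Body mass index
#'
#' @param weight_kg weight in kilograms.
#' @param height_cm height in centimetres.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0) ||
      any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("compute_bmi: weight and height must be positive and finite",
         call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

# z-score cutpoints implied by the reference percentiles used for child
# weight status (5th / 85th / 95th percentile of the standard normal).
child_bmi_cuts <- function() {
  stats::qnorm(c(0.05, 0.85, 0.95))
}

#' Child weight status from a BMI z-score
#'
#' Underweight below the 5th percentile, normal up to the 85th, overweight
#' from the 85th up to the 95th, obese at or above the 95th; percentiles are
#' mapped to z cutpoints through the standard normal quantile. Upper category
#' boundaries are inclusive.
#'
#' @param z BMI z-score(s), finite.
#' @return factor with levels underweight < normal < overweight < obese.
#' @export
classify_child_bmi <- function(z) {
  if (any(!is.finite(z))) stop("classify_child_bmi: z must be finite", call. = FALSE)
  q <- child_bmi_cuts()
  cut(z, breaks = c(-Inf, q, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"),
      ordered_result = TRUE)
}

#' Maternal pre-pregnancy weight status
#'
#' Normal 18.5-24.9, overweight 25-29.9, obese >= 30 kg/m^2. BMI below 18.5
#' (underweight) signals exclusion from analysis and is returned as `NA`
#' so that callers can drop the record with an exclusion count.
#'
#' @param bmi pre-pregnancy BMI, kg/m^2.
#' @return factor with levels normal < overweight < obese; `NA` flags an
#'   underweight exclusion.
#' @export
classify_maternal_bmi <- function(bmi) {
  out <- cut(bmi, breaks = c(18.5, 25, 30, Inf), right = FALSE,
             labels = c("normal", "overweight", "obese"), ordered_result = TRUE)
  out
}

#' IOM gestational weight-gain adequacy ranges (lbs)
#'
#' Closed intervals of adequate total gain by pre-pregnancy weight status.
#' The underweight row is carried for completeness but unused: underweight
#' mothers are excluded upstream. (Its 28-40 lbs range, wider than the
#' normal-weight 25-35 lbs, is reproduced as published, not corrected.)
#'
#' @return data.frame with columns `category`, `lower`, `upper` (lbs).
#' @export
iom_gwg_ranges <- function() {
  data.frame(
    category = c("underweight", "normal", "overweight", "obese"),
    lower = c(28, 25, 15, 11),
    upper = c(40, 35, 25, 20),
    stringsAsFactors = FALSE
  )
}

#' Gestational weight gain in pounds
#'
#' GWG is the last weight measured close to delivery minus the self-reported
#' weight at last menstrual period, converted to lbs (1 lb = 0.45359237 kg).
#' A last measurement taken more than `max_gap_days` before delivery is
#' rejected and GWG set missing for that mother.
#'
#' @param weight_lmp_kg self-reported weight at last menstrual period, kg.
#' @param weight_delivery_kg last measured weight before delivery, kg.
#' @param delivery_gap_days days between that measurement and delivery.
#' @param max_gap_days maximum acceptable gap (default 7).
#' @return GWG in lbs (may be negative); `NA` where the gap exceeds the limit.
#' @export
compute_gwg <- function(weight_lmp_kg, weight_delivery_kg, delivery_gap_days,
                        max_gap_days = 7) {
  if (any(weight_lmp_kg <= 0, na.rm = TRUE) ||
      any(weight_delivery_kg <= 0, na.rm = TRUE)) {
    stop("compute_gwg: weights must be positive", call. = FALSE)
  }
  gwg <- (weight_delivery_kg - weight_lmp_kg) * LB_PER_KG
  gwg[!is.na(delivery_gap_days) & delivery_gap_days > max_gap_days] <- NA_real_
  gwg
}

#' Categorise gestational weight gain against the IOM ranges
#'
#' Gain inside the closed adequacy interval for the mother's weight status is
#' adequate; below it inadequate; above it excessive. The binary mediator
#' used in the mediation models is `excessive` vs not.
#'
#' @param gwg_lbs gestational weight gain, lbs.
#' @param maternal_category factor/character: normal, overweight or obese.
#' @return data.frame with `gwg_category` (ordered factor
#'   inadequate < adequate < excessive) and integer `excessive` (0/1);
#'   `NA` propagates.
#' @export
classify_gwg <- function(gwg_lbs, maternal_category) {
  cat <- as.character(maternal_category)
  n <- max(length(gwg_lbs), length(cat))
  gwg_lbs <- rep_len(gwg_lbs, n); cat <- rep_len(cat, n)
  ranges <- iom_gwg_ranges()
  known <- is.na(cat) | cat %in% ranges$category
  if (!all(known)) {
    stop(sprintf("classify_gwg: unknown maternal category '%s'",
                 cat[!known][1]), call. = FALSE)
  }
  i <- match(cat, ranges$category)
  lo <- ranges$lower[i]; hi <- ranges$upper[i]
  out <- rep(NA_character_, n)
  ok <- !is.na(gwg_lbs) & !is.na(cat)
  out[ok & gwg_lbs < lo] <- "inadequate"
  out[ok & gwg_lbs >= lo & gwg_lbs <= hi] <- "adequate"
  out[ok & gwg_lbs > hi] <- "excessive"
  gwg_category <- factor(out, levels = c("inadequate", "adequate", "excessive"),
                         ordered = TRUE)
  data.frame(gwg_category = gwg_category,
             excessive = ifelse(is.na(out), NA_integer_,
                                as.integer(out == "excessive")))
}

#' Select the outcome measurement in the age-4 window
#'
#' Among a child's growth records, returns the one with the greatest age in
#' `[window[1], window[2]]` months that has both height and weight; `NULL`
#' if none exists (the child is excluded from analysis).
#'
#' @param records data.frame with columns `age`, `height`, `weight`
#'   (one child's records, any order).
#' @param window age window in months, default `c(48, 59)`.
#' @return a single-row data.frame, or `NULL`.
#' @export
select_age4_measurement <- function(records, window = c(48, 59)) {
  ok <- records$age >= window[1] & records$age <= window[2] &
    !is.na(records$height) & !is.na(records$weight)
  if (!any(ok)) return(NULL)
  cand <- records[ok, , drop = FALSE]
  cand[which.max(cand$age), , drop = FALSE]
}

#' Derive one analysis row per mother-child pair
#'
#' Applies the exclusion rules (underweight mother; no usable measurement in
#' the age-4 window), computes GWG and its IOM category / binary mediator,
#' and the age-4 BMI z-score from the LMS reference. Growth records are
#' expected already cleaned (see [clean_growth()]).
#'
#' @param mothers maternal table (one row per mother; see [simulate_cohort()]
#'   for the schema).
#' @param growth long-format child growth table (`id`, `sex`, `age`,
#'   `height`, `weight`).
#' @param lms an `lms_table`.
#' @param window outcome age window in months.
#' @param max_gap_days GWG delivery-gap limit in days.
#' @return data.frame of analysis rows, with an `exclusions` attribute
#'   (named integer vector: rows in, per-rule exclusions, rows analysed).
#' @export
derive_pairs <- function(mothers, growth, lms, window = c(48, 59),
                         max_gap_days = 7) {
  n_in <- nrow(mothers)
  if (!"bmi" %in% names(mothers)) {
    mothers$bmi <- compute_bmi(mothers$weight_pre, mothers$height_cm)
  }
  mat_cat <- classify_maternal_bmi(mothers$bmi)
  excl_under <- !is.na(mothers$bmi) & mothers$bmi < 18.5

  # outcome: last usable record in the window, per child
  growth <- growth[order(growth$id, growth$age), , drop = FALSE]
  in_win <- growth$age >= window[1] & growth$age <= window[2] &
    !is.na(growth$height) & !is.na(growth$weight)
  gw <- growth[in_win, , drop = FALSE]
  last_idx <- tapply(seq_len(nrow(gw)), gw$id, function(i) i[which.max(gw$age[i])])
  sel <- gw[unlist(last_idx), , drop = FALSE]
  mi <- match(mothers$id, sel$id)
  has_window <- !is.na(mi)
  excl_window <- !excl_under & !has_window

  keep <- !excl_under & has_window
  m <- mothers[keep, , drop = FALSE]
  s <- sel[mi[keep], , drop = FALSE]

  bmi4 <- compute_bmi(s$weight, s$height)
  par <- lookup_lms(lms, s$sex, s$age)
  z4 <- lms_zscore(bmi4, par$L, par$M, par$S)

  gwg <- compute_gwg(m$weight_lmp, m$weight_delivery, m$delivery_gap_days,
                     max_gap_days = max_gap_days)
  gcls <- classify_gwg(gwg, mat_cat[keep])

  rows <- data.frame(
    id = m$id,
    bmi = m$bmi,
    mat_category = mat_cat[keep],
    gwg_lbs = gwg,
    gwg_category = gcls$gwg_category,
    gwg_excessive = gcls$excessive,
    age4_months = s$age,
    bmi4 = bmi4,
    zbmi4 = z4,
    child_category = classify_child_bmi(z4),
    stringsAsFactors = FALSE
  )
  covar_cols <- intersect(
    c("race", "education", "smoking", "gdm", "cohort", "mat_age", "cesarean",
      "gest_age_days", "male", "birth_weight_g", "parity"),
    names(m)
  )
  rows <- cbind(rows, m[covar_cols])
  rownames(rows) <- NULL
  structure(rows,
            exclusions = c(rows_in = n_in,
                           underweight_mother = sum(excl_under),
                           no_window_visit = sum(excl_window),
                           rows_analyzed = nrow(rows)))
}
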