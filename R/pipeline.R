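#' Write / read cohort tables
#'
#' `write_cohort()` writes `mothers.csv`, `growth.csv` (long format, header
#' row, UTF-8) and `truth.json` (generating parameters and true effects)
#' into a directory; `read_cohort()` reads the two CSVs back into typed
#' records, rejecting malformed rows with their line numbers.
#'
#' @param cohort a `synthetic_cohort` (or any list with `mothers`,
#'   `growth`, optionally `truth`).
#' @param dir output directory (created if needed).
#' @return `write_cohort()`: the directory, invisibly. `read_cohort()`: a
#'   list with `mothers`, `growth` and a `rejected` attribute on each
#'   table giving 1-based data line numbers of malformed rows.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$mothers, file.path(dir, "mothers.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$growth, file.path(dir, "growth.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(beta = tr$beta, theta = tr$theta, sigma_y = tr$sigma_y,
           effects = unclass(tr$effects)[c("cde", "nde", "nie", "te", "pm",
                                           "a", "a_star", "m_cde")]),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

mothers_schema <- c("id", "bmi", "weight_lmp", "weight_delivery",
                    "delivery_gap_days", "race", "education", "smoking",
                    "gdm", "cohort")
growth_schema <- c("id", "sex", "age", "height", "weight")

#' @rdname write_cohort
#' @param mothers_path,growth_path CSV paths.
#' @export
read_cohort <- function(mothers_path, growth_path) {
  read_checked <- function(path, required, numeric_cols) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                                 call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols)) {
      stop(sprintf("%s: missing column(s): %s", basename(path),
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    bad <- rep(FALSE, nrow(df))
    for (col in intersect(numeric_cols, names(df))) {
      v <- df[[col]]
      if (!is.numeric(v)) {
        suppressWarnings(num <- as.numeric(v))
        bad <- bad | (!is.na(v) & v != "" & is.na(num))
        df[[col]] <- num
      }
    }
    rejected <- which(bad)
    if (length(rejected)) df <- df[!bad, , drop = FALSE]
    structure(df, rejected = rejected)
  }
  mothers <- read_checked(mothers_path, mothers_schema,
                          c("bmi", "weight_pre", "weight_lmp",
                            "weight_delivery", "delivery_gap_days",
                            "height_cm", "mat_age", "gest_age_days",
                            "birth_weight_g", "smoking", "gdm", "cohort",
                            "cesarean", "male"))
  for (v in c("race", "education", "parity")) {
    if (v %in% names(mothers)) {
      lv <- switch(v, race = race_levels, education = education_levels,
                   parity = parity_levels)
      mothers[[v]] <- factor(mothers[[v]], levels = lv)
    }
  }
  growth <- read_checked(growth_path, growth_schema,
                         c("age", "height", "weight"))
  list(mothers = mothers, growth = growth)
}

#' Bivariate cohort summary by child weight status
#'
#' Compares mother-child pairs across the two child strata
#' (underweight/normal vs overweight/obese): continuous variables get the
#' per-stratum mean (SD) and a two-sample t-test p-value (pooled variance
#' by default, Welch by flag); categorical variables get per-level counts
#' with percent of the stratum's non-missing total (rounded to integers
#' for display) and a Pearson chi-square p-value without continuity
#' correction. An empty stratum yields `NA` p-values.
#'
#' @param pairs analysis rows (see [derive_pairs()]); must include
#'   `child_category`.
#' @param continuous,categorical variable names to summarise; defaults
#'   cover the standard cohort table.
#' @param welch use Welch's t-test instead of pooled variance.
#' @return data.frame of class `table1_summary` with one row per variable
#'   level; attributes `n_normal`, `n_overob`.
#' @export
summarize_table1 <- function(pairs,
                             continuous = intersect(
                               c("zbmi4", "bmi", "mat_age", "gest_age_days",
                                 "birth_weight_g", "gwg_lbs"), names(pairs)),
                             categorical = intersect(
                               c("mat_category", "gwg_category", "race",
                                 "education", "smoking", "gdm", "cohort",
                                 "parity", "male", "cesarean"), names(pairs)),
                             welch = FALSE) {
  if (!"child_category" %in% names(pairs)) {
    stop("summarize_table1: child_category column required", call. = FALSE)
  }
  stratum <- ifelse(pairs$child_category %in% c("underweight", "normal"),
                    "normal", "overob")
  n1 <- sum(stratum == "normal"); n2 <- sum(stratum == "overob")
  rows <- list()
  for (v in continuous) {
    x1 <- pairs[[v]][stratum == "normal"]; x2 <- pairs[[v]][stratum == "overob"]
    p <- if (sum(!is.na(x1)) > 1 && sum(!is.na(x2)) > 1) {
      stats::t.test(x1, x2, var.equal = !welch)$p.value
    } else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "",
      normal = sprintf("%.1f (%.1f)", mean(x1, na.rm = TRUE),
                       stats::sd(x1, na.rm = TRUE)),
      overob = sprintf("%.1f (%.1f)", mean(x2, na.rm = TRUE),
                       stats::sd(x2, na.rm = TRUE)),
      count_normal = NA_integer_, count_overob = NA_integer_,
      pct_normal = NA_real_, pct_overob = NA_real_,
      p_value = p, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- pairs[[v]]
    if (is.numeric(x)) x <- factor(x)
    x <- droplevels(factor(x))
    tab <- table(x, stratum)
    tot <- colSums(tab)
    p <- if (all(c("normal", "overob") %in% colnames(tab)) &&
             nrow(tab) > 1 && all(tot > 0)) {
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    } else NA_real_
    cn <- if ("normal" %in% colnames(tab)) tab[, "normal"] else
      rep(0L, nrow(tab))
    co <- if ("overob" %in% colnames(tab)) tab[, "overob"] else
      rep(0L, nrow(tab))
    for (l in rownames(tab)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = l, normal = "", overob = "",
        count_normal = unname(cn[l]), count_overob = unname(co[l]),
        pct_normal = if (sum(cn) > 0) round(100 * cn[l] / sum(cn)) else NA,
        pct_overob = if (sum(co) > 0) round(100 * co[l] / sum(co)) else NA,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_normal = n1, n_overob = n2,
            class = c("table1_summary", "data.frame"))
}

#' Study configuration
#'
#' Exactly one of `generator` (a [cohort_config()]) or `paths` (list with
#' `mothers`, `growth`) must be supplied.
#'
#' @param generator a [cohort_config()], or `NULL` to read data.
#' @param paths list(mothers =, growth =) CSV paths, or `NULL`.
#' @param lms an `lms_table`, or a CSV path, or `NULL` for the synthetic
#'   reference.
#' @param cleaning a [cleaning_config()].
#' @param window outcome age window (months).
#' @param impute `"auto"` (impute iff missingness present), `TRUE`,
#'   `FALSE`.
#' @param m,cycles imputation settings.
#' @param boot bootstrap resamples.
#' @param sensitivity also run the extended-covariate decomposition.
#' @param a,a_star,m_cde exposure contrast and CDE mediator level.
#' @param seed single seed governing all randomness.
#' @return list of class `study_config`.
#' @export
study_config <- function(generator = cohort_config(), paths = NULL,
                         lms = NULL, cleaning = cleaning_config(),
                         window = c(48, 59), impute = "auto", m = 20,
                         cycles = 10, boot = 1000, sensitivity = TRUE,
                         a = 30, a_star = 22, m_cde = 0, seed = 1L) {
  if (is.null(generator) == is.null(paths)) {
    stop_field("generator/paths", "exactly one input source must be supplied")
  }
  if (is.character(lms)) lms <- read_lms(lms)
  if (is.null(lms)) lms <- synthetic_lms_table()
  structure(list(generator = generator, paths = paths, lms = lms,
                 cleaning = cleaning, window = window, impute = impute,
                 m = m, cycles = cycles, boot = boot,
                 sensitivity = isTRUE(sensitivity),
                 a = a, a_star = a_star, m_cde = m_cde,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full study pipeline
#'
#' Simulate (or ingest) the cohort, clean child heights, derive analysis
#' rows with exclusion accounting, summarise the cohort by child weight
#' status, and estimate the effect decomposition with the minimal
#' adjustment set (multiply imputed when covariate missingness is
#' present), plus an extended-set sensitivity decomposition. A single
#' seed governs all randomness; the report is byte-identical across runs
#' with the same configuration.
#'
#' @param config a [study_config()].
#' @return list of class `study_report`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  stage <- "input"
  report <- tryCatch({
    if (!is.null(config$generator)) {
      gen <- config$generator
      gen$seed <- config$seed
      cohort <- simulate_cohort(gen, lms = config$lms)
      mothers <- cohort$mothers; growth <- cohort$growth
      truth <- cohort$truth
    } else {
      dat <- read_cohort(config$paths$mothers, config$paths$growth)
      mothers <- dat$mothers; growth <- dat$growth
      truth <- NULL
    }

    stage <- "clean"
    cleaned <- clean_growth(growth, config$cleaning)
    cleaning_noop <- attr(cleaned, "n_imputed") == 0

    stage <- "derive"
    rows <- derive_pairs(mothers, cleaned, config$lms, window = config$window)
    exclusions <- attr(rows, "exclusions")

    stage <- "table1"
    table1 <- summarize_table1(rows)

    stage <- "mediate"
    covs <- gwg_covariates("minimal")
    any_missing <- anyNA(rows[covs])
    do_impute <- isTRUE(config$impute) ||
      (identical(config$impute, "auto") && any_missing)
    if (do_impute) {
      fit <- gwg_mediate_mi(rows, covariates = covs, m = config$m,
                            cycles = config$cycles, a = config$a,
                            a_star = config$a_star, m_cde = config$m_cde,
                            boot = config$boot, seed = config$seed)
    } else {
      fit <- gwg_mediate(rows, covariates = covs, a = config$a,
                         a_star = config$a_star, m_cde = config$m_cde,
                         boot = config$boot, seed = config$seed)
    }

    sens <- NULL
    if (config$sensitivity) {
      stage <- "sensitivity"
      ext <- intersect(gwg_covariates("extended"), names(rows))
      sens <- gwg_mediate(rows, covariates = ext, a = config$a,
                          a_star = config$a_star, m_cde = config$m_cde,
                          boot = config$boot, seed = config$seed)
    }

    list(n_pairs = nrow(mothers), exclusions = exclusions,
         n_analyzed = nrow(rows),
         cleaning = list(noop = cleaning_noop,
                         n_imputed = attr(cleaned, "n_imputed")),
         imputation = list(used = do_impute,
                           noop = !do_impute && !any_missing),
         table1 = table1, fit = fit, sensitivity_fit = sens,
         truth = truth, seed = config$seed)
  }, error = function(e) {
    stop(sprintf("study failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(report) <- "study_report"
  report
}

report_effects <- function(fit) {
  if (inherits(fit, "gwg_mediation_mi")) {
    est <- fit$pooled
    ci <- fit$ci
  } else {
    est <- coef(fit)
    ci <- fit$ci
  }
  lst <- list()
  for (p in c("cde", "nde", "nie", "te", "pm")) {
    lst[[p]] <- list(estimate = unname(est[p]),
                     ci_lower = if (!is.null(ci)) unname(ci[p, 1]) else NULL,
                     ci_upper = if (!is.null(ci)) unname(ci[p, 2]) else NULL)
  }
  lst
}

#' Write a study report to disk
#'
#' Emits `report.json` (machine-readable) and `report.txt` (human-readable
#' summary) into `dir`.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    n_pairs = report$n_pairs,
    exclusions = as.list(report$exclusions),
    cleaning = report$cleaning,
    imputation = report$imputation,
    effects_minimal = report_effects(report$fit),
    effects_extended = if (!is.null(report$sensitivity_fit))
      report_effects(report$sensitivity_fit),
    truth = if (!is.null(report$truth))
      unclass(report$truth$effects)[c("cde", "nde", "nie", "te", "pm")],
    seed = report$seed
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  sink(con)
  print(report)
  sink()
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n============\n")
  cat(sprintf("Pairs in: %d; analysed: %d\n", x$n_pairs, x$n_analyzed))
  ex <- x$exclusions
  cat(sprintf("Exclusions: underweight mother %d, no age-4 window visit %d\n",
              ex["underweight_mother"], ex["no_window_visit"]))
  cat(sprintf("Cleaning: %s (%d heights imputed)\n",
              if (x$cleaning$noop) "no-op" else "applied",
              x$cleaning$n_imputed))
  cat(sprintf("Imputation: %s\n",
              if (x$imputation$used) "FCS multiple imputation" else
                if (x$imputation$noop) "no-op (no missingness)" else
                  "complete case"))
  cat("\nMinimal adjustment set:\n")
  print(x$fit)
  if (!is.null(x$sensitivity_fit)) {
    cat("\nExtended adjustment set (sensitivity):\n")
    print(x$sensitivity_fit)
  }
  invisible(x)
}
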