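#' Flag departures from a monotone height series
#'
#' Child standing height should not decrease between visits. A value is
#' flagged as a departure when it falls more than `tolerance` cm below the
#' running maximum of the values before it, so a single low outlier is
#' flagged rather than every later (correct) value. Ties are not departures
#' at tolerance 0 (strict inequality). Missing values are always flagged
#' (they must be imputed).
#'
#' @param values numeric measurements in visit order (height, cm).
#' @param tolerance allowed non-increase in cm before a value counts as a
#'   departure (default 0).
#' @return logical vector, `TRUE` where the value departs or is missing.
#' @export
flag_nonmonotone <- function(values, tolerance = 0) {
  stopifnot(tolerance >= 0)
  n <- length(values)
  if (n == 0) return(logical(0))
  flags <- is.na(values)
  runmax <- -Inf
  for (i in seq_len(n)) {
    if (is.na(values[i])) next
    if (i > 1 && is.finite(runmax) && values[i] < runmax - tolerance) {
      flags[i] <- TRUE
    } else {
      runmax <- max(runmax, values[i])
    }
  }
  flags
}

#' Last & Next imputation
#'
#' Arithmetic mean of the nearest usable (unflagged, non-missing) neighbour
#' before and after the index; one-sided if only one neighbour exists.
#'
#' @param values numeric series.
#' @param flags logical, `TRUE` marks values not usable as donors.
#' @param index position to impute (flagged or missing).
#' @return imputed value.
#' @export
impute_last_next <- function(values, flags, index) {
  usable <- which(!flags & !is.na(values))
  before <- usable[usable < index]
  after <- usable[usable > index]
  if (!length(before) && !length(after)) {
    stop(sprintf("impute_last_next: no usable neighbour around index %d", index),
         call. = FALSE)
  }
  if (!length(before)) return(values[min(after)])
  if (!length(after)) return(values[max(before)])
  (values[max(before)] + values[min(after)]) / 2
}

#' Fractional (linear-regression) imputation
#'
#' Ordinary least-squares line through the child's usable (age, value)
#' points, evaluated at the age of the index being imputed. With no age
#' variance among donors the mean of the usable values is returned.
#'
#' @param ages ages in months, same length as `values`.
#' @inheritParams impute_last_next
#' @return imputed value.
#' @export
impute_fractional_regression <- function(ages, values, flags, index) {
  usable <- which(!flags & !is.na(values))
  if (length(usable) < 2) {
    stop("impute_fractional_regression: need at least 2 usable points",
         call. = FALSE)
  }
  x <- ages[usable]; y <- values[usable]
  sxx <- sum((x - mean(x))^2)
  if (sxx < .Machine$double.eps) return(mean(y))
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  a + b * ages[index]
}

#' Cleaning configuration
#'
#' @param w_lastnext weight on the Last & Next imputation (default 0.3).
#' @param w_fracreg weight on the fractional-regression imputation
#'   (default 0.7). Weights must be non-negative and sum to 1.
#' @param tolerance monotonicity tolerance in cm (default 0).
#' @param max_pass bound on re-flagging passes (default 5).
#' @return list of class `cleaning_config`.
#' @export
cleaning_config <- function(w_lastnext = 0.3, w_fracreg = 0.7, tolerance = 0,
                            max_pass = 5L) {
  if (w_lastnext < 0 || w_fracreg < 0) stop_field("weights", "must be >= 0")
  if (abs(w_lastnext + w_fracreg - 1) > 1e-9) stop_field("weights", "must sum to 1")
  if (tolerance < 0) stop_field("tolerance", "must be >= 0")
  structure(list(w_lastnext = w_lastnext, w_fracreg = w_fracreg,
                 tolerance = tolerance, max_pass = as.integer(max_pass)),
            class = "cleaning_config")
}

#' Clean one child's height series
#'
#' Flags departures from monotonicity ([flag_nonmonotone()]), imputes each
#' flagged or missing value as the weighted average
#' `w_lastnext * LastNext + w_fracreg * FractionalRegression`, and repeats
#' (up to `max_pass` passes) until re-flagging finds no departures. If the
#' pass budget is exhausted, remaining sub-running-max values are raised to
#' the running maximum so that the output always satisfies the monotonicity
#' rule. Unflagged values are returned bit-identical.
#'
#' @param ages visit ages in months, strictly ascending.
#' @param values heights (cm), same length; may contain `NA`.
#' @param config a [cleaning_config()].
#' @return list with `values` (cleaned), `imputed` (logical: positions
#'   changed), `passes` (passes used).
#' @export
clean_series <- function(ages, values, config = cleaning_config()) {
  stopifnot(length(ages) == length(values))
  if (length(ages) > 1 && any(diff(ages) <= 0)) {
    stop("clean_series: ages must be strictly ascending", call. = FALSE)
  }
  out <- values
  imputed <- rep(FALSE, length(values))
  passes <- 0L
  repeat {
    flags <- flag_nonmonotone(out, config$tolerance)
    if (!any(flags) || passes >= config$max_pass) break
    passes <- passes + 1L
    new <- out
    for (i in which(flags)) {
      ln <- impute_last_next(out, flags, i)
      fr <- tryCatch(impute_fractional_regression(ages, out, flags, i),
                     error = function(e) ln)
      new[i] <- config$w_lastnext * ln + config$w_fracreg * fr
    }
    imputed <- imputed | flags
    out <- new
  }
  flags <- flag_nonmonotone(out, config$tolerance)
  if (any(flags)) {
    # force monotone: raise remaining departures to the running maximum
    for (i in which(flags)) {
      prev <- out[seq_len(i - 1)]
      out[i] <- max(prev[!is.na(prev)])
      imputed[i] <- TRUE
    }
  }
  list(values = out, imputed = imputed, passes = passes)
}

#' Clean the height column of a long-format growth table
#'
#' Applies [clean_series()] child by child. Weight (mass) is deliberately
#' not cleaned: a child's weight may legitimately decrease between visits,
#' height should not.
#'
#' @param growth data.frame with columns `id`, `age`, `height` (and
#'   typically `weight`, left untouched).
#' @param config a [cleaning_config()].
#' @param log function called once per imputed value with a message
#'   (default `NULL`: silent).
#' @return `growth` with cleaned `height`; attribute `n_imputed` counts
#'   changed values.
#' @export
clean_growth <- function(growth, config = cleaning_config(), log = NULL) {
  growth <- growth[order(growth$id, growth$age), , drop = FALSE]
  n_imp <- 0L
  for (cid in unique(growth$id)) {
    i <- which(growth$id == cid)
    if (length(i) < 2 && !anyNA(growth$height[i])) next
    res <- clean_series(growth$age[i], growth$height[i], config)
    if (any(res$imputed)) {
      if (!is.null(log)) {
        for (j in which(res$imputed)) {
          log(sprintf("clean: child %s age %g height %s -> %.2f",
                      cid, growth$age[i][j],
                      format(growth$height[i][j]), res$values[j]))
        }
      }
      n_imp <- n_imp + sum(res$imputed)
      growth$height[i] <- res$values
    }
  }
  rownames(growth) <- NULL
  structure(growth, n_imputed = n_imp)
}
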