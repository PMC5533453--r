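# Shared helpers: series validation, moment statistics with the population
# (divide-by-n) convention used consistently across the package.

#' Validate an actigraphy tibble and extract its sampling metadata
#'
#' @param data A tibble with columns `time_min` and `counts` (and optionally
#'   `subject_id`, `group`) describing one subject's series.
#' @return A list with `x` (counts), `time_min`, `epoch_minutes`,
#'   `start_clock` (minute-of-day of the first sample) and `n`.
#' @keywords internal
#' @noRd
series_info <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("time_min", "counts") %in% names(data))) {
    stop("actigraphy data needs columns `time_min` and `counts`", call. = FALSE)
  }
  if ("subject_id" %in% names(data) && length(unique(data$subject_id)) > 1L) {
    stop("data contains several subjects; group_by/map over `subject_id` first",
         call. = FALSE)
  }
  t <- as.numeric(data$time_min)
  x <- as.numeric(data$counts)
  n <- length(x)
  if (n < 2L) stop("series must have at least 2 samples", call. = FALSE)
  if (anyNA(t) || anyNA(x)) stop("missing values in series (no imputation is done)", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("timestamps must be equidistant (gap or irregular epoch detected)", call. = FALSE)
  }
  list(x = x, time_min = t, epoch_minutes = dt[1],
       start_clock = t[1] %% 1440, n = n)
}

# population variance (denominator n)
var_pop <- function(x) mean((x - mean(x))^2)

#' Day-to-day summary statistics of a circadian parameter
#'
#' Mean, standard deviation, coefficient of variation, skewness and kurtosis
#' of a small sample of per-day parameter values.  The population convention
#' (denominator n) is used for all central moments, and kurtosis is the
#' Pearson moment ratio m4/m2^2, i.e. 3 for a Gaussian and 9/5 for a uniform
#' distribution; no excess-kurtosis or small-sample bias correction is
#' applied.
#'
#' @param values Numeric vector (at least 2 values; skewness and kurtosis
#'   require at least 4 and are `NA` otherwise).
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `cv`, `skew`,
#'   `kurt`.
#' @examples
#' day_to_day_stats(c(230, 235, 228, 232, 236, 229, 233))
#' @export
day_to_day_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  n <- length(values)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  s <- sqrt(m2)
  cv <- if (abs(m) < .Machine$double.eps * max(1, s)) NA_real_ else s / m
  if (n >= 4L && m2 > 0) {
    skew <- mean((values - m)^3) / m2^1.5
    kurt <- mean((values - m)^4) / m2^2
  } else if (m2 == 0) {
    skew <- 0
    kurt <- NA_real_
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  tibble::tibble(n = n, mean = m, sd = s, cv = cv, skew = skew, kurt = kurt)
}
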