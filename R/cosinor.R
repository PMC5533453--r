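# Single-harmonic cosinor regression y(t) = M + A cos(2*pi*t/T + phi),
# fitted by linear least squares on the (cos, sin) reparameterisation,
# with period scanning and acrophase (clock-time of the daily peak)
# derivation referenced to midnight.

#' Fit the single-harmonic cosinor model at a fixed period
#'
#' Minimises the summed squared residuals of
#' `y(t) = M + A cos(2*pi*t/T + phi)` over (M, A, phi) via the linear
#' reparameterisation `y = M + a cos(2*pi*t/T) + b sin(2*pi*t/T)` with
#' `A = sqrt(a^2 + b^2)`, `phi = atan2(-b, a)`, so the optimum is exact.
#' Time is measured in minutes after the midnight preceding the first
#' sample, hence the acrophase (the clock position of the fitted maximum,
#' 360 deg = 24 h) is referenced to midnight.  For periods T != 1440 min
#' the daily peak drifts by `delta_t = T - 1440` min/day and the reported
#' `acrophase_deg` is the arithmetic mean of the per-day peak positions
#' over the recording.
#'
#' @param data Single-subject actigraphy tibble (`time_min`, `counts`).
#' @param period Trial period T in minutes (default 1440 = 24 h); must
#'   exceed twice the epoch.
#' @return An object of class `cosinor_fit`; see [glance.cosinor_fit()].
#' @examples
#' spec <- cohort_spec(n_subjects = 1, amplitude_day_cv = 0, acrophase_day_sd = 0,
#'                     noise_scale = 0, mesor_sd = 0, integer_counts = FALSE)
#' fit <- fit_cosinor(generate_subject(spec, 0))
#' glance(fit)
#' @export
fit_cosinor <- function(data, period = 1440) {
  info <- series_info(data)
  if (info$n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (period <= 2 * info$epoch_minutes) {
    stop("period must exceed twice the epoch length", call. = FALSE)
  }
  if (var_pop(info$x) == 0) {
    stop("constant series: cosinor R^2 is undefined", call. = FALSE)
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * info$time_min), sin(w * info$time_min))
  fit <- stats::lm.fit(X, info$x)
  cf <- fit$coefficients
  mesor <- cf[[1]]; a <- cf[[2]]; b <- cf[[3]]
  amplitude <- sqrt(a^2 + b^2)
  phi_rad <- atan2(-b, a)                       # in (-pi, pi]
  yhat <- X %*% cf
  r2 <- 1 - sum((info$x - yhat)^2) / sum((info$x - mean(info$x))^2)

  # first model peak (minutes after midnight of day 1): w*t + phi = 0 mod 2pi
  t_peak <- (-phi_rad / (2 * pi) * period) %% period
  delta_t <- period - 1440
  n_days <- max(1, round(info$n * info$epoch_minutes / 1440))
  phi0_day1_min <- t_peak %% 1440
  phi0_mean_min <- (phi0_day1_min + (n_days - 1) / 2 * delta_t) %% 1440
  acrophase_deg <- phi0_mean_min / 1440 * 360

  structure(list(
    subject_id = if ("subject_id" %in% names(data)) data$subject_id[1] else NA_character_,
    group = if ("group" %in% names(data)) data$group[1] else NA_character_,
    period = period, mesor = mesor, amplitude = amplitude,
    phi_deg = phi_rad * 180 / pi,
    acrophase_deg = acrophase_deg,
    acrophase_hhmm = acrophase_clock(acrophase_deg),
    acrophase_day1_deg = phi0_day1_min / 1440 * 360,
    delta_t = delta_t, r_squared = r2,
    coefficients = c(mesor = mesor, a = a, b = b),
    n = info$n, n_days = n_days,
    epoch_minutes = info$epoch_minutes, start_clock = info$start_clock
  ), class = "cosinor_fit")
}

#' Evaluate a fitted cosinor curve
#'
#' @param object A `cosinor_fit`.
#' @param time_min Minutes after midnight of day 1 at which to evaluate;
#'   defaults to the fitted sampling grid.
#' @param ... Unused.
#' @return Numeric vector of model values.
#' @export
predict.cosinor_fit <- function(object, time_min = NULL, ...) {
  if (is.null(time_min)) {
    time_min <- object$start_clock + (seq_len(object$n) - 1) * object$epoch_minutes
  }
  w <- 2 * pi / object$period
  cf <- object$coefficients
  cf[["mesor"]] + cf[["a"]] * cos(w * time_min) + cf[["b"]] * sin(w * time_min)
}

#' Scan trial periods to maximise the fitted cosinor amplitude
#'
#' Fits the cosinor model at every period in `t_grid` and returns the fit
#' whose amplitude A is largest; ties are broken toward the period closest
#' to the ideal 1440 min.  The default grid covers 1440 +/- 120 min in
#' 1-min steps.
#'
#' @inheritParams fit_cosinor
#' @param t_grid Numeric vector of candidate periods (minutes).
#' @return The winning `cosinor_fit`, with the amplitude-vs-period scan
#'   attached as attribute `"scan"` (a tibble with columns `period`,
#'   `amplitude`).
#' @export
scan_period <- function(data, t_grid = seq(1320, 1560, by = 1)) {
  if (length(t_grid) == 0) stop("empty period grid", call. = FALSE)
  info <- series_info(data)
  if (any(t_grid <= 2 * info$epoch_minutes)) {
    stop("all periods must exceed twice the epoch length", call. = FALSE)
  }
  amp <- vapply(t_grid, function(T) {
    w <- 2 * pi / T
    X <- cbind(1, cos(w * info$time_min), sin(w * info$time_min))
    cf <- stats::lm.fit(X, info$x)$coefficients
    sqrt(cf[[2]]^2 + cf[[3]]^2)
  }, numeric(1))
  best <- max(amp)
  cand <- which(amp >= best - 1e-12 * max(1, abs(best)))
  winner <- cand[which.min(abs(t_grid[cand] - 1440))]
  fit <- fit_cosinor(data, period = t_grid[winner])
  attr(fit, "scan") <- tibble::tibble(period = t_grid, amplitude = amp)
  fit
}

#' Convert an acrophase angle to clock time
#'
#' Uses the convention 360 deg = 24 h after midnight: 232 deg -> "15:28",
#' 253 deg -> "16:52".
#'
#' @param acrophase_deg Acrophase in degrees (any finite value; wrapped to
#'   \[0, 360)).
#' @return Character vector "HH:MM", rounded to the nearest minute.
#' @examples
#' acrophase_clock(c(232, 253, 0))
#' @export
acrophase_clock <- function(acrophase_deg) {
  stopifnot(all(is.finite(acrophase_deg)))
  m <- round(acrophase_deg / 360 * 1440) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

#' Per-day acrophase line implied by a fixed-period cosinor fit
#'
#' A period deviation `delta_t = T - 1440` min accumulates day after day,
#' delaying (`delta_t > 0`) or advancing (`delta_t < 0`) the acrophase by
#' `delta_t / 4` degrees per day (4 min = 1 deg).
#'
#' @param fit A `cosinor_fit`.
#' @param n_days Number of days (defaults to the fitted recording length).
#' @return Tibble with columns `day` (1-based) and `acrophase_deg`
#'   (unwrapped, i.e. not reduced modulo 360).
#' @export
acrophase_trajectory <- function(fit, n_days = fit$n_days) {
  stopifnot(inherits(fit, "cosinor_fit"), n_days >= 1)
  d <- seq_len(n_days) - 1
  tibble::tibble(
    day = d + 1L,
    acrophase_deg = fit$acrophase_day1_deg + d * fit$delta_t * 360 / 1440
  )
}

#' Cosinor parameters for every subject of a cohort
#'
#' @param cohort Multi-subject actigraphy tibble.
#' @param t_grid Periods to scan per subject, or `NULL` to fit all subjects
#'   at a fixed 1440-min period.
#' @return One-row-per-subject tibble of cosinor parameters.
#' @export
cosinor_table <- function(cohort, t_grid = NULL) {
  cohort |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(d, key) {
      fit <- if (is.null(t_grid)) fit_cosinor(d) else scan_period(d, t_grid)
      fit$subject_id <- key$subject_id
      if ("group" %in% names(d)) fit$group <- d$group[1]
      glance(fit)
    }) |>
    dplyr::bind_rows()
}

#' @describeIn fit_cosinor One-row tibble of fitted parameters.
#' @param x,object A `cosinor_fit`.
#' @param ... Unused.
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, group = x$group, period = x$period,
    delta_t = x$delta_t, mesor = x$mesor, amplitude = x$amplitude,
    phi_deg = x$phi_deg, acrophase_deg = x$acrophase_deg,
    acrophase_hhmm = x$acrophase_hhmm, r_squared = x$r_squared, n = x$n
  )
}

#' @describeIn fit_cosinor Long tibble of parameter estimates.
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "phi_deg", "acrophase_deg", "period",
             "delta_t", "r_squared"),
    estimate = c(x$mesor, x$amplitude, x$phi_deg, x$acrophase_deg,
                 x$period, x$delta_t, x$r_squared)
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "Cosinor fit (T = %.1f min): M = %.1f, A = %.1f, acrophase = %.1f deg (%s), R^2 = %.3f\n",
    x$period, x$mesor, x$amplitude, x$acrophase_deg, x$acrophase_hhmm,
    x$r_squared))
  invisible(x)
}
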