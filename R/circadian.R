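# Day-by-day circadian parameters (mesor, amplitude, acrophase, period)
# read off the SSA trend + circadian reconstruction, and their day-to-day
# variability summaries.

#' Trend and circadian reconstructions from an SSA decomposition
#'
#' @param d An `ssa_decomp`.
#' @param trend Component indices of the non-oscillating trend (default 1).
#' @param circadian Component indices of the circadian pair (default
#'   `c(2, 3)`, the conventional nearly degenerate pair; use
#'   [auto_circadian_pair()] when the trend splits).
#' @return A tibble with columns `time_min`, `counts` (original series),
#'   `trend` and `circadian` (physical reconstructions `sum sigma_k g_k`).
#' @export
circadian_reconstruction <- function(d, trend = 1L, circadian = c(2L, 3L)) {
  stopifnot(inherits(d, "ssa_decomp"))
  if (length(circadian) == 0) stop("empty circadian component set", call. = FALSE)
  tibble::tibble(
    time_min = d$time_min,
    counts = d$x,
    trend = ssa_reconstruct(d, trend),
    circadian = ssa_reconstruct(d, circadian)
  )
}

# strict local maxima (or minima) indices of a smooth series
local_extrema <- function(g, maxima = TRUE) {
  s <- diff(sign(diff(g)))
  which(if (maxima) s < 0 else s > 0) + 1L
}

# greedy peak selection: highest first, enforcing a minimum separation
select_peaks <- function(g, t, min_sep) {
  cand <- local_extrema(g, maxima = TRUE)
  cand <- cand[order(g[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - t[keep]) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Per-day circadian parameters from a reconstruction
#'
#' Daily acrophases are the clock positions (360 deg = 24 h after midnight)
#' of the successive local maxima of the circadian reconstruction, with
#' maxima constrained to be at least `min_separation_min` apart to suppress
#' ultradian leakage, and unwrapped so consecutive days never jump by
#' +/-360 deg.  Daily periods are the spacings between successive maxima
#' (D-1 values).  The daily amplitude is half the peak-to-trough excursion
#' of the circadian series between the minima bracketing each maximum, and
#' the daily mesor is the mean of the trend over each calendar day.
#' Maxima within 2 h of the series boundary are flagged `edge = TRUE`
#' (diagonal-averaging distorts the reconstruction there).
#'
#' @param recon Output of [circadian_reconstruction()].
#' @param min_separation_min Minimum spacing between accepted maxima
#'   (default 1080 min = 18 h).
#' @return An object of class `daily_circadian`: list with `daily`
#'   (per-day tibble), `summary` (per-parameter mean/SD/CV/Skew/Kurt,
#'   population convention, Gaussian kurtosis = 3) and `r_squared` of the
#'   trend + circadian model.
#' @export
daily_parameters <- function(recon, min_separation_min = 1080) {
  stopifnot(all(c("time_min", "trend", "circadian") %in% names(recon)))
  t <- recon$time_min
  g <- recon$circadian
  peaks <- select_peaks(g, t, min_separation_min)
  if (length(peaks) < 2L) stop("no circadian cycle detected (fewer than 2 maxima)", call. = FALSE)

  # acrophase: minute-of-day of each peak, unwrapped across days
  mod <- t[peaks] %% 1440
  unwrapped <- mod
  if (length(mod) > 1) {
    for (i in 2:length(mod)) {
      dphi <- mod[i] - (unwrapped[i - 1] %% 1440)
      dphi <- dphi - 1440 * round(dphi / 1440)
      unwrapped[i] <- unwrapped[i - 1] + dphi
    }
  }
  acro_deg <- unwrapped / 1440 * 360

  # amplitude: half-range between the minima bracketing each maximum
  mins <- local_extrema(g, maxima = FALSE)
  amp <- vapply(seq_along(peaks), function(i) {
    p <- peaks[i]
    lo <- mins[mins < p]
    hi <- mins[mins > p]
    left <- if (length(lo)) max(lo) else 1L
    right <- if (length(hi)) min(hi) else length(g)
    (g[p] - min(g[left:right])) / 2
  }, numeric(1))

  # mesor: trend mean per calendar day
  day_of <- floor(t / 1440)
  mesor_by_day <- tapply(recon$trend, day_of, mean)

  duration <- t[length(t)] - t[1]
  edge <- t[peaks] - t[1] < 120 | t[length(t)] - t[peaks] < 120

  daily <- tibble::tibble(
    day = seq_along(peaks),
    peak_time_min = t[peaks],
    acrophase_deg = acro_deg,
    acrophase_hhmm = acrophase_clock(acro_deg %% 360),
    amplitude = amp,
    mesor = as.numeric(mesor_by_day[pmin(seq_along(peaks), length(mesor_by_day))]),
    edge = edge
  )
  period <- diff(t[peaks])

  summarise_par <- function(v, name) {
    dplyr::mutate(day_to_day_stats(v), parameter = name, .before = 1)
  }
  summary <- dplyr::bind_rows(
    summarise_par(daily$mesor, "mesor"),
    summarise_par(daily$amplitude, "amplitude"),
    summarise_par(daily$acrophase_deg, "acrophase_deg"),
    if (length(period) >= 2) summarise_par(period, "period") else NULL
  )

  r2 <- ssa_r_squared(recon$counts, recon$trend + recon$circadian)

  structure(list(daily = daily, period = period, summary = summary,
                 r_squared = r2,
                 mean_acrophase_deg = mean(acro_deg) %% 360),
            class = "daily_circadian")
}

#' Coefficient of determination of a model series
#'
#' `R^2 = 1 - Var(x - y) / Var(x)` comparing the residuals around a model
#' `y` with the variance of the series around its mean; used both for the
#' cosinor fit and for the SSA trend + circadian model.
#'
#' @param x Observed series (numeric vector or actigraphy tibble).
#' @param y Model series of the same length.
#' @return A scalar in (-Inf, 1].
#' @export
ssa_r_squared <- function(x, y) {
  if (is.data.frame(x)) x <- series_info(x)$x
  stopifnot(length(x) == length(y))
  ss_tot <- sum((x - mean(x))^2)
  if (ss_tot == 0) stop("constant series: R^2 is undefined", call. = FALSE)
  1 - sum((x - y)^2) / ss_tot
}

#' @describeIn daily_parameters Per-day parameter tibble.
#' @param x A `daily_circadian` object.
#' @param ... Unused.
#' @export
tidy.daily_circadian <- function(x, ...) x$daily

#' @describeIn daily_parameters One-row tibble of day-to-day summaries
#'   (mean/SD/CV/Skew/Kurt per parameter, wide) plus the SSA R^2.
#' @export
glance.daily_circadian <- function(x, ...) {
  wide <- x$summary |>
    tidyr::pivot_longer(c("mean", "sd", "cv", "skew", "kurt"),
                        names_to = "stat", values_to = "value") |>
    dplyr::mutate(name = paste0(.data$stat, "_", .data$parameter)) |>
    dplyr::select("name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")
  dplyr::mutate(wide,
                mean_acrophase_deg = x$mean_acrophase_deg,
                mean_period = mean(x$period),
                r_squared = x$r_squared)
}

#' @export
print.daily_circadian <- function(x, ...) {
  cat(sprintf("Daily circadian parameters over %d detected cycles (R^2 = %.3f)\n",
              nrow(x$daily), x$r_squared))
  print(x$summary)
  invisible(x)
}
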