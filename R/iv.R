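# Intradaily variability: the classic hourly measure and its generalisation
# IV(P) over resampling intervals P, with a fixed-denominator convention
# (variance of the original series) that makes IV(P) a simple function of P.

#' Resample an actigraphy series to a coarser epoch by bin means
#'
#' Each output sample is the mean of the `P / epoch` input samples in its
#' bin, so resampled series stay on the counts/min scale.  Trailing samples
#' that do not fill a complete bin are dropped with a warning.
#'
#' @param data Single-subject actigraphy tibble.
#' @param P New sampling interval in minutes; must be a positive integer
#'   multiple of the current epoch.
#' @return Resampled actigraphy tibble (epoch `P`).
#' @examples
#' s <- tibble::tibble(time_min = 0:3, counts = 1:4)
#' resample_counts(s, 2)$counts  # 1.5 3.5
#' @export
resample_counts <- function(data, P) {
  info <- series_info(data)
  m <- P / info$epoch_minutes
  if (P < info$epoch_minutes || abs(m - round(m)) > 1e-9) {
    stop("P must be an integer multiple of the epoch", call. = FALSE)
  }
  m <- as.integer(round(m))
  if (m == 1L) return(tibble::as_tibble(data))
  nbins <- info$n %/% m
  if (nbins < 1L) stop("P exceeds the series duration", call. = FALSE)
  rem <- info$n - nbins * m
  if (rem > 0L) {
    warning(sprintf("dropping %d trailing samples that do not fill a %g-min bin",
                    rem, P), call. = FALSE)
  }
  xb <- colMeans(matrix(info$x[seq_len(nbins * m)], nrow = m))
  out <- tibble::tibble(time_min = info$time_min[1] + (seq_len(nbins) - 1) * P,
                        counts = xb)
  if ("subject_id" %in% names(data)) out <- dplyr::mutate(out, subject_id = data$subject_id[1], .before = 1)
  if ("group" %in% names(data)) out <- dplyr::mutate(out, group = data$group[1], .after = "subject_id")
  out
}

# Eq-5 style ratio on a prepared series: numerator sum(diff^2)/(N-1),
# denominator population variance (divide by N).
iv_ratio <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples for IV", call. = FALSE)
  den <- var_pop(x)
  if (den == 0) stop("constant series: IV is undefined", call. = FALSE)
  sum(diff(x)^2) / (n - 1) / den
}

#' Classic intradaily variability at a fixed resampling interval
#'
#' Resamples to `P`-minute bins and computes the ratio of the variance of
#' the first differences (divisor N-1) to the variance of the resampled
#' series around its mean (divisor N) — the traditional measure with its
#' hourly convention `P = 60`.
#'
#' @inheritParams resample_counts
#' @param P Resampling interval in minutes (default 60).
#' @return A single nonnegative number.
#' @export
iv_classic <- function(data, P = 60) {
  iv_ratio(resample_counts(data, P)$counts)
}

#' Default resampling grid for IV(P)
#'
#' About 40 log-spaced integer intervals from 1 to 600 min, always
#' including the canonical 60 min, filtered to multiples of `epoch`.
#'
#' @param epoch Epoch of the series in minutes.
#' @return Integer vector of intervals.
#' @export
iv_default_grid <- function(epoch = 1) {
  g <- unique(round(exp(seq(log(1), log(600), length.out = 40))))
  g <- sort(unique(c(g, 60)))
  g[g >= epoch & (g %% epoch) == 0]
}

#' Intradaily variability as a function of the resampling interval
#'
#' For each interval `P` the numerator is the first-difference variance of
#' the bin-mean resampled series `X_P` (divisor N-1).  With
#' `denominator = "original"` it is divided by the variance of the raw
#' series — a constant — so IV(P) is an unambiguous function of P; with
#' `denominator = "resampled"` the classic per-P variance is used instead.
#'
#' @inheritParams resample_counts
#' @param p_values Intervals in minutes (default [iv_default_grid()]).
#' @param denominator `"original"` (fixed Var(x)) or `"resampled"`
#'   (classic Var(X_P)).
#' @return A tibble of class `iv_curve` with columns `P`, `iv`,
#'   `denominator`.
#' @export
iv_curve <- function(data, p_values = NULL,
                     denominator = c("original", "resampled")) {
  denominator <- match.arg(denominator)
  info <- series_info(data)
  if (is.null(p_values)) p_values <- iv_default_grid(info$epoch_minutes)
  if (length(p_values) == 0) stop("empty P grid", call. = FALSE)
  var_x <- var_pop(info$x)
  if (var_x == 0) stop("constant series: IV is undefined", call. = FALSE)
  iv <- vapply(p_values, function(P) {
    xb <- suppressWarnings(resample_counts(data, P)$counts)
    if (length(xb) < 3L) return(NA_real_)
    num <- sum(diff(xb)^2) / (length(xb) - 1)
    num / (if (denominator == "original") var_x else var_pop(xb))
  }, numeric(1))
  out <- tibble::tibble(P = as.numeric(p_values), iv = iv,
                        denominator = denominator)
  class(out) <- c("iv_curve", class(out))
  out
}
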