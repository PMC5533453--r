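# Power-law structure of the ultradian scree tail: lambda_k ~ 1/k^gamma,
# fitted by ordinary least squares in log10-log10 coordinates, with a
# two-range crossover fit and the fractional variance in the
# log10(k) in [1.4, 1.6] band where ~60-90-min ultradian rhythms live.

scree_lambda <- function(scree) {
  if (is.data.frame(scree)) {
    stopifnot("k" %in% names(scree),
              any(c("lambda", "lambda_frac") %in% names(scree)))
    lam <- if ("lambda" %in% names(scree)) scree$lambda else scree$lambda_frac
    list(k = scree$k, lambda = lam,
         frac = if ("lambda_frac" %in% names(scree)) scree$lambda_frac else lam / sum(lam))
  } else {
    lam <- as.numeric(scree)
    list(k = seq_along(lam), lambda = lam, frac = lam / sum(lam))
  }
}

#' Fit a power law to ordered partial variances
#'
#' Ordinary least squares of `log10(lambda_k)` on `log10(k)` over a range
#' of `log10(k)`; the exponent is minus the slope.  Scale-invariant: a
#' constant factor on lambda only shifts the intercept.
#'
#' @param scree A scree tibble from [ssa_scree()] (columns `k` and `lambda`
#'   or `lambda_frac`) or a bare vector of ordered partial variances.
#' @param log10k_range Two-element range of `log10(k)` (default
#'   `c(0.78, 3.0)`, the single-law ultradian range).
#' @return A list with `gamma`, `r_squared`, `n_points`.
#' @examples
#' fit_power_law(100 / (1:1000))$gamma  # 1
#' @export
fit_power_law <- function(scree, log10k_range = c(0.78, 3.0)) {
  s <- scree_lambda(scree)
  sel <- log10(s$k) >= log10k_range[1] & log10(s$k) <= log10k_range[2]
  if (sum(sel) < 5L) stop("fewer than 5 scree points in the fit range", call. = FALSE)
  if (any(s$lambda[sel] <= 0)) stop("nonpositive partial variance in the fit range", call. = FALSE)
  lx <- log10(s$k[sel]); ly <- log10(s$lambda[sel])
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  res <- ly - mean(ly) - slope * (lx - mean(lx))
  r2 <- 1 - sum(res^2) / sum((ly - mean(ly))^2)
  list(gamma = -slope, r_squared = r2, n_points = sum(sel))
}

#' Single-law and crossover power-law fits of a scree diagram
#'
#' Fits (i) a single exponent `gamma` over `log10(k)` in \[0.78, 3.0\],
#' (ii) `gamma1` before the crossover (\[0.8, 1.5\]) and `gamma2` after it
#' (\[1.6, 2.0\]), and (iii) the summed fractional partial variance
#' `band_fraction` over the \[1.4, 1.6\] band (ranks k = 26..39,
#' corresponding to mean ultradian periods of roughly 60-90 min at
#' L = 1440).  A 1/f-like tail gives `gamma1 ~ gamma2`; excess narrowband
#' ultradian power flattens the pre-crossover range and steepens the
#' post-crossover one (`gamma2 > gamma1`).
#'
#' @inheritParams fit_power_law
#' @param single_range,pre_range,post_range,band_range `log10(k)` windows
#'   for the respective fits.
#' @return An object of class `scaling_fit` (also a one-row tibble) with
#'   columns `gamma`, `gamma1`, `gamma2`, `crossover` (= gamma2 - gamma1),
#'   `band_fraction` and the three fit `r_squared`s.
#' @export
crossover_fit <- function(scree,
                          single_range = c(0.78, 3.0),
                          pre_range = c(0.8, 1.5),
                          post_range = c(1.6, 2.0),
                          band_range = c(1.4, 1.6)) {
  s <- scree_lambda(scree)
  if (max(log10(s$k)) < post_range[2]) {
    stop("scree does not reach log10(k) = ", post_range[2], call. = FALSE)
  }
  f0 <- fit_power_law(scree, single_range)
  f1 <- fit_power_law(scree, pre_range)
  f2 <- fit_power_law(scree, post_range)
  band <- log10(s$k) >= band_range[1] & log10(s$k) <= band_range[2]
  out <- tibble::tibble(
    gamma = f0$gamma, gamma1 = f1$gamma, gamma2 = f2$gamma,
    crossover = f2$gamma - f1$gamma,
    band_fraction = sum(s$frac[band]),
    r_squared_single = f0$r_squared,
    r_squared_pre = f1$r_squared,
    r_squared_post = f2$r_squared
  )
  class(out) <- c("scaling_fit", class(out))
  out
}

#' Physical period range spanned by a band of scree ranks
#'
#' Estimates the mean period of every component with rank `k` in
#' `k_range` and returns the min/max over the non-trend ones, so scree
#' bands can be labelled in physical time units (e.g. the ranks near
#' log10(k) = 1.5 map to ~60-90-min ultradian periods).
#'
#' @param d An `ssa_decomp`.
#' @param k_range Two-element integer range of scree ranks.
#' @return Tibble with columns `k_min`, `k_max`, `period_min`,
#'   `period_max` (minutes).
#' @export
band_to_frequency <- function(d, k_range) {
  stopifnot(inherits(d, "ssa_decomp"), length(k_range) == 2)
  ks <- seq(max(1L, k_range[1]), min(d$r, k_range[2]))
  g <- ssa_components(d, ks)
  per <- apply(g, 2, estimate_component_period, epoch_minutes = d$epoch_minutes)
  per <- per[is.finite(per)]
  if (length(per) == 0) stop("all components in range are trend-like", call. = FALSE)
  tibble::tibble(k_min = ks[1], k_max = ks[length(ks)],
                 period_min = min(per), period_max = max(per))
}
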