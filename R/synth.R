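# Synthetic actigraphy cohorts with known ground truth.
#
# A generated subject is the sum of (i) a cosine with subject-level mesor,
# day-varying amplitude and day-jittered acrophase, (ii) an ultradian
# stochastic component that is either 1/f-shaped noise or 1/f noise plus a
# quasi-periodic ~90-min narrowband oscillation, and (iii) optional
# multiplicative burst intermittency, clipped to the device count range.

#' Specification of one synthetic actigraphy group
#'
#' Defaults emulate a healthy young-adult control group wearing a count
#' actigraph at 1-min epochs for one week: mesor ~216 counts/min (SD 56
#' between subjects), circadian amplitude 178 counts/min with day-to-day
#' CV 0.28, mid-afternoon acrophase (232 deg after midnight, i.e. ~15:28)
#' with 26 deg day-to-day jitter, 24-h period, a 1/f-like ultradian tail
#' and counts clipped to 0..3000.  The default `noise_scale` of 290
#' counts/min makes the single-harmonic cosinor fit explain ~0.13 of the
#' variance, the scale typical of real wrist actigraphy in young adults.
#'
#' @param n_subjects Subjects in the group.
#' @param n_days Recording days per subject (default 7).
#' @param epoch_minutes Epoch length P in minutes (default 1).
#' @param mesor_mean,mesor_sd Between-subject mean/SD of the mesor
#'   (counts/min).
#' @param amplitude_mean Circadian amplitude (counts/min).
#' @param amplitude_day_cv Day-to-day coefficient of variation of the
#'   amplitude (dimensionless).
#' @param acrophase_mean Acrophase in degrees after midnight (360 deg = 24 h).
#' @param acrophase_day_sd Day-to-day SD of the acrophase, degrees.
#' @param period_minutes Circadian period T (minutes); values other than
#'   1440 inject a daily acrophase drift of T - 1440 min/day.
#' @param ultradian_mode `"one_over_f"` for a pure 1/f-shaped ultradian
#'   tail, `"brac90"` to add a quasi-periodic oscillation near
#'   `brac_period_minutes`.
#' @param brac_period_minutes Centre period of the narrowband ultradian
#'   oscillation (default 90 min).
#' @param brac_relative_power Variance of the narrowband oscillation
#'   relative to the 1/f component (>= 0; only used in `"brac90"` mode).
#' @param noise_scale Standard deviation (counts/min) of the stochastic
#'   ultradian component before clipping.
#' @param burst_prob,burst_scale Optional "spiky" intermittency: each epoch
#'   is multiplied, with probability `burst_prob`, by 1 + Exp(mean =
#'   `burst_scale`). Default off.
#' @param count_ceiling Device saturation (counts/min, default 3000).
#' @param integer_counts Round generated counts to integers (default TRUE,
#'   as real devices report integer counts). Set FALSE for exact
#'   parameter-recovery experiments.
#' @param seed Integer seed; each subject's stream is derived from
#'   (`seed`, subject index) so subjects are independently reproducible.
#' @return A list of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_subjects = 2, seed = 1)
#' subj <- generate_subject(spec, 0)
#' @export
cohort_spec <- function(n_subjects = 20,
                        n_days = 7,
                        epoch_minutes = 1,
                        mesor_mean = 216,
                        mesor_sd = 56,
                        amplitude_mean = 178,
                        amplitude_day_cv = 0.28,
                        acrophase_mean = 232,
                        acrophase_day_sd = 26,
                        period_minutes = 1440,
                        ultradian_mode = c("one_over_f", "brac90"),
                        brac_period_minutes = 90,
                        brac_relative_power = 0.5,
                        noise_scale = 290,
                        burst_prob = 0,
                        burst_scale = 3,
                        count_ceiling = 3000,
                        integer_counts = TRUE,
                        seed = 1L) {
  ultradian_mode <- match.arg(ultradian_mode)
  spec <- list(
    n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
    epoch_minutes = epoch_minutes, mesor_mean = mesor_mean,
    mesor_sd = mesor_sd, amplitude_mean = amplitude_mean,
    amplitude_day_cv = amplitude_day_cv, acrophase_mean = acrophase_mean,
    acrophase_day_sd = acrophase_day_sd, period_minutes = period_minutes,
    ultradian_mode = ultradian_mode,
    brac_period_minutes = brac_period_minutes,
    brac_relative_power = brac_relative_power, noise_scale = noise_scale,
    burst_prob = burst_prob, burst_scale = burst_scale,
    count_ceiling = count_ceiling, integer_counts = isTRUE(integer_counts),
    seed = as.integer(seed)
  )
  with(spec, {
    stopifnot(n_subjects >= 1, n_days >= 1, epoch_minutes > 0,
              period_minutes > 0, brac_period_minutes > 0,
              brac_relative_power >= 0, noise_scale >= 0,
              amplitude_mean >= 0, amplitude_day_cv >= 0,
              acrophase_day_sd >= 0, burst_prob >= 0, burst_prob <= 1,
              count_ceiling > 0)
    if (acrophase_mean < 0 || acrophase_mean >= 360) {
      stop("acrophase_mean must lie in [0, 360)", call. = FALSE)
    }
    n <- n_days * 1440 / epoch_minutes
    if (abs(n - round(n)) > 1e-9) {
      stop("n_days * 1440 / epoch_minutes must be an integer series length",
           call. = FALSE)
    }
  })
  structure(spec, class = "cohort_spec")
}

# Unit-variance 1/f-shaped Gaussian noise via spectral amplitude shaping
# (amplitude ~ f^(-1/2) so power ~ 1/f); DC removed.  The shaping is
# band-limited below `f_min` (default: periods longer than 12 h excluded)
# so that the stochastic component stays ultradian and does not inject
# spurious multi-day trend wander.
one_over_f_noise <- function(n, f_min = 0) {
  z <- stats::fft(stats::rnorm(n))
  f <- pmin(0:(n - 1), n - (0:(n - 1))) / n   # physical frequency per epoch
  amp <- ifelse(f >= max(f_min, 1 / n), f^(-0.5), 0)
  u <- Re(stats::fft(z * amp, inverse = TRUE)) / n
  u / stats::sd(u)
}

# Unit-variance quasi-periodic oscillation near `period` epochs: Gaussian
# spectral band of 15% relative width centred on 1/period.
narrowband_noise <- function(n, period) {
  z <- stats::fft(stats::rnorm(n))
  f <- pmin(0:(n - 1), n - (0:(n - 1))) / n
  f0 <- 1 / period
  amp <- exp(-(f - f0)^2 / (2 * (0.15 * f0)^2))
  u <- Re(stats::fft(z * amp, inverse = TRUE)) / n
  u / stats::sd(u)
}

subject_seed <- function(seed, subject_index) {
  as.integer((as.double(seed) * 1009 + as.double(subject_index) * 7919 + 1) %%
               2147483629)
}

#' Generate one synthetic actigraphy subject
#'
#' Deterministic for a fixed (`spec$seed`, `subject_index`) pair.  The
#' injected ground truth (subject mesor and per-day amplitude/acrophase) is
#' attached as attribute `"truth"`; the fraction of samples clipped at 0 or
#' at the ceiling as attribute `"clipped_fraction"`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Zero-based subject index within the group.
#' @param subject_id,group Labels stored in the output columns.
#' @return A tibble with columns `subject_id`, `group`, `time_min`, `counts`.
#' @export
generate_subject <- function(spec, subject_index = 0,
                             subject_id = sprintf("S%03d", subject_index + 1),
                             group = "control") {
  stopifnot(inherits(spec, "cohort_spec"), subject_index >= 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(subject_seed(spec$seed, subject_index))

  P <- spec$epoch_minutes
  n <- as.integer(round(spec$n_days * 1440 / P))
  t <- (seq_len(n) - 1) * P

  mesor <- stats::rnorm(1, spec$mesor_mean, spec$mesor_sd)
  amp_day <- pmax(0, spec$amplitude_mean *
                    (1 + spec$amplitude_day_cv * stats::rnorm(spec$n_days)))
  jitter_min <- stats::rnorm(spec$n_days, 0, spec$acrophase_day_sd * 4) # 1 deg = 4 min
  phi0_min <- spec$acrophase_mean / 360 * 1440

  # day-level modulation: i.i.d. Gaussian values anchored at the successive
  # nominal peak times and interpolated linearly in between, so parameters
  # change from day to day without discontinuous midnight jumps
  if (spec$n_days == 1L) {
    amp_t <- rep(amp_day, n)
    jit_t <- rep(jitter_min, n)
  } else {
    knots <- phi0_min + (seq_len(spec$n_days) - 1) * 1440
    amp_t <- stats::approx(knots, amp_day, xout = t, rule = 2)$y
    jit_t <- stats::approx(knots, jitter_min, xout = t, rule = 2)$y
  }

  circ <- mesor + amp_t *
    cos(2 * pi * (t - phi0_min - jit_t) / spec$period_minutes)

  u <- numeric(n)
  if (spec$noise_scale > 0) {
    u <- one_over_f_noise(n, f_min = P / 720)
    if (spec$ultradian_mode == "brac90" && spec$brac_relative_power > 0) {
      u <- u + sqrt(spec$brac_relative_power) *
        narrowband_noise(n, spec$brac_period_minutes / P)
    }
    u <- spec$noise_scale * u
  }

  x <- circ + u
  if (spec$burst_prob > 0) {
    hit <- stats::runif(n) < spec$burst_prob
    x[hit] <- x[hit] * (1 + stats::rexp(sum(hit), 1 / spec$burst_scale))
  }
  clipped <- mean(x < 0 | x > spec$count_ceiling)
  x <- pmin(pmax(x, 0), spec$count_ceiling)
  if (spec$integer_counts) x <- round(x)

  # injected minute-of-day of the circadian peak for each day
  drift <- spec$period_minutes - 1440
  truth <- tibble::tibble(
    day = seq_len(spec$n_days),
    mesor = mesor,
    amplitude = amp_day,
    acrophase_min = phi0_min + jitter_min + (seq_len(spec$n_days) - 1) * drift,
    acrophase_deg = (phi0_min + jitter_min +
                       (seq_len(spec$n_days) - 1) * drift) / 1440 * 360
  )

  out <- tibble::tibble(subject_id = subject_id, group = group,
                        time_min = t, counts = x)
  attr(out, "truth") <- truth
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Generate a two-group synthetic cohort
#'
#' @param control_spec,case_spec [cohort_spec()]s for the two groups; subject
#'   streams are derived from each spec's own seed, so two identical specs
#'   yield two identical groups.
#' @param groups Character vector of the two group labels.
#' @return A tibble stacking all subjects' series, with per-subject injected
#'   parameters in attribute `"truth"` (a named list of tibbles).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 1, seed = 1),
#'                        cohort_spec(n_subjects = 1, seed = 2))
#' dplyr::count(coh, group)
#' @export
generate_cohort <- function(control_spec, case_spec,
                            groups = c("control", "case")) {
  stopifnot(inherits(control_spec, "cohort_spec"),
            inherits(case_spec, "cohort_spec"), length(groups) == 2)
  specs <- list(control_spec, case_spec)
  truth <- list()
  parts <- list()
  for (g in 1:2) {
    for (i in seq_len(specs[[g]]$n_subjects)) {
      id <- sprintf("%s_%02d", groups[g], i)
      s <- generate_subject(specs[[g]], i - 1, subject_id = id,
                            group = groups[g])
      truth[[id]] <- attr(s, "truth")
      parts[[length(parts) + 1L]] <- s
    }
  }
  out <- dplyr::bind_rows(parts)
  attr(out, "truth") <- truth
  out
}
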