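# Cohort-level statistics: Kruskal-Wallis group comparisons of per-subject
# parameters, minute-of-day mean 24 h profiles with per-minute tests, and
# cosinor-vs-SSA agreement per subject.

#' Kruskal-Wallis comparison of a parameter between groups
#'
#' Rank-based H with tie correction and a chi-square p-value (df = number
#' of groups - 1), as implemented by [stats::kruskal.test()].  When every
#' value is identical across all groups the statistic degenerates to H = 0,
#' p = 1.
#'
#' @param values Numeric vector of per-subject parameter values.
#' @param group Group label for each value (at least 2 values per group).
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble with `H`, `df`, `p_value`, `significant`.
#' @examples
#' kw_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kw_test <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  stopifnot(length(values) == length(group), nlevels(group) >= 2)
  if (any(table(group) < 2)) stop("need at least 2 values per group", call. = FALSE)
  if (length(unique(values)) == 1L) {
    h <- 0; df <- nlevels(group) - 1L; p <- 1
  } else {
    kt <- stats::kruskal.test(values, group)
    h <- unname(kt$statistic); df <- unname(kt$parameter); p <- kt$p.value
  }
  tibble::tibble(H = h, df = df, p_value = p, significant = p < alpha)
}

#' Group comparison table for per-subject parameters
#'
#' @param params One-row-per-subject tibble (e.g. from [cosinor_table()])
#'   with a `group` column.
#' @param vars Character vector of parameter columns to compare.
#' @param alpha Significance level.
#' @return A tibble with one row per parameter: per-group `mean_<g>` /
#'   `sd_<g>` summaries (sample SD, as usually reported for cohorts),
#'   `H`, `p_value`, `significant`.
#' @export
compare_groups <- function(params, vars, alpha = 0.05) {
  stopifnot("group" %in% names(params), all(vars %in% names(params)))
  purrr::map_dfr(vars, function(v) {
    x <- params[[v]]
    g <- params$group
    sums <- tibble::tibble(group = g, value = x) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "group", values_from = c("mean", "sd"))
    dplyr::bind_cols(tibble::tibble(parameter = v), sums,
                     kw_test(x, g, alpha))
  })
}

#' Mean 24-hour activity profile with per-minute group comparison
#'
#' For each minute of day, activity is first averaged over days within each
#' subject, then compared between groups with a Kruskal-Wallis test across
#' subjects (subjects, not days, are the replication unit), and averaged
#' across subjects for the group profile.  No multiplicity correction is
#' applied by default — each of the 1440 tests is reported at raw
#' `alpha` — matching the usual presentation of transition-band
#' significance; set `adjust = "BH"` for a Benjamini-Hochberg-corrected
#' version.
#'
#' @param cohort Multi-subject actigraphy tibble, all at 1-min epochs and
#'   whole days.
#' @param alpha Per-minute significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `profile_24h`: list with `profile` (tibble:
#'   `minute`, `group`, `mean`), `minutes` (tibble: `minute`, `H`,
#'   `p_value`, `significant`) and `intervals` (contiguous significant
#'   stretches with start/end clock times).
#' @export
mean_24h_profile <- function(cohort, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  per_subj <- cohort |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::group_modify(function(d, key) {
      info <- series_info(d)
      if (abs(info$epoch_minutes - 1) > 1e-9) {
        stop("profile requires 1-min epochs for all subjects", call. = FALSE)
      }
      if (abs(info$n %% 1440) > 1e-9) {
        stop("profile requires whole recording days", call. = FALSE)
      }
      tibble::tibble(minute = info$time_min %% 1440, counts = info$x) |>
        dplyr::group_by(.data$minute) |>
        dplyr::summarise(day_mean = mean(.data$counts), .groups = "drop")
    }) |>
    dplyr::ungroup()

  if (any(table(dplyr::distinct(per_subj, .data$subject_id, .data$group)$group) < 2)) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }

  profile <- per_subj |>
    dplyr::group_by(.data$minute, .data$group) |>
    dplyr::summarise(mean = mean(.data$day_mean), .groups = "drop")

  minutes <- per_subj |>
    dplyr::group_by(.data$minute) |>
    dplyr::group_modify(~ kw_test(.x$day_mean, .x$group, alpha)) |>
    dplyr::ungroup()
  if (adjust == "BH") {
    minutes$p_value <- stats::p.adjust(minutes$p_value, "BH")
    minutes$significant <- minutes$p_value < alpha
  }

  r <- rle(minutes$significant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sig <- which(r$values)
  intervals <- tibble::tibble(
    start_min = minutes$minute[starts[sig]],
    end_min = minutes$minute[ends[sig]],
    start_hhmm = acrophase_clock(minutes$minute[starts[sig]] / 4),
    end_hhmm = acrophase_clock(minutes$minute[ends[sig]] / 4),
    n_minutes = r$lengths[sig]
  )
  structure(list(profile = profile, minutes = minutes, intervals = intervals,
                 alpha = alpha, adjust = adjust),
            class = "profile_24h")
}

#' Agreement between the cosinor and SSA circadian descriptions
#'
#' Pearson and Spearman correlations between the cosinor model curve and
#' the SSA trend + circadian reconstruction of the same subject.
#'
#' @param cosinor_model Numeric cosinor model series, or a `cosinor_fit`
#'   (evaluated on the reconstruction's time grid).
#' @param ssa_model Numeric SSA model series, or the tibble from
#'   [circadian_reconstruction()] (uses `trend + circadian`).
#' @return One-row tibble with `pearson_r`, `spearman_rho`.
#' @export
cosinor_ssa_agreement <- function(cosinor_model, ssa_model) {
  if (is.data.frame(ssa_model)) {
    tm <- ssa_model$time_min
    ssa_model <- ssa_model$trend + ssa_model$circadian
  } else {
    tm <- NULL
  }
  if (inherits(cosinor_model, "cosinor_fit")) {
    cosinor_model <- predict(cosinor_model, time_min = tm)
  }
  stopifnot(length(cosinor_model) == length(ssa_model))
  if (stats::sd(cosinor_model) == 0 || stats::sd(ssa_model) == 0) {
    warning("constant model series: correlation undefined", call. = FALSE)
    return(tibble::tibble(pearson_r = NA_real_, spearman_rho = NA_real_))
  }
  tibble::tibble(
    pearson_r = stats::cor(cosinor_model, ssa_model),
    spearman_rho = stats::cor(cosinor_model, ssa_model, method = "spearman")
  )
}

#' @export
print.profile_24h <- function(x, ...) {
  cat(sprintf("Mean 24h profile: %d significant minutes at alpha = %g (%s)\n",
              sum(x$minutes$significant), x$alpha,
              if (x$adjust == "none") "uncorrected" else x$adjust))
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}
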