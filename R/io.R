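# Plain-CSV input/output: one subject per file (timestamp + counts), cohort
# manifests, and per-subject result tables.

origin_day <- function() as.POSIXct("2000-01-03 00:00:00", tz = "UTC")

#' Read one subject's actigraphy series from CSV
#'
#' Expects a header with columns `timestamp` (ISO-8601) and `counts`.
#' Timestamps must be strictly increasing and equidistant; the epoch is
#' inferred from the first two rows and the clock time of the first sample
#' anchors `time_min` to minutes after the midnight preceding it.
#'
#' @param path CSV file path.
#' @param subject_id,group Labels for the returned series.
#' @return A tibble with columns `subject_id`, `group`, `time_min`, `counts`.
#' @export
read_actigraphy_csv <- function(path, subject_id = "S001", group = "control") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("timestamp", "counts") %in% names(df))) {
    stop("CSV must have columns `timestamp` and `counts`", call. = FALSE)
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) stop("unparseable or missing timestamps", call. = FALSE)
  if (anyNA(df$counts)) stop("missing counts (no imputation is done)", call. = FALSE)
  if (any(df$counts < 0)) stop("negative counts are invalid", call. = FALSE)
  dt <- as.numeric(diff(ts), units = "mins")
  if (length(dt) < 1L) stop("need at least 2 samples", call. = FALSE)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6) {
    stop("timestamps must be strictly increasing and equidistant", call. = FALSE)
  }
  first <- ts[1]
  midnight <- trunc(first, units = "days")
  start_clock <- as.numeric(first - midnight, units = "mins")
  tibble::tibble(
    subject_id = subject_id, group = group,
    time_min = start_clock + (seq_along(ts) - 1) * dt[1],
    counts = as.numeric(df$counts)
  )
}

#' Write one subject's series to CSV (timestamp + counts)
#'
#' Timestamps are synthesised on an arbitrary reference week (midnight of
#' day 1 = 2000-01-03T00:00:00Z shifted by the series' start clock time),
#' so that `read_actigraphy_csv()` recovers `time_min` and `counts` exactly.
#'
#' @param data A single-subject actigraphy tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_actigraphy_csv <- function(data, path) {
  info <- series_info(data)
  ts <- origin_day() + info$time_min * 60
  readr::write_csv(
    tibble::tibble(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   counts = info$x),
    path
  )
  invisible(path)
}

#' Write a cohort as one CSV per subject plus a manifest
#'
#' @param cohort A multi-subject actigraphy tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path (`manifest.csv` in `dir`), invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort |>
    dplyr::distinct(.data$subject_id, .data$group) |>
    dplyr::mutate(file = paste0(.data$subject_id, ".csv"))
  for (i in seq_len(nrow(manifest))) {
    write_actigraphy_csv(
      dplyr::filter(cohort, .data$subject_id == manifest$subject_id[i]),
      file.path(dir, manifest$file[i])
    )
  }
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  invisible(mpath)
}

#' Read a cohort back from a manifest written by [write_cohort_csv()]
#'
#' @param manifest_path Path to `manifest.csv` (columns `subject_id`,
#'   `group`, `file`; files are resolved relative to the manifest).
#' @return A stacked cohort tibble.
#' @export
read_cohort_csv <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("subject_id", "group", "file") %in% names(man)))
  purrr::pmap(man, function(subject_id, group, file, ...) {
    read_actigraphy_csv(file.path(dirname(manifest_path), file),
                        subject_id = subject_id, group = group)
  }) |> dplyr::bind_rows()
}

#' Write a homogeneous list of per-subject records as a CSV table
#'
#' @param records A data frame / tibble (one row per subject) or a list of
#'   named lists with identical keys.
#' @param path Output file; values are written at full double precision.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) {
    if (length(records) > 0) {
      keys <- lapply(records, function(r) sort(names(r)))
      if (length(unique(keys)) > 1L) {
        stop("heterogeneous record keys", call. = FALSE)
      }
    }
    records <- dplyr::bind_rows(lapply(records, tibble::as_tibble))
  }
  readr::write_csv(records, path)
  invisible(path)
}
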