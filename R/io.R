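iso8601 <- function(time) format(time, "%Y-%m-%dT%H:%M:%OS3%z")

parse_iso <- function(x, tz = "UTC") {
  out <- as.POSIXct(x, tz = tz, format = "%Y-%m-%dT%H:%M:%OS%z")
  fallback <- is.na(out)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], tz = tz,
                                tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                               "%Y-%m-%d %H:%M:%OS"))
  }
  out
}

#' Read a raw tri-axial acceleration CSV
#'
#' Expects one sample per row with a time column (ISO-8601 or numeric epoch
#' seconds) and three acceleration columns. Column names are configurable via
#' `col_map` to accommodate device-export layouts; gzip-compressed files are
#' read transparently. Values in milli-g are converted to g with
#' `units = "mg"`.
#'
#' @param path CSV (or CSV.gz) file path.
#' @param col_map named character vector mapping the canonical names
#'   `time`, `x`, `y`, `z` to the file's column names.
#' @param tz time zone for the timestamps.
#' @param units `"g"` (default) or `"mg"` (values divided by 1000 on ingest).
#' @return A tibble `time`, `x`, `y`, `z` with a `sample_rate` attribute.
#' @export
read_raw_csv <- function(path, col_map = c(time = "time", x = "x", y = "y", z = "z"),
                         tz = "UTC", units = c("g", "mg")) {
  units <- match.arg(units)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(col_map), names(df))
  if (length(missing_cols)) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  out <- tibble::tibble(
    time = df[[col_map[["time"]]]],
    x = as.numeric(df[[col_map[["x"]]]]),
    y = as.numeric(df[[col_map[["y"]]]]),
    z = as.numeric(df[[col_map[["z"]]]])
  )
  if (is.numeric(out$time)) {
    out$time <- as.POSIXct(out$time, origin = "1970-01-01", tz = tz)
  } else if (!inherits(out$time, "POSIXct")) {
    out$time <- parse_iso(as.character(out$time), tz)
  } else {
    attr(out$time, "tzone") <- tz
  }
  bad_na <- which(is.na(out$x) | is.na(out$y) | is.na(out$z) | is.na(out$time))
  if (length(bad_na)) {
    abort(paste0("missing values in rows ",
                 paste(head(bad_na, 5), collapse = ", "),
                 if (length(bad_na) > 5) paste0(" (and ", length(bad_na) - 5, " more)"),
                 " of ", path, "."))
  }
  non_mono <- which(diff(as.numeric(out$time)) <= 0)
  if (length(non_mono)) {
    abort(paste0("timestamps not strictly increasing at row(s) ",
                 paste(head(non_mono + 1, 5), collapse = ", "), " of ", path, "."))
  }
  if (units == "mg") {
    out$x <- out$x / 1000; out$y <- out$y / 1000; out$z <- out$z / 1000
  }
  if (nrow(out) >= 2) {
    attr(out, "sample_rate") <- 1 / median(as.numeric(diff(out$time), units = "secs"))
  }
  out
}

#' Write / read an epoch series CSV
#'
#' The interchange format between modules: columns `start_time` (ISO-8601
#' with offset), `epoch_length_s`, `kind`, `value`, one epoch per row (the
#' first three columns are constant metadata). The round trip is lossless.
#'
#' @param x an [epoch_series()].
#' @param path file path (`.gz` for compressed output).
#' @export
write_epoch_csv <- function(x, path) {
  el <- epoch_length_of(x)
  readr::write_csv(tibble::tibble(
    start_time = iso8601(x$time[1]),
    epoch_length_s = el,
    kind = series_kind(x),
    value = x$value
  ), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_epoch_csv
#' @param tz time zone for the reconstructed timestamps.
#' @export
read_epoch_csv <- function(path, tz = "UTC") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  el <- df$epoch_length_s[1]
  t0 <- parse_iso(df$start_time[1], tz)
  epoch_series(t0 + (seq_len(nrow(df)) - 1) * el, df$value,
               kind = df$kind[1], epoch_length = el)
}

#' Write / read a detected-windows CSV
#'
#' Columns: `day_id`, `onset_iso`, `wake_iso`, `duration_min`,
#' `threshold_used_deg`, `algorithm`, `n_blocks_merged` (plus any extra
#' columns such as `low_contrast` / `complete_day`).
#'
#' @param windows a windows tibble.
#' @param path file path.
#' @export
write_windows_csv <- function(windows, path) {
  out <- windows
  out$onset_iso <- iso8601(out$onset)
  out$wake_iso <- iso8601(out$wake)
  out$onset <- NULL
  out$wake <- NULL
  front <- c("day_id", "onset_iso", "wake_iso", "duration_min",
             "threshold_used_deg", "algorithm", "n_blocks_merged")
  out <- out[c(front, setdiff(names(out), front))]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_windows_csv
#' @param tz time zone for the timestamps.
#' @export
read_windows_csv <- function(path, tz = "UTC") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df$onset <- parse_iso(df$onset_iso, tz)
  df$wake <- parse_iso(df$wake_iso, tz)
  df$onset_iso <- NULL
  df$wake_iso <- NULL
  df$day_id <- as.Date(df$day_id)
  front <- c("day_id", "onset", "wake", "duration_min", "threshold_used_deg",
             "algorithm", "n_blocks_merged")
  tibble::as_tibble(df[c(front, setdiff(names(df), front))])
}

#' Read a sleep diary CSV
#'
#' Expects columns `night_date` (date of the night's evening), `onset_hhmm`
#' and `wake_hhmm` (clock times); an optional `id` column. Clock times before
#' noon are resolved to the morning after `night_date`.
#'
#' @param path file path.
#' @param tz time zone.
#' @return A tibble `night_id` (`Date`), `onset`, `wake` (POSIXct), plus `id`
#'   when present.
#' @export
read_diary_csv <- function(path, tz = "UTC") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("night_date", "onset_hhmm", "wake_hhmm")
  if (!all(need %in% names(df))) {
    abort(paste0("diary file needs columns ", paste(need, collapse = ", "), "."))
  }
  night <- as.Date(df$night_date)
  out <- tibble::tibble(
    night_id = night,
    onset = night_time(as.character(df$onset_hhmm), night, tz),
    wake = night_time(as.character(df$wake_hhmm), night, tz)
  )
  if ("id" %in% names(df)) out$id <- df$id
  out
}

#' @rdname read_diary_csv
#' @param diary tibble with `night_id`, `onset`, `wake`.
#' @export
write_diary_csv <- function(diary, path) {
  readr::write_csv(tibble::tibble(
    night_date = diary$night_id,
    onset_hhmm = format(diary$onset, "%H:%M"),
    wake_hhmm = format(diary$wake, "%H:%M")
  ), path, progress = FALSE)
  invisible(path)
}

valid_stages <- c("W", "N1", "N2", "N3", "REM")

#' Write / read a hypnogram CSV
#'
#' Columns `start_time` (ISO-8601 per epoch), `epoch_s`, `stage`
#' (W/N1/N2/N3/REM); one scored epoch per row.
#'
#' @param hypnogram tibble `time`, `stage` with an `epoch_length` attribute.
#' @param path file path.
#' @export
write_hypnogram_csv <- function(hypnogram, path) {
  el <- attr(hypnogram, "epoch_length") %||% epoch_length_of(hypnogram)
  readr::write_csv(tibble::tibble(
    start_time = iso8601(hypnogram$time),
    epoch_s = el,
    stage = hypnogram$stage
  ), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @param tz time zone.
#' @export
read_hypnogram_csv <- function(path, tz = "UTC") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  bad <- setdiff(unique(df$stage), valid_stages)
  if (length(bad)) {
    abort(paste0("unknown sleep stage(s): ", paste(bad, collapse = ", "),
                 " (expected ", paste(valid_stages, collapse = "/"), ")."))
  }
  out <- tibble::tibble(time = parse_iso(df$start_time, tz),
                        stage = as.character(df$stage))
  attr(out, "epoch_length") <- df$epoch_s[1]
  out
}

#' Read a run configuration from YAML
#'
#' The file mirrors [hdcza_params()] under a `params` key, plus `algorithm`
#' (`HDCZA` or `L5PM6`), `input`/`output` paths, `timezone`, `seed` and
#' `log_level`.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cfg$algorithm <- toupper(cfg$algorithm %||% "HDCZA")
  if (!cfg$algorithm %in% c("HDCZA", "L5PM6")) {
    abort(paste0("unknown algorithm '", cfg$algorithm, "' (expected HDCZA or L5PM6)."))
  }
  cfg$timezone <- cfg$timezone %||% "UTC"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$log_level <- cfg$log_level %||% "info"
  cfg$params <- do.call(hdcza_params, cfg$params %||% list())
  if (is.null(cfg$input)) abort("config is missing `input` (raw CSV path).")
  if (!file.exists(cfg$input)) abort(paste0("input file not found: ", cfg$input, "."))
  cfg$output <- cfg$output %||% dirname(cfg$input)
  cfg
}

log_msg <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(...)
  invisible(NULL)
}

#' Run the detection pipeline on a raw recording
#'
#' Reads the raw CSV, computes z-angle, ENMO and the variance statistic,
#' detects SPT windows with the configured algorithm, scores sleep episodes
#' within each window, and writes `windows.csv` and `summary.csv` to the
#' output directory. Parameters, per-day thresholds and the package version
#' are logged for provenance. The pipeline is a pure function of its inputs
#' and configuration, so reruns produce byte-identical outputs.
#'
#' @param cfg a config list from [read_config()] (or of the same shape).
#' @return Invisibly, a list with the detected `windows`, the episode
#'   `summary`, and the written `paths`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  log_msg(cfg, "sleepwin ", as.character(packageVersion("sleepwin")),
          " | algorithm ", cfg$algorithm, " | input ", cfg$input)
  raw <- read_raw_csv(cfg$input, tz = cfg$timezone)
  z <- compute_z_angle(raw)
  if (cfg$algorithm == "HDCZA") {
    vs <- rolling_var_statistic(z)
    windows <- detect_spt_multiday(vs, cfg$params)
  } else {
    enmo <- compute_enmo(raw)
    days <- sort(unique(noon_day_id(z$time)))
    windows <- purrr::map_dfr(days, function(d) {
      w <- tryCatch(detect_spt_l5(enmo, z, d), error = function(e) empty_windows())
      if (nrow(w)) w$day_id <- d
      w
    })
  }
  for (i in seq_len(nrow(windows))) {
    log_msg(cfg, "  day ", as.character(windows$day_id[i]), ": threshold ",
            format(windows$threshold_used_deg[i], digits = 3), " deg, window ",
            format(windows$duration_min[i], digits = 4), " min")
  }
  sibs <- detect_sib(z)
  detected <- windows[!is.na(windows$onset), , drop = FALSE]
  summary <- purrr::map_dfr(seq_len(nrow(detected)), function(i) {
    summarize_sleep(detected[i, , drop = FALSE], sibs)
  })
  if (!dir.exists(cfg$output)) dir.create(cfg$output, recursive = TRUE)
  paths <- list(windows = file.path(cfg$output, "windows.csv"),
                summary = file.path(cfg$output, "summary.csv"))
  write_windows_csv(windows, paths$windows)
  readr::write_csv(
    dplyr::mutate(summary, onset = iso8601(.data$onset),
                  wake = iso8601(.data$wake)),
    paths$summary, progress = FALSE)
  log_msg(cfg, "  wrote ", paths$windows, " and ", paths$summary)
  invisible(list(windows = windows, summary = summary, paths = paths))
}

#' Write a comparison report as JSON
#'
#' Serialises the aggregate ([glance()]) and per-night/per-stage ([tidy()])
#' tables of a comparison object to one JSON file.
#'
#' @param report a `diary_comparison` or `psg_comparison` object.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(summary = glance(report), detail = tidy(report)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
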