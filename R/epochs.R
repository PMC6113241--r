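#' Construct an epoch series
#'
#' An epoch series is a tibble with a `time` column (POSIXct left edge of each
#' half-open epoch interval `[t, t + epoch_length)`) and a `value` column, plus
#' `epoch_length` (seconds) and `kind` attributes. All detection functions
#' consume and produce epoch series; when the attributes have been stripped
#' (e.g. by dplyr verbs) the epoch length is re-inferred from the time stamps.
#'
#' @param time POSIXct vector of epoch left edges, strictly increasing.
#' @param value numeric vector, same length as `time`. Degrees for kind
#'   `"z_angle"` and `"var_stat"`, gravitational units (g) for `"enmo"`.
#' @param kind one of `"z_angle"`, `"enmo"`, `"var_stat"`.
#' @param epoch_length epoch duration in seconds.
#' @return A tibble with columns `time`, `value` and attributes
#'   `epoch_length`, `kind`.
#' @export
epoch_series <- function(time, value, kind = c("z_angle", "enmo", "var_stat"),
                         epoch_length = 5) {
  kind <- match.arg(kind)
  if (length(time) != length(value)) {
    abort("`time` and `value` must have the same length.")
  }
  if (kind == "z_angle" && length(value) &&
      (min(value) < -90 - 1e-9 || max(value) > 90 + 1e-9)) {
    abort("z-angle values must lie in [-90, 90] degrees.")
  }
  if (kind == "enmo" && length(value) && min(value) < 0) {
    abort("ENMO values must be non-negative.")
  }
  out <- tibble::tibble(time = time, value = value)
  attr(out, "epoch_length") <- as.numeric(epoch_length)
  attr(out, "kind") <- kind
  out
}

#' Epoch length of a series, in seconds
#'
#' Reads the `epoch_length` attribute when present, otherwise infers it as the
#' median spacing of the time stamps.
#'
#' @param x an epoch series (tibble with a `time` column).
#' @return epoch duration in seconds.
#' @export
epoch_length_of <- function(x) {
  el <- attr(x, "epoch_length")
  if (!is.null(el)) return(as.numeric(el))
  if (nrow(x) >= 2) {
    return(median(as.numeric(diff(x$time), units = "secs")))
  }
  abort("cannot infer the epoch length of a single-epoch series; supply an `epoch_length` attribute.")
}

series_kind <- function(x) attr(x, "kind") %||% NA_character_

tz_of <- function(time) {
  tz <- attr(time, "tzone")
  if (is.null(tz) || identical(tz, "")) "UTC" else tz[[1]]
}

clock_to_seconds <- function(clock) {
  parts <- strsplit(clock, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2 || anyNA(suppressWarnings(as.numeric(parts)))) {
    abort(paste0("cannot parse clock time '", clock, "' (expected HH:MM or HH:MM:SS)."))
  }
  s <- as.numeric(parts[1]) * 3600 + as.numeric(parts[2]) * 60
  if (length(parts) >= 3) s <- s + as.numeric(parts[3])
  s
}

#' Assign times to noon-to-noon analysis days
#'
#' The analysis unit is the 24-hour day anchored at local noon, so a night is
#' never split across two days. Times are labelled with the calendar date on
#' which the day starts; local clock labels are used, so daylight-saving
#' transitions yield 23- or 25-hour days rather than shifted anchors.
#'
#' @param time POSIXct vector.
#' @param anchor clock time at which a day starts, default `"12:00"`.
#' @return A `Date` vector: the date of the anchoring noon.
#' @export
noon_day_id <- function(time, anchor = "12:00") {
  anchor_s <- clock_to_seconds(anchor)
  tz <- tz_of(time)
  if (tz %in% c("UTC", "GMT")) {
    as.Date(floor((as.numeric(time) - anchor_s) / 86400), origin = "1970-01-01")
  } else {
    lt <- as.POSIXlt(time, tz = tz)
    secs <- lt$hour * 3600 + lt$min * 60 + lt$sec
    as.Date(lt) - (secs < anchor_s)
  }
}

#' Resolve a diary clock time onto the noon-noon axis of a night
#'
#' Clock times before the anchor (noon) belong to the morning after
#' `night_date`; times at or after it belong to the evening of `night_date`
#' itself, so e.g. 23:50 and 00:10 of one night are 20 minutes apart.
#'
#' @param clock character clock time `"HH:MM"` (or `"HH:MM:SS"`).
#' @param night_date `Date` labelling the night (the date of its noon anchor).
#' @param tz time zone of the recording.
#' @param anchor clock time anchoring the day, default `"12:00"`.
#' @return POSIXct time.
#' @export
night_time <- function(clock, night_date, tz = "UTC", anchor = "12:00") {
  anchor_s <- clock_to_seconds(anchor)
  s <- vapply(clock, clock_to_seconds, numeric(1), USE.NAMES = FALSE)
  base <- as.POSIXct(paste(night_date, "00:00:00"), tz = tz)
  base + s + ifelse(s < anchor_s, 86400, 0)
}

# subset an epoch series to one noon-noon day, preserving attributes
slice_day <- function(x, day, anchor = "12:00") {
  keep <- noon_day_id(x$time, anchor) == day
  out <- x[keep, , drop = FALSE]
  attr(out, "epoch_length") <- attr(x, "epoch_length")
  attr(out, "kind") <- attr(x, "kind")
  out
}
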