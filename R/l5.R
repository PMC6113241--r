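#' Locate the least active five hours (L5) of a day
#'
#' Slides a contiguous 5-hour window across the day's ENMO epochs at epoch
#' resolution and returns the window with the lowest mean ENMO; ties go to
#' the earliest window. L5 localises the nocturnal rest period on the
#' activity axis and anchors the naive reference detector.
#'
#' @param enmo an [epoch_series()] of kind `"enmo"`.
#' @param day `Date` of the noon-noon day, or `NULL` to use the whole series.
#' @param hours window length in hours (5 for L5).
#' @return A one-row tibble with `start`, `end` (POSIXct) and `mean_enmo`.
#' @export
find_l5 <- function(enmo, day = NULL, hours = 5) {
  x <- if (is.null(day)) enmo else slice_day(enmo, day)
  el <- epoch_length_of(enmo)
  w <- as.integer(round(hours * 3600 / el))
  if (nrow(x) < w) {
    abort(paste0("need at least ", hours, " hours of epochs (", w,
                 ") to locate L", hours, "; got ", nrow(x), "."))
  }
  n_start <- nrow(x) - w + 1L
  # windowed sums via sum() per slice: identical fp result for identical
  # windows, so ties on constant series resolve to the earliest start
  means <- vapply(seq_len(n_start), function(i) sum(x$value[i:(i + w - 1L)]),
                  numeric(1)) / w
  i <- which.min(means)
  tibble::tibble(start = x$time[i], end = x$time[i] + w * el,
                 mean_enmo = means[i])
}

#' Detect sustained inactivity bouts from the z-angle
#'
#' A sustained inactivity bout (SIB) is a maximal period during which the arm
#' elevation angle never changes by more than `angle_tol` degrees between
#' successive epochs, kept when it lasts strictly longer than `min_dur`
#' minutes. SIBs proxy sleep episodes; scanning consecutive-epoch changes
#' operationalises "absence of change" on the epoch grid.
#'
#' @param z an [epoch_series()] of kind `"z_angle"`.
#' @param angle_tol tolerated consecutive-epoch angle change, degrees.
#' @param min_dur minimum bout duration, minutes (strict).
#' @return A tibble of non-overlapping, ordered bouts with columns `start`,
#'   `end` (POSIXct, half-open) and `duration_min`.
#' @export
detect_sib <- function(z, angle_tol = 5, min_dur = 5) {
  if (nrow(z) == 0) abort("empty z-angle series.")
  el <- epoch_length_of(z)
  empty <- tibble::tibble(start = z$time[0], end = z$time[0],
                          duration_min = numeric(0))
  if (nrow(z) < 2) return(empty)
  ok <- abs(diff(z$value)) <= angle_tol
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i0 <- starts[r$values]          # first diff of the run -> first epoch
  i1 <- ends[r$values] + 1L       # last diff -> its right epoch
  dur <- (i1 - i0 + 1L) * el / 60
  keep <- dur > min_dur
  if (!any(keep)) return(empty)
  tibble::tibble(start = z$time[i0[keep]], end = z$time[i1[keep]] + el,
                 duration_min = dur[keep])
}

#' Detect the SPT window with the naive L5+/-6 reference algorithm
#'
#' Takes the 12-hour window centred on L5 (the least active five hours by
#' ENMO) and defines the SPT window from the start of the first to the end of
#' the last sustained inactivity bout inside it. Requires more than 12 hours
#' of data, so it is unsuitable for in-bed-only recordings; a 12-hour window
#' extending past the recording edge is truncated with a warning.
#'
#' @param enmo an [epoch_series()] of kind `"enmo"`.
#' @param z an [epoch_series()] of kind `"z_angle"` on the same grid.
#' @param day `Date` of the noon-noon day, or `NULL` for the whole series.
#' @param angle_tol,min_dur passed to [detect_sib()].
#' @return A one-row windows tibble (`algorithm = "L5PM6"`), or a zero-row
#'   tibble when no bout falls inside the 12-hour window.
#' @export
detect_spt_l5 <- function(enmo, z, day = NULL, angle_tol = 5, min_dur = 5) {
  el <- epoch_length_of(z)
  coverage_h <- (nrow(z) * el) / 3600
  if (coverage_h <= 12) {
    abort(paste0("the L5+/-6 reference needs more than 12 hours of data; got ",
                 round(coverage_h, 2), " hours."))
  }
  l5 <- find_l5(enmo, day)
  centre <- l5$start + as.numeric(l5$end - l5$start, units = "secs") / 2
  win_start <- centre - 6 * 3600
  win_end <- centre + 6 * 3600
  rec_start <- min(z$time)
  rec_end <- max(z$time) + el
  if (win_start < rec_start || win_end > rec_end) {
    warn("12-hour search window truncated at the recording edge.")
    win_start <- max(win_start, rec_start)
    win_end <- min(win_end, rec_end)
  }
  sibs <- detect_sib(z, angle_tol, min_dur)
  inside <- sibs$end > win_start & sibs$start < win_end
  if (!any(inside)) return(empty_windows(tz_of(z$time)))
  s <- sibs[inside, , drop = FALSE]
  onset <- max(min(s$start), win_start)
  wake <- min(max(s$end), win_end)
  tibble::tibble(
    day_id = noon_day_id(centre),
    onset = onset, wake = wake,
    duration_min = as.numeric(wake - onset, units = "mins"),
    threshold_used_deg = NA_real_,
    algorithm = "L5PM6",
    n_blocks_merged = as.integer(nrow(s)),
    low_contrast = NA
  )
}
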