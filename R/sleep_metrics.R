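#' Score sleep episodes within an SPT window
#'
#' Sleep episodes are the sustained inactivity bouts intersected with the
#' detected sleep period time window; bouts straddling a window boundary are
#' clipped, not dropped, so durations are conserved. Sleep efficiency is the
#' percentage of the window spent asleep; wake after sleep onset (WASO) is
#' the remainder, so `total_sleep_min + waso_min` equals the window duration
#' exactly.
#'
#' @param spt a one-row windows tibble ([detect_spt()] / [detect_spt_l5()]).
#' @param sibs a bouts tibble from [detect_sib()].
#' @return A one-row tibble: `day_id`, `algorithm`, `onset`, `wake`,
#'   `duration_min`, `n_episodes`, `total_sleep_min`, `efficiency_pct`,
#'   `waso_min`.
#' @export
#' @examples
#' t0 <- as.POSIXct("2024-03-04 23:00:00", tz = "UTC")
#' spt <- tibble::tibble(day_id = as.Date("2024-03-04"), onset = t0,
#'                       wake = t0 + 8 * 3600, duration_min = 480,
#'                       algorithm = "HDCZA")
#' sibs <- tibble::tibble(start = t0, end = t0 + 4 * 3600, duration_min = 240)
#' summarize_sleep(spt, sibs)$efficiency_pct # 50
summarize_sleep <- function(spt, sibs) {
  if (nrow(spt) != 1) abort("`spt` must be a one-row window tibble.")
  if (is.na(spt$onset) || is.na(spt$wake) || spt$onset >= spt$wake) {
    abort("`spt` must have onset < wake.")
  }
  d_secs <- as.numeric(spt$wake - spt$onset, units = "secs")
  if (nrow(sibs)) {
    start <- pmax(sibs$start, spt$onset)
    end <- pmin(sibs$end, spt$wake)
    keep <- end > start
    start <- start[keep]; end <- end[keep]
  } else {
    start <- end <- spt$onset[0]
  }
  t_secs <- sum(as.numeric(end - start, units = "secs"))
  total <- t_secs / 60
  waso <- (d_secs - t_secs) / 60
  tibble::tibble(
    day_id = if ("day_id" %in% names(spt)) spt$day_id else noon_day_id(spt$onset),
    algorithm = if ("algorithm" %in% names(spt)) spt$algorithm else NA_character_,
    onset = spt$onset, wake = spt$wake,
    # assembled as sleep + waso so the decomposition is exact by construction
    duration_min = total + waso,
    n_episodes = length(start),
    total_sleep_min = total,
    efficiency_pct = 100 * t_secs / d_secs,
    waso_min = waso
  )
}

#' Episodes of an SPT window, clipped to its span
#'
#' The bout-level counterpart of [summarize_sleep()]: the sustained
#' inactivity bouts intersected with the window, one row per (clipped) bout.
#'
#' @inheritParams summarize_sleep
#' @return A bouts tibble (`start`, `end`, `duration_min`).
#' @export
sleep_episodes <- function(spt, sibs) {
  if (nrow(spt) != 1) abort("`spt` must be a one-row window tibble.")
  if (!nrow(sibs)) return(sibs)
  start <- pmax(sibs$start, spt$onset)
  end <- pmin(sibs$end, spt$wake)
  keep <- end > start
  tibble::tibble(start = start[keep], end = end[keep],
                 duration_min = as.numeric(end[keep] - start[keep], units = "mins"))
}
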