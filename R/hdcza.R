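#' Parameters of the heuristic z-angle window detector
#'
#' Bundles the tunable settings of the adaptive-threshold detector. The
#' defaults reproduce the published configuration: the threshold is the 10th
#' percentile of the day's variance statistic multiplied by 15; candidate
#' blocks must last longer than 30 minutes; gaps shorter than 60 minutes
#' between blocks are absorbed; days run from local noon to noon.
#'
#' `clamp` constrains the derived threshold to a fixed range in degrees. For
#' in-bed-only (polysomnography-style) recordings, which lack a full day of
#' movement to derive the threshold from, use `clamp = c(0.13, 0.50)` — the
#' 2.5th and 97.5th percentiles of thresholds observed in daily-life
#' recordings.
#'
#' @param percentile fraction in (0, 1); quantile of the day's variance
#'   statistic from which the threshold is derived.
#' @param multiplier positive factor applied to that quantile.
#' @param min_block minimum block duration, minutes; blocks must be strictly
#'   longer to be kept (see `strict`).
#' @param max_gap gaps strictly shorter than this (minutes) are counted
#'   towards the surrounding blocks.
#' @param day_anchor clock time at which an analysis day starts.
#' @param clamp optional `c(lo, hi)` threshold bounds in degrees, or `NULL`.
#' @param percentile_type `"linear"` for interpolated quantiles (default) or
#'   `"nearest"` for the nearest-rank (inverse empirical CDF) definition.
#' @param strict when `TRUE` (default) the boundary comparisons are
#'   `value < threshold`, `duration > min_block`, `gap < max_gap`; when
#'   `FALSE` they become `<=`, `>=`, `<=`.
#' @return An object of class `hdcza_params`.
#' @export
hdcza_params <- function(percentile = 0.10, multiplier = 15,
                         min_block = 30, max_gap = 60,
                         day_anchor = "12:00", clamp = NULL,
                         percentile_type = c("linear", "nearest"),
                         strict = TRUE) {
  percentile_type <- match.arg(percentile_type)
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 1) {
    abort("`percentile` must lie strictly between 0 and 1.")
  }
  if (!is.numeric(multiplier) || multiplier <= 0) abort("`multiplier` must be positive.")
  if (!is.numeric(min_block) || min_block <= 0) abort("`min_block` must be positive.")
  if (!is.numeric(max_gap) || max_gap < 0) abort("`max_gap` must be non-negative.")
  clock_to_seconds(day_anchor) # validates
  if (!is.null(clamp)) {
    if (length(clamp) != 2 || !is.numeric(clamp) || clamp[1] >= clamp[2]) {
      abort("`clamp` must be c(lo, hi) with lo < hi.")
    }
  }
  structure(
    list(percentile = percentile, multiplier = multiplier,
         min_block = min_block, max_gap = max_gap, day_anchor = day_anchor,
         clamp = clamp, percentile_type = percentile_type,
         strict = isTRUE(strict)),
    class = "hdcza_params"
  )
}

#' @export
print.hdcza_params <- function(x, ...) {
  cat("HDCZA parameters: threshold = P", x$percentile * 100, " x ",
      x$multiplier, ", blocks > ", x$min_block, " min, gaps < ", x$max_gap,
      " min, day anchor ", x$day_anchor,
      if (!is.null(x$clamp)) paste0(", clamp [", x$clamp[1], ", ", x$clamp[2], "] deg"),
      "\n", sep = "")
  invisible(x)
}

as_hdcza_params <- function(x) {
  if (inherits(x, "hdcza_params")) return(x)
  do.call(hdcza_params, x)
}

#' Derive the adaptive detection threshold for one day
#'
#' The threshold is `quantile(var_stat within day, percentile) * multiplier`,
#' optionally clamped into `params$clamp`. It adapts to the individual's
#' z-angle change distribution: quiet sleepers get lower thresholds.
#'
#' @param var_stat an [epoch_series()] of kind `"var_stat"`.
#' @param day `Date` of the noon-noon day (see [noon_day_id()]), or `NULL` to
#'   use every epoch in `var_stat` (appropriate for recordings shorter than a
#'   day, e.g. overnight polysomnography).
#' @param params an [hdcza_params()] object.
#' @return Threshold in degrees (length-1 numeric).
#' @export
derive_threshold <- function(var_stat, day = NULL, params = hdcza_params()) {
  params <- as_hdcza_params(params)
  x <- if (is.null(day)) var_stat else slice_day(var_stat, day, params$day_anchor)
  if (nrow(x) == 0) {
    abort(paste0("no variance-statistic epochs fall in day ", day, "."))
  }
  type <- if (params$percentile_type == "linear") 7 else 1
  thr <- unname(quantile(x$value, params$percentile, type = type, names = FALSE)) *
    params$multiplier
  if (!is.null(params$clamp)) {
    thr <- min(max(thr, params$clamp[1]), params$clamp[2])
  }
  thr
}

#' Detect sustained below-threshold blocks
#'
#' Finds maximal runs of epochs whose variance statistic lies below the
#' threshold (strictly, by default) and keeps those lasting longer than
#' `params$min_block` minutes.
#'
#' @param var_stat an [epoch_series()] of kind `"var_stat"` (already
#'   restricted to the day of interest, if relevant).
#' @param threshold degrees.
#' @param params an [hdcza_params()] object.
#' @return A tibble with columns `start`, `end` (POSIXct, half-open
#'   interval), `duration_min`, `n_blocks` (always 1 here; gap absorption
#'   accumulates it).
#' @export
detect_blocks <- function(var_stat, threshold, params = hdcza_params()) {
  params <- as_hdcza_params(params)
  if (!is.numeric(threshold) || threshold <= 0) abort("`threshold` must be positive.")
  el <- epoch_length_of(var_stat)
  below <- if (params$strict) var_stat$value < threshold else var_stat$value <= threshold
  empty <- tibble::tibble(start = var_stat$time[0], end = var_stat$time[0],
                          duration_min = numeric(0), n_blocks = integer(0))
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i0 <- starts[r$values]
  i1 <- ends[r$values]
  dur <- (i1 - i0 + 1L) * el / 60
  keep <- if (params$strict) dur > params$min_block else dur >= params$min_block
  if (!any(keep)) return(empty)
  tibble::tibble(
    start = var_stat$time[i0[keep]],
    end = var_stat$time[i1[keep]] + el,
    duration_min = dur[keep],
    n_blocks = 1L
  )
}

#' Absorb short gaps between detected blocks
#'
#' A single left-to-right pass merges adjacent blocks whose separating gap is
#' shorter than `params$max_gap` minutes, counting the gap towards the merged
#' block. Merging is transitive: chains of blocks separated by short gaps
#' collapse into one, so all gaps in the result are at least `max_gap`.
#'
#' @param blocks tibble as returned by [detect_blocks()], ordered and
#'   non-overlapping.
#' @param params an [hdcza_params()] object.
#' @return A tibble with the same columns; `n_blocks` counts the original
#'   blocks merged into each row.
#' @export
absorb_gaps <- function(blocks, params = hdcza_params()) {
  params <- as_hdcza_params(params)
  n <- nrow(blocks)
  if (n <= 1) return(blocks)
  start <- blocks$start
  end <- blocks$end
  nb <- blocks$n_blocks %||% rep(1L, n)
  out_start <- start[1]; out_end <- end[1]; out_nb <- nb[1]
  for (i in 2:n) {
    gap <- as.numeric(start[i] - out_end[length(out_end)], units = "mins")
    merge <- if (params$strict) gap < params$max_gap else gap <= params$max_gap
    j <- length(out_end)
    if (merge) {
      out_end[j] <- end[i]
      out_nb[j] <- out_nb[j] + nb[i]
    } else {
      out_start <- c(out_start, start[i])
      out_end <- c(out_end, end[i])
      out_nb <- c(out_nb, nb[i])
    }
  }
  tibble::tibble(
    start = out_start, end = out_end,
    duration_min = as.numeric(out_end - out_start, units = "mins"),
    n_blocks = as.integer(out_nb)
  )
}

empty_windows <- function(tz = "UTC") {
  t0 <- as.POSIXct(character(0), tz = tz)
  tibble::tibble(
    day_id = as.Date(character(0)), onset = t0, wake = t0,
    duration_min = numeric(0), threshold_used_deg = numeric(0),
    algorithm = character(0), n_blocks_merged = integer(0),
    low_contrast = logical(0)
  )
}

#' Detect the sleep period time window for one day
#'
#' Composes the per-day pipeline: derive the adaptive threshold, detect
#' sustained below-threshold blocks, absorb short gaps, and select the
#' longest resulting block as the SPT window (ties broken by earliest onset).
#' The window runs from sleep onset (start of the block) to waking time (end
#' of the block).
#'
#' The `low_contrast` flag marks windows whose unclamped threshold exceeded
#' 0.5 degrees — outside the range observed in daily-life recordings — which
#' happens when day and night show similarly little z-angle change and the
#' detected window is therefore unreliable.
#'
#' @param var_stat an [epoch_series()] of kind `"var_stat"`.
#' @param day `Date` of the noon-noon day, or `NULL` to treat the whole
#'   series as one span (short recordings).
#' @param params an [hdcza_params()] object.
#' @return A one-row tibble (`day_id`, `onset`, `wake`, `duration_min`,
#'   `threshold_used_deg`, `algorithm`, `n_blocks_merged`, `low_contrast`),
#'   or a zero-row tibble when no block survives.
#' @export
detect_spt <- function(var_stat, day = NULL, params = hdcza_params()) {
  params <- as_hdcza_params(params)
  x <- if (is.null(day)) var_stat else slice_day(var_stat, day, params$day_anchor)
  thr <- derive_threshold(x, NULL, params)
  blocks <- absorb_gaps(detect_blocks(x, thr, params), params)
  if (is.null(day)) day <- noon_day_id(x$time[1], params$day_anchor)
  if (nrow(blocks) == 0) return(empty_windows(tz_of(var_stat$time)))
  best <- which.max(blocks$duration_min) # first maximum: earliest wins ties
  tibble::tibble(
    day_id = day,
    onset = blocks$start[best],
    wake = blocks$end[best],
    duration_min = blocks$duration_min[best],
    threshold_used_deg = thr,
    algorithm = "HDCZA",
    n_blocks_merged = blocks$n_blocks[best],
    low_contrast = thr > 0.5
  )
}

#' Detect SPT windows over a multi-day recording
#'
#' Partitions the variance statistic into noon-noon days and applies
#' [detect_spt()] to each. Every day present in the recording yields one row;
#' days where no block survives get `NA` onset/wake. Days covering less than
#' 23 hours of epochs (typically the first and last, partial, days) are
#' flagged with `complete_day = FALSE`.
#'
#' @inheritParams detect_spt
#' @return A tibble with one row per day (columns of [detect_spt()] plus
#'   `complete_day`); zero rows for an empty series.
#' @export
detect_spt_multiday <- function(var_stat, params = hdcza_params()) {
  params <- as_hdcza_params(params)
  if (nrow(var_stat) == 0) {
    out <- empty_windows()
    out$complete_day <- logical(0)
    return(out)
  }
  el <- epoch_length_of(var_stat)
  ids <- noon_day_id(var_stat$time, params$day_anchor)
  days <- sort(unique(ids))
  purrr::map_dfr(days, function(d) {
    x <- var_stat[ids == d, , drop = FALSE]
    attr(x, "epoch_length") <- el
    attr(x, "kind") <- attr(var_stat, "kind")
    w <- detect_spt(x, NULL, params)
    if (nrow(w) == 0) {
      w <- tibble::tibble(
        day_id = d, onset = as.POSIXct(NA, tz = tz_of(var_stat$time)),
        wake = as.POSIXct(NA, tz = tz_of(var_stat$time)),
        duration_min = NA_real_,
        threshold_used_deg = derive_threshold(x, NULL, params),
        algorithm = "HDCZA", n_blocks_merged = NA_integer_,
        low_contrast = NA
      )
    } else {
      w$day_id <- d
    }
    w$complete_day <- nrow(x) * el >= 23 * 3600
    w
  })
}
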