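#' @noRd
#' Centered rolling median with truncated (shrinking) edge windows.
#' The window at position i is x[max(1, i-h) : min(n, i+h)] with h = (k-1)/2;
#' interior positions are delegated to stats::runmed, edges computed directly.
rolling_median <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n == 1) return(x)
  if (k %% 2 == 0) k <- k - 1
  h <- (k - 1) %/% 2
  if (n <= k) {
    return(vapply(seq_len(n), function(i) {
      median(x[max(1, i - h):min(n, i + h)])
    }, numeric(1)))
  }
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  for (i in seq_len(h)) {
    out[i] <- median(x[1:(i + h)])
    out[n - i + 1] <- median(x[(n - i + 1 - h):n])
  }
  out
}

# nearest odd window size for a span in seconds at a given sample rate
odd_window <- function(seconds, rate) {
  k <- max(1L, as.integer(round(seconds * rate)))
  if (k %% 2L == 0L) k - 1L else k
}

infer_sample_rate <- function(raw) {
  sr <- attr(raw, "sample_rate")
  if (!is.null(sr)) return(as.numeric(sr))
  if (nrow(raw) < 2) {
    abort("cannot infer the sample rate of a recording with fewer than 2 samples.")
  }
  1 / median(as.numeric(diff(raw$time), units = "secs"))
}

check_raw <- function(raw) {
  if (!all(c("time", "x", "y", "z") %in% names(raw))) {
    abort("a raw recording needs columns time, x, y, z.")
  }
  if (nrow(raw) == 0) abort("empty recording.")
  invisible(raw)
}

# mean of `values` per 5-s (or epoch_length) epoch; partial trailing epoch dropped
epoch_means <- function(values, time0, rate, epoch_length) {
  n <- length(values)
  n_ep <- floor(n / (rate * epoch_length))
  if (n_ep < 1) {
    abort("recording shorter than one epoch; nothing to aggregate.")
  }
  idx <- floor((seq_len(n) - 1) / (rate * epoch_length))
  keep <- idx < n_ep
  idx <- idx[keep]
  v <- values[keep]
  sums <- rowsum(v, idx, reorder = TRUE)
  counts <- tabulate(idx + 1L, nbins = n_ep)
  list(value = as.numeric(sums) / counts,
       time = time0 + (seq_len(n_ep) - 1) * epoch_length)
}

#' Estimate the arm z-angle per 5-second epoch
#'
#' Computes the angle of the forearm's dorsal-ventral axis relative to the
#' horizontal plane from raw tri-axial acceleration. Each axis is first
#' smoothed with a centered rolling median over `median_window` seconds
#' (stride one sample, windows truncated at the recording edges), then
#'
#' \deqn{angle_z = \arctan\!\big(a_z / \sqrt{a_x^2 + a_y^2}\big) \cdot 180/\pi}
#'
#' and the instantaneous angles are averaged per `epoch_length`-second epoch.
#' The square root in the denominator makes the expression a proper elevation
#' angle of the gravity vector. When the horizontal components vanish the
#' angle is defined as +/-90 degrees by the sign of `a_z` (0 when all three
#' components are zero). A partial trailing epoch is dropped.
#'
#' @param raw tibble with columns `time` (POSIXct), `x`, `y`, `z` in g units.
#' @param median_window per-axis rolling median span, seconds.
#' @param epoch_length epoch duration, seconds.
#' @return An [epoch_series()] of kind `"z_angle"`, one value per epoch,
#'   length `floor(duration / epoch_length)`.
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   time = as.POSIXct("2024-03-04 12:00:00", tz = "UTC") + seq(0, 9.9, 0.1),
#'   x = 0, y = 0, z = 1
#' )
#' compute_z_angle(raw)$value # 90 90
compute_z_angle <- function(raw, median_window = 5, epoch_length = 5) {
  check_raw(raw)
  if (median_window <= 0) abort("`median_window` must be positive.")
  rate <- infer_sample_rate(raw)
  k <- odd_window(median_window, rate)
  xm <- rolling_median(raw$x, k)
  ym <- rolling_median(raw$y, k)
  zm <- rolling_median(raw$z, k)
  horiz <- sqrt(xm^2 + ym^2)
  ang <- atan(zm / horiz) * 180 / pi
  degen <- horiz == 0
  if (any(degen)) ang[degen] <- sign(zm[degen]) * 90
  ep <- epoch_means(ang, raw$time[1], rate, epoch_length)
  epoch_series(ep$time, ep$value, "z_angle", epoch_length)
}

#' Compute ENMO per epoch
#'
#' Euclidean Norm Minus One with negative values rounded to zero:
#' `max(sqrt(x^2 + y^2 + z^2) - 1, 0)` per sample, in g, averaged per epoch.
#' A stationary device reads 1 g of gravity and hence ENMO 0.
#'
#' @inheritParams compute_z_angle
#' @return An [epoch_series()] of kind `"enmo"`.
#' @export
compute_enmo <- function(raw, epoch_length = 5) {
  check_raw(raw)
  rate <- infer_sample_rate(raw)
  enmo <- pmax(sqrt(raw$x^2 + raw$y^2 + raw$z^2) - 1, 0)
  ep <- epoch_means(enmo, raw$time[1], rate, epoch_length)
  epoch_series(ep$time, ep$value, "enmo", epoch_length)
}

#' Rolling variance statistic of the z-angle
#'
#' The change statistic the window detector thresholds: absolute differences
#' between successive epoch z-angle values, smoothed with a centered rolling
#' median over a `window`-minute span. The median window holds
#' `window * 60 / epoch_length` difference values, reduced by one when that
#' count is even so the window is symmetric; edge windows shrink to the
#' available values. Because `|(-a) - (-b)| = |a - b|`, the statistic is
#' invariant to the orientation of the device on the wrist.
#'
#' The output has one value per difference (length `nrow(z) - 1`) and is
#' assigned to the epoch grid of the left element of each difference, so that
#' threshold comparisons stay on the same grid as the z-angle itself.
#'
#' @param z an [epoch_series()] of kind `"z_angle"`.
#' @param window rolling median span, minutes.
#' @return An [epoch_series()] of kind `"var_stat"`, in degrees.
#' @export
rolling_var_statistic <- function(z, window = 5) {
  el <- epoch_length_of(z)
  m <- as.integer(round(window * 60 / el))
  need <- m + 1L
  if (nrow(z) < need) {
    abort(paste0("series too short for a ", window, "-minute rolling median: ",
                 "need at least ", need, " epochs, got ", nrow(z), "."))
  }
  if (m %% 2L == 0L) m <- m - 1L
  d <- abs(diff(z$value))
  v <- rolling_median(d, m)
  epoch_series(z$time[seq_along(v)], v, "var_stat", el)
}
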