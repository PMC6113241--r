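# Small in-code fixtures shared across test files.

t_utc <- function(s, date = "2024-03-04") {
  as.POSIXct(paste(date, s), tz = "UTC")
}

# raw recording with constant acceleration triple
const_raw <- function(x, y, z, duration_s = 10, rate = 10,
                      start = t_utc("12:00:00")) {
  n <- duration_s * rate
  out <- tibble::tibble(time = start + (seq_len(n) - 1) / rate,
                        x = rep(x, n), y = rep(y, n), z = rep(z, n))
  attr(out, "sample_rate") <- rate
  out
}

# epoch series from plain values on a 5-s grid starting at local noon
es <- function(values, kind = "var_stat", el = 5, start = t_utc("12:00:00")) {
  epoch_series(start + (seq_along(values) - 1) * el, values, kind, el)
}

# var_stat vector for a day: high-variance day, low-variance stretches where
# `quiet` lists (start_hr, end_hr) pairs on the noon-noon axis
day_var_values <- function(quiet, el = 5, low = 0.02, high = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- 86400 / el
    t_hr <- (seq_len(n) - 1) * el / 3600
    v <- abs(rnorm(n, high, 0.3))
    for (q in quiet) {
      sel <- t_hr >= q[1] & t_hr < q[2]
      v[sel] <- abs(rnorm(sum(sel), low, 0.005))
    }
    v
  })
}

one_window <- function(onset, wake, day_id = as.Date("2024-03-04"),
                       algorithm = "HDCZA") {
  tibble::tibble(day_id = day_id, onset = onset, wake = wake,
                 duration_min = as.numeric(wake - onset, units = "mins"),
                 threshold_used_deg = 0.3, algorithm = algorithm,
                 n_blocks_merged = 1L, low_contrast = FALSE)
}

bout <- function(start, end) {
  tibble::tibble(start = start, end = end,
                 duration_min = as.numeric(end - start, units = "mins"))
}

# reflect an unbounded trajectory into the valid angle range
fold_angle_t <- function(x, lim = 85) lim - abs((2 * lim) - ((x + lim) %% (4 * lim)))
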