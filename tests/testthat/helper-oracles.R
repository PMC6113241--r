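# Naive loop-based reference implementations. These stay deliberately
# unvectorised and independent of the package internals: explicit loops,
# sort-based medians, fixed-point merging. They define the expected
# semantics that the fast implementations are checked against.

oracle_rolling_median <- function(x, k) {
  if (k %% 2 == 0) k <- k - 1
  h <- (k - 1) %/% 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    w <- sort(x[lo:hi])
    m <- length(w)
    out[i] <- if (m %% 2 == 1) w[(m + 1) / 2] else (w[m / 2] + w[m / 2 + 1]) / 2
  }
  out
}

# raw (n x 3 matrix) -> per-epoch z-angle, all explicit loops
oracle_z_angle <- function(mat, rate, median_window = 5, epoch_length = 5) {
  n <- nrow(mat)
  k <- max(1, round(median_window * rate))
  if (k %% 2 == 0) k <- k - 1
  sm <- matrix(0, n, 3)
  for (j in 1:3) sm[, j] <- oracle_rolling_median(mat[, j], k)
  ang <- numeric(n)
  for (i in seq_len(n)) {
    horiz <- sqrt(sm[i, 1]^2 + sm[i, 2]^2)
    ang[i] <- if (horiz == 0) sign(sm[i, 3]) * 90 else atan(sm[i, 3] / horiz) * 180 / pi
  }
  n_ep <- floor(n / (rate * epoch_length))
  out <- numeric(n_ep)
  for (e in seq_len(n_ep)) {
    idx <- which(floor((seq_len(n) - 1) / (rate * epoch_length)) == e - 1)
    out[e] <- mean(ang[idx])
  }
  out
}

oracle_var_stat <- function(z_values, window_epochs) {
  m <- window_epochs
  if (m %% 2 == 0) m <- m - 1
  d <- numeric(length(z_values) - 1)
  for (i in seq_along(d)) d[i] <- abs(z_values[i + 1] - z_values[i])
  oracle_rolling_median(d, m)
}

# linear-interpolation percentile by sort-and-index (quantile type 7)
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# maximal below-threshold runs kept when strictly longer than min_block
oracle_blocks <- function(values, threshold, epoch_length, min_block_min) {
  n <- length(values)
  blocks <- list()
  i <- 1
  while (i <= n) {
    if (values[i] < threshold) {
      j <- i
      while (j < n && values[j + 1] < threshold) j <- j + 1
      dur_min <- (j - i + 1) * epoch_length / 60
      if (dur_min > min_block_min) blocks[[length(blocks) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  blocks
}

# fixed point of pairwise gap merging (re-scan until no change)
oracle_merge <- function(blocks, max_gap_min, epoch_length) {
  repeat {
    changed <- FALSE
    if (length(blocks) >= 2) {
      for (i in seq_len(length(blocks) - 1)) {
        gap_min <- (blocks[[i + 1]][1] - blocks[[i]][2] - 1) * epoch_length / 60
        if (gap_min < max_gap_min) {
          blocks[[i]] <- c(blocks[[i]][1], blocks[[i + 1]][2])
          blocks[[i + 1]] <- NULL
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) return(blocks)
  }
}

# full adaptive-threshold chain on a value vector: threshold, blocks, merge,
# longest (earliest on ties); returns NULL or c(first_epoch, last_epoch, thr)
oracle_spt_chain <- function(var_values, epoch_length, percentile = 0.10,
                             multiplier = 15, min_block = 30, max_gap = 60,
                             clamp = NULL) {
  thr <- oracle_percentile(var_values, percentile) * multiplier
  if (!is.null(clamp)) thr <- min(max(thr, clamp[1]), clamp[2])
  if (thr <= 0) return(NULL)
  blocks <- oracle_blocks(var_values, thr, epoch_length, min_block)
  blocks <- oracle_merge(blocks, max_gap, epoch_length)
  if (length(blocks) == 0) return(NULL)
  best <- 1
  for (i in seq_along(blocks)) {
    len_i <- blocks[[i]][2] - blocks[[i]][1]
    len_b <- blocks[[best]][2] - blocks[[best]][1]
    if (len_i > len_b) best <- i
  }
  c(blocks[[best]], thr)
}

# exhaustive least-active-window scan
oracle_l5 <- function(values, w) {
  best_i <- 1
  best_mean <- Inf
  for (i in seq_len(length(values) - w + 1)) {
    s <- 0
    for (j in i:(i + w - 1)) s <- s + values[j]
    m <- s / w
    if (m < best_mean) {
      best_mean <- m
      best_i <- i
    }
  }
  c(best_i, best_mean)
}

# sustained-inactivity scan over consecutive-epoch changes
oracle_sib <- function(z_values, epoch_length, angle_tol = 5, min_dur_min = 5) {
  n <- length(z_values)
  bouts <- list()
  i <- 1
  while (i < n) {
    if (abs(z_values[i + 1] - z_values[i]) <= angle_tol) {
      j <- i
      while (j + 1 < n && abs(z_values[j + 2] - z_values[j + 1]) <= angle_tol) j <- j + 1
      dur_min <- (j - i + 2) * epoch_length / 60
      if (dur_min > min_dur_min) bouts[[length(bouts) + 1]] <- c(i, j + 1)
      i <- j + 2
    } else {
      i <- i + 1
    }
  }
  bouts
}
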