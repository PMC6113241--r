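#' Specify the structure of a simulated night and day
#'
#' Describes one daily cycle of a simulated wrist recording: when the subject
#' sleeps, which wake bouts interrupt the night, which daytime naps occur,
#' and how much the arm angle moves in each regime. The defaults emulate an
#' older adult cohort: sleep 23:45-07:30 (about 7.7 hours) with one 20-minute
#' awakening, a daytime random-walk step of 8 degrees per 5-second epoch (wakeful
#' arm movement routinely exceeds the 5-degree inactivity tolerance) and
#' a night-time angular jitter of 0.02 degrees — which places the unclamped
#' adaptive threshold inside the 0.13-0.50 degree range seen in daily-life
#' recordings.
#'
#' @param sleep_onset,wake_time clock times `"HH:MM"`; onset at or after
#'   noon belongs to the evening, before noon to the small hours.
#' @param wake_bouts list of `c(start = "HH:MM", duration_min)` pairs, i.e.
#'   `list(c("03:00", 20))`; must fall within the night.
#' @param naps list of the same shape; must fall outside the night.
#' @param movement_intensity_day random-walk step, degrees per epoch.
#' @param movement_intensity_night angular jitter sd, degrees per epoch.
#' @param diary_noise_sd sd (minutes) of the reporting error added to the
#'   true onset/wake when writing the simulated diary.
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @return An object of class `night_spec`.
#' @export
night_spec <- function(sleep_onset = "23:45", wake_time = "07:30",
                       wake_bouts = list(c("03:00", 20)), naps = list(),
                       movement_intensity_day = 8,
                       movement_intensity_night = 0.02,
                       diary_noise_sd = 10, seed) {
  if (missing(seed)) abort("`seed` is mandatory: every fixture must be reproducible.")
  onset_s <- clock_to_seconds(sleep_onset)
  wake_s <- clock_to_seconds(wake_time)
  # seconds on the noon-noon axis (12:00 -> 0, 36:00 -> 86400)
  axis <- function(s) (s - 43200) %% 86400
  night <- c(axis(onset_s), axis(wake_s))
  if (night[1] >= night[2]) abort("sleep onset must precede wake time on the noon-noon axis.")
  parse_bouts <- function(lst, what, inside) {
    if (length(lst) == 0) {
      return(tibble::tibble(start_s = numeric(0), dur_s = numeric(0)))
    }
    b <- purrr::map_dfr(lst, function(bt) {
      tibble::tibble(start_s = axis(clock_to_seconds(bt[[1]])),
                     dur_s = as.numeric(bt[[2]]) * 60)
    })
    b <- b[order(b$start_s), , drop = FALSE]
    in_night <- b$start_s >= night[1] & (b$start_s + b$dur_s) <= night[2]
    if (inside && !all(in_night)) abort(paste(what, "must fall within the night."))
    if (!inside && any(b$start_s < night[2] & b$start_s + b$dur_s > night[1])) {
      abort(paste(what, "must fall outside the night."))
    }
    if (nrow(b) > 1 && any(diff(b$start_s) < head(b$dur_s, -1))) {
      abort(paste("overlapping", what, "in the specification."))
    }
    b
  }
  structure(
    list(sleep_onset = sleep_onset, wake_time = wake_time,
         night_axis_s = night,
         wake_bouts = parse_bouts(wake_bouts, "wake bouts", TRUE),
         naps = parse_bouts(naps, "naps", FALSE),
         movement_intensity_day = movement_intensity_day,
         movement_intensity_night = movement_intensity_night,
         diary_noise_sd = diary_noise_sd, seed = as.integer(seed)),
    class = "night_spec"
  )
}

# fold an angle trajectory into [-85, 85] by reflection (clipping would
# fabricate motionless stretches at the boundary)
fold_angle <- function(x, lim = 85) {
  lim - abs((2 * lim) - ((x + lim) %% (4 * lim)))
}

# per-epoch latent state for one noon-noon day: "wake", "sleep", "nap"
day_states <- function(spec, n_epochs, el) {
  t_axis <- (seq_len(n_epochs) - 1) * el
  state <- rep("wake", n_epochs)
  night <- spec$night_axis_s
  state[t_axis >= night[1] & t_axis < night[2]] <- "sleep"
  mark <- function(b, lab) {
    for (i in seq_len(nrow(b))) {
      sel <- t_axis >= b$start_s[i] & t_axis < b$start_s[i] + b$dur_s[i]
      state[sel] <<- lab
    }
  }
  mark(spec$wake_bouts, "wake")
  mark(spec$naps, "nap")
  state
}

# epoch-level angle trajectory given the state sequence
angle_trajectory <- function(state, spec) {
  n <- length(state)
  theta <- numeric(n)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    i <- starts[k]:ends[k]
    m <- r$lengths[k]
    if (r$values[k] == "wake") {
      theta[i] <- fold_angle(runif(1, -45, 45) +
                               cumsum(rnorm(m, 0, spec$movement_intensity_day)))
    } else {
      # quiet regime: stable posture with jitter and occasional posture shifts
      shifts <- cumsum(runif(m) < 1 / 480) # about one shift every 40 minutes
      postures <- runif(1, -60, 60) + cumsum(c(0, rnorm(max(shifts), 0, 12)))
      theta[i] <- fold_angle(postures[shifts + 1] +
                               rnorm(m, 0, spec$movement_intensity_night))
    }
  }
  theta
}

#' Generate a synthetic multi-day wrist recording with ground truth
#'
#' Builds a raw tri-axial recording whose arm-angle dynamics follow the
#' latent sleep/wake structure of `spec`, repeated for `days` noon-noon days,
#' together with the true SPT windows, a hypnogram and a noisy diary. Nights
#' are near-constant orientation with small jitter and sparse posture shifts;
#' days are a wandering arm orientation with added accelerometer activity
#' noise and occasional high-acceleration bursts (so ENMO separates day from
#' night); naps get night-like dynamics but are excluded from the true
#' windows. Orientation is converted to gravity-consistent unit-norm triples
#' (elevation plus a slowly wandering azimuth) before noise is added.
#'
#' @param spec a [night_spec()].
#' @param days number of noon-noon days.
#' @param sample_rate samples per second of the raw recording. The detector
#'   consumes 5-second epochs, so the rate matters only through the per-axis
#'   rolling median; 10 Hz keeps multi-recording corpora cheap.
#' @param tz,start_date time zone and the date whose noon starts the
#'   recording.
#' @param epoch_length epoch length (seconds) used for the latent trajectory
#'   and hypnogram truth (hypnogram epochs are 30 s).
#' @return A list: `raw` (tibble `time`, `x`, `y`, `z` in g), `truth`
#'   (tibble `day_id`, `onset`, `wake`, `duration_min`), `hypnogram`
#'   (tibble `time`, `stage`), `diary` (tibble `id`, `night_id`, `onset`,
#'   `wake`), and `spec`.
#' @export
generate_recording <- function(spec, days = 1, sample_rate = 10, tz = "UTC",
                               start_date = as.Date("2024-03-04"),
                               epoch_length = 5) {
  stopifnot(inherits(spec, "night_spec"))
  withr::with_seed(spec$seed, {
    el <- epoch_length
    n_day <- as.integer(86400 / el)
    t0 <- as.POSIXct(paste(start_date, "12:00:00"), tz = tz)
    state <- rep(day_states(spec, n_day, el), days)
    n_ep <- length(state)
    theta <- angle_trajectory(state, spec)
    phi <- (cumsum(rnorm(n_ep, 0, 0.5))) %% 360
    # raw samples: piecewise-constant orientation within each epoch
    spe <- sample_rate * el
    n_s <- as.integer(round(n_ep * spe))
    ep_of <- floor((seq_len(n_s) - 1) / spe) + 1
    th <- theta[ep_of] * pi / 180
    ph <- phi[ep_of] * pi / 180
    gx <- cos(th) * cos(ph)
    gy <- cos(th) * sin(ph)
    gz <- sin(th)
    quiet <- state[ep_of] != "wake"
    noise_sd <- ifelse(quiet, 0.002, 0.05)
    burst_ep <- runif(n_ep) < 0.02 & state == "wake"
    noise_sd[burst_ep[ep_of]] <- 0.25
    raw <- tibble::tibble(
      time = t0 + (seq_len(n_s) - 1) / sample_rate,
      x = gx + rnorm(n_s, 0, noise_sd),
      y = gy + rnorm(n_s, 0, noise_sd),
      z = gz + rnorm(n_s, 0, noise_sd)
    )
    attr(raw, "sample_rate") <- sample_rate
    day_ids <- start_date + seq_len(days) - 1
    night <- spec$night_axis_s
    noons <- as.POSIXct(paste(day_ids, "12:00:00"), tz = tz)
    truth <- tibble::tibble(
      day_id = day_ids,
      onset = noons + night[1],
      wake = noons + night[2],
      duration_min = (night[2] - night[1]) / 60
    )
    # hypnogram: 30-s epochs, cyclic stage architecture inside the night
    elh <- 30
    n_h_day <- as.integer(86400 / elh)
    state_h <- rep(day_states(spec, n_h_day, elh), days)
    cycle <- c(rep("N1", 10), rep("N2", 40), rep("N3", 40), rep("N2", 20),
               rep("REM", 30)) # 70-minute cycle
    stage <- rep("W", length(state_h))
    asleep <- state_h != "wake"
    stage[asleep] <- rep_len(cycle, sum(asleep))
    hypnogram <- tibble::tibble(
      time = t0 + (seq_along(stage) - 1) * elh,
      stage = stage
    )
    attr(hypnogram, "epoch_length") <- elh
    diary <- tibble::tibble(
      id = "sim",
      night_id = day_ids,
      onset = truth$onset + round(rnorm(days, 0, spec$diary_noise_sd)) * 60,
      wake = truth$wake + round(rnorm(days, 0, spec$diary_noise_sd)) * 60
    )
    list(raw = raw, truth = truth, hypnogram = hypnogram, diary = diary,
         spec = spec)
  })
}

#' Generate an in-bed z-angle series with a matched hypnogram
#'
#' Emulates an overnight polysomnography session: an 8-10-hour in-bed span
#' starting with a wake latency period, followed by semi-Markov sleep cycles
#' (stage run lengths exponential around `stage_means`, in the order N1, N2,
#' N3, N2, REM, with occasional brief awakenings between cycles) and ending
#' with wakefulness. Angle variability is tied to the stage and ordered
#' W > N1 > REM > N2 > N3. Returns the 5-second z-angle epoch series
#' directly, plus the 30-second hypnogram.
#'
#' @param seed integer seed.
#' @param start clock time at which the recording starts.
#' @param duration_hr in-bed span, hours (8-10 is typical).
#' @param latency_min initial wakefulness before sleep onset, minutes.
#' @param wake_after_min trailing wakefulness, minutes.
#' @param stage_means named mean run lengths in minutes for N1, N2, N3, REM
#'   and the between-cycle wake bouts W.
#' @param fixed_stage force every in-sleep epoch to one stage (e.g. `"N3"`),
#'   or `"W"` for an all-wake recording; `NULL` for the cyclic architecture.
#' @param date,tz calendar date of the evening and time zone.
#' @return A list: `z` (an [epoch_series()]), `hypnogram` (tibble `time`,
#'   `stage`), `truth` (one-row tibble with the true sleep onset/wake).
#' @export
generate_psg_fixture <- function(seed, start = "23:00", duration_hr = 9,
                                 latency_min = 15, wake_after_min = 10,
                                 stage_means = c(N1 = 4, N2 = 20, N3 = 25,
                                                 REM = 18, W = 1.5),
                                 fixed_stage = NULL,
                                 date = as.Date("2024-03-04"), tz = "UTC") {
  withr::with_seed(as.integer(seed), {
    elh <- 30
    n_h <- as.integer(round(duration_hr * 3600 / elh))
    n_lat <- as.integer(round(latency_min * 60 / elh))
    n_tail <- as.integer(round(wake_after_min * 60 / elh))
    n_sleep <- n_h - n_lat - n_tail
    if (n_sleep <= 0) abort("duration too short for the requested latency and trailing wake.")
    if (!is.null(fixed_stage)) {
      if (identical(fixed_stage, "W")) {
        stage <- rep("W", n_h)
      } else {
        stage <- c(rep("W", n_lat), rep(fixed_stage, n_sleep), rep("W", n_tail))
      }
    } else {
      order_ <- c("N1", "N2", "N3", "N2", "REM")
      seq_stages <- character(0)
      while (length(seq_stages) < n_sleep) {
        for (s in order_) {
          run <- max(1L, as.integer(round(stats::rexp(1, 1 / stage_means[[s]]) * 60 / elh)))
          seq_stages <- c(seq_stages, rep(s, run))
        }
        if (runif(1) < 0.5) { # brief awakening between cycles
          run <- max(1L, as.integer(round(stats::rexp(1, 1 / stage_means[["W"]]) * 60 / elh)))
          seq_stages <- c(seq_stages, rep("W", run))
        }
      }
      stage <- c(rep("W", n_lat), seq_stages[seq_len(n_sleep)], rep("W", n_tail))
    }
    s0 <- clock_to_seconds(start)
    t0 <- as.POSIXct(paste(date, "00:00:00"), tz = tz) + s0 +
      ifelse(s0 < 43200, 86400, 0)
    hypnogram <- tibble::tibble(time = t0 + (seq_len(n_h) - 1) * elh,
                                stage = stage)
    attr(hypnogram, "epoch_length") <- elh
    # 5-s z-angle: per-stage variability, W a random walk, sleep jittered postures
    el <- 5
    stage5 <- rep(stage, each = elh / el)
    jitter_sd <- c(N1 = 0.05, REM = 0.04, N2 = 0.02, N3 = 0.008)
    n5 <- length(stage5)
    theta <- numeric(n5)
    r <- rle(stage5)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      i <- starts[k]:ends[k]
      m <- r$lengths[k]
      if (r$values[k] == "W") {
        theta[i] <- fold_angle(runif(1, -45, 45) + cumsum(rnorm(m, 0, 2)))
      } else {
        shifts <- cumsum(runif(m) < 1 / 480)
        postures <- runif(1, -60, 60) + cumsum(c(0, rnorm(max(shifts), 0, 12)))
        theta[i] <- fold_angle(postures[shifts + 1] +
                                 rnorm(m, 0, jitter_sd[[r$values[k]]]))
      }
    }
    z <- epoch_series(t0 + (seq_len(n5) - 1) * el, theta, "z_angle", el)
    sleep_idx <- which(stage != "W")
    truth <- if (length(sleep_idx)) {
      tibble::tibble(onset = hypnogram$time[min(sleep_idx)],
                     wake = hypnogram$time[max(sleep_idx)] + elh)
    } else {
      tibble::tibble(onset = as.POSIXct(NA, tz = tz), wake = as.POSIXct(NA, tz = tz))
    }
    list(z = z, hypnogram = hypnogram, truth = truth)
  })
}
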