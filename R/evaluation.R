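#' Signed difference between two times of the same night, in minutes
#'
#' Both times are mapped onto the continuous noon-to-noon axis of their night
#' (12:00 to 36:00), so differences across midnight stay linear: 23:50 vs
#' 00:10 is -20 minutes, not -1420. Errors if the times do not belong to the
#' same noon-noon day.
#'
#' @param a,b POSIXct times (recycled to a common length).
#' @return Signed minutes `a - b`.
#' @export
diff_minutes <- function(a, b) {
  if (any(noon_day_id(a) != noon_day_id(b))) {
    abort("times fall in different noon-noon days; assign both to the same night first.")
  }
  (as.numeric(a) - as.numeric(b)) / 60
}

# c-statistic of a binary classifier against binary truth: balanced accuracy
# (sensitivity + specificity)/2, the one-operating-point trapezoidal AUC.
# NA when the truth is single-class (sensitivity or specificity undefined).
binary_cstat <- function(truth, pred) {
  pos <- sum(truth)
  neg <- sum(!truth)
  if (pos == 0 || neg == 0) return(NA_real_)
  sens <- sum(pred & truth) / pos
  spec <- sum(!pred & !truth) / neg
  (sens + spec) / 2
}

# epoch-level agreement of two windows on a grid of epoch left edges
window_agreement <- function(grid, ref_onset, ref_wake, alg_onset, alg_wake) {
  truth <- grid >= ref_onset & grid < ref_wake
  pred <- grid >= alg_onset & grid < alg_wake
  list(accuracy_pct = 100 * mean(truth == pred),
       c_statistic = binary_cstat(truth, pred))
}

mins_from_noon <- function(time, day_id) {
  noon <- as.POSIXct(paste(day_id, "12:00:00"), tz = tz_of(time))
  as.numeric(time - noon, units = "mins")
}

#' Compare detected SPT windows with a sleep diary
#'
#' Matches detected windows to diary nights on the noon-noon day and computes,
#' per night, signed differences (diary minus algorithm, minutes) in sleep
#' onset, waking time and window duration, together with epoch-level accuracy
#' and c-statistic of the binary SPT classification on the noon-noon grid.
#' Aggregates are the mean absolute error per parameter, the pooled combined
#' MAE over onset and waking-time errors, Pearson correlations of the timings
#' on the noon-noon axis, and the c-statistic averaged first per day and then
#' per participant.
#'
#' @param windows a windows tibble ([detect_spt_multiday()] output or the
#'   like); an optional `id` column identifies participants.
#' @param diary a tibble with columns `night_id` (`Date`), `onset`, `wake`
#'   (POSIXct), e.g. from [read_diary_csv()]; an optional `id` column must
#'   then match `windows$id`.
#' @param grid_epoch evaluation grid resolution in seconds (default 5).
#' @return An object of class `diary_comparison`: use [tidy()] for the
#'   per-night rows, [glance()] for the aggregate row, and [autoplot()] for
#'   the difference distributions.
#' @export
compare_diary <- function(windows, diary, grid_epoch = 5) {
  if (!"id" %in% names(windows)) windows$id <- "participant"
  if (!"id" %in% names(diary)) diary$id <- "participant"
  w <- windows[!is.na(windows$onset), , drop = FALSE]
  m <- dplyr::inner_join(
    w, dplyr::rename(diary, diary_onset = "onset", diary_wake = "wake"),
    by = c("id", "day_id" = "night_id")
  )
  if (nrow(m) == 0) abort("no diary night matches a detected window.")
  tz <- tz_of(m$onset)
  per_night <- purrr::pmap_dfr(
    list(m$day_id, m$id, m$onset, m$wake, m$diary_onset, m$diary_wake),
    function(day, id, onset, wake, d_onset, d_wake) {
      noon <- as.POSIXct(paste(day, "12:00:00"), tz = tz)
      grid <- noon + seq(0, 86400 - grid_epoch, by = grid_epoch)
      agr <- window_agreement(grid, d_onset, d_wake, onset, wake)
      tibble::tibble(
        id = id, night_id = day,
        onset_diff = as.numeric(d_onset - onset, units = "mins"),
        wake_diff = as.numeric(d_wake - wake, units = "mins"),
        duration_diff = as.numeric(d_wake - d_onset, units = "mins") -
          as.numeric(wake - onset, units = "mins"),
        accuracy_pct = agr$accuracy_pct,
        c_statistic = agr$c_statistic
      )
    }
  )
  per_participant <- dplyr::summarise(
    dplyr::group_by(per_night, .data$id),
    c_statistic = mean(.data$c_statistic, na.rm = TRUE), .groups = "drop"
  )
  summary <- tibble::tibble(
    n_nights = nrow(per_night),
    n_participants = nrow(per_participant),
    mae_onset_min = mean(abs(per_night$onset_diff)),
    mae_wake_min = mean(abs(per_night$wake_diff)),
    mae_duration_min = mean(abs(per_night$duration_diff)),
    mae_combined_min = mean(c(abs(per_night$onset_diff), abs(per_night$wake_diff))),
    mean_onset_diff_min = mean(per_night$onset_diff),
    mean_wake_diff_min = mean(per_night$wake_diff),
    mean_duration_diff_min = mean(per_night$duration_diff),
    r_onset = cor_or_na(mins_from_noon(m$diary_onset, m$day_id),
                        mins_from_noon(m$onset, m$day_id)),
    r_wake = cor_or_na(mins_from_noon(m$diary_wake, m$day_id),
                       mins_from_noon(m$wake, m$day_id)),
    r_duration = cor_or_na(
      as.numeric(m$diary_wake - m$diary_onset, units = "mins"),
      as.numeric(m$wake - m$onset, units = "mins")),
    mean_accuracy_pct = mean(per_night$accuracy_pct),
    c_statistic = mean(per_participant$c_statistic)
  )
  structure(list(nights = per_night, summary = summary,
                 participants = per_participant),
            class = "diary_comparison")
}

cor_or_na <- function(x, y) {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' @export
print.diary_comparison <- function(x, ...) {
  cat("Diary comparison over", x$summary$n_nights, "nights,",
      x$summary$n_participants, "participant(s)\n")
  cat(sprintf("  MAE onset %.1f min, wake %.1f min, duration %.1f min (combined %.1f)\n",
              x$summary$mae_onset_min, x$summary$mae_wake_min,
              x$summary$mae_duration_min, x$summary$mae_combined_min))
  cat(sprintf("  mean c-statistic %.3f, mean accuracy %.1f%%\n",
              x$summary$c_statistic, x$summary$mean_accuracy_pct))
  invisible(x)
}

#' @rdname compare_diary
#' @param x a `diary_comparison` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.diary_comparison <- function(x, ...) x$nights

#' @rdname compare_diary
#' @exportS3Method generics::glance
glance.diary_comparison <- function(x, ...) x$summary

#' Stratify duration differences by accumulated wakefulness
#'
#' Categorises nights by wake-after-sleep-onset hours into left-closed bins
#' (`[0-1)`, `[1-2)`, ..., last bin open-ended: a night with exactly 60
#' minutes of wakefulness falls in `[1-2)`) and reports the mean
#' diary-minus-algorithm duration difference and the prevalence of each
#' category. Nights with much wakefulness are where a single contiguous
#' window is hardest to place.
#'
#' @param nights a tibble with columns `waso_min` and `duration_diff`
#'   (e.g. [tidy()] of a comparison joined with [summarize_sleep()] output).
#' @param bounds increasing category boundaries in hours.
#' @return A tibble with `category`, `n`, `prevalence_pct`,
#'   `mean_duration_diff_min`.
#' @export
stratify_by_wakefulness <- function(nights, bounds = c(1, 2, 3, 4)) {
  breaks <- c(0, bounds, Inf)
  labs <- paste0("[", head(breaks, -1), "-", tail(breaks, -1), ")")
  labs[length(labs)] <- paste0(">=", breaks[length(breaks) - 1])
  cat_ <- cut(nights$waso_min / 60, breaks = breaks, right = FALSE, labels = labs)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(category = cat_,
                                   duration_diff = nights$duration_diff),
                    .data$category),
    n = dplyr::n(),
    mean_duration_diff_min = mean(.data$duration_diff),
    .groups = "drop"
  ) |>
    dplyr::mutate(prevalence_pct = 100 * .data$n / sum(.data$n))
}

#' Pad a recording with simulated wakefulness
#'
#' In-bed-only recordings give the detector no out-of-bed movement to find
#' the edges of the sleep window against, and too little data to derive its
#' threshold from. This prepends and appends `pad` minutes of simulated
#' wakefulness: for the z-angle a sine wave of amplitude 40 degrees and
#' period 15 minutes plus Gaussian noise (mean 0, sd 10), sampled per epoch
#' and clipped to the valid \[-90, 90\] range; for the hypnogram, stage W.
#' The shape only needs to be too variable to ever look like sleep.
#'
#' @param z an [epoch_series()] of kind `"z_angle"`; may have zero rows if it
#'   carries `epoch_length` and `start_time` attributes.
#' @param hypnogram optional hypnogram tibble (`time`, `stage`) to pad with
#'   stage `"W"` in step.
#' @param pad minutes of simulated data on each side.
#' @param seed integer seed for the noise (mandatory, for reproducibility).
#' @return A list with elements `z` and (when supplied) `hypnogram`, each
#'   extended by `pad` minutes on both sides; the padded `z` carries a
#'   `pad_epochs` attribute with the number of simulated epochs per side.
#' @export
pad_with_wakefulness <- function(z, hypnogram = NULL, pad = 90, seed) {
  if (missing(seed)) abort("`seed` is required so padded recordings are reproducible.")
  if (pad <= 0) abort("`pad` must be positive.")
  el <- attr(z, "epoch_length") %||% epoch_length_of(z)
  if (nrow(z) > 0) {
    t0 <- z$time[1]
    t_end <- z$time[nrow(z)] + el
  } else {
    t0 <- attr(z, "start_time")
    if (is.null(t0)) abort("an empty series needs a `start_time` attribute to pad around.")
    t_end <- t0
  }
  n_pad <- as.integer(round(pad * 60 / el))
  sim_angle <- function(n) {
    t_rel <- (seq_len(n) - 1) * el
    v <- 40 * sin(2 * pi * t_rel / (15 * 60)) + rnorm(n, 0, 10)
    pmin(pmax(v, -90), 90)
  }
  vals <- withr::with_seed(seed, list(pre = sim_angle(n_pad), post = sim_angle(n_pad)))
  pre_t <- t0 - rev(seq_len(n_pad)) * el
  post_t <- t_end + (seq_len(n_pad) - 1) * el
  zp <- epoch_series(c(pre_t, z$time, post_t),
                     c(vals$pre, z$value, vals$post), "z_angle", el)
  attr(zp, "pad_epochs") <- n_pad
  out <- list(z = zp)
  if (!is.null(hypnogram)) {
    elh <- attr(hypnogram, "epoch_length") %||% epoch_length_of(hypnogram)
    n_ph <- as.integer(round(pad * 60 / elh))
    h0 <- if (nrow(hypnogram)) hypnogram$time[1] else t0
    h_end <- if (nrow(hypnogram)) hypnogram$time[nrow(hypnogram)] + elh else t0
    hp <- tibble::tibble(
      time = c(h0 - rev(seq_len(n_ph)) * elh, hypnogram$time,
               h_end + (seq_len(n_ph) - 1) * elh),
      stage = c(rep("W", n_ph), hypnogram$stage, rep("W", n_ph))
    )
    attr(hp, "epoch_length") <- elh
    out$hypnogram <- hp
  }
  out
}

# repeat hypnogram stages onto a finer epoch grid, truncating to the overlap
# with the z-angle series
align_hypnogram <- function(z, hypnogram) {
  el <- epoch_length_of(z)
  elh <- attr(hypnogram, "epoch_length") %||% epoch_length_of(hypnogram)
  rep_each <- elh / el
  if (abs(rep_each - round(rep_each)) > 1e-9 || rep_each < 1) {
    abort("hypnogram epoch length must be a multiple of the z-angle epoch length.")
  }
  stage_fine <- rep(hypnogram$stage, each = as.integer(round(rep_each)))
  t_fine <- hypnogram$time[1] + (seq_along(stage_fine) - 1) * el
  start <- max(z$time[1], t_fine[1])
  end <- min(z$time[nrow(z)], t_fine[length(t_fine)])
  keep_z <- z$time >= start & z$time <= end
  zt <- z[keep_z, , drop = FALSE]
  attr(zt, "epoch_length") <- el
  attr(zt, "kind") <- "z_angle"
  keep_h <- t_fine >= start & t_fine <= end
  list(z = zt, stage = stage_fine[keep_h], time = t_fine[keep_h])
}

#' Compare the detector with a polysomnography hypnogram
#'
#' Runs the full in-bed evaluation protocol: the z-angle series and the
#' hypnogram are aligned to a common 5-second grid, padded with `pad` minutes
#' of simulated wakefulness per side ([pad_with_wakefulness()]), the detector
#' is run with a clamped threshold over the padded span, and `trim` minutes
#' of simulated data are removed from each side before computing agreement,
#' so the evaluated span is the real recording plus `2 * (pad - trim)`
#' minutes. The PSG reference SPT window runs from the first to the end of
#' the last non-wake epoch.
#'
#' Reported metrics: signed differences (PSG minus algorithm) and absolute
#' errors in onset, waking time and duration; epoch-level accuracy and
#' c-statistic on the trimmed span and on a full 24-hour noon-noon grid where
#' everything outside the recording counts as correctly classified
#' wakefulness (the "24-hour" estimate); per-stage sensitivity (percentage of
#' N1/N2/N3/REM epochs inside the detected window); and sleep-within-window
#' duration and efficiency differences, with the algorithm's sleep episodes
#' scored as sustained inactivity bouts.
#'
#' @param z an [epoch_series()] of kind `"z_angle"` covering the in-bed span.
#' @param hypnogram tibble (`time`, `stage` in W/N1/N2/N3/REM) with an
#'   `epoch_length` attribute (typically 30 s).
#' @param params an [hdcza_params()]; default applies the daily-life
#'   threshold clamp `c(0.13, 0.50)` required for short recordings.
#' @param pad,trim simulated-wakefulness padding and pre-comparison trim,
#'   minutes.
#' @param seed integer seed for the simulated padding.
#' @param var_window rolling-median span for the variance statistic, minutes.
#' @return An object of class `psg_comparison` with elements `summary`
#'   (one-row tibble), `stages` (per-stage sensitivity) and `windows`
#'   (algorithm and PSG windows); [glance()] returns the summary, [tidy()]
#'   the per-stage table.
#' @export
compare_psg <- function(z, hypnogram,
                        params = hdcza_params(clamp = c(0.13, 0.50)),
                        pad = 90, trim = 60, seed = 1, var_window = 5) {
  params <- as_hdcza_params(params)
  if (trim > pad) abort("`trim` cannot exceed `pad`.")
  al <- align_hypnogram(z, hypnogram)
  if (nrow(al$z) == 0) abort("z-angle series and hypnogram do not overlap.")
  el <- epoch_length_of(al$z)
  real_start <- al$z$time[1]
  real_end <- al$z$time[nrow(al$z)] + el
  padded <- pad_with_wakefulness(al$z, pad = pad, seed = seed)
  vs <- rolling_var_statistic(padded$z, var_window)
  win <- detect_spt(vs, day = NULL, params = params)
  if (nrow(win) == 0) {
    abort("no SPT window detected in the padded recording.")
  }
  sleep_idx <- which(al$stage != "W")
  if (length(sleep_idx) == 0) abort("hypnogram contains no sleep epochs.")
  psg_onset <- al$time[min(sleep_idx)]
  psg_wake <- al$time[max(sleep_idx)] + el
  margin <- (pad - trim) * 60
  eval_start <- real_start - margin
  eval_end <- real_end + margin
  grid <- seq(from = as.numeric(eval_start), to = as.numeric(eval_end) - el,
              by = el)
  grid <- as.POSIXct(grid, origin = "1970-01-01", tz = tz_of(al$z$time))
  agr <- window_agreement(grid, psg_onset, psg_wake, win$onset, win$wake)
  noon <- as.POSIXct(paste(noon_day_id(real_start), "12:00:00"),
                     tz = tz_of(al$z$time))
  grid24 <- noon + seq(0, 86400 - el, by = el)
  agr24 <- window_agreement(grid24, psg_onset, psg_wake, win$onset, win$wake)
  in_alg <- al$time >= win$onset & al$time < win$wake
  stages <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(stage = al$stage, in_alg = in_alg),
                    .data$stage),
    n_epochs = dplyr::n(),
    sensitivity_pct = 100 * mean(.data$in_alg),
    .groups = "drop"
  )
  stages <- stages[stages$stage != "W", , drop = FALSE]
  # sleep within each window: PSG by stages, algorithm by inactivity bouts
  psg_sleep_min <- sum(al$stage != "W" &
                         al$time >= psg_onset & al$time < psg_wake) * el / 60
  psg_dur <- as.numeric(psg_wake - psg_onset, units = "mins")
  sibs <- detect_sib(al$z)
  alg_summary <- summarize_sleep(win, sibs)
  summary <- tibble::tibble(
    onset_diff_min = diff_minutes(psg_onset, win$onset),
    wake_diff_min = diff_minutes(psg_wake, win$wake),
    duration_diff_min = psg_dur - win$duration_min,
    abs_onset_err_min = abs(diff_minutes(psg_onset, win$onset)),
    abs_wake_err_min = abs(diff_minutes(psg_wake, win$wake)),
    accuracy_pct = agr$accuracy_pct,
    c_statistic = agr$c_statistic,
    accuracy_24h_pct = agr24$accuracy_pct,
    c_statistic_24h = agr24$c_statistic,
    sleep_sensitivity_pct = 100 * mean(in_alg[al$stage != "W"]),
    sleep_duration_diff_min = psg_sleep_min - alg_summary$total_sleep_min,
    efficiency_diff_pct = 100 * psg_sleep_min / psg_dur - alg_summary$efficiency_pct,
    threshold_used_deg = win$threshold_used_deg,
    eval_span_min = as.numeric(eval_end - eval_start, units = "mins"),
    real_span_min = as.numeric(real_end - real_start, units = "mins")
  )
  windows <- dplyr::bind_rows(
    win,
    tibble::tibble(day_id = noon_day_id(psg_onset), onset = psg_onset,
                   wake = psg_wake, duration_min = psg_dur,
                   threshold_used_deg = NA_real_, algorithm = "PSG",
                   n_blocks_merged = NA_integer_, low_contrast = NA)
  )
  structure(list(summary = summary, stages = stages, windows = windows),
            class = "psg_comparison")
}

#' @export
print.psg_comparison <- function(x, ...) {
  cat("PSG comparison\n")
  cat(sprintf("  onset diff %.1f min, wake diff %.1f min, duration diff %.1f min\n",
              x$summary$onset_diff_min, x$summary$wake_diff_min,
              x$summary$duration_diff_min))
  cat(sprintf("  accuracy %.1f%% (24 h: %.1f%%), c-statistic %.3f (24 h: %.3f)\n",
              x$summary$accuracy_pct, x$summary$accuracy_24h_pct,
              x$summary$c_statistic, x$summary$c_statistic_24h))
  invisible(x)
}

#' @rdname compare_psg
#' @param x a `psg_comparison` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.psg_comparison <- function(x, ...) x$stages

#' @rdname compare_psg
#' @exportS3Method generics::glance
glance.psg_comparison <- function(x, ...) x$summary

#' Sweep detector parameters over a corpus with known ground truth
#'
#' Re-runs the detector for every row of a parameter grid over a corpus of
#' recordings with known true windows and reports the mean absolute onset and
#' waking-time errors per setting — a sensitivity analysis of the parameter
#' configuration.
#'
#' @param corpus a list of elements each holding `var_stat` (an
#'   [epoch_series()]) and `truth` (a tibble with `day_id`, `onset`, `wake`),
#'   e.g. built from [generate_recording()].
#' @param grid a data frame whose columns are [hdcza_params()] argument names
#'   (`percentile`, `multiplier`, `min_block`, `max_gap`); one row per
#'   setting to evaluate.
#' @param base an [hdcza_params()] supplying the settings not in the grid.
#' @return A tibble: the grid columns plus `n_nights`, `mean_abs_onset_err_min`,
#'   `mean_abs_wake_err_min`, `mean_duration_min` and `is_default` (flagging
#'   rows equal to the package defaults).
#' @export
parameter_sweep <- function(corpus, grid, base = hdcza_params()) {
  if (length(corpus) == 0) abort("`corpus` is empty; nothing to sweep over.")
  if (is.null(dim(grid)) || nrow(grid) == 0) abort("`grid` must have at least one row.")
  base <- as_hdcza_params(base)
  defaults <- hdcza_params()
  purrr::pmap_dfr(as.list(grid), function(...) {
    row <- list(...)
    p <- base
    for (nm in names(row)) p[[nm]] <- row[[nm]]
    p <- as_hdcza_params(unclass(p))
    errs <- purrr::map_dfr(corpus, function(rec) {
      w <- detect_spt_multiday(rec$var_stat, p)
      truth <- tibble::tibble(day_id = rec$truth$day_id,
                              true_onset = rec$truth$onset,
                              true_wake = rec$truth$wake)
      m <- dplyr::inner_join(w[!is.na(w$onset), , drop = FALSE], truth,
                             by = "day_id")
      if (nrow(m) == 0) return(tibble::tibble())
      tibble::tibble(
        onset_err = abs(as.numeric(m$onset - m$true_onset, units = "mins")),
        wake_err = abs(as.numeric(m$wake - m$true_wake, units = "mins")),
        duration = m$duration_min
      )
    })
    tibble::as_tibble(row) |>
      dplyr::mutate(
        n_nights = nrow(errs),
        mean_abs_onset_err_min = mean(errs$onset_err),
        mean_abs_wake_err_min = mean(errs$wake_err),
        mean_duration_min = mean(errs$duration),
        is_default = all(purrr::map_lgl(names(row), function(nm) {
          isTRUE(all.equal(row[[nm]], defaults[[nm]]))
        }))
      )
  })
}
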