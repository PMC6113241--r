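test_that("night-time differences are linear across midnight", {
  expect_equal(diff_minutes(t_utc("23:00:00"), t_utc("23:30:00")), -30)
  expect_equal(diff_minutes(t_utc("23:50:00"), t_utc("00:10:00", "2024-03-05")), -20)
  expect_equal(diff_minutes(t_utc("03:00:00"), t_utc("03:00:00")), 0)
  # times from different nights are refused
  expect_error(diff_minutes(t_utc("23:00:00"), t_utc("23:00:00", "2024-03-05")),
               "different noon-noon days")
})

make_diary <- function(onset, wake, day = as.Date("2024-03-04")) {
  tibble::tibble(night_id = day, onset = onset, wake = wake)
}

test_that("diary comparison is exact for perfect agreement and 0.5 for all-positive", {
  onset <- t_utc("23:30:00"); wake <- t_utc("07:15:00", "2024-03-05")
  w <- one_window(onset, wake)
  cmp <- compare_diary(w, make_diary(onset, wake), grid_epoch = 60)
  expect_equal(tidy(cmp)$onset_diff, 0)
  expect_equal(tidy(cmp)$wake_diff, 0)
  expect_equal(tidy(cmp)$c_statistic, 1.0)
  expect_equal(glance(cmp)$mean_accuracy_pct, 100)
  # algorithm marking the whole day as sleep has no discrimination
  w_all <- one_window(t_utc("12:00:00"), t_utc("12:00:00", "2024-03-05"))
  cmp_all <- compare_diary(w_all, make_diary(onset, wake), grid_epoch = 60)
  expect_equal(tidy(cmp_all)$c_statistic, 0.5)
  expect_error(compare_diary(w, make_diary(onset, wake, as.Date("2020-01-01"))),
               "no diary night")
})

test_that("the c-statistic equals (sensitivity + specificity) / 2 from confusion counts", {
  # construct windows whose overlap yields known TP/FP/TN/FN epoch counts on
  # a 1-minute grid: diary 22:00-06:00 (480 pos), algorithm 23:00-07:00
  onset_d <- t_utc("22:00:00"); wake_d <- t_utc("06:00:00", "2024-03-05")
  onset_a <- t_utc("23:00:00"); wake_a <- t_utc("07:00:00", "2024-03-05")
  cmp <- compare_diary(one_window(onset_a, wake_a),
                       make_diary(onset_d, wake_d), grid_epoch = 60)
  tp <- 420; fn <- 60; fp <- 60; tn <- 1440 - tp - fn - fp
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  expect_equal(tidy(cmp)$c_statistic, (sens + spec) / 2, tolerance = 1e-12)
  expect_equal(tidy(cmp)$accuracy_pct, 100 * (tp + tn) / 1440, tolerance = 1e-12)
  # combined MAE pools onset and wake errors
  expect_equal(glance(cmp)$mae_combined_min, mean(c(60, 60)))
})

test_that("wakefulness stratification uses left-closed hour bins", {
  nights <- tibble::tibble(waso_min = c(30, 45, 60, 90, 125, 250),
                           duration_diff = c(10, 20, -5, -15, -60, -200))
  s <- stratify_by_wakefulness(nights)
  expect_equal(as.character(s$category), c("[0-1)", "[1-2)", "[2-3)", ">=4"))
  # exactly 60 minutes falls in [1-2)
  expect_equal(s$n[s$category == "[1-2)"], 2L)
  expect_equal(s$mean_duration_diff_min[s$category == "[0-1)"], 15)
  expect_equal(sum(s$prevalence_pct), 100)
  # all nights under an hour: a single category
  s1 <- stratify_by_wakefulness(tibble::tibble(waso_min = rep(30, 4),
                                               duration_diff = 1:4))
  expect_equal(nrow(s1), 1)
})

test_that("wakefulness padding adds the right number of epochs and stages", {
  z <- es(rep(10, 720), kind = "z_angle", start = t_utc("23:00:00"))
  h <- tibble::tibble(time = t_utc("23:00:00") + (0:119) * 30,
                      stage = rep("N2", 120))
  attr(h, "epoch_length") <- 30
  p <- pad_with_wakefulness(z, h, pad = 90, seed = 5)
  expect_equal(nrow(p$z), 720 + 2 * 90 * 12)
  expect_equal(nrow(p$hypnogram), 120 + 2 * 90 * 2)
  expect_true(all(p$hypnogram$stage[1:180] == "W"))
  expect_true(all(abs(p$z$value) <= 90))
  expect_identical(p$z$value[1081:1800], z$value)
  # reproducible under the same seed, different under another
  p2 <- pad_with_wakefulness(z, h, pad = 90, seed = 5)
  expect_identical(p$z, p2$z)
  p3 <- pad_with_wakefulness(z, h, pad = 90, seed = 6)
  expect_false(identical(p$z$value, p3$z$value))
  # zero-length input: a pad-only series of 2 * pad minutes
  z0 <- es(numeric(0), kind = "z_angle")
  attr(z0, "start_time") <- t_utc("23:00:00")
  expect_equal(nrow(pad_with_wakefulness(z0, pad = 90, seed = 1)$z), 2160)
  expect_error(pad_with_wakefulness(z, h, pad = 90), "seed")
})

test_that("an all-N2 constant-angle night is classified perfectly", {
  z <- es(rep(20, 8 * 720), kind = "z_angle", start = t_utc("23:00:00"))
  h <- tibble::tibble(time = t_utc("23:00:00") + (0:(8 * 120 - 1)) * 30,
                      stage = rep("N2", 8 * 120))
  attr(h, "epoch_length") <- 30
  cmp <- compare_psg(z, h, seed = 11)
  g <- glance(cmp)
  expect_equal(g$accuracy_pct, 100, tolerance = 0.2)
  expect_equal(tidy(cmp)$sensitivity_pct, 100, tolerance = 5e-4)
  expect_equal(g$c_statistic_24h, 1, tolerance = 0.005)
  # bookkeeping: evaluated span is the real span plus 2 * (pad - trim)
  expect_equal(g$eval_span_min, g$real_span_min + 60)
  # fixed seed: bit-reproducible
  cmp2 <- compare_psg(z, h, seed = 11)
  expect_identical(glance(cmp), glance(cmp2))
})

test_that("a programmed mid-night long wake splits the window as expected", {
  # 90-minute wake >= the 60-minute gap limit: the detector keeps the longer
  # segment, so PSG-minus-algorithm duration is about the dropped part
  fx <- generate_psg_fixture(seed = 12, duration_hr = 9.5, latency_min = 15,
                             wake_after_min = 10, fixed_stage = "N2")
  # inject a 90-minute W block 3 h after sleep onset into hypnogram and angle
  h <- fx$hypnogram
  i_on <- which(h$stage != "W")[1]
  wi <- i_on + (3 * 120):(3 * 120 + 179)
  h$stage[wi] <- "W"
  z <- fx$z
  zi <- (i_on - 1) * 6 + (3 * 720):(3 * 720 + 1079)
  z$value[zi] <- fold_angle_t(withr::with_seed(13, cumsum(rnorm(1080, 0, 8))))
  cmp <- compare_psg(z, h, seed = 14)
  seg1 <- 180 # minutes before the wake block
  real_sleep_span <- as.numeric(
    diff(range(which(h$stage != "W"))) + 1, units = "mins") / 2 # 30-s epochs
  seg2 <- real_sleep_span - seg1 - 90
  longer <- max(seg1, seg2)
  expect_equal(glance(cmp)$duration_diff_min, real_sleep_span - longer,
               tolerance = 12)
})

test_that("24-hour expansion can only improve accuracy when daytime is correct", {
  for (s in c(21, 22, 23)) {
    fx <- generate_psg_fixture(seed = s)
    cmp <- compare_psg(fx$z, fx$hypnogram, seed = s + 100)
    g <- glance(cmp)
    expect_gte(g$accuracy_24h_pct, g$accuracy_pct - 1e-9)
  }
})

test_that("the parameter sweep reproduces single-run errors and rejects empty input", {
  corpus <- purrr::map(1:3, function(s) {
    rec <- generate_recording(night_spec(seed = s), sample_rate = 10)
    list(var_stat = rolling_var_statistic(compute_z_angle(rec$raw)),
         truth = rec$truth)
  })
  sw <- parameter_sweep(corpus, tibble::tibble(multiplier = 15))
  expect_equal(nrow(sw), 1)
  expect_true(sw$is_default)
  expect_equal(sw$n_nights, 3)
  # grid of one equals direct per-recording errors
  direct <- purrr::map_dfr(corpus, function(rec) {
    w <- detect_spt_multiday(rec$var_stat)
    tibble::tibble(e_on = abs(diff_minutes(w$onset, rec$truth$onset)),
                   e_wk = abs(diff_minutes(w$wake, rec$truth$wake)))
  })
  expect_equal(sw$mean_abs_onset_err_min, mean(direct$e_on))
  expect_equal(sw$mean_abs_wake_err_min, mean(direct$e_wk))
  # multiplier grid: detected duration is monotone non-decreasing
  sw3 <- parameter_sweep(corpus, tibble::tibble(multiplier = c(10, 15, 20)))
  expect_true(all(diff(sw3$mean_duration_min) >= 0))
  expect_false(sw3$is_default[1] || sw3$is_default[3])
  expect_error(parameter_sweep(list(), tibble::tibble(multiplier = 15)), "empty")
  expect_error(parameter_sweep(corpus, tibble::tibble(multiplier = numeric(0))),
               "at least one row")
})
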