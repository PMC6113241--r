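test_that("the adaptive threshold is the day percentile times the multiplier", {
  vs <- es(rep(0.2, 17280))
  expect_equal(derive_threshold(vs, as.Date("2024-03-04")), 3.0)
  # clamp floor engages on a nearly motionless recording
  vs_low <- es(rep(0.001, 17280))
  p <- hdcza_params(clamp = c(0.13, 0.50))
  expect_equal(derive_threshold(vs_low, as.Date("2024-03-04"), p), 0.13)
  # clamp ceiling
  vs_high <- es(rep(1, 17280))
  expect_equal(derive_threshold(vs_high, as.Date("2024-03-04"), p), 0.50)
  expect_error(derive_threshold(vs, as.Date("2030-01-01")), "no variance")
})

test_that("the threshold percentile matches a sort-and-index oracle on mixtures", {
  withr::with_seed(52, {
    for (i in 1:20) {
      vals <- c(abs(rnorm(300, 0.03, 0.01)), abs(rnorm(150, 2, 0.5)))
      vals <- sample(vals)
      vs <- es(vals)
      expect_equal(derive_threshold(vs, NULL),
                   oracle_percentile(vals, 0.10) * 15, tolerance = 1e-12)
    }
  })
})

test_that("block detection keeps only runs lasting longer than the minimum", {
  # everything below threshold: one block spanning the series
  vs <- es(rep(0.1, 500))
  b <- detect_blocks(vs, 1)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_min, 500 * 5 / 60)
  # a 25-minute run is discarded (25 < 30)
  vals <- c(rep(2, 100), rep(0.1, 300), rep(2, 100)) # 300 epochs = 25 min
  expect_equal(nrow(detect_blocks(es(vals), 1)), 0)
  # exactly 30 minutes is discarded too (strictly longer than)
  vals <- c(rep(2, 100), rep(0.1, 360), rep(2, 100))
  expect_equal(nrow(detect_blocks(es(vals), 1)), 0)
  expect_equal(nrow(detect_blocks(es(c(rep(2, 100), rep(0.1, 361), rep(2, 100))), 1)), 1)
})

test_that("block detection equals a run-length oracle on random binary patterns", {
  withr::with_seed(53, {
    p <- hdcza_params(min_block = 2) # short blocks so patterns stay small
    for (i in 1:50) {
      vals <- ifelse(runif(400) < 0.5, 0.1, 2)
      got <- detect_blocks(es(vals), 1, p)
      want <- oracle_blocks(vals, 1, 5, 2)
      expect_equal(nrow(got), length(want))
      for (j in seq_along(want)) {
        i0 <- want[[j]][1]; i1 <- want[[j]][2]
        expect_equal(got$start[j], t_utc("12:00:00") + (i0 - 1) * 5)
        expect_equal(got$end[j], t_utc("12:00:00") + i1 * 5)
      }
    }
  })
})

test_that("gap absorption merges short gaps transitively and leaves long gaps", {
  t0 <- t_utc("22:00:00")
  blocks <- tibble::tibble(
    start = c(t0, t0 + 7 * 3600 + 50 * 60),
    end = c(t0 + 7 * 3600, t0 + 7 * 3600 + 95 * 60),
    duration_min = c(420, 45), n_blocks = c(1L, 1L)
  )
  merged <- absorb_gaps(blocks)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$duration_min, 8 * 60 + 35) # 7 h + 50 min gap + 45 min
  expect_equal(merged$n_blocks, 2L)

  far <- blocks
  far$start[2] <- t0 + 7 * 3600 + 90 * 60
  far$end[2] <- far$start[2] + 45 * 60
  expect_equal(nrow(absorb_gaps(far)), 2) # 90 >= 60: unchanged

  # a gap of exactly 60 minutes is not absorbed (strict <)
  exact <- blocks
  exact$start[2] <- t0 + 7 * 3600 + 60 * 60
  exact$end[2] <- exact$start[2] + 45 * 60
  expect_equal(nrow(absorb_gaps(exact)), 2)
})

test_that("gap absorption reaches the fixed point of repeated pairwise merging", {
  withr::with_seed(54, {
    t0 <- t_utc("12:00:00")
    for (i in 1:100) {
      n <- sample(1:6, 1)
      starts <- sort(sample(0:2000, n)) * 60
      lens <- sample(30:400, n, replace = TRUE) * 60
      ends <- starts + lens
      if (n > 1) { # enforce ordered, non-overlapping blocks
        for (j in 2:n) {
          starts[j] <- max(starts[j], ends[j - 1] + 60)
          ends[j] <- starts[j] + lens[j]
        }
      }
      blocks <- tibble::tibble(start = t0 + starts, end = t0 + ends,
                               duration_min = lens / 60, n_blocks = 1L)
      got <- absorb_gaps(blocks)
      # express the oracle on an epoch index grid (1 epoch = 60 s here)
      want <- oracle_merge(purrr::map(seq_len(n), function(j) {
        c(starts[j] / 60 + 1, ends[j] / 60)
      }), 60, 60)
      expect_equal(nrow(got), length(want))
      for (j in seq_along(want)) {
        expect_equal(as.numeric(got$start[j] - t0, units = "mins"), want[[j]][1] - 1)
        expect_equal(as.numeric(got$end[j] - t0, units = "mins"), want[[j]][2])
      }
      # all residual gaps are at least the maximum absorbed gap
      if (nrow(got) > 1) {
        gaps <- as.numeric(got$start[-1] - head(got$end, -1), units = "mins")
        expect_true(all(gaps >= 60))
      }
    }
  })
})

test_that("the longest merged block becomes the window; ties go to the earliest", {
  day <- as.Date("2024-03-04")
  # two quiescent stretches, 6 h and 3 h, separated by 3 h of movement
  vals <- day_var_values(list(c(10, 16), c(19, 22)))
  w <- detect_spt(es(vals), day)
  expect_equal(nrow(w), 1)
  expect_equal(as.numeric(w$onset - t_utc("12:00:00"), units = "hours"), 10,
               tolerance = 0.1)
  expect_equal(w$duration_min, 360, tolerance = 6)
  # continuous movement with a clamped threshold: no window
  busy <- es(day_var_values(list()))
  expect_equal(nrow(detect_spt(busy, day, hdcza_params(clamp = c(0.13, 0.50)))), 0)
  # equal-length stretches: earliest wins
  vals_tie <- c(rep(2, 720), rep(0.01, 720), rep(2, 720), rep(0.01, 720), rep(2, 720))
  w_tie <- detect_spt(es(vals_tie), day)
  expect_equal(w_tie$onset, t_utc("12:00:00") + 720 * 5)
})

test_that("full chain matches the naive reference on randomized series", {
  withr::with_seed(55, {
    for (i in 1:40) {
      vals <- day_var_values(list(c(runif(1, 8, 11), runif(1, 16, 20))),
                             seed = 1000 + i)
      got <- detect_spt(es(vals), as.Date("2024-03-04"))
      want <- oracle_spt_chain(vals, 5)
      expect_equal(got$threshold_used_deg, want[3], tolerance = 1e-9)
      expect_equal(as.numeric(got$onset - t_utc("12:00:00"), units = "secs"), (want[1] - 1) * 5,
                   tolerance = 1e-9)
      expect_equal(as.numeric(got$wake - t_utc("12:00:00"), units = "secs"), want[2] * 5,
                   tolerance = 1e-9)
    }
  })
})

test_that("multi-day detection returns one row per day with containment", {
  vals3 <- c(day_var_values(list(c(11, 19)), seed = 61),
             day_var_values(list(c(11.5, 19)), seed = 62),
             day_var_values(list(c(10.5, 18.5)), seed = 63))
  vs <- es(vals3)
  w <- detect_spt_multiday(vs)
  expect_equal(nrow(w), 3)
  expect_true(all(!is.na(w$onset)))
  expect_true(all(w$onset < w$wake))
  expect_equal(w$day_id, as.Date("2024-03-04") + 0:2)
  # containment in the noon-noon day
  expect_true(all(noon_day_id(w$onset) == w$day_id))
  expect_true(all(noon_day_id(w$wake - 1) == w$day_id))
  # a day of continuous movement yields an NA row under a clamped threshold
  vals2 <- c(day_var_values(list(c(11, 19)), seed = 64),
             day_var_values(list(), seed = 65))
  w2 <- detect_spt_multiday(es(vals2), hdcza_params(clamp = c(0.13, 0.50)))
  expect_equal(nrow(w2), 2)
  expect_true(!is.na(w2$onset[1]) && is.na(w2$onset[2]))
  # empty series: zero rows
  expect_equal(nrow(detect_spt_multiday(es(numeric(0)))), 0)
})

test_that("clamped thresholds always stay inside the clamp range", {
  p <- hdcza_params(clamp = c(0.13, 0.50))
  withr::with_seed(56, {
    for (i in 1:20) {
      vals <- abs(rnorm(1000, runif(1, 0.001, 3), 0.3))
      thr <- derive_threshold(es(vals), NULL, p)
      expect_gte(thr, 0.13)
      expect_lte(thr, 0.50)
    }
  })
})

test_that("parameter validation rejects invalid settings", {
  expect_error(hdcza_params(percentile = 0), "percentile")
  expect_error(hdcza_params(multiplier = -1), "multiplier")
  expect_error(hdcza_params(clamp = c(2, 1)), "clamp")
  expect_error(detect_blocks(es(rep(0.1, 10)), -1), "threshold")
})
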