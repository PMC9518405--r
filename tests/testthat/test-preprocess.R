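test_that("sliding-window counts follow the segmentation formula", {
  rec20 <- generate_record(500, 20, seed = 1)
  expect_length(segment_signal(rec20, 5, 1), 16L)
  rec25 <- generate_record(500, 25, seed = 1)
  expect_length(segment_signal(rec25, 5, 1), 21L)
  rec5 <- generate_record(500, 5, seed = 1)
  expect_length(segment_signal(rec5, 5, 1), 1L)
  # property: count == floor((duration - window)/step) + 1
  set.seed(42)
  for (i in 1:10) {
    dur <- runif(1, 6, 30)
    win <- runif(1, 1, 5)
    step <- runif(1, 0.5, 2)
    rec <- list(samples = numeric(round(100 * dur)), fs = 100)
    wins <- segment_signal(rec, win, step)
    expect_length(wins, floor((length(rec$samples) / 100 - win) / step) + 1L)
    expect_true(all(lengths(wins) == round(win * 100)))
  }
  expect_warning(out <- segment_signal(rec5, 10, 1), "shorter")
  expect_length(out, 0L)
})

test_that("windows are ordered and aligned to step multiples", {
  rec <- generate_record(500, 20, seed = 2)
  wins <- segment_signal(rec, 5, 1)
  starts <- attr(wins, "starts_s")
  expect_equal(starts, 0:15)
  expect_identical(wins[[2]][1], rec$samples[501])
})

test_that("resampling preserves DC, identity, and tone frequency", {
  expect_equal(resample_window(rep(2.5, 1234), 500L), rep(2.5, 500L),
               tolerance = 1e-9)
  x <- rnorm(500)
  expect_identical(resample_window(x, 500L), x)
  t <- (0:2499) / 500
  y <- resample_window(sin(2 * pi * 5 * t), 500L)
  expect_length(y, 500L)
  sp <- amplitude_spectrum(y, 100)
  expect_equal(sp$freq[which.max(sp$amp)], 5)
  expect_error(resample_window(x, 600L), "target_len")
  expect_error(resample_window(numeric(0)), "empty")
})

test_that("min-max normalization matches its closed form and contracts", {
  m <- fit_minmax(cbind(a = c(0, 5, 10), b = c(3, 3, 3)))
  out <- apply_minmax(m, cbind(c(0, 5, 10), c(3, 3, 3)))
  expect_equal(out[, 1], c(0, 0.5, 1))
  expect_equal(out[, 2], c(0, 0, 0))   # constant feature -> 0
  expect_equal(apply_minmax(m, cbind(20, 3))[1, 1], 2)  # extrapolation
  expect_error(apply_minmax(m, matrix(1, 2, 3)), "mismatch")
  # idempotence: renormalizing already-normalized training data is identity
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3)
  m1 <- fit_minmax(x)
  y <- apply_minmax(m1, x)
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(apply_minmax(fit_minmax(y), y), y, tolerance = 1e-12)
})

test_that("Fisher-Yates labelling follows the rank rule", {
  fy <- fisher_yates_labels(c(3L, 4L, 5L))
  expect_identical(fy$labels, c(1L, 1L, 0L))  # Worse, Worse, Better
  expect_equal(fy$values, qnorm((1:3) / 4))
  # ties: an all-identical series sits at the median rank -> score 0 -> Worse
  same <- fisher_yates_labels(rep(3L, 6))
  expect_equal(same$values, rep(0, 6))
  expect_identical(same$labels, rep(1L, 6))
  expect_error(fisher_yates_labels(c(2L, 6L)), "1..5")
  # monotone in HI within a subject; label marginal identity
  set.seed(3)
  for (i in 1:10) {
    hi <- sample(1:5, 12, replace = TRUE)
    fy <- fisher_yates_labels(hi)
    expect_true(all(diff(fy$values[order(hi)]) >= -1e-12))
    expect_equal(mean(fy$labels == 0L), mean(fy$values > 0))
  }
})

test_that("segment datasets carry labels, provenance, and the lag", {
  co <- generate_cohort(cohort_spec(2, 6, duration_range_s = c(8, 10),
                                    seed = 5))
  ds0 <- make_segment_dataset(co, window_s = 5, step_s = 1,
                              target_len = 250L, lag = 0L)
  expect_s3_class(ds0, "segment_dataset")
  expect_identical(ncol(ds0$segments), 250L)
  expect_identical(nrow(ds0$segments), length(ds0$labels))
  expect_true(all(ds0$labels %in% 0:1))
  expect_identical(nrow(ds0$segments), nrow(ds0$meta))
  # one-day-forward pairing drops each subject's last day
  ds1 <- make_segment_dataset(co, window_s = 5, step_s = 1,
                              target_len = 250L, lag = 1L)
  expect_true(all(ds1$meta$label_day == ds1$meta$day_index + 1L))
  expect_false(any(ds1$meta$day_index == 6L))
})
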