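test_that("record generation is seeded, sized, and validated", {
  r1 <- generate_record(fs = 500, duration_s = 20, wellness_class = "better",
                        seed = 1)
  r2 <- generate_record(fs = 500, duration_s = 20, wellness_class = "better",
                        seed = 1)
  expect_identical(r1$samples, r2$samples)
  expect_length(r1$samples, 10000L)
  expect_true(all(is.finite(r1$samples)))
  r3 <- generate_record(fs = 500, duration_s = 20, wellness_class = "worse",
                        seed = 1)
  expect_length(r3$samples, 10000L)
  expect_error(generate_record(fs = -1), "fs")
  expect_error(generate_record(duration_s = 0), "duration")
  expect_error(generate_record(class_effect = -0.5), "class_effect")
})

test_that("worse records have stochastically larger beat-interval spread", {
  bsd <- vapply(1:50, function(s)
    sd(generate_record(500, 20, "better", class_effect = 1.5, seed = s)$rr_s),
    numeric(1))
  wsd <- vapply(101:150, function(s)
    sd(generate_record(500, 20, "worse", class_effect = 1.5, seed = s)$rr_s),
    numeric(1))
  p <- wilcox.test(wsd, bsd, alternative = "greater")$p.value
  expect_lt(p, 1e-4)
})

test_that("amplitude ranges of the two classes overlap", {
  rb <- range(generate_record(500, 20, "better", seed = 3)$samples)
  rw <- range(generate_record(500, 20, "worse", seed = 4)$samples)
  expect_lt(max(rb[1], rw[1]), min(rb[2], rw[2]))
})

test_that("irregularity raises multiscale entropy at coarse scales", {
  # Monte-Carlo: mean sample entropy at scale tau = 10 differs between the
  # regularity regimes beyond 2 pooled standard errors (50 segments/class)
  tau10_entropy <- function(cls, seeds) {
    vapply(seeds, function(s) {
      x <- make_test_segment(seed = s, wellness_class = cls)
      r_abs <- 0.15 * sd(x)
      cnt <- c(0, 0)
      for (k in 1:10)
        cnt <- cnt + sample_entropy_counts(coarse_grain(x, 10L, k), 2L, r_abs)
      -log(cnt[2] / cnt[1])
    }, numeric(1))
  }
  b <- tau10_entropy("better", 1:50)
  w <- tau10_entropy("worse", 201:250)
  pooled_se <- sqrt(var(b) / length(b) + var(w) / length(w))
  expect_gt(mean(w) - mean(b), 2 * pooled_se)
})

test_that("cohort generation is reproducible with coupled HI and class", {
  sp <- cohort_spec(n_subjects = 2, days_per_subject = 10, seed = 7)
  co <- generate_cohort(sp)
  expect_length(co, 20L)
  keys <- vapply(co, function(r) paste(r$subject_id, r$day_index), "")
  expect_length(unique(keys), 20L)
  his <- vapply(co, `[[`, 1L, "hi")
  expect_true(all(his %in% 1:5))
  co2 <- generate_cohort(sp)
  expect_identical(his, vapply(co2, `[[`, 1L, "hi"))
  expect_identical(co[[5]]$samples, co2[[5]]$samples)
  # non-degenerate ordinal distribution -> within-subject HI variability
  by_subj <- split(his, vapply(co, `[[`, "", "subject_id"))
  expect_true(all(vapply(by_subj, function(h) length(unique(h)) > 1L,
                         logical(1))))
  # waveform regime tied to the label rule: Fisher-Yates > 0 <=> "better"
  for (subj in split(seq_along(co), vapply(co, `[[`, "", "subject_id"))) {
    fy <- fisher_yates_labels(vapply(co[subj], `[[`, 1L, "hi"))
    cls <- vapply(co[subj], `[[`, "", "wellness_class")
    expect_identical(cls == "better", fy$values > 0)
  }
})

test_that("cohort CSV writer and reader round-trip", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(2, 3, duration_range_s = c(6, 8),
                                    seed = 2))
  write_cohort_csv(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort_csv(dir)
  expect_length(back, 6L)
  i <- 4L
  expect_equal(back[[i]]$samples, co[[i]]$samples, tolerance = 1e-6)
  expect_identical(back[[i]]$hi, co[[i]]$hi)
  expect_identical(back[[i]]$subject_id, co[[i]]$subject_id)
})
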