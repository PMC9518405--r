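test_that("coarse-graining takes offset block means", {
  x <- c(1, 2, 3, 4)
  expect_identical(coarse_grain(x, 1L, 1L), x)
  expect_equal(coarse_grain(x, 2L, 1L), c(1.5, 3.5))
  expect_equal(coarse_grain(x, 2L, 2L), 2.5)
  expect_error(coarse_grain(x, 2L, 3L), "1..tau")
  expect_error(coarse_grain(x, 2L, 0L), "1..tau")
  set.seed(2)
  y <- rnorm(101)
  expect_length(coarse_grain(y, 7L, 3L), (101 - 3 + 1) %/% 7)
})

test_that("template match counts equal the brute-force oracle exactly", {
  # all-match and no-match boundary cases
  cst <- sample_entropy_counts(rep(1, 20), 2L, 0.1)
  expect_identical(unname(cst[1]), unname(cst[2]))
  expect_equal(unname(cst[2] / cst[1]), 1)
  apart <- sample_entropy_counts(c(0, 10, 40, 90, 160, 250), 2L, 1)
  expect_equal(unname(apart), c(0, 0))
  set.seed(13)
  for (i in 1:5) {
    y <- rnorm(200)
    r_abs <- 0.2 * sd(y)
    expect_identical(unname(sample_entropy_counts(y, 2L, r_abs)),
                     unname(as.numeric(sampen_oracle(y, 2L, r_abs))))
  }
  expect_error(sample_entropy_counts(rnorm(3), 2L, 0.1), "short")
})

test_that("RCMSE at scale 1 is sample entropy; constants give 0", {
  set.seed(21)
  x <- rnorm(500)
  curve <- rcmse(x, rcmse_params(tau_max = 5))
  cnt <- sample_entropy_counts(x, 2L, 0.15 * sd(x))
  expect_equal(as.numeric(curve)[1], -log(unname(cnt[2] / cnt[1])))
  cc <- suppressWarnings(rcmse(rep(2, 100), rcmse_params(tau_max = 4)))
  expect_equal(as.numeric(cc), rep(0, 4))
  expect_error(rcmse(rnorm(30), rcmse_params(tau_max = 20)), "short")
})

test_that("white-noise entropy decreases with scale", {
  set.seed(31)
  curves <- replicate(20, {
    as.numeric(rcmse(rnorm(2000), rcmse_params(tau_max = 10)))
  })
  expect_true(all(diff(rowMeans(curves)) < 0))
})

test_that("undefined scales are imputed 0, flagged, and warned about", {
  set.seed(41)
  x <- rnorm(120)
  expect_warning(curve <- rcmse(x, rcmse_params(r = 1e-8, tau_max = 5)),
                 "undefined")
  undef <- attr(curve, "undefined")
  expect_true(any(undef))
  expect_true(all(curve[undef] == 0))
})

test_that("composite counting yields no more undefined scales than naive MSE", {
  set.seed(51)
  n_rc <- 0L
  n_naive <- 0L
  for (i in 1:20) {
    x <- rnorm(300)
    curve <- suppressWarnings(rcmse(x, rcmse_params(tau_max = 20)))
    n_rc <- n_rc + sum(attr(curve, "undefined"))
    n_naive <- n_naive + sum(naive_mse_undefined(x, 2L, 0.15, 20L))
  }
  expect_lte(n_rc, n_naive)
})

test_that("the 20-scale feature block serializes the entropy curve", {
  x <- make_test_segment(seed = 15)
  v <- rcmse_features(x)
  expect_length(v, 20L)
  expect_identical(names(v), paste0("F", 165:184))
  expect_identical(v, rcmse_features(x))
  p <- rcmse_params()
  r_abs <- p$r * sd(x)
  for (tau in c(1L, 7L, 20L)) {
    cnt <- c(0, 0)
    for (k in seq_len(tau))
      cnt <- cnt + sample_entropy_counts(coarse_grain(x, tau, k), p$m, r_abs)
    expect_equal(unname(v[tau]), -log(unname(cnt[2] / cnt[1])))
  }
})
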