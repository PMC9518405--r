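# Shared fixtures and independent oracles for the test suite.

# A resampled 500-point segment from a seeded synthetic record.
make_test_segment <- function(seed = 1L, wellness_class = "better",
                              duration_s = 20) {
  rec <- generate_record(fs = 500, duration_s = duration_s,
                         wellness_class = wellness_class, seed = seed)
  resample_window(segment_signal(rec)[[1L]], 500L)
}

# Brute-force O(n^2) template-pair counting oracle for sample entropy:
# plain double loop, independent of the package's counting code.
sampen_oracle <- function(y, m, r_abs) {
  n <- length(y)
  nt <- n - m
  Bm <- 0L
  Bm1 <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      d <- max(abs(y[i:(i + m - 1L)] - y[j:(j + m - 1L)]))
      if (d <= r_abs) {
        Bm <- Bm + 1L
        if (abs(y[i + m] - y[j + m]) <= r_abs) Bm1 <- Bm1 + 1L
      }
    }
  }
  c(B_m = Bm, B_m1 = Bm1)
}

# Naive (single-offset) multiscale sample entropy: undefined scales flagged.
naive_mse_undefined <- function(x, m, r_frac, tau_max) {
  r_abs <- r_frac * stats::sd(x)
  vapply(seq_len(tau_max), function(tau) {
    cnt <- sample_entropy_counts(coarse_grain(x, tau, 1L), m, r_abs)
    cnt[1L] == 0 || cnt[2L] == 0
  }, logical(1))
}

# Fast EEMD config for cohort-scale extraction in tests.
fast_feature_configs <- function(seed = 1L) {
  feature_configs(eemd = eemd_config(trials = 10L, seed = seed))
}
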