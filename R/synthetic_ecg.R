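#' Synthetic single-lead ECG records
#'
#' Generates a seeded, quasi-periodic ECG-like waveform built from a per-beat
#' template of Gaussian bumps (P, Q, R, S, T) on a jittered beat grid, plus
#' additive Gaussian measurement noise. Two regularity regimes are supported:
#' \code{"better"} records have low beat-to-beat interval and morphology
#' variability, \code{"worse"} records have both inflated by
#' \code{class_effect}. The amplitude range of the two regimes is deliberately
#' similar; the classes differ in regularity, not in scale.
#'
#' @param fs Sampling rate in Hz (default 500).
#' @param duration_s Record duration in seconds.
#' @param wellness_class \code{"better"} or \code{"worse"}.
#' @param class_effect Non-negative regularity contrast between classes; 0
#'   makes the classes indistinguishable.
#' @param seed Integer seed; identical arguments reproduce identical samples.
#' @param snr_db Signal-to-noise ratio of the additive measurement noise, in
#'   dB (default 20).
#' @param subject_id,day_index,hi Optional provenance fields stored on the
#'   record.
#' @return An object of class \code{ecg_record}: a list with \code{samples},
#'   \code{fs}, \code{subject_id}, \code{day_index}, \code{hi},
#'   \code{wellness_class} and the realized beat intervals \code{rr_s}.
#' @export
generate_record <- function(fs = 500, duration_s = 20,
                            wellness_class = c("better", "worse"),
                            class_effect = 1.5, seed = 1L, snr_db = 20,
                            subject_id = "S1", day_index = 1L, hi = NA_integer_) {
  wellness_class <- match.arg(wellness_class)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("`duration_s` must be a single positive number", call. = FALSE)
  if (class_effect < 0)
    stop("`class_effect` must be >= 0", call. = FALSE)

  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1L) / fs
  sev <- if (wellness_class == "worse") class_effect else 0

  with_seed(seed, {
    rr_mean <- 0.8                      # ~75 bpm resting elderly
    rr_sd <- 0.02 * (1 + sev)           # beat-interval jitter, inflated if worse
    n_beats <- ceiling(duration_s / (rr_mean - 4 * min(rr_sd, 0.1))) + 3L
    rr <- rr_mean * pmax(0.5, 1 + rnorm(n_beats, 0, rr_sd / rr_mean))
    r_times <- cumsum(rr) - rr[1L] * 0.5
    keep <- r_times < duration_s + 0.5
    r_times <- r_times[keep]

    # P-QRS-T morphology: (offset s, amplitude, width s) per bump
    bumps <- list(
      P = c(-0.20, 0.15, 0.030),
      Q = c(-0.028, -0.10, 0.012),
      R = c(0.00, 1.00, 0.014),
      S = c(0.030, -0.18, 0.012),
      T = c(0.28, 0.30, 0.060)
    )
    clean <- numeric(n)
    amp_sd <- 0.03 * (1 + sev)          # per-beat morphology perturbation
    for (rt in r_times) {
      gain <- max(0.2, 1 + rnorm(1L, 0, amp_sd))
      wmul <- max(0.5, 1 + rnorm(1L, 0, amp_sd / 2))
      for (b in bumps) {
        mu <- rt + b[1L]
        sdw <- b[3L] * wmul
        lo <- max(1L, floor((mu - 5 * sdw) * fs) + 1L)
        hiidx <- min(n, ceiling((mu + 5 * sdw) * fs) + 1L)
        if (lo > hiidx) next
        idx <- lo:hiidx
        clean[idx] <- clean[idx] +
          gain * b[2L] * exp(-((t[idx] - mu)^2) / (2 * sdw^2))
      }
    }
    noise_sd <- stats::sd(clean) * 10^(-snr_db / 20)
    samples <- clean + rnorm(n, 0, noise_sd)

    structure(
      list(samples = samples, fs = fs, subject_id = subject_id,
           day_index = as.integer(day_index), hi = as.integer(hi),
           wellness_class = wellness_class,
           rr_s = rr[seq_along(r_times)]),
      class = "ecg_record"
    )
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject %s day %d: %d samples @ %g Hz (%.1f s), HI=%s, class=%s\n",
              x$subject_id, x$day_index, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              ifelse(is.na(x$hi), "?", x$hi), x$wellness_class))
  invisible(x)
}

#' Cohort specification for the synthetic generator
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param days_per_subject Days of daily records per subject (>= 1).
#' @param fs Sampling rate in Hz.
#' @param duration_range_s Min/max record duration in seconds; each record's
#'   duration is drawn uniformly from this range.
#' @param class_effect Regularity contrast passed to [generate_record()].
#' @param hi_probs Marginal probabilities of the ordinal health-index levels
#'   1..5 (self-rated Poor..Excellent).
#' @param hi_rho Day-to-day persistence of the latent wellness process
#'   (AR(1) coefficient in \[0, 1)); wellness on consecutive days is
#'   correlated, which is what makes one-day-forward prediction informative.
#' @param snr_db Measurement-noise SNR in dB.
#' @param seed Master seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects, days_per_subject, fs = 500,
                        duration_range_s = c(20, 25), class_effect = 1.5,
                        hi_probs = c(0.08, 0.17, 0.30, 0.27, 0.18),
                        hi_rho = 0.6, snr_db = 20, seed = 1L) {
  stopifnot(n_subjects >= 1, days_per_subject >= 1, fs > 0,
            length(duration_range_s) == 2L,
            duration_range_s[1L] > 0,
            duration_range_s[2L] >= duration_range_s[1L],
            class_effect >= 0, length(hi_probs) == 5L, all(hi_probs >= 0),
            hi_rho >= 0, hi_rho < 1)
  structure(
    list(n_subjects = as.integer(n_subjects),
         days_per_subject = as.integer(days_per_subject), fs = fs,
         duration_range_s = duration_range_s, class_effect = class_effect,
         hi_probs = hi_probs / sum(hi_probs), hi_rho = hi_rho,
         snr_db = snr_db, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic subject-day ECG cohort
#'
#' One record per subject-day. Each subject's daily health index (HI, ordinal
#' 1..5) follows a latent AR(1) wellness process discretized by the marginal
#' level probabilities, so wellness persists from day to day. The waveform
#' regularity regime of each record is tied monotonically to HI through the
#' same rank-based rule the labelling stage applies downstream: days whose
#' Fisher-Yates normal score (within the subject's own HI series) is positive
#' are generated in the "better" regime, the rest in the "worse" regime.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class \code{ecg_cohort}: a list of
#'   \code{ecg_record}s with a \code{spec} attribute.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  J <- spec$n_subjects
  I <- spec$days_per_subject
  seeds <- spawn_seeds(spec$seed, J * (I + 2L))
  records <- vector("list", J * I)
  k <- 0L
  for (j in seq_len(J)) {
    sid <- sprintf("S%02d", j)
    hi <- with_seed(seeds[(j - 1L) * (I + 2L) + 1L],
                    simulate_hi_series(I, spec$hi_probs, spec$hi_rho))
    fy <- fisher_yates_values(hi)
    cls <- ifelse(fy > 0, "better", "worse")
    dur <- with_seed(seeds[(j - 1L) * (I + 2L) + 2L],
                     runif(I, spec$duration_range_s[1L],
                           spec$duration_range_s[2L]))
    for (i in seq_len(I)) {
      k <- k + 1L
      records[[k]] <- generate_record(
        fs = spec$fs, duration_s = dur[i], wellness_class = cls[i],
        class_effect = spec$class_effect,
        seed = seeds[(j - 1L) * (I + 2L) + 2L + i], snr_db = spec$snr_db,
        subject_id = sid, day_index = i, hi = hi[i]
      )
    }
  }
  structure(records, class = "ecg_cohort", spec = spec)
}

# Latent AR(1) wellness discretized to the ordinal 1..5 scale by the
# quantile breaks of the marginal level probabilities.
simulate_hi_series <- function(n_days, probs, rho) {
  z <- numeric(n_days)
  z[1L] <- rnorm(1L)
  if (n_days > 1L) {
    innov <- rnorm(n_days - 1L, 0, sqrt(1 - rho^2))
    for (i in 2L:n_days) z[i] <- rho * z[i - 1L] + innov[i - 1L]
  }
  breaks <- qnorm(cumsum(probs)[-5L])
  as.integer(findInterval(z, breaks) + 1L)
}

#' @export
print.ecg_cohort <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<ecg_cohort> %d records (%d subjects x %d days) @ %g Hz\n",
              length(x), sp$n_subjects, sp$days_per_subject, sp$fs))
  invisible(x)
}

#' Write / read a cohort as plain CSV files
#'
#' One two-column CSV (\code{time_s}, \code{amplitude}) per record plus a
#' \code{manifest.csv} (subject_id, day_index, hi, wellness_class, fs, file).
#'
#' @param cohort An \code{ecg_cohort} or list of \code{ecg_record}s.
#' @param dir Output directory (created if missing).
#' @return \code{write_cohort_csv}: the manifest path, invisibly.
#'   \code{read_cohort_csv}: a list of \code{ecg_record}s.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(cohort), function(k) {
    r <- cohort[[k]]
    file <- sprintf("%s_day%03d.csv", r$subject_id, r$day_index)
    data.table::fwrite(
      data.table::data.table(
        time_s = (seq_along(r$samples) - 1L) / r$fs,
        amplitude = r$samples),
      file.path(dir, file))
    data.table::data.table(subject_id = r$subject_id,
                           day_index = r$day_index, hi = r$hi,
                           wellness_class = r$wellness_class,
                           fs = r$fs, file = file)
  })
  manifest <- data.table::rbindlist(rows)
  path <- file.path(dir, "manifest.csv")
  data.table::fwrite(manifest, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  manifest <- as.data.frame(data.table::fread(file.path(dir, "manifest.csv")))
  records <- lapply(seq_len(nrow(manifest)), function(k) {
    m <- manifest[k, ]
    sig <- data.table::fread(file.path(dir, m$file))
    structure(
      list(samples = sig$amplitude, fs = m$fs, subject_id = m$subject_id,
           day_index = as.integer(m$day_index), hi = as.integer(m$hi),
           wellness_class = m$wellness_class, rr_s = NULL),
      class = "ecg_record"
    )
  })
  structure(records, class = "ecg_cohort")
}
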