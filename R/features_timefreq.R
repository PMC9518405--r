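#' Thirteen time-domain waveform statistics
#'
#' The classical dimensioned and dimensionless waveform indicators: absolute
#' mean, peak, peak-to-peak, variance about the absolute mean, root
#' amplitude, crest factor, skewness, kurtosis, shape factor, clearance
#' factor, impulse factor, RMS, and variation coefficient. Two of them are
#' deliberately non-standard and kept so: the variance \eqn{D_x} is centered
#' on the absolute mean rather than the ordinary mean, and the variation
#' coefficient is \eqn{K_x = D_x / x_{av}}. Ratio statistics whose
#' denominator vanishes (e.g. on an all-zero signal) are set to 0 and a
#' warning is logged once per call.
#'
#' @param x Numeric vector, length >= 2.
#' @return Named numeric vector of length 13 (\code{x_av}, \code{x_p},
#'   \code{x_pp}, \code{D_x}, \code{x_r}, \code{C_f}, \code{SK_f},
#'   \code{K_f}, \code{S_f}, \code{CL_f}, \code{I_f}, \code{x_rms},
#'   \code{K_x}).
#' @export
time_domain_stats <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  n <- length(x)
  x_av <- mean(abs(x))
  x_p <- max(abs(x))
  x_pp <- max(x) - min(x)
  D_x <- mean((x - x_av)^2)          # centered on the absolute mean
  x_r <- mean(sqrt(abs(x)))^2        # root amplitude
  x_rms <- sqrt(mean(x^2))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  out <- c(
    x_av = x_av, x_p = x_p, x_pp = x_pp, D_x = D_x, x_r = x_r,
    C_f = ratio(x_p, x_rms),
    SK_f = ratio(m3, m2^1.5),
    K_f = ratio(m4, m2^2),
    S_f = ratio(x_rms, x_av),
    CL_f = ratio(x_p, x_r),
    I_f = ratio(x_p, x_av),
    x_rms = x_rms,
    K_x = ratio(D_x, x_av)
  )
  if (degenerate)
    warning("degenerate input: zero-denominator statistics set to 0",
            call. = FALSE)
  out
}

#' One-sided FFT amplitude spectrum
#'
#' Amplitude-calibrated one-sided spectrum: a pure sinusoid of amplitude A
#' yields a dominant bin of height approximately A (interior bins scaled
#' 2/N, DC and Nyquist 1/N).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param drop_dc Drop the DC bin (default \code{FALSE}).
#' @return List with \code{freq} (Hz) and \code{amp}.
#' @export
amplitude_spectrum <- function(x, fs, drop_dc = FALSE) {
  n <- length(x)
  X <- fft(x)
  half <- floor(n / 2) + 1L
  amp <- Mod(X[seq_len(half)]) / n
  # double interior bins to fold in the negative frequencies
  interior <- seq(2L, half - if (n %% 2L == 0L) 1L else 0L)
  amp[interior] <- 2 * amp[interior]
  freq <- (seq_len(half) - 1L) * fs / n
  if (drop_dc) {
    amp <- amp[-1L]
    freq <- freq[-1L]
  }
  list(freq = freq, amp = amp)
}

#' Thirteen frequency-domain statistics
#'
#' Applies the same 13 statistics as [time_domain_stats()] to the one-sided
#' FFT amplitude spectrum of the signal.
#'
#' @inheritParams time_domain_stats
#' @param fs Sampling rate in Hz.
#' @param drop_dc Exclude the DC bin from the spectrum (default
#'   \code{FALSE}).
#' @return Named numeric vector of length 13 (same names as
#'   [time_domain_stats()]).
#' @export
frequency_domain_stats <- function(x, fs, drop_dc = FALSE) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  spec <- amplitude_spectrum(x, fs, drop_dc = drop_dc)
  time_domain_stats(spec$amp)
}

#' The 26 time- and frequency-domain features (F1-F26)
#'
#' Concatenation of [time_domain_stats()] (F1-F13) and
#' [frequency_domain_stats()] (F14-F26).
#'
#' @inheritParams frequency_domain_stats
#' @return Named numeric vector of length 26 (\code{F1}..\code{F26}).
#' @export
timefreq_features <- function(x, fs, drop_dc = FALSE) {
  out <- c(time_domain_stats(x), frequency_domain_stats(x, fs, drop_dc))
  names(out) <- paste0("F", 1:26)
  out
}
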