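#' RCMSE parameters
#'
#' @param m Embedding (template) dimension, >= 1 (default 2).
#' @param r Similarity tolerance as a fraction of the original series'
#'   standard deviation (default 0.15).
#' @param tau_max Maximum scale factor (default 20).
#' @return An object of class \code{rcmse_params}.
#' @export
rcmse_params <- function(m = 2L, r = 0.15, tau_max = 20L) {
  stopifnot(m >= 1L, r > 0, tau_max >= 1L)
  structure(list(m = as.integer(m), r = r, tau_max = as.integer(tau_max)),
            class = "rcmse_params")
}

#' Coarse-grained series at scale tau
#'
#' Non-overlapping block means of length \code{tau} starting at offset
#' \code{k}: \eqn{y_i = mean(x[(k-1) + (i-1)\tau + 1 .. (k-1) + i\tau])}.
#' \code{tau = 1} is the identity.
#'
#' @param x Numeric vector, length >= tau.
#' @param tau Scale factor.
#' @param k Starting offset in 1..tau.
#' @return Numeric vector of length \code{floor((length(x) - k + 1) / tau)}.
#' @export
coarse_grain <- function(x, tau, k = 1L) {
  stopifnot(length(x) >= tau, tau >= 1L)
  if (k < 1L || k > tau)
    stop("`k` must be in 1..tau", call. = FALSE)
  n_out <- (length(x) - k + 1L) %/% tau
  if (n_out == 0L) return(numeric(0))
  idx <- k:(k + n_out * tau - 1L)
  colMeans(matrix(x[idx], nrow = tau))
}

#' Sample-entropy template match counts
#'
#' Number of template pairs (i < j, self-matches excluded) whose Chebyshev
#' distance is within \code{r_abs}, for m-length and (m+1)-length templates
#' over the same i range.
#'
#' @param y Numeric vector, length >= m + 2.
#' @param m Template length.
#' @param r_abs Absolute similarity tolerance.
#' @return Numeric vector \code{c(B_m, B_m1)} of match counts.
#' @export
sample_entropy_counts <- function(y, m, r_abs) {
  if (length(y) < m + 2L)
    stop("series too short for the template length", call. = FALSE)
  counts <- .sampen_counts_cpp(as.numeric(y), as.integer(m), r_abs)
  stats::setNames(counts, c("B_m", "B_m1"))
}

#' Refined composite multiscale sample entropy (RCMSE)
#'
#' For each scale tau = 1..tau_max, sums the m- and (m+1)-template match
#' counts over all tau coarse-graining offsets and takes
#' \eqn{-\ln(\Sigma B_{m+1} / \Sigma B_m)}. Aggregating counts across
#' offsets before the logarithm is what distinguishes RCMSE from naive
#' multiscale sample entropy and reduces the incidence of undefined values
#' on short series. The tolerance \code{r} is anchored once to the standard
#' deviation of the original series, not per scale. At tau = 1 the value is
#' exactly the sample entropy of \code{x}. Scales where either aggregate
#' count is zero are undefined: imputed 0, flagged, and a warning logged.
#'
#' @param x Numeric vector, length >= (m + 2) * tau_max.
#' @param params An [rcmse_params()].
#' @return Numeric vector of length \code{tau_max} (the entropy curve),
#'   with a logical \code{undefined} attribute marking imputed scales.
#' @export
rcmse <- function(x, params = rcmse_params()) {
  stopifnot(inherits(params, "rcmse_params"))
  x <- as.numeric(x)
  if (length(x) < (params$m + 2L) * params$tau_max)
    stop("series too short for tau_max at this template length",
         call. = FALSE)
  r_abs <- params$r * stats::sd(x)
  out <- numeric(params$tau_max)
  undef <- logical(params$tau_max)
  for (tau in seq_len(params$tau_max)) {
    Bm <- 0; Bm1 <- 0
    for (k in seq_len(tau)) {
      y <- coarse_grain(x, tau, k)
      cnt <- .sampen_counts_cpp(y, params$m, r_abs)
      Bm <- Bm + cnt[1L]
      Bm1 <- Bm1 + cnt[2L]
    }
    if (Bm == 0 || Bm1 == 0) {
      undef[tau] <- TRUE
      out[tau] <- 0
    } else {
      out[tau] <- -log(Bm1 / Bm)
    }
  }
  if (any(undef))
    warning(sprintf("undefined entropy at %d scale(s); imputed 0",
                    sum(undef)), call. = FALSE)
  structure(out, undefined = undef)
}

#' RCMSE features (F165-F184)
#'
#' The RCMSE entropy curve over scales 1..tau_max serialized in scale order.
#'
#' @inheritParams rcmse
#' @return Named numeric vector of length \code{params$tau_max}
#'   (\code{F165}..\code{F184} at the default 20 scales).
#' @export
rcmse_features <- function(x, params = rcmse_params()) {
  curve <- rcmse(x, params)
  out <- as.numeric(curve)
  names(out) <- paste0("F", seq(165L, length.out = length(out)))
  attr(out, "undefined") <- attr(curve, "undefined")
  out
}
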