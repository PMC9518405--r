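#' Empirical mode decomposition (EMD)
#'
#' Classical sifting: cubic-spline upper and lower envelopes through the
#' local maxima/minima (with mirrored boundary extrema), subtract the
#' envelope mean, and iterate until the normalized squared envelope-mean
#' criterion falls below \code{sift_tolerance} or \code{max_siftings} is
#' reached. Extraction stops when the residue has fewer than two maxima or
#' two minima (e.g. it is monotone). The decomposition is subtractive, so
#' \code{rowSums(imfs) + residue} reconstructs the input to machine
#' precision.
#'
#' @param x Numeric vector, length >= 8.
#' @param max_siftings Maximum sifting iterations per IMF (default 10).
#' @param sift_tolerance Stopping threshold for the sifting criterion
#'   (default 0.2).
#' @param max_imfs Safety cap on the number of extracted IMFs.
#' @return List with \code{imfs} (matrix, one column per IMF, highest
#'   frequency first; zero columns for a monotone input) and \code{residue}.
#' @export
emd <- function(x, max_siftings = 10L, sift_tolerance = 0.2,
                max_imfs = 16L) {
  if (length(x) < 8L) stop("need at least 8 samples", call. = FALSE)
  .emd_cpp(as.numeric(x), as.integer(max_siftings), sift_tolerance,
           as.integer(max_imfs))
}

#' EEMD configuration
#'
#' @param trials Ensemble size M: number of noise realizations averaged
#'   (default 100).
#' @param noise_ratio White-noise standard deviation as a fraction of the
#'   signal's standard deviation (default 0.2).
#' @param n_imfs_out Fixed number of IMF slots in the feature layout
#'   (default 10); extra IMFs are dropped, missing ones zero-padded.
#' @param max_siftings,sift_tolerance Sifting controls, see [emd()].
#' @param seed Master seed; each trial's noise comes from a deterministic
#'   sub-stream.
#' @return An object of class \code{eemd_config}.
#' @export
eemd_config <- function(trials = 100L, noise_ratio = 0.2, n_imfs_out = 10L,
                        max_siftings = 10L, sift_tolerance = 0.2,
                        seed = 1L) {
  if (trials < 1L) stop("`trials` must be >= 1", call. = FALSE)
  if (noise_ratio < 0) stop("`noise_ratio` must be >= 0", call. = FALSE)
  if (n_imfs_out < 1L) stop("`n_imfs_out` must be >= 1", call. = FALSE)
  structure(
    list(trials = as.integer(trials), noise_ratio = noise_ratio,
         n_imfs_out = as.integer(n_imfs_out),
         max_siftings = as.integer(max_siftings),
         sift_tolerance = sift_tolerance, seed = as.integer(seed)),
    class = "eemd_config"
  )
}

#' Ensemble empirical mode decomposition (EEMD)
#'
#' Runs \code{cfg$trials} EMD decompositions of the input plus fresh white
#' noise (std = \code{noise_ratio} x sd(x)), retains I = the minimum IMF
#' count across trials, and averages the i-th IMF over trials for i <= I.
#' The residue is the ensemble mean of the per-trial remainders, so the
#' averaged IMFs plus residue reconstruct x up to the unreduced noise
#' (RMS error shrinks as 1/sqrt(M)). With \code{noise_ratio = 0} and
#' \code{trials = 1} the result is plain [emd()].
#'
#' @param x Numeric vector.
#' @param cfg An [eemd_config()].
#' @return An object of class \code{imf_set}: list with \code{imfs} (list of
#'   ensemble-mean IMF vectors, highest frequency first), \code{residue},
#'   and \code{I} (retained IMF count).
#' @export
eemd <- function(x, cfg = eemd_config()) {
  stopifnot(inherits(cfg, "eemd_config"))
  x <- as.numeric(x)
  n <- length(x)
  noise_sd <- cfg$noise_ratio * stats::sd(x)
  with_seed(cfg$seed, {
    trials <- vector("list", cfg$trials)
    counts <- integer(cfg$trials)
    for (p in seq_len(cfg$trials)) {
      xp <- if (noise_sd > 0) x + rnorm(n, 0, noise_sd) else x
      dec <- .emd_cpp(xp, cfg$max_siftings, cfg$sift_tolerance, 16L)
      trials[[p]] <- list(imfs = dec$imfs, input = xp)
      counts[p] <- ncol(dec$imfs)
    }
    I <- min(counts)
    imfs <- vector("list", I)
    if (I > 0L) {
      for (i in seq_len(I)) {
        acc <- numeric(n)
        for (p in seq_len(cfg$trials)) acc <- acc + trials[[p]]$imfs[, i]
        imfs[[i]] <- acc / cfg$trials
      }
    }
    res_acc <- numeric(n)
    for (p in seq_len(cfg$trials)) {
      kept <- if (I > 0L) rowSums(trials[[p]]$imfs[, seq_len(I), drop = FALSE])
              else numeric(n)
      res_acc <- res_acc + (trials[[p]]$input - kept)
    }
    structure(list(imfs = imfs, residue = res_acc / cfg$trials, I = I),
              class = "imf_set")
  })
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d ensemble-mean IMFs of length %d\n",
              x$I, length(x$residue)))
  invisible(x)
}

#' EEMD time-domain features (F35-F164)
#'
#' The 13 time-domain statistics of [time_domain_stats()] computed on each
#' of \code{cfg$n_imfs_out} IMF slots (default 10), IMF-major: the 13
#' statistics of IMF1 (highest frequency) first, then IMF2, and so on.
#' Segments yielding fewer IMFs than slots have the trailing slots
#' zero-padded, whose statistics are all 0.
#'
#' @inheritParams eemd
#' @return Named numeric vector of length \code{13 * cfg$n_imfs_out}
#'   (130 at the defaults), named \code{F35}..\code{F164} when the default
#'   layout is used.
#' @export
eemd_features <- function(x, cfg = eemd_config()) {
  dec <- eemd(x, cfg)
  n <- length(x)
  out <- numeric(0)
  for (i in seq_len(cfg$n_imfs_out)) {
    if (i <= dec$I) {
      out <- c(out, time_domain_stats(dec$imfs[[i]]))
    } else {
      out <- c(out, suppressWarnings(time_domain_stats(numeric(n))))
    }
  }
  names(out) <- paste0("F", seq(35L, by = 1L, length.out = length(out)))
  out
}
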