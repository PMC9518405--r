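# Orthonormal Daubechies decomposition filters (low-pass; sum = sqrt(2)).
# High-pass is the alternating flip g[n] = (-1)^n h[L-1-n].
wpt_filter <- function(name) {
  h <- switch(
    name,
    haar = ,
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(0.48296291314469025, 0.8365163037378079,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415,
            0.6308807679295904, -0.02798376941698385,
            -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    stop(sprintf("unknown wavelet '%s' (supported: haar/db1, db2, db4)", name),
         call. = FALSE)
  )
  list(h = h, g = rev(h) * (-1)^(seq_along(h) - 1L))
}

# One periodized analysis step: circular convolution + dyadic decimation.
wpt_step <- function(v, filt) {
  n <- length(v)
  half <- n %/% 2L
  L <- length(filt$h)
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(L) - 1L, "+") %% n + 1L
  vm <- matrix(v[idx], half, L)
  list(low = as.numeric(vm %*% filt$h), high = as.numeric(vm %*% filt$g))
}

#' Wavelet-packet sub-band energies (F27-F34)
#'
#' Full wavelet-packet decomposition of a segment to depth \code{level}
#' (default 3, giving 2^3 = 8 equal-width sub-bands) and the energy (sum of
#' squared coefficients) of each terminal node, ordered from the lowest to
#' the highest frequency band. The transform is periodized and orthonormal,
#' so the eight energies sum exactly to the signal energy; the segment is
#' zero-padded to the next multiple of 2^level first (zero padding adds no
#' energy).
#'
#' @param x Numeric vector, length >= 2^level.
#' @param wavelet_name Wavelet family: \code{"db4"} (default), \code{"db2"},
#'   or \code{"haar"}/\code{"db1"}.
#' @param level Decomposition depth (default 3).
#' @return Named numeric vector of length 2^level (\code{E1}..\code{E8} at
#'   the default depth), low to high frequency.
#' @export
wavelet_packet_energy <- function(x, wavelet_name = "db4", level = 3L) {
  filt <- wpt_filter(wavelet_name)
  n <- length(x)
  if (n < 2^level)
    stop(sprintf("need at least 2^%d samples", level), call. = FALSE)
  pad <- (2^level - n %% 2^level) %% 2^level
  v <- c(as.numeric(x), numeric(pad))
  nodes <- list(v)
  for (l in seq_len(level)) {
    nodes <- unlist(lapply(nodes, function(nd) {
      s <- wpt_step(nd, filt)
      list(s$low, s$high)
    }), recursive = FALSE)
  }
  e_nat <- vapply(nodes, function(nd) sum(nd^2), numeric(1))
  # natural (filter-path) order -> frequency order via the Gray code: the
  # high-pass branch flips the spectrum after decimation
  k <- 0:(2^level - 1L)
  gray <- bitwXor(k, bitwShiftR(k, 1L))
  e <- e_nat[gray + 1L]
  names(e) <- paste0("E", seq_along(e))
  e
}
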