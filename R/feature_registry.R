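#' Feature extraction configuration
#'
#' Bundles the per-family settings used by [extract_all()] /
#' [extract_matrix()].
#'
#' @param drop_dc Exclude the DC bin from the frequency-domain statistics
#'   (default \code{FALSE}).
#' @param wavelet_name,wavelet_level Wavelet-packet settings, see
#'   [wavelet_packet_energy()].
#' @param eemd An [eemd_config()].
#' @param rcmse An [rcmse_params()].
#' @return A list of class \code{feature_configs}.
#' @export
feature_configs <- function(drop_dc = FALSE, wavelet_name = "db4",
                            wavelet_level = 3L, eemd = eemd_config(),
                            rcmse = rcmse_params()) {
  stopifnot(inherits(eemd, "eemd_config"), inherits(rcmse, "rcmse_params"))
  wpt_filter(wavelet_name) # validate early
  structure(
    list(drop_dc = drop_dc, wavelet_name = wavelet_name,
         wavelet_level = as.integer(wavelet_level), eemd = eemd,
         rcmse = rcmse),
    class = "feature_configs"
  )
}

#' Feature group index map
#'
#' The canonical partition of the 184-feature layout into its four
#' extractor families.
#'
#' @return Named list of integer index ranges: \code{timefreq} (F1-F26),
#'   \code{wavelet} (F27-F34), \code{eemd} (F35-F164), \code{rcmse}
#'   (F165-F184).
#' @export
feature_groups <- function() {
  list(timefreq = 1:26, wavelet = 27:34, eemd = 35:164, rcmse = 165:184)
}

#' Extract the full 184-feature vector for one segment
#'
#' Concatenates, in the canonical order, the 26 time/frequency statistics,
#' the 8 wavelet-packet sub-band energies, the 130 per-IMF time-domain
#' statistics from EEMD, and the 20 RCMSE entropy values. Deterministic
#' under the seeds carried in \code{configs}.
#'
#' @param x Numeric vector, one segment (default layout expects 500 points).
#' @param fs Effective sampling rate of the segment in Hz.
#' @param configs A [feature_configs()].
#' @return Named numeric vector of length 184 (\code{F1}..\code{F184}) with
#'   a \code{groups} attribute, see [feature_groups()].
#' @export
extract_all <- function(x, fs, configs = feature_configs()) {
  stopifnot(inherits(configs, "feature_configs"))
  run <- function(family, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("feature family '%s' failed: %s", family,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  tf <- run("timefreq", timefreq_features(x, fs, configs$drop_dc))
  wv <- run("wavelet",
            wavelet_packet_energy(x, configs$wavelet_name,
                                  configs$wavelet_level))
  em <- run("eemd", eemd_features(x, configs$eemd))
  rc <- run("rcmse", rcmse_features(x, configs$rcmse))
  out <- c(unname(tf), unname(wv), unname(em), unname(rc))
  names(out) <- paste0("F", seq_along(out))
  attr(out, "groups") <- feature_groups()
  out
}

#' Extract the feature matrix for a segment dataset
#'
#' Applies [extract_all()] to every segment, preserving row order. Undefined
#' RCMSE scales and degenerate-denominator statistics inside individual
#' segments are imputed (and counted) rather than aborting the run.
#'
#' @param dataset A \code{segment_dataset} (see [make_segment_dataset()]) or
#'   a plain numeric matrix of segments (rows).
#' @param fs Effective per-segment sampling rate in Hz.
#' @param configs A [feature_configs()].
#' @param progress_every Log a progress line every this many rows
#'   (0 disables, the default).
#' @return Numeric matrix (n x 184) with column names \code{F1}..\code{F184}.
#' @export
extract_matrix <- function(dataset, fs, configs = feature_configs(),
                           progress_every = 0L) {
  segs <- if (inherits(dataset, "segment_dataset")) dataset$segments
          else as.matrix(dataset)
  n <- nrow(segs)
  p <- 184L
  out <- matrix(NA_real_, n, p,
                dimnames = list(NULL, paste0("F", seq_len(p))))
  for (i in seq_len(n)) {
    row <- tryCatch(
      suppressWarnings(extract_all(segs[i, ], fs, configs)),
      error = function(e) {
        stop(sprintf("row %d: %s", i, conditionMessage(e)), call. = FALSE)
      })
    out[i, ] <- row
    if (progress_every > 0L && i %% progress_every == 0L)
      message(sprintf("extracted %d / %d segments", i, n))
  }
  out
}

#' Write / read a feature matrix with labels and provenance as CSV
#'
#' @param features Numeric matrix with \code{F*} columns.
#' @param labels Integer 0/1 labels, one per row.
#' @param meta Optional provenance data.frame (one row per segment).
#' @param path Output CSV path.
#' @return \code{write_feature_csv}: \code{path}, invisibly.
#'   \code{read_feature_csv}: list with \code{features}, \code{labels},
#'   \code{meta}.
#' @export
write_feature_csv <- function(features, labels, path, meta = NULL) {
  stopifnot(nrow(features) == length(labels))
  df <- data.table::as.data.table(features)
  data.table::set(df, j = "label", value = as.integer(labels))
  if (!is.null(meta)) df <- cbind(df, data.table::as.data.table(meta))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- data.table::fread(path)
  fcols <- grep("^F[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^F", "", fcols)))]
  list(features = as.matrix(df[, fcols, with = FALSE]),
       labels = df$label,
       meta = as.data.frame(
         df[, setdiff(names(df), c(fcols, "label")), with = FALSE]))
}
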