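#' Sliding-window segmentation of an ECG record
#'
#' Splits a record into overlapping fixed-duration windows. Windows start at
#' integer multiples of \code{step_s} from t = 0 and a partial trailing window
#' is discarded, so a record of duration D yields
#' \code{floor((D - window_s) / step_s) + 1} windows (a 20 s record at the
#' default 5 s window / 1 s step gives 16).
#'
#' @param record An \code{ecg_record} (or any list with \code{samples} and
#'   \code{fs}).
#' @param window_s Window length in seconds (default 5).
#' @param step_s Slide step in seconds (default 1).
#' @return A list of numeric vectors (raw windows at the record's sampling
#'   rate), with a \code{starts_s} attribute giving window start times. A
#'   record shorter than one window returns an empty list with a warning.
#' @export
segment_signal <- function(record, window_s = 5, step_s = 1) {
  stopifnot(window_s > 0, step_s > 0)
  fs <- record$fs
  x <- record$samples
  duration <- length(x) / fs
  if (duration < window_s) {
    warning(sprintf("record %.2f s shorter than window %.2f s: no windows",
                    duration, window_s), call. = FALSE)
    return(structure(list(), starts_s = numeric(0)))
  }
  n_win <- floor((duration - window_s) / step_s) + 1L
  wlen <- round(window_s * fs)
  starts <- (seq_len(n_win) - 1L) * step_s
  out <- lapply(starts, function(s) {
    i0 <- round(s * fs)
    x[(i0 + 1L):(i0 + wlen)]
  })
  structure(out, starts_s = starts)
}

#' Resample a raw window to the model input length
#'
#' Polyphase anti-aliased resampling (FIR low-pass then rate change) of one
#' raw window down to \code{target_len} points, e.g. a 2500-sample 5 s window
#' at 500 Hz to the 500-point model input (effective 100 Hz). The identity
#' case (\code{target_len == length(window)}) bypasses filtering.
#'
#' @param window Numeric vector, the raw samples.
#' @param target_len Output length (default 500); must not exceed the input
#'   length.
#' @return Numeric vector of length \code{target_len}.
#' @export
resample_window <- function(window, target_len = 500L) {
  n <- length(window)
  if (n == 0L) stop("empty window", call. = FALSE)
  if (target_len > n)
    stop("`target_len` exceeds window length (upsampling not supported)",
         call. = FALSE)
  if (target_len == n) return(as.numeric(window))
  # detrend to the window mean before filtering so edge taper acts on the
  # fluctuation, then restore the DC level
  mu <- mean(window)
  y <- signal::resample(as.numeric(window) - mu, p = target_len, q = n)
  y <- y[seq_len(target_len)] + mu
  if (length(y) < target_len) y <- c(y, rep(mu, target_len - length(y)))
  y
}

#' Build a labelled segment dataset from a cohort
#'
#' Runs sliding-window segmentation and resampling over every record, derives
#' per-subject binary wellness labels from the HI series via
#' [fisher_yates_labels()], and pairs each day's segments with the label of
#' the day \code{lag} days ahead (one-day-forward prediction by default).
#' Days with no label available at \code{day + lag} are dropped.
#'
#' @param cohort An \code{ecg_cohort} or list of \code{ecg_record}s with
#'   \code{hi} fields.
#' @param window_s,step_s Segmentation parameters, see [segment_signal()].
#' @param target_len Per-segment model input length, see [resample_window()].
#' @param lag Days between the predictor signal and the label (default 1;
#'   0 labels each day with its own wellness).
#' @return An object of class \code{segment_dataset}: list with
#'   \code{segments} (n x target_len matrix), \code{labels} (integer 0/1,
#'   0 = Better, 1 = Worse), and a provenance data.frame \code{meta}
#'   (subject_id, day_index, window_start_s, label_day).
#' @export
make_segment_dataset <- function(cohort, window_s = 5, step_s = 1,
                                 target_len = 500L, lag = 1L) {
  stopifnot(lag >= 0)
  # per-subject label tables
  subj <- split(seq_along(cohort), vapply(cohort, `[[`, "", "subject_id"))
  seg_rows <- list()
  lab <- integer(0)
  meta <- list()
  for (ids in subj) {
    days <- vapply(cohort[ids], `[[`, 1L, "day_index")
    ids <- ids[order(days)]
    days <- sort(days)
    his <- vapply(cohort[ids], `[[`, 1L, "hi")
    fy <- fisher_yates_labels(his)
    day_label <- stats::setNames(fy$labels, days)
    for (k in seq_along(ids)) {
      target_day <- days[k] + lag
      if (!as.character(target_day) %in% names(day_label)) next
      rec <- cohort[[ids[k]]]
      wins <- segment_signal(rec, window_s, step_s)
      if (length(wins) == 0L) next
      starts <- attr(wins, "starts_s")
      segs <- t(vapply(wins, resample_window, numeric(target_len),
                       target_len = target_len))
      seg_rows[[length(seg_rows) + 1L]] <- segs
      lab <- c(lab, rep(day_label[[as.character(target_day)]], nrow(segs)))
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = rec$subject_id, day_index = rec$day_index,
        window_start_s = starts, label_day = target_day,
        stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows)
              else matrix(numeric(0), 0L, target_len)
  structure(
    list(segments = segments, labels = as.integer(lab),
         meta = if (length(meta)) do.call(rbind, meta)
                else data.frame(subject_id = character(0),
                                day_index = integer(0),
                                window_start_s = numeric(0),
                                label_day = integer(0))),
    class = "segment_dataset"
  )
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("<segment_dataset> %d segments x %d points; labels: %d Better (0) / %d Worse (1)\n",
              nrow(x$segments), ncol(x$segments),
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Min-max feature normalization
#'
#' \code{fit_minmax()} learns per-feature minima and maxima on a training
#' matrix; \code{apply_minmax()} maps a matrix to
#' \code{(x - min) / (max - min)}. Training data maps into \[0, 1\]; test data
#' may fall outside that range. A feature constant on the training data
#' (max == min) maps to 0 everywhere.
#'
#' @param x Numeric matrix (rows = samples, columns = features).
#' @return \code{fit_minmax()}: an object of class \code{minmax_model} with
#'   \code{min} and \code{max} vectors. \code{apply_minmax()}: the normalized
#'   matrix.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one training row", call. = FALSE)
  structure(
    list(min = apply(x, 2L, min), max = apply(x, 2L, max)),
    class = "minmax_model"
  )
}

#' @rdname fit_minmax
#' @param model A fitted \code{minmax_model}.
#' @export
apply_minmax <- function(model, x) {
  stopifnot(inherits(model, "minmax_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$min))
    stop(sprintf("feature count mismatch: model has %d, matrix has %d",
                 length(model$min), ncol(x)), call. = FALSE)
  range <- model$max - model$min
  degenerate <- range == 0
  range[degenerate] <- 1
  out <- sweep(sweep(x, 2L, model$min, "-"), 2L, range, "/")
  if (any(degenerate)) out[, degenerate] <- 0
  out
}

# Rank-based normal scores of one subject's HI series (mid-ranks for ties,
# boundary-safe G/(I+1) plug-in so the extreme ranks stay finite).
fisher_yates_values <- function(hi) {
  I <- length(hi)
  g <- rank(hi, ties.method = "average")
  qnorm(g / (I + 1))
}

#' Fisher-Yates normalization of self-rated health indices
#'
#' Converts one subject's ordinal HI series (1..5, Poor..Excellent) to
#' standard-normal scores via the inverse normal CDF of within-subject
#' relative mid-ranks, then binarizes at 0: scores > 0 are "Better"
#' (label 0), the rest "Worse" (label 1). Because ranks are taken within the
#' subject, the transform removes between-subject differences in how the
#' ordinal scale is used. The rank plug-in is G/(I+1) so that the largest
#' rank maps to a finite score.
#'
#' @param hi Integer vector of HI values in \{1..5\}, one per day, for a
#'   single subject.
#' @return List with \code{values} (normal scores) and \code{labels}
#'   (integer, 0 = Better, 1 = Worse).
#' @export
fisher_yates_labels <- function(hi) {
  if (length(hi) < 1L) stop("empty HI series", call. = FALSE)
  if (any(!hi %in% 1:5))
    stop("HI values must be integers in 1..5", call. = FALSE)
  values <- fisher_yates_values(hi)
  list(values = values, labels = as.integer(!(values > 0)))
}
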