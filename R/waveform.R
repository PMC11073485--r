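#' Construct a waveform object
#'
#' A `waveform` holds one continuous single-channel arterial pressure
#' recording on a uniform time grid. Pressure units are arbitrary
#' (tonometer output is uncalibrated); all downstream analysis is invariant
#' to pressure offset and positive scaling.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing with constant spacing.
#' @param pressure Numeric vector of pressure samples, same length as
#'   `times`, all finite.
#' @param subject_id Character scalar identifying the subject.
#' @return An object of class `waveform` with fields `subject_id`, `times`,
#'   `pressure` and `sampling_rate` (Hz, inferred from the median spacing).
#' @export
waveform <- function(times, pressure, subject_id = "unknown") {
  times <- as.numeric(times)
  pressure <- as.numeric(pressure)
  if (length(times) < 2L) abort_malformed("waveform needs at least 2 samples")
  if (length(times) != length(pressure))
    abort_malformed("times and pressure must have equal length")
  if (anyNA(pressure) || any(!is.finite(pressure)))
    abort_malformed("pressure contains missing or non-finite values")
  if (anyNA(times) || any(!is.finite(times)))
    abort_malformed("times contains missing or non-finite values")
  d <- diff(times)
  if (any(d <= 0)) abort_malformed("times must be strictly increasing")
  med <- stats::median(d)
  if (any(abs(d - med) > 1e-6 * med))
    abort_malformed("time grid is not uniform (relative tolerance 1e-6)")
  structure(
    list(subject_id = as.character(subject_id), times = times,
         pressure = pressure, sampling_rate = 1 / med),
    class = "waveform")
}

#' Read a waveform from a two-column CSV file
#'
#' Expects a header row `time_s,pressure` followed by at least two rows of
#' uniformly spaced samples.
#'
#' @param path Path to the CSV file.
#' @param subject_id Subject identifier to attach; defaults to the file name
#'   without extension.
#' @return A [waveform] object.
#' @export
read_waveform <- function(path, subject_id = NULL) {
  if (!file.exists(path)) abort_malformed(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "pressure") %in% names(df)))
    abort_malformed("CSV must have columns 'time_s' and 'pressure'")
  if (nrow(df) < 2L) abort_malformed("CSV must have at least 2 data rows")
  sid <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  waveform(df$time_s, df$pressure, sid)
}

#' Write a waveform to CSV
#'
#' Inverse of [read_waveform()]: writes columns `time_s,pressure` with a
#' header row, full double precision.
#'
#' @param w A [waveform].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  df <- data.frame(time_s = format(w$times, digits = 17, trim = TRUE, scientific = FALSE),
                   pressure = format(w$pressure, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> subject %s: %d samples @ %.6g Hz (%.2f s)\n",
              x$subject_id, length(x$pressure), x$sampling_rate,
              length(x$pressure) / x$sampling_rate))
  invisible(x)
}

#' @export
plot.waveform <- function(x, ...) {
  graphics::plot(x$times, x$pressure, type = "l", xlab = "time (s)",
                 ylab = "pressure (a.u.)", main = x$subject_id, ...)
  invisible(x)
}

#' Segmentation configuration
#'
#' Parameters controlling automatic beat-onset detection.
#'
#' @param hr_range Plausible heart-rate search range in bpm; consecutive
#'   onsets closer than `60/hr_range[2]` seconds are suppressed.
#' @param smooth_sec Moving-average smoothing window in seconds applied
#'   before differentiation.
#' @param min_prominence Fraction of the robust maximum upstroke slope a
#'   candidate upstroke must reach.
#' @return A list of class `segment_config`.
#' @export
segment_config <- function(hr_range = c(40, 220), smooth_sec = 0.02,
                           min_prominence = 0.3) {
  if (length(hr_range) != 2L || !all(is.finite(hr_range)) ||
      hr_range[1] <= 0 || hr_range[2] <= hr_range[1])
    abort_config("hr_range must be positive and increasing")
  if (!is_number(smooth_sec) || smooth_sec < 0)
    abort_config("smooth_sec must be a nonnegative number")
  if (!is_number(min_prominence) || min_prominence <= 0 || min_prominence > 1)
    abort_config("min_prominence must be in (0, 1]")
  structure(list(hr_range = as.numeric(hr_range), smooth_sec = smooth_sec,
                 min_prominence = min_prominence), class = "segment_config")
}

#' Detect beat onsets in a continuous recording
#'
#' Automatic surrogate for manual cycle selection: the systolic upstroke is
#' located as a peak of the smoothed first derivative, with a refractory
#' period of `60/hr_range[2]` seconds between upstrokes, and the onset (foot
#' of the pulse) is the local pressure minimum immediately preceding each
#' upstroke.
#'
#' @param w A [waveform].
#' @param cfg A [segment_config()].
#' @return Integer vector of onset sample indices (1-based); empty when no
#'   pulse-like activity is found (a flat signal is not an error).
#' @export
detect_beats <- function(w, cfg = segment_config()) {
  stopifnot(inherits(w, "waveform"))
  if (!inherits(cfg, "segment_config")) cfg <- do.call(segment_config, cfg)
  fs <- w$sampling_rate
  p <- w$pressure
  n <- length(p)
  ps <- moving_average(p, round(cfg$smooth_sec * fs))
  if (stats::sd(ps) < 1e-12 * (abs(mean(ps)) + 1)) return(integer(0))
  slope <- c(0, diff(ps)) * fs
  pos <- slope[slope > 0]
  if (length(pos) == 0L) return(integer(0))
  thr <- cfg$min_prominence * stats::quantile(pos, 0.99, names = FALSE)
  # dominant beat period from the autocorrelation of the smoothed signal,
  # searched over the configured heart-rate range; it widens the refractory
  # window so the dicrotic (diastolic) upstroke cannot double-fire
  lag_lo <- max(2L, as.integer(floor(60 / cfg$hr_range[2] * fs)))
  lag_hi <- as.integer(ceiling(60 / cfg$hr_range[1] * fs))
  period <- NA_integer_
  if (n > 2L * lag_lo) {
    lag_hi <- min(lag_hi, n - 1L)
    ac <- stats::acf(ps, lag.max = lag_hi, plot = FALSE,
                     demean = TRUE)$acf[-1]
    if (lag_hi >= lag_lo) {
      seg <- ac[lag_lo:lag_hi]
      if (max(seg) > 0.2) period <- lag_lo + which.max(seg) - 1L
    }
  }
  refr <- max(2L, as.integer(round(60 / cfg$hr_range[2] * fs)))
  if (!is.na(period)) refr <- max(refr, as.integer(round(0.6 * period)))
  # local maxima of the slope above threshold
  cand <- which(slope > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[slope[cand] >= slope[cand - 1L] & slope[cand] >= slope[cand + 1L]]
  if (length(cand) == 0L) return(integer(0))
  # greedy refractory suppression keeping the steepest upstroke per cluster
  keep <- integer(0)
  i <- 1L
  while (i <= length(cand)) {
    j <- i
    while (j < length(cand) && cand[j + 1L] - cand[i] < refr) j <- j + 1L
    grp <- cand[i:j]
    keep <- c(keep, grp[which.max(slope[grp])])
    i <- j + 1L
  }
  # onset: minimum of the smoothed signal in a window before each upstroke
  back <- max(2L, as.integer(round(0.35 * 60 / cfg$hr_range[1] * fs)))
  onsets <- vapply(keep, function(k) {
    lo <- max(1L, k - back)
    seg <- ps[lo:k]
    # last local minimum before the upstroke; else the window minimum
    lm <- local_minima(seg)
    if (length(lm)) lo + lm[length(lm)] - 1L else lo + which.min(seg) - 1L
  }, integer(1))
  # refine each onset against the lightly smoothed raw signal: the wide
  # detection smoothing biases the foot a few samples early
  ps3 <- moving_average(p, 3L)
  h <- max(3L, as.integer(round(cfg$smooth_sec * fs / 2)))
  onsets <- vapply(onsets, function(o) {
    lo <- max(1L, o - h); hi <- min(n, o + h)
    lo + which.min(ps3[lo:hi]) - 1L
  }, integer(1))
  onsets <- sort(unique(onsets))
  # enforce refractory spacing greedily (keep the earlier onset, drop the
  # follower, and compare the next candidate with the last kept onset)
  if (length(onsets) > 1L) {
    kept <- onsets[1L]
    last <- onsets[1L]
    for (o in onsets[-1L]) {
      if (o - last >= refr) {
        kept <- c(kept, o)
        last <- o
      }
    }
    onsets <- kept
  }
  # interval-consistency cleanup: drop onsets creating intervals far below
  # the median beat-to-beat interval (residual double-detections)
  if (length(onsets) > 3L) {
    iv <- diff(onsets)
    med <- stats::median(iv)
    keep <- c(TRUE, iv >= 0.7 * med)
    onsets <- onsets[keep]
  }
  onsets
}
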