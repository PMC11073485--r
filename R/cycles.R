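#' Construct a cardiac cycle
#'
#' One beat of pressure on a cycle-local time grid `[0, T)`, with `t = 0` at
#' the beat onset (foot of the pulse). `T0` is the systolic duration, i.e.
#' the dicrotic-notch time marking aortic-valve closure: systole is
#' `[0, T0)` and diastole `[T0, T)`.
#'
#' @param pressure Numeric pressure samples on the local grid.
#' @param sampling_rate Sampling rate in Hz.
#' @param T0 Systolic duration in seconds, `0 < T0 < T`.
#' @param subject_id,index Provenance labels.
#' @param quality Quality score in `[0, 1]` (see [quality_scores()]).
#' @param t0_fallback Logical; `TRUE` when `T0` came from the fallback rule
#'   rather than a detected notch.
#' @return An object of class `cardiac_cycle` with fields `pressure`,
#'   `times`, `T`, `T0`, `quality`, `t0_fallback`, `subject_id`, `index`.
#' @export
cardiac_cycle <- function(pressure, sampling_rate, T0, subject_id = "unknown",
                          index = 1L, quality = NA_real_, t0_fallback = FALSE) {
  pressure <- as.numeric(pressure)
  n <- length(pressure)
  if (n < 32L) abort_malformed("cardiac cycle needs at least 32 samples")
  if (anyNA(pressure) || any(!is.finite(pressure)))
    abort_malformed("cycle pressure contains non-finite values")
  Tdur <- n / sampling_rate
  if (!is_number(T0) || T0 <= 0 || T0 >= Tdur)
    abort_malformed("T0 must satisfy 0 < T0 < T")
  times <- (seq_len(n) - 1L) / sampling_rate
  n_sys <- sum(times < T0)
  if (n_sys < 16L || n - n_sys < 16L)
    abort_malformed("need at least 16 samples in systole and 16 in diastole")
  structure(
    list(pressure = pressure, times = times, T = Tdur, T0 = T0,
         sampling_rate = sampling_rate, quality = quality,
         t0_fallback = t0_fallback, subject_id = as.character(subject_id),
         index = as.integer(index)),
    class = "cardiac_cycle")
}

#' @export
print.cardiac_cycle <- function(x, ...) {
  cat(sprintf("<cardiac_cycle> %s #%d: T = %.3f s, T0 = %.3f s, %d samples, quality %s\n",
              x$subject_id, x$index, x$T, x$T0, length(x$pressure),
              ifelse(is.na(x$quality), "NA", sprintf("%.2f", x$quality))))
  invisible(x)
}

#' Estimate the dicrotic-notch time of a cycle
#'
#' The notch (aortic-valve closure) is located as the most prominent local
#' minimum of the lightly smoothed pressure within a physiologic systolic
#' window, by default `[0.15 T, 0.6 T]`. When no local minimum exists in the
#' window (e.g. a monotone decaying signal) the estimate falls back to
#' `0.35 T` and the cycle is flagged, which later incurs a quality penalty.
#' The estimate is invariant to pressure offset and positive scaling.
#'
#' @param pressure Numeric pressure samples of a single cycle.
#' @param sampling_rate Sampling rate in Hz.
#' @param window Search window as fractions of the cycle length.
#' @return List with `T0` (seconds) and `fallback` (logical).
#' @export
estimate_notch <- function(pressure, sampling_rate, window = c(0.15, 0.6)) {
  n <- length(pressure)
  Tdur <- n / sampling_rate
  ps <- moving_average(pressure, max(3L, round(0.008 * sampling_rate)))
  lo <- max(2L, ceiling(window[1] * n))
  hi <- min(n - 1L, floor(window[2] * n))
  if (hi - lo < 2L) return(list(T0 = 0.35 * Tdur, fallback = TRUE))
  seg <- ps[lo:hi]
  mins <- local_minima(seg)
  if (length(mins) == 0L) return(list(T0 = 0.35 * Tdur, fallback = TRUE))
  prom <- vapply(mins, function(m) {
    left <- max(seg[1:m]) - seg[m]
    right <- max(seg[m:length(seg)]) - seg[m]
    min(left, right)
  }, numeric(1))
  if (max(prom) <= 0) return(list(T0 = 0.35 * Tdur, fallback = TRUE))
  idx <- lo + mins[which.max(prom)] - 1L
  T0 <- (idx - 1L) / sampling_rate
  T0 <- min(max(T0, 1 / sampling_rate), Tdur - 1 / sampling_rate)
  list(T0 = T0, fallback = FALSE)
}

#' Cycle quality scores from a median beat template
#'
#' Threshold-free surrogate for manual "good signal quality" judgement:
#' each cycle is resampled to a common length, a pointwise median template
#' is formed, and quality is one minus the RMS discrepancy from the template
#' normalized by the template's own pulsatile RMS, clamped to `[0, 1]`.
#' Cycles whose notch came from the fallback rule lose 0.25.
#'
#' @param cycles List of [cardiac_cycle] objects.
#' @param m Number of resampling points for the template.
#' @return Numeric vector of quality scores in `[0, 1]`.
#' @export
quality_scores <- function(cycles, m = 101L) {
  if (length(cycles) == 0L) return(numeric(0))
  mat <- vapply(cycles, function(cy) resample_uniform(cy$pressure, m), numeric(m))
  template <- apply(mat, 1L, stats::median)
  denom <- sqrt(mean((template - mean(template))^2))
  if (denom < .Machine$double.eps) denom <- 1
  q <- vapply(seq_along(cycles), function(i) {
    1 - sqrt(mean((mat[, i] - template)^2)) / denom
  }, numeric(1))
  q <- q - 0.25 * vapply(cycles, function(cy) isTRUE(cy$t0_fallback), logical(1))
  pmin(pmax(q, 0), 1)
}

#' Segment a recording into cardiac cycles
#'
#' Slices the recording between consecutive beat onsets, re-bases each slice
#' to cycle-local time (`t = 0` at onset, half-open `[0, T)`), estimates the
#' systolic duration with [estimate_notch()], and scores quality with
#' [quality_scores()]. Slices violating cycle invariants (too few samples in
#' systole or diastole) are dropped with a warning.
#'
#' @param w A [waveform].
#' @param onsets Integer onset indices from [detect_beats()].
#' @param t0_override Optional fixed systolic duration in seconds applied to
#'   every cycle instead of notch estimation.
#' @return List of [cardiac_cycle] objects (possibly empty).
#' @export
segment_cycles <- function(w, onsets, t0_override = NULL) {
  stopifnot(inherits(w, "waveform"))
  onsets <- sort(unique(as.integer(onsets)))
  if (length(onsets) < 2L) return(list())
  fs <- w$sampling_rate
  out <- list()
  dropped <- character(0)
  for (k in seq_len(length(onsets) - 1L)) {
    i <- onsets[k]; j <- onsets[k + 1L]
    pr <- w$pressure[i:(j - 1L)]
    cyc <- tryCatch({
      if (is.null(t0_override)) {
        est <- estimate_notch(pr, fs)
        cardiac_cycle(pr, fs, est$T0, w$subject_id, k, t0_fallback = est$fallback)
      } else {
        cardiac_cycle(pr, fs, t0_override, w$subject_id, k)
      }
    }, if_malformed_error = function(e) {
      dropped <<- c(dropped, sprintf("cycle %d: %s", k, conditionMessage(e)))
      NULL
    })
    if (!is.null(cyc)) out[[length(out) + 1L]] <- cyc
  }
  if (length(dropped))
    warning(sprintf("dropped %d cycle(s) [%s]: %s", length(dropped),
                    w$subject_id, paste(dropped, collapse = "; ")),
            call. = FALSE)
  if (length(out)) {
    q <- quality_scores(out)
    for (i in seq_along(out)) out[[i]]$quality <- q[i]
  }
  out
}

#' Select good-quality cycles for analysis
#'
#' Keeps the `min(k_max, available)` highest-quality cycles, returned in
#' recording order; quality ties are broken in favour of the earlier cycle.
#' When fewer than `k_min` cycles are available all of them are returned and
#' the result carries attribute `insufficient = TRUE`.
#'
#' @param cycles List of [cardiac_cycle] objects with quality scores.
#' @param k_min,k_max Minimum and maximum number of cycles to use
#'   (protocol default: three to five).
#' @return Sub-list of `cycles`, attribute `insufficient` set accordingly.
#' @export
select_cycles <- function(cycles, k_min = 3L, k_max = 5L) {
  n <- length(cycles)
  if (n == 0L)
    return(structure(list(), insufficient = TRUE))
  q <- vapply(cycles, function(cy) cy$quality, numeric(1))
  ord <- order(-q, seq_len(n))           # stable: earlier cycle wins ties
  take <- sort(ord[seq_len(min(k_max, n))])
  structure(cycles[take], insufficient = n < k_min)
}
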