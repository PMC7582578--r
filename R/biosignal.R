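# Wearable biosignal processing: PPG band-pass + threshold filtering,
# heart-rate estimation, skin-temperature outlier removal, core-temperature
# estimation from the skin-ambient gradient.

#' Uniformly sampled signal trace
#'
#' Light container for a sensor stream: sample values, sampling rate and
#' start time.
#'
#' @param values numeric sample vector.
#' @param fs sampling rate, Hz (> 0).
#' @param t0 start time (POSIXct), defaults to the epoch.
#' @return Object of class `signal_trace` (list with `values`, `fs`, `t0`).
#' @export
signal_trace <- function(values, fs, t0 = as.POSIXct(0, origin = "1970-01-01",
                                                     tz = "UTC")) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number", call. = FALSE)
  structure(list(values = as.numeric(values), fs = fs, t0 = t0),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz (%.1f s) from %s\n",
              length(x$values), x$fs, length(x$values) / x$fs,
              format(x$t0)))
  invisible(x)
}

#' Sample times of a trace, seconds from start
#' @param trace a [signal_trace()].
#' @return Numeric vector of sample offsets in seconds.
#' @export
trace_times <- function(trace) (seq_along(trace$values) - 1) / trace$fs

#' Band-pass filter a PPG trace
#'
#' Zero-phase Butterworth band-pass (order 4 overall, applied
#' forward-backward so no group delay is introduced) with the 0.5-4 Hz
#' passband that retains the cardiac pulsation while removing baseline
#' wander and high-frequency noise. DC is removed; length is preserved.
#'
#' @param trace a [signal_trace()]; `fs` must be at least 10 Hz so the 4 Hz
#'   passband edge is resolvable. If the trace carries the artifact mask
#'   from [threshold_filter_ppg()], masked samples are linearly
#'   interpolated before filtering (a saturated spike would otherwise be
#'   smeared across its neighbourhood by the filter) and the mask is
#'   carried through to the output.
#' @param low,high passband edges, Hz.
#' @return Filtered [signal_trace()].
#' @examples
#' tr <- signal_trace(sin(2 * pi * 1.5 * (0:499) / 50) + 3, fs = 50)
#' filt <- bandpass_ppg(tr)
#' @export
bandpass_ppg <- function(trace, low = 0.5, high = 4) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$fs < 10)
    stop("fs must be >= 10 Hz to resolve the 4 Hz passband", call. = FALSE)
  if (high >= trace$fs / 2)
    stop("upper passband edge must be below the Nyquist frequency",
         call. = FALSE)
  x <- trace$values
  mask <- attr(trace, "mask")
  if (!is.null(mask) && any(!mask)) {
    idx <- which(mask)
    if (length(idx) < 2) stop("too few unmasked samples", call. = FALSE)
    x <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  }
  bf <- signal::butter(2, c(low, high) / (trace$fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x - mean(x))
  out <- signal_trace(y, trace$fs, trace$t0)
  attr(out, "mask") <- mask
  out
}

#' Amplitude threshold filter for PPG artifacts
#'
#' Flags samples outside `[lo, hi]` (sensor saturation, motion clipping) as
#' artifacts. Retained samples are unchanged; the mask is attached so beat
#' detection can skip flagged regions.
#'
#' @param trace a [signal_trace()].
#' @param lo,hi amplitude bounds, `lo < hi`.
#' @return The trace with an `attr(, "mask")` logical vector, TRUE for
#'   retained samples.
#' @export
threshold_filter_ppg <- function(trace, lo, hi) {
  stopifnot(inherits(trace, "signal_trace"))
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("need lo < hi", call. = FALSE)
  mask <- trace$values >= lo & trace$values <= hi
  out <- trace
  attr(out, "mask") <- mask
  out
}

#' Heart rate from a band-passed PPG trace
#'
#' Beat detection by local-maximum peak picking with a prominence threshold
#' of 0.3 times the windowed signal standard deviation and a 240 ms
#' refractory period (60/250 s, the shortest physiological inter-beat
#' interval considered). The rate in each non-overlapping window is
#' `60 * (beats - 1) / inter-beat span`; windows with fewer than two beats
#' are flagged invalid. Samples masked as artifacts are linearly
#' interpolated before peak picking so clipped excursions cannot register
#' as beats.
#'
#' @param trace a band-passed [signal_trace()], optionally carrying the
#'   artifact mask from [threshold_filter_ppg()].
#' @param window window length in seconds (>= 5).
#' @return Data frame of class `heart_rate_series`: `t_mid` (window centre,
#'   s from trace start), `hr_bpm`, `n_beats`, `valid`.
#' @export
estimate_heart_rate <- function(trace, window = 10) {
  stopifnot(inherits(trace, "signal_trace"))
  if (length(trace$values) == 0) stop("empty trace", call. = FALSE)
  if (window < 5) stop("window must be >= 5 s", call. = FALSE)
  x <- trace$values
  mask <- attr(trace, "mask")
  if (!is.null(mask) && any(!mask)) {
    idx <- which(mask)
    if (length(idx) < 2) stop("too few unmasked samples", call. = FALSE)
    x <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  }
  fs <- trace$fs
  n <- length(x)
  wlen <- round(window * fs)
  starts <- seq(1, n, by = wlen)
  starts <- starts[starts + wlen - 1 <= n | starts == 1]
  refractory <- max(1L, round(0.24 * fs))
  rows <- lapply(starts, function(s) {
    e <- min(s + wlen - 1, n)
    seg <- x[s:e]
    thr <- 0.3 * stats::sd(seg)
    pk <- NULL
    if (is.finite(thr) && thr > 0)
      pk <- pracma::findpeaks(seg, minpeakheight = thr,
                              minpeakdistance = refractory)
    if (is.null(pk) || nrow(pk) < 2)
      return(data.frame(t_mid = (s + e) / 2 / fs, hr_bpm = NA_real_,
                        n_beats = if (is.null(pk)) 0L else nrow(pk),
                        valid = FALSE))
    loc <- sort(pk[, 2])
    span <- (loc[length(loc)] - loc[1]) / fs
    data.frame(t_mid = (s + e) / 2 / fs,
               hr_bpm = 60 * (length(loc) - 1) / span,
               n_beats = length(loc), valid = TRUE)
  })
  out <- do.call(rbind, rows)
  out$valid <- out$valid & !is.na(out$hr_bpm) &
    out$hr_bpm > 0 & out$hr_bpm < 250
  out$hr_bpm[!out$valid] <- NA_real_
  class(out) <- c("heart_rate_series", "data.frame")
  out
}

#' Hampel outlier filter for skin-temperature traces
#'
#' Sliding-window median filter: a sample deviating from the windowed median
#' by more than `k` robust standard deviations (1.4826 * MAD) is replaced by
#' that median; all other samples pass through unchanged. Robust against
#' the brief contact-loss spikes typical of arm-worn temperature sensors
#' while leaving slow physiological drift untouched. The pass is repeated
#' until no further sample is flagged (recursive Hampel; correcting a
#' large spike can unmask a borderline neighbour on the next pass), so
#' the filter is idempotent by construction — in practice one or two
#' passes suffice. The trace is reflected at both ends so edge samples see
#' a full window.
#'
#' @param trace a [signal_trace()].
#' @param half_window half window width in samples (window is
#'   `2 * half_window + 1`).
#' @param k threshold in robust standard deviations.
#' @return Filtered [signal_trace()] with `attr(, "outliers")` giving the
#'   indices of replaced samples. Traces shorter than the window are
#'   returned unchanged with a warning.
#' @examples
#' tr <- signal_trace(c(rep(36, 10), 45, rep(36, 10)), fs = 1 / 60)
#' hampel_filter_temp(tr)
#' @export
hampel_filter_temp <- function(trace, half_window = 5, k = 3) {
  stopifnot(inherits(trace, "signal_trace"))
  if (half_window < 1 || k <= 0)
    stop("need half_window >= 1 and k > 0", call. = FALSE)
  x <- trace$values
  if (length(x) < 2 * half_window + 1) {
    warning("trace shorter than the filter window; returned unchanged")
    attr(trace, "outliers") <- integer(0)
    return(trace)
  }
  # reflect-pad so edge samples get full windows too, then trim
  hw <- half_window
  n <- length(x)
  flagged <- integer(0)
  for (pass in 1:10) {
    xp <- c(x[(hw + 1):2], x, x[(n - 1):(n - hw)])
    h <- pracma::hampel(xp, k = hw, t0 = k)
    ind <- h$ind[h$ind > hw & h$ind <= hw + n] - hw
    if (length(ind) == 0) break
    flagged <- union(flagged, ind)
    x[ind] <- h$y[ind + hw]
  }
  out <- signal_trace(x, trace$fs, trace$t0)
  attr(out, "outliers") <- sort(as.integer(flagged))
  out
}

# Body-part adjustment coefficients for the skin->core temperature gradient.
.core_alpha <- c(rectal = 0.0699, head = 0.3094, torso = 0.5067,
                 hand = 0.7665, foot = 2.1807)

#' Body-part core-temperature adjustment coefficients
#' @return Named numeric vector of the gradient coefficient alpha per
#'   sensor body part.
#' @export
body_part_alpha <- function() .core_alpha

#' Core temperature estimated from skin and ambient temperature
#'
#' `Tcore = Tskin + alpha * (Tskin - Tambient)`, where alpha is the
#' body-part-specific gradient coefficient. An arm-worn device uses the hand
#' coefficient 0.7665 (the default).
#'
#' @param t_skin skin temperature, degC (vectorized).
#' @param t_ambient ambient (dry-bulb) temperature, degC.
#' @param part sensor body part, one of `names(body_part_alpha())`.
#' @return Estimated core temperature, degC.
#' @examples
#' estimate_core_temperature(36, 30)           # hand: 40.599
#' estimate_core_temperature(36, 30, "foot")   # 49.0842
#' @export
estimate_core_temperature <- function(t_skin, t_ambient, part = "hand") {
  part <- match.arg(part, names(.core_alpha))
  if (!is.numeric(t_skin) || !is.numeric(t_ambient) ||
      any(!is.finite(t_skin)) || any(!is.finite(t_ambient)))
    stop("temperatures must be finite numeric", call. = FALSE)
  t_skin + .core_alpha[[part]] * (t_skin - t_ambient)
}
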