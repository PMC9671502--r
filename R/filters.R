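# Time-series filtering and dF/F0.
#
# Filter family: 4th-order Butterworth throughout. Zero-phase filtering is a
# forward-backward pass (signal::filtfilt, no group delay); causal filtering
# is a single forward pass whose output is advanced by round(fps / fc)
# samples to compensate the delay, with the tail padded by the last value.

butter_lp <- function(fc, fps) {
  if (fc <= 0 || fc >= fps / 2)
    stop("parameter error: cutoff must satisfy 0 < fc < fps/2")
  signal::butter(4, fc / (fps / 2), type = "low")
}

# One-pass IIR filter with the step transient removed: the filter runs on
# the series minus its first value and the value re-enters through the DC
# gain, so a constant input yields an exactly constant output.
filter_settled <- function(bf, x) {
  dc <- sum(bf$b) / sum(bf$a)
  as.numeric(signal::filter(bf, x - x[1])) + x[1] * dc
}

# Forward-backward (zero-phase) filtering with odd-reflection padding of
# about three corner periods on each side, so edge transients decay inside
# the padding (signal::filtfilt itself starts from zero state and leaks
# long transients at slow corner frequencies).
filtfilt_padded <- function(bf, x, f_corner, fps) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * fps / f_corner)))
  ext <- c(2 * x[1] - x[seq(pad + 1L, 2L)], x, 2 * x[n] - x[seq(n - 1L, n - pad)])
  y <- filter_settled(bf, ext)
  y <- rev(filter_settled(bf, rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Low-pass filter a trace
#'
#' @param trace numeric vector.
#' @param fc cutoff frequency in Hz (`0 < fc < fps/2`).
#' @param fps sampling rate in Hz.
#' @param mode `"zero_phase"` (forward-backward, no delay) or `"causal"`
#'   (one-pass filter, then the output is advanced by `round(fps / fc)`
#'   samples -- e.g. 30 fps at fc = 0.3 Hz gives a 100-sample shift -- with
#'   the tail padded by the last filtered value).
#' @return filtered trace, same length as the input.
#' @export
lowpass_filter <- function(trace, fc, fps, mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  bf <- butter_lp(fc, fps)
  if (mode == "zero_phase") {
    filtfilt_padded(bf, trace, fc, fps)
  } else {
    y <- filter_settled(bf, trace)
    shift <- causal_filter_shift(fc, fps)
    n <- length(y)
    if (shift >= n) stop("trace shorter than the causal delay correction")
    c(y[(shift + 1):n], rep(y[n], shift))
  }
}

#' Delay correction of the causal low-pass filter
#'
#' The one-pass filter delays the trace by roughly one cutoff period; the
#' correction advances it by `round(fps * 1 / fc)` samples.
#'
#' @inheritParams lowpass_filter
#' @return integer number of samples.
#' @export
causal_filter_shift <- function(fc, fps) {
  if (fc <= 0 || fc >= fps / 2)
    stop("parameter error: cutoff must satisfy 0 < fc < fps/2")
  as.integer(round(fps / fc))
}

#' Band-pass filter a trace (zero phase)
#'
#' Default preprocessing of raw fluorescence: a 0.1-6 Hz band removes the
#' DC baseline (so the output plays the role of dF/F0) and high-frequency
#' noise.
#'
#' @param trace numeric vector.
#' @param lo,hi band corner frequencies in Hz, `0 < lo < hi < fps/2`.
#' @param fps sampling rate in Hz.
#' @return filtered trace with mean approximately 0.
#' @export
bandpass_filter <- function(trace, lo = 0.1, hi = 6, fps = 30) {
  if (!(lo > 0 && lo < hi && hi < fps / 2))
    stop("parameter error: band must satisfy 0 < lo < hi < fps/2")
  bf <- signal::butter(2, c(lo, hi) / (fps / 2), type = "pass")
  filtfilt_padded(bf, trace, lo, fps)
}

#' Sliding-baseline dF/F0 around an event
#'
#' For an analysis window of +/- `half_window_s` seconds around the event,
#' the baseline F0 is the mean of the immediately preceding window of the
#' same length: for a +/-3 s analysis window, F0 comes from the -6 to -3 s
#' window. Output is `(F - F0) / F0` over the analysis window.
#'
#' @param trace full-session fluorescence trace.
#' @param fps sampling rate in Hz.
#' @param event_time_s event time in seconds from trace start.
#' @param half_window_s analysis half-window in seconds (default 3).
#' @return list with `dff` (the dF/F0 series over `[-W, +W)`) and
#'   `times_s` (peri-event time axis).
#' @export
compute_dff <- function(trace, fps, event_time_s, half_window_s = 3) {
  w <- as.integer(round(half_window_s * fps))
  e <- time_to_index(event_time_s, fps)
  a0 <- e - w; a1 <- e + w - 1L   # analysis [-W, +W)
  b0 <- e - 2L * w; b1 <- e - w - 1L  # baseline [-2W, -W)
  if (b0 < 1) stop("insufficient history before the event for the baseline window")
  if (a1 > length(trace)) stop("analysis window extends past the end of the trace")
  f0 <- mean(trace[b0:b1])
  if (f0 == 0) stop("undefined baseline: F0 = 0")
  list(dff = (trace[a0:a1] - f0) / f0,
       times_s = (seq(a0, a1) - e) / fps)
}
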