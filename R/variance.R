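# Trial-to-trial variance traces and the earliest variance (decrease)
# detection time (EVDT).
#
# The EVDT of a session/area is the earliest time at which the across-trial
# variance, in a 1-s sliding window (one-frame step, closed on the left),
# stays beyond a threshold derived from a pre-event baseline: mean minus
# k standard deviations of the variance over -30..-15 s (decrease mode), or
# |variance - baseline mean| > k sd in absolute mode (for subjects whose
# pre-movement variance increases). Detections outside -6..+0.5 s are
# discarded. The statistic is threshold-sensitive by construction; EVDT is
# intended for non-lockout trial sets (pooled lockout sets carry much
# higher intra-session variance).

#' Across-trial variance trace of one area
#'
#' @param ts a `trial_set` (>= 5 trials).
#' @param area feature label.
#' @param smooth if `TRUE`, Savitzky-Golay smooth the variance trace
#'   (31 samples, order 3) before thresholding -- used e.g. for noisy
#'   visual-cortex data.
#' @return list with `times_s` and `variance` (sample variance across
#'   trials at each peri-event time point).
#' @export
variance_trace <- function(ts, area, smooth = FALSE) {
  ai <- match(area, ts$feature_desc)
  if (is.na(ai)) stop("unknown area label: ", area)
  if (n_trials(ts) < 5) stop("need at least 5 trials for a variance trace")
  v <- apply(ts$data[, ai, ], 2, stats::var)
  if (smooth) v <- as.numeric(signal::sgolayfilt(v, p = 3, n = 31))
  list(times_s = ts$times_s, variance = v)
}

#' Earliest variance change time from a variance trace
#'
#' @param variance per-timepoint across-trial variance (see
#'   [variance_trace()]).
#' @param times_s matching peri-event time axis covering the baseline
#'   window and the valid range.
#' @param baseline_window_s baseline span (default `c(-30, -15)`).
#' @param k threshold multiplier in baseline standard deviations
#'   (default 2; detection is monotone in `k`: larger `k` never yields an
#'   earlier EVDT).
#' @param valid_range_s detections outside this range are discarded
#'   (default `c(-6, 0.5)`).
#' @param mode `"decrease"`: every sample of a 1-s window below
#'   `mean_b - k sd_b`; `"absolute"`: every sample with
#'   `|v - mean_b| > k sd_b`.
#' @param window_len_s qualifying window length (default 1 s).
#' @return object of class `evdt_result` with `evdt_s` (`NA` when
#'   undetected), `detected`, `threshold`, `mode`, and the baseline
#'   moments.
#' @export
compute_evdt <- function(variance, times_s,
                         baseline_window_s = c(-30, -15), k = 2,
                         valid_range_s = c(-6, 0.5),
                         mode = c("decrease", "absolute"),
                         window_len_s = 1) {
  mode <- match.arg(mode)
  bsel <- times_s >= baseline_window_s[1] & times_s < baseline_window_s[2]
  if (sum(bsel) < 10) stop("variance trace does not cover the baseline window")
  mu_b <- mean(variance[bsel])
  sd_b <- stats::sd(variance[bsel])
  if (sd_b == 0) {
    # a globally constant trace can never cross the threshold: undetected;
    # a varying trace over a flat baseline has no usable threshold: error
    if (all(variance == variance[1]))
      return(structure(list(evdt_s = NA_real_, detected = FALSE,
                            mode = mode, k = k, threshold = NA_real_,
                            baseline_mean = mu_b, baseline_sd = 0,
                            times_s = times_s, variance = variance),
                       class = "evdt_result"))
    stop("degenerate baseline: zero variance-of-variance")
  }
  fps <- 1 / stats::median(diff(times_s))
  wlen <- as.integer(round(window_len_s * fps))
  qual <- if (mode == "decrease") variance < mu_b - k * sd_b
          else abs(variance - mu_b) > k * sd_b
  n <- length(qual)
  # earliest start of a fully-qualifying 1-s window (left-closed)
  run <- stats::filter(as.numeric(qual), rep(1, wlen), sides = 1)
  starts <- which(run[seq(wlen, n)] == wlen)
  det <- NA_real_
  if (length(starts)) {
    t0 <- times_s[starts[1]]
    if (t0 >= valid_range_s[1] && t0 <= valid_range_s[2]) det <- t0
  }
  structure(list(evdt_s = det, detected = is.finite(det),
                 mode = mode, k = k,
                 threshold = if (mode == "decrease") mu_b - k * sd_b else k * sd_b,
                 baseline_mean = mu_b, baseline_sd = sd_b,
                 times_s = times_s, variance = variance),
            class = "evdt_result")
}

#' @export
print.evdt_result <- function(x, ...) {
  cat(sprintf("<evdt_result> %s mode: %s\n", x$mode,
              if (x$detected) sprintf("EVDT = %.3f s", x$evdt_s) else "undetected"))
  invisible(x)
}

#' Session EVDT for one area
#'
#' Extracts trials, computes the across-trial variance trace and applies
#' [compute_evdt()]. Warns when applied to pooled lockout trial sets.
#'
#' @param ts a `trial_set` whose window covers the baseline (-30 s) and
#'   the valid range.
#' @param area feature label.
#' @param smooth smooth the variance trace first (see [variance_trace()]).
#' @param ... passed to [compute_evdt()].
#' @return an `evdt_result`.
#' @export
session_evdt <- function(ts, area, smooth = FALSE, ...) {
  vt <- variance_trace(ts, area, smooth = smooth)
  compute_evdt(vt$variance, vt$times_s, ...)
}
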