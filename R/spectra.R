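# Welch power spectral density of slow oscillations and longitudinal
# trends in peak frequency/power across sessions.

#' Welch power spectral density
#'
#' Mean-removed Hann-windowed segments of length `nperseg` with 50%
#' overlap; one-sided density normalized so that the integral over
#' frequency equals the signal variance (a unit-amplitude sinusoid has
#' total power 1/2 concentrated at its frequency).
#'
#' @param trace numeric vector.
#' @param fps sampling rate in Hz.
#' @param nperseg segment length in samples (default `min(n, 512)`).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power / Hz).
#' @export
psd_welch <- function(trace, fps, nperseg = min(length(trace), 512L),
                      overlap = 0.5) {
  n <- length(trace)
  if (nperseg < 8) stop("trace too short for spectral estimation")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  scale <- 1 / (fps * sum(w^2))
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- trace[s0:(s0 + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nf)]
  }
  psd <- acc / length(starts) * scale
  # one-sided: double everything except DC (and Nyquist for even nperseg)
  dbl <- 2:(nf - if (nperseg %% 2L == 0L) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_len(nf) - 1L) * fps / nperseg, psd = psd)
}

#' Peak frequency and power of a trace within a band
#'
#' Welch PSD restricted to `band`; the peak is the argmax. Applied both to
#' session trial-averages and to single trials; slow-oscillation peaks are
#' expected in 0.2-0.6 Hz. Invariant to a DC offset.
#'
#' @param trace numeric vector (at least `2 / band[1]` seconds long).
#' @param fps sampling rate in Hz.
#' @param band frequency band `c(lo, hi)` in Hz (default `c(0.05, 2)`).
#' @param ... passed to [psd_welch()].
#' @return list with `peak_freq` (Hz) and `peak_power` (power / Hz).
#' @export
psd_peak <- function(trace, fps, band = c(0.05, 2), ...) {
  if (length(trace) / fps < 2 / band[1])
    stop("trace too short: need at least ", 2 / band[1], " s")
  ps <- psd_welch(trace, fps, ...)
  sel <- which(ps$freq >= band[1] & ps$freq <= band[2])
  if (!length(sel)) stop("no frequency bins inside the band")
  i <- sel[which.max(ps$psd[sel])]
  list(peak_freq = ps$freq[i], peak_power = ps$psd[i])
}

#' Longitudinal trend of a per-session quantity
#'
#' Pearson correlation of a value (EDT, peak frequency, pull count, ...)
#' against the session ordinal, with a two-sided p value. The first
#' `burn_in` sessions (habituation) can be discarded.
#'
#' @param session_index ordered integer session ordinals.
#' @param values matching per-session values.
#' @param burn_in drop sessions with ordinal <= `burn_in` (default 0;
#'   7 discards the first week).
#' @return list with `pearson_r`, `p_value`, `n`; constant values yield
#'   `pearson_r = NA` with a flag `degenerate = TRUE`.
#' @export
longitudinal_trend <- function(session_index, values, burn_in = 0) {
  keep <- session_index > burn_in
  x <- session_index[keep]; y <- values[keep]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 sessions after burn-in")
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(pearson_r = NA_real_, p_value = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), degenerate = FALSE)
}
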