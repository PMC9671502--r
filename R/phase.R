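# Single-trial sinusoid fits and circular statistics of the
# slow-oscillation phase at action time.
#
# Over a 5-s window a sinusoid fit is unidentifiable without frequency
# constraints, so the fit multi-starts over a frequency grid (0.1..1 Hz,
# bounds 0.05..2 Hz); at each start amplitude and phase are initialized by
# linear regression on sin/cos components and refined with
# Levenberg-Marquardt least squares. The best-RMSE start wins.

#' Fit a sinusoid to a single pre-movement trial trace
#'
#' Nonlinear least squares of `A sin(2 pi f t + phi) + c` over the fit
#' window; the phase at t = 0 is `wrap(phi)` in (-pi, pi].
#'
#' @param trace single-trial trace.
#' @param times_s matching peri-event time axis in seconds.
#' @param fit_window_s fit window (default `c(-5, 0)`, the last 5 s before
#'   the action).
#' @param freq_grid multi-start frequency grid in Hz.
#' @param freq_bounds frequency bounds in Hz.
#' @return object of class `phase_fit`: `amplitude`, `freq`,
#'   `phase_at_zero`, `offset`, `fit_rmse`, `converged`.
#' @export
fit_sinusoid <- function(trace, times_s, fit_window_s = c(-5, 0),
                         freq_grid = seq(0.1, 1, by = 0.1),
                         freq_bounds = c(0.05, 2)) {
  sel <- times_s >= fit_window_s[1] & times_s < fit_window_s[2] + 1e-9
  if (sum(sel) < 8) stop("fit window outside the trial or too short")
  tt <- times_s[sel]
  y <- trace[sel]

  best <- NULL
  for (f0 in freq_grid) {
    # linear initialization at fixed frequency
    S <- sin(2 * pi * f0 * tt); C <- cos(2 * pi * f0 * tt)
    co <- tryCatch(stats::coef(stats::lm(y ~ S + C)), error = function(e) NULL)
    if (is.null(co) || any(!is.finite(co))) next
    A0 <- unname(sqrt(co[2]^2 + co[3]^2))
    phi0 <- unname(atan2(co[3], co[2]))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * sin(2 * pi * f * tt + phi) + c0,
        start = list(A = max(A0, 1e-6), f = f0, phi = phi0, c0 = unname(co[1])),
        lower = c(A = 0, f = freq_bounds[1], phi = -2 * pi, c0 = -Inf),
        upper = c(A = Inf, f = freq_bounds[2], phi = 2 * pi, c0 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(stats::resid(fit)^2))
    if (is.null(best) || rmse < best$fit_rmse) {
      p <- stats::coef(fit)
      best <- list(amplitude = unname(p["A"]), freq = unname(p["f"]),
                   phase_at_zero = wrap_angle(unname(p["phi"])),
                   offset = unname(p["c0"]), fit_rmse = rmse,
                   converged = TRUE)
    }
  }
  if (is.null(best))
    best <- list(amplitude = NA_real_, freq = NA_real_,
                 phase_at_zero = NA_real_, offset = NA_real_,
                 fit_rmse = NA_real_, converged = FALSE)
  structure(best, class = "phase_fit")
}

#' Sinusoid-fit phases at t = 0 for every trial of an area
#'
#' @param ts a `trial_set` whose time axis covers the fit window.
#' @param area feature label to fit (e.g. `"limb_L"`).
#' @param ... passed to [fit_sinusoid()].
#' @return data.frame with one row per trial: `phase`, `freq`,
#'   `amplitude`, `rmse`, `converged`; non-convergent trials carry NA.
#' @export
trial_phases <- function(ts, area, ...) {
  ai <- match(area, ts$feature_desc)
  if (is.na(ai)) stop("unknown area label: ", area)
  fits <- lapply(seq_len(n_trials(ts)), function(i)
    fit_sinusoid(ts$data[i, ai, ], ts$times_s, ...))
  data.frame(phase = vapply(fits, `[[`, 1, "phase_at_zero"),
             freq = vapply(fits, `[[`, 1, "freq"),
             amplitude = vapply(fits, `[[`, 1, "amplitude"),
             rmse = vapply(fits, `[[`, 1, "fit_rmse"),
             converged = vapply(fits, `[[`, TRUE, "converged"))
}

#' Circular summary statistics of a phase sample
#'
#' Circular mean and resultant length by trigonometric moments, and the
#' Rayleigh test of uniformity with the standard finite-n correction.
#'
#' @param phases angles in radians (>= 5 values).
#' @return list with `circ_mean` (radians in (-pi, pi]),
#'   `resultant_length` (0..1) and `rayleigh_p`.
#' @export
phase_stats <- function(phases) {
  phases <- phases[is.finite(phases)]
  n <- length(phases)
  if (n < 5) stop("need at least 5 phases")
  C <- mean(cos(phases)); S <- mean(sin(phases))
  R <- sqrt(C^2 + S^2)
  Z <- n * R^2
  # Zar's finite-n corrected Rayleigh p
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(circ_mean = atan2(S, C), resultant_length = R,
       rayleigh_p = min(1, max(0, p)))
}

#' Pairwise circular correlation of per-trial phases between areas
#'
#' Fisher-Lee circular-circular correlation between every pair of areas'
#' per-trial phases (plain Pearson on wrapped angles is wrong at the
#' +/- pi seam). Areas with (near-)constant phases yield NA entries.
#'
#' @param phase_mat matrix `[trials x areas]` of angles in radians
#'   (>= 5 complete rows).
#' @return symmetric correlation matrix with unit diagonal, plus the
#'   median off-diagonal value as attribute `"median_offdiag"`.
#' @export
interarea_phase_corr <- function(phase_mat) {
  phase_mat <- phase_mat[stats::complete.cases(phase_mat), , drop = FALSE]
  n <- nrow(phase_mat); m <- ncol(phase_mat)
  if (n < 5) stop("need at least 5 complete trials")
  sines <- lapply(seq_len(m), function(j) {
    a <- phase_mat[, j]
    sin(outer(a, a, `-`))
  })
  denoms <- vapply(sines, function(sa) sum(sa^2), 1)
  out <- diag(1, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    den <- sqrt(denoms[i] * denoms[j])
    out[i, j] <- out[j, i] <-
      if (den < 1e-12) NA_real_ else sum(sines[[i]] * sines[[j]]) / den
  }
  dimnames(out) <- list(colnames(phase_mat), colnames(phase_mat))
  off <- out[upper.tri(out)]
  attr(out, "median_offdiag") <- stats::median(off, na.rm = TRUE)
  out
}
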