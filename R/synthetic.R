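# Synthetic session generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# per-area slow oscillations (0.2-0.6 Hz) of area-dependent amplitude riding
# on mean-reverting (Ornstein-Uhlenbeck) noise; a self-initiated rewarded
# lever-pull train with a refractory lockout; and, locked to each rewarded
# event, (i) a pre-event inhibitory ramp in motor/limb areas, (ii) a
# continuous pull of the oscillation phase so that the phase at t = 0 follows
# a von Mises law, and (iii) a scaling of the noise amplitude from a
# configurable pre-event onset. Paw-position tracks contain movement bouts
# co-occurring with lever events plus independent bouts. Every implanted
# parameter is recorded in the session metadata for recovery tests.

#' Synthetic session configuration
#'
#' Defaults encode the emulated recording conditions: 1330-s sessions at
#' 30 Hz neural / 15 Hz video, ten bilateral cortical areas with slow
#' oscillation frequencies drawn in 0.2-0.6 Hz and limb-cortex amplitude
#' ten times visual-cortex amplitude, a 3-s lever lockout, an inhibitory
#' ramp in motor/limb cortex starting 5 s before each rewarded pull, phase
#' concentration at the pull, and a trial-to-trial variance decrease from
#' 3 s before the pull.
#'
#' @param duration_s session length in seconds (default 1330).
#' @param fps_neural,fps_video sampling rates in Hz.
#' @param n_areas number of areas (10 gives the named bilateral set).
#' @param area_labels optional label vector.
#' @param osc_freq_hz per-area oscillation frequency in Hz; `NULL` draws
#'   each uniformly in `[0.2, 0.6]` at generation time.
#' @param osc_amp per-area oscillation amplitude (a.u.); `NULL` uses
#'   limb 0.10, motor 0.06, barrel/retrosplenial 0.04, visual 0.01.
#' @param noise_sd stationary standard deviation of the OU background.
#' @param ou_tau_s OU mean-reversion time constant in seconds.
#' @param event_rate_hz rewarded lever-pull rate before lockout thinning.
#' @param unrewarded_rate_hz,lick_rate_hz rates of the other event kinds.
#' @param lockout_s refractory lockout between rewarded pulls (> 0).
#' @param signal_onset_s ground-truth decodability onset in seconds
#'   (<= 0); ramp and phase pull start here.
#' @param ramp_depth per-area inhibitory ramp depth (a.u., applied
#'   negatively); `NULL` uses 0.05 for motor/limb and 0 elsewhere.
#' @param phase_mu,phase_kappa von Mises mean and concentration of the
#'   oscillation phase at t = 0 (`phase_kappa >= 0`).
#' @param var_change_onset_s start of the pre-event noise-amplitude change
#'   (seconds, <= 0).
#' @param var_change_factor multiplier on the noise sd from
#'   `var_change_onset_s` to the event (< 1 decrease, > 1 increase; > 0).
#' @param bout_rate_hz,bout_amp_px,bout_dur_s,track_noise_px paw-track bout
#'   parameters (rate of spontaneous bouts, displacement amplitude and
#'   duration, positional jitter).
#' @param seed optional default seed (the `seed` argument of
#'   [generate_session()] takes precedence).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 1330, fps_neural = 30, fps_video = 15,
                         n_areas = 10, area_labels = NULL,
                         osc_freq_hz = NULL, osc_amp = NULL,
                         noise_sd = 0.025, ou_tau_s = 1,
                         event_rate_hz = 0.03, unrewarded_rate_hz = 0.03,
                         lick_rate_hz = 0.1,
                         lockout_s = 3,
                         signal_onset_s = -5, ramp_depth = NULL,
                         phase_mu = pi / 2, phase_kappa = 10,
                         var_change_onset_s = -3, var_change_factor = 0.5,
                         bout_rate_hz = 0.05, bout_amp_px = 20,
                         bout_dur_s = 0.5, track_noise_px = 0.5,
                         seed = NULL) {
  if (signal_onset_s > 0) stop("`signal_onset_s` must be <= 0")
  if (lockout_s <= 0) stop("`lockout_s` must be > 0")
  if (phase_kappa < 0) stop("`phase_kappa` must be >= 0")
  if (var_change_factor <= 0) stop("`var_change_factor` must be > 0")
  if (var_change_onset_s > 0) stop("`var_change_onset_s` must be <= 0")
  if (is.null(area_labels))
    area_labels <- if (n_areas == 10) default_area_labels()
                   else sprintf("area_%02d", seq_len(n_areas))
  if (length(area_labels) != n_areas) stop("`area_labels` length != n_areas")
  amp_for <- function(lab) {
    if (grepl("^limb", lab)) 0.10
    else if (grepl("^motor", lab)) 0.06
    else if (grepl("^visual", lab)) 0.01
    else 0.04
  }
  if (is.null(osc_amp)) osc_amp <- vapply(area_labels, amp_for, 1)
  if (is.null(ramp_depth))
    ramp_depth <- ifelse(grepl("^(motor|limb)", area_labels), 0.05, 0)
  osc_amp <- rep_len(osc_amp, n_areas)
  ramp_depth <- rep_len(ramp_depth, n_areas)
  if (!is.null(osc_freq_hz)) osc_freq_hz <- rep_len(osc_freq_hz, n_areas)
  structure(list(duration_s = duration_s, fps_neural = fps_neural,
                 fps_video = fps_video, n_areas = n_areas,
                 area_labels = area_labels, osc_freq_hz = osc_freq_hz,
                 osc_amp = osc_amp, noise_sd = noise_sd, ou_tau_s = ou_tau_s,
                 event_rate_hz = event_rate_hz,
                 unrewarded_rate_hz = unrewarded_rate_hz,
                 lick_rate_hz = lick_rate_hz, lockout_s = lockout_s,
                 signal_onset_s = signal_onset_s, ramp_depth = ramp_depth,
                 phase_mu = phase_mu, phase_kappa = phase_kappa,
                 var_change_onset_s = var_change_onset_s,
                 var_change_factor = var_change_factor,
                 bout_rate_hz = bout_rate_hz, bout_amp_px = bout_amp_px,
                 bout_dur_s = bout_dur_s, track_noise_px = track_noise_px,
                 seed = seed),
            class = "synth_config")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- wrap_angle(sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f))) + mu)
      i <- i + 1L
    }
  }
  out
}

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

# Poisson event train thinned so consecutive kept events are >= gap_s apart.
poisson_train <- function(rate_hz, duration_s, gap_s = 0) {
  if (rate_hz <= 0) return(numeric(0))
  n_exp <- stats::rpois(1, rate_hz * duration_s * 1.5) + 20L
  tt <- cumsum(stats::rexp(n_exp, rate_hz))
  tt <- tt[tt < duration_s]
  if (gap_s > 0 && length(tt) > 1) {
    keep <- rep(FALSE, length(tt))
    last <- -Inf
    for (i in seq_along(tt)) {
      if (tt[i] - last >= gap_s) { keep[i] <- TRUE; last <- tt[i] }
    }
    tt <- tt[keep]
  }
  tt
}

# Ornstein-Uhlenbeck background with stationary sd ~= 1.
ou_noise <- function(n, dt, tau) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  a <- exp(-dt / tau)
  b <- sqrt(1 - a^2)
  innov <- stats::rnorm(n - 1)
  for (i in 2:n) x[i] <- a * x[i - 1] + b * innov[i - 1]
  x
}

#' Generate a synthetic session
#'
#' See [synth_config()] for the implanted structure. Locked to each rewarded
#' lever pull the generator (i) cross-fades the area oscillation, over
#' `[signal_onset_s, 0]`, into an event-locked sinusoid whose phase at
#' t = 0 is a von Mises draw (a continuous phase pull -- the trace stays
#' smooth and, over the final seconds, is an exact sinusoid with the
#' implanted phase), (ii) adds a half-cosine inhibitory ramp reaching
#' `-ramp_depth` at t = 0, and (iii) scales the noise sd by
#' `var_change_factor` from `var_change_onset_s`. The ground-truth record
#' (implanted onsets, per-event phases, per-area parameters) is stored in
#' `meta$ground_truth`.
#'
#' @param cfg a `synth_config`.
#' @param seed integer seed; the same `(cfg, seed)` pair always yields an
#'   identical session.
#' @return a `premove_session`.
#' @export
generate_session <- function(cfg, seed = cfg$seed) {
  generate_session_impl(cfg, seed, structured = TRUE)
}

#' Generate a null session (no pre-event structure)
#'
#' Identical background process and event trains as [generate_session()]
#' but with no ramp, no phase pull and no variance change: neural activity
#' around events is statistically indistinguishable from random periods of
#' activity. Used as the negative control for decoding, phase and variance
#' analyses.
#'
#' @inheritParams generate_session
#' @return a `premove_session`.
#' @export
generate_null_session <- function(cfg, seed = cfg$seed) {
  generate_session_impl(cfg, seed, structured = FALSE)
}

generate_session_impl <- function(cfg, seed, structured) {
  if (!inherits(cfg, "synth_config")) stop("`cfg` must be a synth_config")
  with_seed(seed, {
    fps <- cfg$fps_neural
    n <- as.integer(round(cfg$duration_s * fps))
    tt <- (seq_len(n) - 1) / fps
    dt <- 1 / fps

    freqs <- cfg$osc_freq_hz %||% stats::runif(cfg$n_areas, 0.2, 0.6)
    theta0 <- stats::runif(cfg$n_areas, -pi, pi)

    rewarded <- poisson_train(cfg$event_rate_hz, cfg$duration_s, cfg$lockout_s)
    unrewarded <- poisson_train(cfg$unrewarded_rate_hz, cfg$duration_s)
    # unrewarded pulls cannot coincide with a reward delivery
    if (length(unrewarded) && length(rewarded)) {
      d <- vapply(unrewarded, function(u) min(abs(u - rewarded)), 1)
      unrewarded <- unrewarded[d > 0.5]
    }
    licks <- poisson_train(cfg$lick_rate_hz, cfg$duration_s)
    if (length(rewarded)) {  # consummatory lick burst after each reward
      burst <- as.vector(outer(rewarded + 0.35, 0.3 * (0:4), `+`))
      licks <- sort(c(licks, burst[burst < cfg$duration_s]))
    }

    psi <- rvonmises(length(rewarded), cfg$phase_mu, cfg$phase_kappa)

    pre_len <- -cfg$signal_onset_s
    neural <- matrix(0, cfg$n_areas, n)
    for (a in seq_len(cfg$n_areas)) {
      osc <- cfg$osc_amp[a] * sin(2 * pi * freqs[a] * tt + theta0[a])
      ramp <- numeric(n)
      env <- rep(1, n)
      if (structured && length(rewarded)) {
        for (e in seq_along(rewarded)) {
          Te <- rewarded[e]
          i0 <- max(1L, time_to_index(Te + cfg$signal_onset_s, fps))
          i1 <- min(n, time_to_index(Te, fps))
          i2 <- min(n, time_to_index(Te + 1.5, fps))
          if (i1 > i0 && pre_len > 0) {
            idx <- i0:i1
            # cross-fade weight: completes within the first ~15% of the
            # pre-window, so structure emerges promptly at the nominal onset
            # and most of the window is an exact event-locked sinusoid
            u <- (tt[idx] - (Te + cfg$signal_onset_s)) / pre_len
            w <- smoothstep(u / 0.15)
            target <- cfg$osc_amp[a] * sin(2 * pi * freqs[a] * (tt[idx] - Te) + psi[e])
            osc[idx] <- (1 - w) * osc[idx] + w * target
            if (i2 > i1) {  # release back to the background oscillation
              idx2 <- i1:i2
              u2 <- (tt[idx2] - Te) / 1.5
              w2 <- 1 - smoothstep(u2)
              target2 <- cfg$osc_amp[a] * sin(2 * pi * freqs[a] * (tt[idx2] - Te) + psi[e])
              osc[idx2] <- (1 - w2) * osc[idx2] + w2 * target2
            }
            # inhibitory half-cosine ramp, released over 1 s post event
            if (cfg$ramp_depth[a] != 0) {
              ramp[idx] <- -cfg$ramp_depth[a] * (1 - cos(pi * pmin(1, u))) / 2
              i3 <- min(n, time_to_index(Te + 1, fps))
              if (i3 > i1) {
                idx3 <- i1:i3
                ramp[idx3] <- -cfg$ramp_depth[a] * (1 + cos(pi * (tt[idx3] - Te))) / 2
              }
            }
          }
          # noise-amplitude change from var_change_onset_s to the event
          iv <- max(1L, time_to_index(Te + cfg$var_change_onset_s, fps))
          if (i1 > iv) env[iv:i1] <- cfg$var_change_factor
        }
      }
      noise <- ou_noise(n, dt, cfg$ou_tau_s) * cfg$noise_sd * env
      neural[a, ] <- osc + ramp + noise
    }

    tr <- make_tracks(cfg, rewarded, unrewarded)

    ev <- event_table(
      c(rewarded, unrewarded, licks, tr$left_paw_times, tr$right_paw_times),
      c(rep("lever_rewarded", length(rewarded)),
        rep("lever_unrewarded", length(unrewarded)),
        rep("lick", length(licks)),
        rep("left_paw", length(tr$left_paw_times)),
        rep("right_paw", length(tr$right_paw_times))))

    gt <- list(structured = structured,
               signal_onset_s = cfg$signal_onset_s,
               ramp_depth = as.list(stats::setNames(cfg$ramp_depth, cfg$area_labels)),
               phase_mu = cfg$phase_mu, phase_kappa = cfg$phase_kappa,
               event_phases = psi,
               var_change_onset_s = cfg$var_change_onset_s,
               var_change_factor = cfg$var_change_factor,
               osc_freq_hz = as.list(stats::setNames(freqs, cfg$area_labels)),
               osc_phase0 = as.list(stats::setNames(theta0, cfg$area_labels)),
               osc_amp = as.list(stats::setNames(cfg$osc_amp, cfg$area_labels)),
               noise_sd = cfg$noise_sd,
               rewarded_times = rewarded)
    if (!structured) {
      gt$event_phases <- NULL
      gt[c("signal_onset_s", "var_change_onset_s")] <- list(NULL, NULL)
    }

    session(neural, fps_neural = fps, area_labels = cfg$area_labels,
            events = ev, tracks = tr$tracks,
            session_id = sprintf("synth_%s_%s",
                                 if (structured) "struct" else "null",
                                 seed %||% "x"),
            session_index = 1L,
            meta = list(ground_truth = gt, generator_seed = seed))
  })
}

# Paw/jaw/nose position tracks: baseline + jitter + half-sine movement
# bouts. Right-paw bouts co-occur with every lever event (the pulling paw);
# both paws also move in independent spontaneous bouts.
make_tracks <- function(cfg, rewarded, unrewarded) {
  fps <- cfg$fps_video
  nv <- as.integer(round(cfg$duration_s * fps))
  tv <- (seq_len(nv) - 1) / fps
  base <- list(left_paw = c(120, 200), right_paw = c(180, 200),
               jaw = c(150, 120), nose = c(150, 80))
  bout_profile <- function(times) {
    dx <- numeric(nv)
    for (T in times) {
      i0 <- max(1L, time_to_index(T, fps))
      i1 <- min(nv, time_to_index(T + cfg$bout_dur_s, fps))
      if (i1 > i0)
        dx[i0:i1] <- dx[i0:i1] +
          cfg$bout_amp_px * sin(pi * (tv[i0:i1] - T) / cfg$bout_dur_s)
    }
    dx
  }
  left_times <- poisson_train(cfg$bout_rate_hz, cfg$duration_s, cfg$bout_dur_s)
  right_spont <- poisson_train(cfg$bout_rate_hz, cfg$duration_s, cfg$bout_dur_s)
  right_times <- sort(unique(c(right_spont, rewarded, unrewarded)))
  other_times <- list(jaw = poisson_train(cfg$bout_rate_hz / 2, cfg$duration_s),
                      nose = poisson_train(cfg$bout_rate_hz / 2, cfg$duration_s))
  mk <- function(name, times) {
    dx <- bout_profile(times)
    cbind(x = base[[name]][1] + dx + stats::rnorm(nv, 0, cfg$track_noise_px),
          y = base[[name]][2] + 0.4 * dx + stats::rnorm(nv, 0, cfg$track_noise_px))
  }
  tracks <- body_track(list(left_paw = mk("left_paw", left_times),
                            right_paw = mk("right_paw", right_times),
                            jaw = mk("jaw", other_times$jaw),
                            nose = mk("nose", other_times$nose)),
                       fps_video = fps)
  list(tracks = tracks, left_paw_times = left_times,
       right_paw_times = right_times)
}
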