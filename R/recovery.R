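# Parameter-recovery experiments: run the full pipeline on generated
# sessions and measure how well the implanted ground truth is recovered.
# These are the package's validation experiments; the problem sizes
# (windows, evaluation grid, session counts) are fixed here and discussed
# in the methods vignette.

#' Keep the first n trials of a trial set
#' @param ts a `trial_set`.
#' @param n trial count to keep (head of the acquisition order).
#' @return the truncated `trial_set`.
#' @export
head_trials <- function(ts, n) {
  n <- min(n, n_trials(ts))
  ts$data <- ts$data[seq_len(n), , , drop = FALSE]
  ts$provenance <- ts$provenance[seq_len(n), , drop = FALSE]
  ts
}

# Generate sessions until the pooled rewarded-event count (with full
# peri-event windows) reaches n_needed.
generate_until <- function(cfg, seed, n_needed, window_s, max_sessions = 12L,
                           null = FALSE) {
  gen <- if (null) generate_null_session else generate_session
  sess <- list()
  usable <- 0L
  lo <- -window_s[1]; hi <- cfg$duration_s - window_s[2]
  for (i in seq_len(max_sessions)) {
    s <- gen(cfg, seed = (seed * 131L + i) %% .Machine$integer.max)
    sess[[i]] <- s
    rew <- event_times(s$events, "lever_rewarded")
    usable <- usable + sum(rew >= lo & rew <= hi)
    if (usable >= n_needed) break
  }
  if (usable < n_needed)
    stop("could not accumulate ", n_needed, " usable trials")
  sess
}

#' EDT recovery on structured synthetic sessions
#'
#' Generates sessions with a known decodability onset, pools trials across
#' sessions in a shared PCA basis, decodes behavior against random
#' controls, and returns the recovered earliest decoding time.
#'
#' @param seed integer seed for this replicate.
#' @param signal_onset_s implanted decodability onset (default -4 s).
#' @param n_per_class trials per class (default 200).
#' @param window_s peri-event window (default `c(-6.5, 1.5)`).
#' @param eval_stride decoder evaluation-grid stride in frames (default 6,
#'   i.e. a 5 Hz grid).
#' @param folds cross-validation folds (default 10).
#' @return recovered EDT in seconds.
#' @export
edt_recovery_run <- function(seed, signal_onset_s = -4, n_per_class = 200,
                             window_s = c(-6.5, 1.5), eval_stride = 6L,
                             folds = 10) {
  cfg <- synth_config(signal_onset_s = signal_onset_s)
  sess <- generate_until(cfg, seed, n_per_class + 10L, window_s)
  ct <- suppressMessages(
    concat_sessions(sess, window_s = window_s, min_trials = n_per_class,
                    seed = seed))
  beh <- head_trials(ct$behavior, n_per_class)
  ctl <- head_trials(ct$control, n_per_class)
  decode_session(beh, ctl, folds = folds, seed = seed,
                 eval_stride = eval_stride)$edt$edt_s
}

#' EDT false positives on null sessions
#'
#' As [edt_recovery_run()] but on sessions with no pre-event structure;
#' the expected EDT is 0 (not predicted).
#'
#' @inheritParams edt_recovery_run
#' @param n_per_class trials per class (default 60).
#' @param window_s peri-event window (default `c(-6, 1)`).
#' @return EDT in seconds (0 when, correctly, nothing is decodable).
#' @export
edt_null_run <- function(seed, n_per_class = 60, window_s = c(-6, 1),
                         eval_stride = 6L, folds = 10) {
  cfg <- synth_config(duration_s = 2800)
  sess <- generate_until(cfg, seed, n_per_class + 2L, window_s, null = TRUE)
  beh <- head_trials(
    bind_trial_sets(lapply(sess, function(s)
      suppressMessages(extract_trials(s, "lever_rewarded", window_s)))),
    n_per_class)
  ctl <- bind_trial_sets(lapply(seq_along(sess), function(i) {
    s <- sess[[i]]
    nb <- sum(beh$provenance$session_id == s$session_id)
    if (nb == 0) return(NULL)
    extract_trials(s, sample_control_triggers(s, nb, 3, window_s,
                                              seed = seed + 7L * i),
                   window_s)
  }))
  decode_session(beh, ctl, folds = folds, seed = seed,
                 eval_stride = eval_stride)$edt$edt_s
}

#' Phase recovery across a concentration sweep
#'
#' Generates sessions at a given von Mises concentration, fits single-trial
#' sinusoids over the final 5 s before each isolated rewarded pull, and
#' summarizes the fitted phases at t = 0.
#'
#' @param kappa implanted von Mises concentration.
#' @param seed integer seed.
#' @param n_sessions sessions pooled (default 10).
#' @param area area fitted (default `"limb_L"`, the strongest oscillator).
#' @param isolation_s events with another rewarded pull closer than this
#'   are excluded, keeping the fit window free of neighboring implants
#'   (default 5 s).
#' @return list with `resultant_length`, `circ_mean`, `rayleigh_p`, `n`.
#' @export
phase_recovery_run <- function(kappa, seed, n_sessions = 10, area = "limb_L",
                               isolation_s = 6.5) {
  cfg <- synth_config(phase_kappa = kappa)
  phases <- unlist(lapply(seq_len(n_sessions), function(i) {
    s <- generate_session(cfg, seed = (seed * 113L + i) %% .Machine$integer.max)
    ts <- suppressMessages(extract_trials(s, "lever_rewarded", c(-6, 1)))
    tp <- suppressWarnings(trial_phases(ts, area))
    rew <- event_times(s$events, "lever_rewarded")
    iso <- vapply(ts$provenance$event_time, function(T) {
      oth <- rew[rew != T]
      !length(oth) || all(abs(oth - T) >= isolation_s)
    }, TRUE)
    tp$phase[tp$converged & iso]
  }))
  st <- phase_stats(phases)
  list(resultant_length = st$resultant_length, circ_mean = st$circ_mean,
       rayleigh_p = st$rayleigh_p, n = length(phases))
}

#' EVDT recovery on an implanted variance change
#'
#' Generates sessions whose only pre-event structure is a noise-variance
#' change, pools trials, and measures the earliest variance decrease time
#' in an area with negligible oscillation variance.
#'
#' @param seed integer seed.
#' @param var_change_onset_s implanted onset (default -3 s).
#' @param var_change_factor implanted noise-sd multiplier (default 0.5).
#' @param n_sessions sessions pooled (default 6, ~200 trials).
#' @param area area measured (default `"visual_L"`).
#' @return EVDT in seconds, or `NA` if undetected.
#' @export
evdt_recovery_run <- function(seed, var_change_onset_s = -3,
                              var_change_factor = 0.5, n_sessions = 6,
                              area = "visual_L") {
  cfg <- synth_config(phase_kappa = 0, ramp_depth = 0,
                      var_change_onset_s = var_change_onset_s,
                      var_change_factor = var_change_factor)
  sess <- lapply(seq_len(n_sessions), function(i)
    generate_session(cfg, seed = (seed * 127L + i) %% .Machine$integer.max))
  ts <- bind_trial_sets(lapply(sess, function(s)
    suppressMessages(extract_trials(s, "lever_rewarded", c(-31, 2)))))
  session_evdt(ts, area)$evdt_s
}

#' Hull AUC of structured versus null sessions
#'
#' Normalized area under the hull-ratio curve for one generated session:
#' below 1 when pre-event neural activity contracts toward the action,
#' near 1 for null sessions.
#'
#' @param seed integer seed.
#' @param structured generate pre-event structure (`TRUE`) or a null
#'   session (`FALSE`).
#' @param n_reps random-trigger repetitions (default 5).
#' @return normalized AUC.
#' @export
hull_auc_run <- function(seed, structured = TRUE, n_reps = 5) {
  cfg <- synth_config()
  s <- if (structured) generate_session(cfg, seed = seed)
       else generate_null_session(cfg, seed = seed)
  hull_auc_analysis(s, offsets = -10:0, n_reps = n_reps, seed = seed)$auc
}
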