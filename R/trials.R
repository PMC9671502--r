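# Peri-event trial extraction, control sampling, PCA denoising and
# multi-session concatenation.

#' Construct a trial set
#'
#' Aligned peri-event tensor with labels and provenance; the decoder input.
#'
#' @param data numeric array `[n_trials x n_features x n_window_frames]`.
#' @param times_s per-frame peri-event time axis (strictly increasing,
#'   containing t = 0).
#' @param label `"behavior"` or `"control"`.
#' @param feature_desc character vector describing each feature row
#'   (area labels or principal-component names).
#' @param provenance data.frame with one row per trial: `session_id`,
#'   `event_time`.
#' @param fps sampling rate of the time axis in Hz.
#' @param pca_model optional attached basis (see [pca_denoise()]).
#' @return object of class `trial_set`.
#' @export
trial_set <- function(data, times_s, label = c("behavior", "control"),
                      feature_desc, provenance, fps, pca_model = NULL) {
  label <- match.arg(label)
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times_s),
            dim(data)[2] == length(feature_desc),
            dim(data)[1] == nrow(provenance))
  if (any(diff(times_s) <= 0)) stop("time axis must be strictly increasing")
  if (!any(abs(times_s) < 1e-9)) stop("time axis must include t = 0")
  structure(list(data = data, times_s = times_s, label = label,
                 feature_desc = as.character(feature_desc),
                 provenance = provenance, fps = fps, pca_model = pca_model),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d %s trials x %d features x %d frames (%.2f..%.2f s @ %g Hz)\n",
              d[1], x$label, d[2], d[3], min(x$times_s), max(x$times_s), x$fps))
  invisible(x)
}

#' Number of trials in a trial set
#' @param ts a `trial_set`.
#' @return integer trial count.
#' @export
n_trials <- function(ts) dim(ts$data)[1]

#' Extract peri-event trials from a session
#'
#' One trial per event whose full half-open window `[start, end)` fits in
#' the session; events too close to the session edges are dropped (a
#' message reports the count).
#'
#' @param s a `premove_session`.
#' @param events either an event kind (see [event_kinds()]) or a numeric
#'   vector of trigger times in seconds (e.g. control triggers).
#' @param window_s peri-event window `c(start, end)` in seconds,
#'   `start < 0 <= end`.
#' @param label trial-set label; defaults to `"behavior"` for an event kind
#'   and `"control"` for numeric triggers.
#' @return a `trial_set` over the session's areas.
#' @export
extract_trials <- function(s, events = "lever_rewarded",
                           window_s = c(-15, 15), label = NULL) {
  fps <- s$fps_neural
  if (is.character(events)) {
    times <- event_times(s$events, events)
    label <- label %||% "behavior"
  } else {
    times <- as.numeric(events)
    label <- label %||% "control"
  }
  if (!length(times)) stop("empty-set error: no trigger events")
  o0 <- as.integer(round(window_s[1] * fps))
  o1 <- as.integer(round(window_s[2] * fps)) - 1L
  nfr <- ncol(s$neural)
  e_idx <- time_to_index(times, fps)
  ok <- (e_idx + o0 >= 1L) & (e_idx + o1 <= nfr)
  if (!any(ok)) stop("empty-set error: no event window fits in the session")
  if (any(!ok))
    message(sum(!ok), " event(s) dropped: window does not fit in the session")
  times <- times[ok]; e_idx <- e_idx[ok]
  n_tr <- length(times)
  n_ar <- nrow(s$neural)
  offs <- o0:o1
  dat <- array(NA_real_, c(n_tr, n_ar, length(offs)))
  for (i in seq_len(n_tr))
    dat[i, , ] <- s$neural[, e_idx[i] + offs, drop = FALSE]
  trial_set(dat, times_s = offs / fps, label = label,
            feature_desc = s$area_labels,
            provenance = data.frame(session_id = s$session_id,
                                    event_time = times),
            fps = fps)
}

#' Sample random control trigger times
#'
#' Uniform random times whose distance to every lever event (rewarded and
#' unrewarded) is at least `min_gap_s` and whose full peri-event window fits
#' in the session.
#'
#' @param s a `premove_session`.
#' @param n number of triggers.
#' @param min_gap_s minimum distance to any lever pull in seconds
#'   (default 3).
#' @param window_s peri-event window that must fit around each trigger.
#' @param seed RNG seed.
#' @return numeric vector of `n` times in seconds.
#' @export
sample_control_triggers <- function(s, n, min_gap_s = 3,
                                    window_s = c(-15, 15), seed = NULL) {
  lever <- sort(c(event_times(s$events, "lever_rewarded"),
                  event_times(s$events, "lever_unrewarded")))
  lo <- -window_s[1]
  hi <- session_duration(s) - window_s[2]
  if (hi <= lo) stop("feasibility error: session shorter than the window")
  with_seed(seed, {
    out <- numeric(0)
    for (attempt in seq_len(200)) {
      cand <- stats::runif(4 * n, lo, hi)
      if (length(lever)) {
        d <- vapply(cand, function(x) min(abs(x - lever)), 1)
        cand <- cand[d >= min_gap_s]
      }
      out <- c(out, cand)
      if (length(out) >= n) break
    }
    if (length(out) < n)
      stop("feasibility error: could not place ", n,
           " control triggers respecting the gap")
    out[seq_len(n)]
  })
}

#' PCA-denoise a trial set
#'
#' Fits a PCA basis on the trial data arranged `[samples x features]`
#' (frames as samples) and keeps the smallest number of components whose
#' cumulative explained variance reaches `var_target`. The returned basis
#' must be applied to the behavior and control sets of the same session
#' (see [apply_pca_basis()]).
#'
#' @param ts a `trial_set`.
#' @param var_target explained-variance target in (0, 1] (default 0.95).
#' @param fixed_k optional fixed component count overriding `var_target`.
#' @return list with `trialset` (component traces per trial) and `basis`.
#' @export
pca_denoise <- function(ts, var_target = 0.95, fixed_k = NULL) {
  X <- trialset_to_samples(ts)
  if (nrow(X) < 2) stop("need at least 2 samples for PCA")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (all(pc$sdev < 1e-12)) stop("degenerate data: zero variance")
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- if (!is.null(fixed_k)) min(fixed_k, length(pc$sdev))
       else which(cumvar >= var_target - 1e-12)[1]
  basis <- list(center = pc$center,
                rotation = pc$rotation[, seq_len(k), drop = FALSE],
                sdev = pc$sdev, k = k, var_explained = cumvar[k])
  class(basis) <- "pca_basis"
  list(trialset = apply_pca_basis(ts, basis), basis = basis)
}

#' Apply a fitted PCA basis to a trial set
#'
#' @param ts a `trial_set`.
#' @param basis a `pca_basis` from [pca_denoise()] (feature dimension must
#'   match).
#' @return a `trial_set` whose features are the component traces.
#' @export
apply_pca_basis <- function(ts, basis) {
  if (length(basis$center) != dim(ts$data)[2])
    stop("mismatched feature bases: trial set has ", dim(ts$data)[2],
         " features, basis expects ", length(basis$center))
  X <- trialset_to_samples(ts)
  S <- sweep(X, 2, basis$center) %*% basis$rotation
  d <- dim(ts$data)
  arr <- aperm(array(S, c(d[1], d[3], basis$k)), c(1, 3, 2))
  trial_set(arr, ts$times_s, ts$label,
            feature_desc = colnames(basis$rotation),
            provenance = ts$provenance, fps = ts$fps, pca_model = basis)
}

# [trials x features x frames] -> [(trials*frames) x features]
trialset_to_samples <- function(ts) {
  d <- dim(ts$data)
  matrix(aperm(ts$data, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
}

#' Restrict a trial set to selected features
#'
#' @param ts a `trial_set` whose features are areas.
#' @param areas area labels, or a stem (`"limb"`) selecting the bilateral
#'   pair (`limb_L`, `limb_R`).
#' @return a `trial_set` over the selected features.
#' @export
subset_features <- function(ts, areas) {
  hit <- ts$feature_desc %in% areas |
    sub("_[LR]$", "", ts$feature_desc) %in% areas
  if (!any(hit)) stop("unknown area label(s): ", paste(areas, collapse = ", "))
  trial_set(ts$data[, hit, , drop = FALSE], ts$times_s, ts$label,
            feature_desc = ts$feature_desc[hit],
            provenance = ts$provenance, fps = ts$fps)
}

#' Pool trials across sequential sessions in a shared basis
#'
#' Each session is first denoised with its own >= `var_target` PCA basis;
#' the denoised series are concatenated and a multi-session basis is fit on
#' a seeded random sample (`sample_frac`) of the concatenated frames; all
#' sessions are projected onto a fixed number of components; behavior
#' trials and matched control trials are pooled.
#'
#' @param sessions ordered list of `premove_session` objects.
#' @param event_kind behavior event kind (default rewarded lever pulls).
#' @param window_s peri-event window in seconds.
#' @param min_trials minimum pooled behavior trials (default 200).
#' @param fixed_k number of shared components (default 20, capped at the
#'   feature dimension).
#' @param sample_frac fraction of concatenated frames used to fit the
#'   shared basis (default 0.03).
#' @param min_gap_s control-trigger distance to lever pulls (default 3).
#' @param var_target per-session denoising target (default 0.95).
#' @param seed RNG seed (basis sampling and control triggers).
#' @return list of class `concat_trials` with `behavior` and `control`
#'   trial sets (shared basis) and the `basis` itself.
#' @export
concat_sessions <- function(sessions, event_kind = "lever_rewarded",
                            window_s = c(-15, 15), min_trials = 200,
                            fixed_k = 20, sample_frac = 0.03,
                            min_gap_s = 3, var_target = 0.95, seed = 1L) {
  if (!length(sessions)) stop("need at least one session")
  n_feat <- nrow(sessions[[1]]$neural)
  # per-session denoising in frame space
  denoised <- lapply(sessions, function(s) {
    X <- t(s$neural)
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- which(cumvar >= var_target - 1e-12)[1]
    rec <- pc$x[, seq_len(k), drop = FALSE] %*%
      t(pc$rotation[, seq_len(k), drop = FALSE])
    sweep(rec, 2, pc$center, `+`)
  })
  all_frames <- do.call(rbind, denoised)
  with_seed(seed, {
    idx <- sample.int(nrow(all_frames), max(2L, round(sample_frac * nrow(all_frames))))
    pc <- stats::prcomp(all_frames[idx, , drop = FALSE], center = TRUE, scale. = FALSE)
    k <- min(fixed_k, ncol(pc$rotation))
    basis <- list(center = pc$center,
                  rotation = pc$rotation[, seq_len(k), drop = FALSE],
                  sdev = pc$sdev, k = k,
                  var_explained = sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2))
    class(basis) <- "pca_basis"

    beh <- list(); ctl <- list()
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      proj <- t(sweep(denoised[[i]], 2, basis$center) %*% basis$rotation)
      sp <- session(proj, fps_neural = s$fps_neural,
                    area_labels = colnames(basis$rotation),
                    events = s$events, tracks = s$tracks,
                    session_id = s$session_id, session_index = s$session_index)
      b <- extract_trials(sp, event_kind, window_s)
      ctrig <- sample_control_triggers(sp, n_trials(b), min_gap_s = min_gap_s,
                                       window_s = window_s,
                                       seed = sample.int(.Machine$integer.max, 1))
      beh[[i]] <- b
      ctl[[i]] <- extract_trials(sp, ctrig, window_s)
    }
    behavior <- bind_trial_sets(beh)
    control <- bind_trial_sets(ctl)
    if (n_trials(behavior) < min_trials)
      stop("insufficient-trials error: pooled ", n_trials(behavior),
           " behavior trials, need ", min_trials)
    behavior$pca_model <- basis
    control$pca_model <- basis
    structure(list(behavior = behavior, control = control, basis = basis),
              class = "concat_trials")
  })
}

#' Concatenate trial sets along the trial dimension
#' @param ts_list list of `trial_set` objects with identical shape,
#'   features and time axis.
#' @return a pooled `trial_set`.
#' @export
bind_trial_sets <- function(ts_list) {
  ts_list <- ts_list[!vapply(ts_list, is.null, TRUE)]
  stopifnot(length(ts_list) >= 1)
  t1 <- ts_list[[1]]
  for (ts in ts_list[-1])
    if (!isTRUE(all.equal(ts$times_s, t1$times_s)) ||
        !identical(ts$feature_desc, t1$feature_desc))
      stop("trial sets differ in time axis or features")
  dat <- do.call(abind3, lapply(ts_list, `[[`, "data"))
  prov <- do.call(rbind, lapply(ts_list, `[[`, "provenance"))
  trial_set(dat, t1$times_s, t1$label, t1$feature_desc, prov, t1$fps,
            pca_model = t1$pca_model)
}

# rbind for [trials x features x frames] arrays
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  ntot <- sum(vapply(arrs, function(a) dim(a)[1], 1L))
  out <- array(NA_real_, c(ntot, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Filter every area trace of a session
#'
#' @param s a `premove_session`.
#' @param type `"bandpass"` (default, zero-phase 0.1-6 Hz) or `"lowpass"`.
#' @param ... passed to [bandpass_filter()] or [lowpass_filter()]
#'   (`lo`, `hi`, or `fc`, `mode`).
#' @return the session with filtered neural traces.
#' @export
filter_session <- function(s, type = c("bandpass", "lowpass"), ...) {
  type <- match.arg(type)
  fun <- switch(type,
                bandpass = function(x) bandpass_filter(x, fps = s$fps_neural, ...),
                lowpass = function(x) lowpass_filter(x, fps = s$fps_neural, ...))
  s$neural <- t(apply(s$neural, 1, fun))
  rownames(s$neural) <- s$area_labels
  s
}
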