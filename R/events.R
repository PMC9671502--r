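# Behavioral event processing: movement-initiation detection on body
# tracks, lockout filtering of target events, pooling of locked-out trials,
# quiescent-bout selection, and a stereotypy embedding of binarized
# behavior.

#' Lockout specification
#'
#' @param lockout_s lockout duration in seconds (>= 0).
#' @param bin_s quiescence evaluation bin in seconds (default 0.250).
#' @param edge_allowance if `TRUE` (default) the first bin of the lockout
#'   span and the bin immediately before the event may contain movement
#'   (video-resolution tolerance).
#' @param blocked_kinds event kinds that break quiescence.
#' @return list of class `lockout_spec`.
#' @export
lockout_spec <- function(lockout_s, bin_s = 0.25, edge_allowance = TRUE,
                         blocked_kinds = c("lever_rewarded", "lever_unrewarded")) {
  if (lockout_s < 0) stop("`lockout_s` must be >= 0")
  if (bin_s <= 0) stop("`bin_s` must be > 0")
  structure(list(lockout_s = lockout_s, bin_s = bin_s,
                 edge_allowance = edge_allowance,
                 blocked_kinds = blocked_kinds),
            class = "lockout_spec")
}

# Smoothed per-frame speed (px/s) of one track feature.
track_speed <- function(m, fps_video, smoothing = c("moving_mean_30", "savgol_31_3")) {
  smoothing <- match.arg(smoothing)
  sm <- switch(smoothing,
               moving_mean_30 = function(v) moving_average(v, 30L),
               savgol_31_3 = function(v) as.numeric(signal::sgolayfilt(v, p = 3, n = 31)))
  xs <- sm(m[, 1]); ys <- sm(m[, 2])
  c(0, sqrt(diff(xs)^2 + diff(ys)^2)) * fps_video
}

#' Detect movement initiations from a body-part track
#'
#' Positions are smoothed, per-frame Euclidean speed is computed, and an
#' initiation is an upward crossing of `k_std` times the speed standard
#' deviation over the whole session. Initiations preceded by another
#' initiation of the same feature within `refractory_s` are removed.
#'
#' @param track a `body_track`.
#' @param feature feature name (e.g. `"left_paw"`).
#' @param k_std threshold multiplier (default 3; 1 is also in use for
#'   body-movement decoding).
#' @param refractory_s refractory period in seconds (default 3).
#' @param smoothing `"moving_mean_30"` (30-frame sliding mean, default) or
#'   `"savgol_31_3"` (Savitzky-Golay, 31 frames, order 3).
#' @return initiation times in seconds (empty for an immobile track).
#' @export
detect_initiations <- function(track, feature, k_std = 3, refractory_s = 3,
                               smoothing = c("moving_mean_30", "savgol_31_3")) {
  if (!feature %in% names(track$features))
    stop("feature not tracked: ", feature)
  m <- track$features[[feature]]
  if (nrow(m) <= 31) stop("track shorter than the smoothing window")
  sp <- track_speed(m, track$fps_video, match.arg(smoothing))
  thr <- k_std * stats::sd(sp)
  if (thr == 0) return(numeric(0))
  up <- which(sp >= thr & c(-Inf, sp[-length(sp)]) < thr)
  if (!length(up)) return(numeric(0))
  times <- index_to_time(up, track$fps_video)
  keep <- rep(TRUE, length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last < refractory_s) keep[i] <- FALSE
    else last <- times[i]
  }
  times[keep]
}

#' Movement initiations for every tracked feature
#' @inheritParams detect_initiations
#' @return named list of initiation-time vectors.
#' @export
detect_all_initiations <- function(track, k_std = 3, refractory_s = 3,
                                   smoothing = "moving_mean_30") {
  stats::setNames(lapply(names(track$features), function(f)
    detect_initiations(track, f, k_std, refractory_s, smoothing)),
    names(track$features))
}

#' Apply a behavioral lockout to target events
#'
#' Keeps target events whose preceding `lockout_s` seconds contain no
#' blocked-kind event, evaluated on a `bin_s` grid. With the edge
#' allowance, the first bin of the lockout span and the bin immediately
#' before the event may contain movement. Targets whose lockout window
#' extends before the session start are dropped.
#'
#' @param events an `event_table`.
#' @param target_kind kind of the events to filter.
#' @param spec a `lockout_spec`.
#' @return surviving target event times in seconds (a subset of the
#'   input; survivor count is non-increasing in `lockout_s`).
#' @export
apply_lockout <- function(events, target_kind, spec) {
  targets <- event_times(events, target_kind)
  if (spec$lockout_s == 0) return(targets)
  blocked <- sort(unlist(lapply(spec$blocked_kinds, event_times, events = events)))
  n_bins <- ceiling(spec$lockout_s / spec$bin_s - 1e-9)
  keep <- vapply(targets, function(T) {
    if (T - spec$lockout_s < 0) return(FALSE)
    if (!length(blocked)) return(TRUE)
    inw <- blocked[blocked >= T - spec$lockout_s & blocked < T]
    if (!length(inw)) return(TRUE)
    bins <- pmin(floor((inw - (T - spec$lockout_s)) / spec$bin_s) + 1, n_bins)
    if (spec$edge_allowance)
      bins <- bins[bins != 1L & bins != n_bins]
    length(bins) == 0
  }, TRUE)
  targets[keep]
}

#' Group locked-out trials into overlapping pooled sessions
#'
#' Sliding windows `[s, min(s + group_size, n))` for
#' `s = 0, stride, 2 stride, ...`, emitted while the window holds at least
#' `min_size` trials; trailing windows that share the same end are kept.
#' 503 trials with window 200 and stride 50 yield the 10 groups
#' 1..200, 51..250, ..., 451..503.
#'
#' @param n_trials_total number of trials, ordered by acquisition time.
#' @param group_size maximum trials per group (default 200).
#' @param stride window stride in trials (default 50).
#' @param min_size minimum group size (default 50).
#' @return list of integer index vectors (1-based).
#' @export
pool_lockout_trials <- function(n_trials_total, group_size = 200,
                                stride = 50, min_size = 50) {
  n <- n_trials_total
  if (n < min_size)
    stop("insufficient-trials error: ", n, " trials, need ", min_size)
  groups <- list()
  s <- 0L
  repeat {
    e <- min(s + group_size, n)
    if (e - s < min_size) break
    groups[[length(groups) + 1L]] <- (s + 1L):e
    s <- s + stride
  }
  groups
}

#' Select body-movement initiations isolated from other behavior
#'
#' Keeps initiations of `target_kind` with (a) no lever pull (rewarded or
#' unrewarded) within `[-lever_pre_s, +lever_post_s]` and (b) no initiation
#' of any tracked body feature in the preceding `body_quiescence_s`
#' seconds. The duration of pre-event quiescence is attached for raster
#' ordering.
#'
#' @param s a `premove_session` with tracks.
#' @param target_kind body event kind (default `"left_paw"`).
#' @param lever_pre_s,lever_post_s lever exclusion window (default 15 / 5 s).
#' @param body_quiescence_s required preceding body quiescence (default 5 s).
#' @param initiations optional named list of initiation times per feature
#'   (defaults to the stored body event kinds of the session).
#' @return data.frame with columns `time_s` and `quiescence_s`
#'   (pre-event quiescence duration), possibly empty.
#' @export
select_quiescent_bouts <- function(s, target_kind = "left_paw",
                                   lever_pre_s = 15, lever_post_s = 5,
                                   body_quiescence_s = 5,
                                   initiations = NULL) {
  if (is.null(initiations)) {
    kinds <- intersect(c("left_paw", "right_paw", "lick"),
                       unique(s$events$kind))
    initiations <- stats::setNames(lapply(kinds, event_times, events = s$events),
                                   kinds)
  }
  targets <- initiations[[target_kind]]
  if (is.null(targets) || !length(targets))
    return(data.frame(time_s = numeric(0), quiescence_s = numeric(0)))
  lever <- sort(c(event_times(s$events, "lever_rewarded"),
                  event_times(s$events, "lever_unrewarded")))
  body <- sort(unlist(initiations, use.names = FALSE))
  out_t <- numeric(0); out_q <- numeric(0)
  for (T in targets) {
    if (length(lever) && any(lever >= T - lever_pre_s & lever <= T + lever_post_s))
      next
    prior <- body[body < T]
    q <- if (length(prior)) T - max(prior) else T
    if (q < body_quiescence_s) next
    out_t <- c(out_t, T); out_q <- c(out_q, q)
  }
  data.frame(time_s = out_t, quiescence_s = out_q)
}

#' Two-dimensional stereotypy embedding of pre-event behavior
#'
#' Per trial, movement of each body part is binarized (moving = speed above
#' the initiation detector's threshold) over the pre-event window at video
#' rate, the body parts are concatenated and flattened, and PCA returns
#' the first two component scores per trial. Tight clusters indicate
#' stereotyped pre-event movement patterns.
#'
#' @param track a `body_track`.
#' @param event_times_s trigger times in seconds (>= 3).
#' @param window_s pre-event window (default `c(-10, 0)`).
#' @param k_std binarization threshold multiplier (default 3).
#' @param features body parts to include (default paws + jaw if present).
#' @return matrix `[n_trials x 2]` of component scores (mean-centered).
#' @export
stereotypy_embedding <- function(track, event_times_s, window_s = c(-10, 0),
                                 k_std = 3,
                                 features = intersect(c("left_paw", "right_paw", "jaw", "tongue"),
                                                      names(track$features))) {
  if (length(event_times_s) < 3) stop("need at least 3 trials")
  fps <- track$fps_video
  nfr <- nrow(track$features[[1]])
  moving <- lapply(features, function(f) {
    sp <- track_speed(track$features[[f]], fps)
    as.numeric(sp >= k_std * stats::sd(sp))
  })
  o0 <- as.integer(round(window_s[1] * fps))
  o1 <- as.integer(round(window_s[2] * fps)) - 1L
  rows <- lapply(event_times_s, function(T) {
    e <- time_to_index(T, fps)
    if (e + o0 < 1 || e + o1 > nfr) return(NULL)
    unlist(lapply(moving, function(mv) mv[(e + o0):(e + o1)]))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) < 3) stop("need at least 3 trials inside the session")
  X <- do.call(rbind, rows)
  if (all(X == 0)) stop("degenerate behavior matrix: no movement in any trial")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  emb <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  if (ncol(emb) == 1) emb <- cbind(emb, 0)
  colnames(emb) <- c("PC1", "PC2")
  emb
}
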