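# Data model: Session, EventTable, BodyTrack, PipelineConfig.
#
# Time convention used throughout the package: event times are seconds from
# session start (float); frame index i (0-based) corresponds to time i / fps;
# peri-event time t = 0 at the event; windows are half-open [t_start, t_end)
# in frames. Events detected on 15 Hz video are stored in seconds and mapped
# to the nearest neural frame when trials are extracted.

#' Default cortical area labels
#'
#' Ten bilateral area-level components as produced by an upstream
#' atlas-aligned decomposition of widefield calcium data: retrosplenial,
#' somatosensory-barrel, somatosensory-limb, visual and motor cortex, left
#' and right hemispheres.
#'
#' @return character vector of 10 labels, e.g. `"limb_L"`.
#' @export
default_area_labels <- function() {
  as.vector(outer(c("retrosplenial", "barrel", "limb", "visual", "motor"),
                  c("L", "R"), paste, sep = "_"))
}

#' Event kinds recognized by the pipeline
#' @return character vector of the five event kinds.
#' @export
event_kinds <- function() {
  c("lever_rewarded", "lever_unrewarded", "lick", "left_paw", "right_paw")
}

#' Construct an event table
#'
#' @param time_s event times in seconds from session start.
#' @param kind event kind, one of [event_kinds()]; recycled if scalar.
#' @return a `data.frame` with columns `time_s` (sorted ascending within
#'   kind) and `kind`, of class `event_table`.
#' @export
event_table <- function(time_s = numeric(0), kind = character(0)) {
  if (length(kind) == 1 && length(time_s) > 1) kind <- rep(kind, length(time_s))
  if (length(time_s) != length(kind))
    stop("`time_s` and `kind` must have equal length")
  if (length(time_s) && (!all(is.finite(time_s)) || any(time_s < 0)))
    stop("event times must be finite and non-negative")
  bad <- setdiff(unique(kind), event_kinds())
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  ev <- data.frame(time_s = as.numeric(time_s), kind = as.character(kind),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$kind, ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Times of events of one kind
#' @param events an `event_table`.
#' @param kind event kind to select.
#' @return sorted numeric vector of times in seconds.
#' @export
event_times <- function(events, kind) {
  sort(events$time_s[events$kind == kind])
}

#' Construct body-part position tracks
#'
#' @param features named list of two-column (x, y) matrices in pixels, one
#'   per tracked feature; all must have the same number of video frames.
#'   Feature names come from
#'   `{left_paw, right_paw, jaw, nose, ear, tongue, lever}`.
#' @param fps_video video sampling rate in Hz (default 15).
#' @return object of class `body_track`.
#' @export
body_track <- function(features, fps_video = 15) {
  allowed <- c("left_paw", "right_paw", "jaw", "nose", "ear", "tongue", "lever")
  if (!length(features) || is.null(names(features)))
    stop("`features` must be a named list of (x, y) matrices")
  bad <- setdiff(names(features), allowed)
  if (length(bad)) stop("unknown track feature(s): ", paste(bad, collapse = ", "))
  features <- lapply(features, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2) stop("each track must be an [n_frames x 2] (x, y) matrix")
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    m
  })
  nf <- vapply(features, nrow, 1L)
  if (length(unique(nf)) != 1) stop("all track features must have equal length")
  structure(list(features = features, fps_video = fps_video),
            class = "body_track")
}

#' Construct a recording session
#'
#' A session bundles the area-level neural matrix, its sampling rate, the
#' behavioral event table, optional body-part tracks and free-form metadata.
#'
#' @param neural numeric matrix `[n_areas x n_frames]` of fluorescence or
#'   dF/F values (a.u.); rownames are taken as area labels if
#'   `area_labels` is missing.
#' @param fps_neural neural sampling rate in Hz (default 30).
#' @param area_labels unique area labels, length `nrow(neural)`.
#' @param events an `event_table` (may be empty).
#' @param tracks a `body_track` or `NULL` when no video is available.
#' @param session_id character identifier.
#' @param session_index integer ordinal (recording day) for longitudinal
#'   analyses.
#' @param meta free-form named list (the synthetic generator stores its
#'   ground-truth record here).
#' @return object of class `premove_session`.
#' @export
session <- function(neural, fps_neural = 30,
                    area_labels = rownames(neural),
                    events = event_table(), tracks = NULL,
                    session_id = "session", session_index = 1L,
                    meta = list()) {
  neural <- as.matrix(neural)
  storage.mode(neural) <- "double"
  if (is.null(area_labels))
    area_labels <- sprintf("area_%02d", seq_len(nrow(neural)))
  if (length(area_labels) != nrow(neural))
    stop("`area_labels` must have one entry per neural row")
  if (anyDuplicated(area_labels)) stop("`area_labels` must be unique")
  rownames(neural) <- area_labels
  s <- structure(list(neural = neural, fps_neural = fps_neural,
                      area_labels = as.character(area_labels),
                      events = events, tracks = tracks,
                      session_id = as.character(session_id),
                      session_index = as.integer(session_index),
                      meta = meta),
                 class = "premove_session")
  validate_session(s)
  s
}

#' Session duration in seconds
#' @param s a `premove_session`.
#' @return duration in seconds (`n_frames / fps`).
#' @export
session_duration <- function(s) ncol(s$neural) / s$fps_neural

#' Validate session invariants
#'
#' Checks that all event times fall in `[0, duration)`, that area labels are
#' unique, and that tracks (if present) are finite and of equal length.
#'
#' @param s a `premove_session`.
#' @return `s`, invisibly; signals a validation error otherwise.
#' @export
validate_session <- function(s) {
  if (!inherits(s, "premove_session")) stop("not a premove_session")
  dur <- session_duration(s)
  if (nrow(s$events) &&
      (any(!is.finite(s$events$time_s)) ||
       any(s$events$time_s < 0) || any(s$events$time_s >= dur)))
    stop("validation error: event times must lie in [0, duration)")
  if (anyDuplicated(s$area_labels))
    stop("validation error: duplicate area labels")
  if (!is.null(s$tracks)) {
    if (!inherits(s$tracks, "body_track"))
      stop("validation error: `tracks` must be a body_track")
    ok <- vapply(s$tracks$features, function(m) all(is.finite(m)), TRUE)
    if (!all(ok)) stop("validation error: non-finite track positions")
  }
  invisible(s)
}

#' @export
print.premove_session <- function(x, ...) {
  cat(sprintf("<premove_session> %s (day %d)\n", x$session_id, x$session_index))
  cat(sprintf("  neural: %d areas x %d frames @ %g Hz (%.0f s)\n",
              nrow(x$neural), ncol(x$neural), x$fps_neural, session_duration(x)))
  if (nrow(x$events)) {
    tab <- table(x$events$kind)
    cat("  events:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else cat("  events: none\n")
  cat(sprintf("  tracks: %s\n",
              if (is.null(x$tracks)) "absent"
              else paste(names(x$tracks$features), collapse = ", ")))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the analysis parameters shared across modules.
#'
#' @param window_s peri-event extraction window in seconds,
#'   `c(start, end)` with `start < 0 < end` (default `c(-15, 15)`).
#' @param feature_window_s decoder feature window length in seconds
#'   (default 1).
#' @param folds cross-validation folds (default 10, >= 2).
#' @param alpha significance level (default 0.05).
#' @param lockout_s behavioral lockout duration in seconds (default 3).
#' @param band_hz band-pass corner frequencies in Hz (default `c(0.1, 6)`).
#' @param lowpass_hz low-pass cutoff for filtered-feature decoding (0.3 Hz).
#' @param seed base RNG seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = c(-15, 15), feature_window_s = 1,
                            folds = 10, alpha = 0.05, lockout_s = 3,
                            band_hz = c(0.1, 6), lowpass_hz = 0.3,
                            seed = 1L) {
  if (!(window_s[1] < 0 && 0 < window_s[2]))
    stop("`window_s` must satisfy start < 0 < end")
  if (folds < 2) stop("`folds` must be >= 2")
  structure(list(window_s = window_s, feature_window_s = feature_window_s,
                 folds = folds, alpha = alpha, lockout_s = lockout_s,
                 band_hz = band_hz, lowpass_hz = lowpass_hz, seed = seed),
            class = "pipeline_config")
}
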