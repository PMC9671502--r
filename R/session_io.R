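# On-disk session container.
#
# A session is stored as a directory:
#   meta.json   -- session_id, session_index, fps values, area labels,
#                  free-form metadata (including generator ground truth)
#   neural.csv  -- [n_frames x n_areas] numeric, header = area labels
#   events.csv  -- columns time_s,kind (header required, '.' decimal)
#   tracks.csv  -- columns feature,x,y in video-frame order (only when
#                  tracks are present)
# The layout is array + table + key/value, mirroring the logical groups
# neural / events / tracks / meta. All values round-trip exactly.

#' Write a session to disk
#'
#' @param s a valid `premove_session`.
#' @param path directory to create (overwritten if it already exists).
#' @return `path`, invisibly. Writing the same session twice produces
#'   byte-identical files.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create session directory: ", path)

  meta <- list(session_id = s$session_id,
               session_index = s$session_index,
               fps_neural = s$fps_neural,
               area_labels = as.list(s$area_labels),
               has_tracks = !is.null(s$tracks),
               fps_video = if (!is.null(s$tracks)) s$tracks$fps_video else NULL,
               track_features = if (!is.null(s$tracks)) as.list(names(s$tracks$features)) else NULL,
               meta = s$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)

  # numeric columns are written as %.17g so doubles round-trip exactly
  write_exact_csv(stats::setNames(as.data.frame(t(s$neural)), s$area_labels),
                  file.path(path, "neural.csv"))
  write_exact_csv(data.frame(time_s = s$events$time_s, kind = s$events$kind),
                  file.path(path, "events.csv"))
  if (!is.null(s$tracks)) {
    tr <- do.call(rbind, lapply(names(s$tracks$features), function(f) {
      m <- s$tracks$features[[f]]
      data.frame(feature = f, x = m[, 1], y = m[, 2])
    }))
    write_exact_csv(tr, file.path(path, "tracks.csv"))
  }
  invisible(path)
}

write_exact_csv <- function(df, file) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(file, "wb")  # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(lines, con)
}

#' Read a session from disk
#'
#' @param path directory written by [write_session()].
#' @return a `premove_session` satisfying all invariants; a container
#'   without `tracks.csv` yields `tracks = NULL`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("format error: no session directory at ", path)
  need <- c("meta.json", "neural.csv", "events.csv")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("format error: container is missing ", sub("\\..*$", "", f),
           " (", f, ")")

  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)

  neu <- data.table::fread(file.path(path, "neural.csv"), header = TRUE)
  neural <- t(as.matrix(neu))
  labels <- as.character(unlist(meta$area_labels))
  if (nrow(neural) != length(labels))
    stop("format error: neural matrix width does not match area_labels")
  rownames(neural) <- labels

  ev <- data.table::fread(file.path(path, "events.csv"), header = TRUE,
                          colClasses = list(numeric = "time_s", character = "kind"))
  if (!all(c("time_s", "kind") %in% names(ev)))
    stop("format error: events table must have columns time_s,kind")
  events <- event_table(ev$time_s, ev$kind)

  tracks <- NULL
  if (isTRUE(meta$has_tracks)) {
    tf <- file.path(path, "tracks.csv")
    if (!file.exists(tf)) stop("format error: container is missing tracks")
    tr <- data.table::fread(tf, header = TRUE)
    feats <- lapply(split(tr, by = "feature", sorted = FALSE),
                    function(d) cbind(x = d$x, y = d$y))
    # preserve the declared feature order
    feats <- feats[as.character(unlist(meta$track_features))]
    tracks <- body_track(feats, fps_video = meta$fps_video)
  }

  session(neural,
          fps_neural = meta$fps_neural,
          area_labels = labels,
          events = events,
          tracks = tracks,
          session_id = meta$session_id,
          session_index = meta$session_index,
          meta = if (length(meta$meta)) meta$meta else list())
}
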