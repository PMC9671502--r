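# Shared fixtures: short synthetic sessions, built in code and memoized so
# expensive generation runs once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

short_session <- function(seed = 1, duration_s = 300, ...) {
  fixture(paste0("short_", seed, "_", duration_s, "_", paste(c(...), collapse = "_")),
          function() generate_session(synth_config(duration_s = duration_s, ...),
                                      seed = seed))
}

# deterministic toy session: known sinusoid per area, events on a grid
toy_session <- function(duration_s = 120, fps = 30, n_areas = 3,
                        freqs = c(0.2, 0.3, 0.5),
                        event_times_s = c(30, 60, 90)) {
  tt <- (seq_len(duration_s * fps) - 1) / fps
  neural <- t(sapply(freqs, function(f) sin(2 * pi * f * tt)))
  session(neural, fps_neural = fps,
          area_labels = paste0("area_", seq_len(n_areas)),
          events = event_table(event_times_s, "lever_rewarded"),
          session_id = "toy")
}
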