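# Filtering, dF/F0, trial extraction, control sampling, PCA denoising and
# multi-session concatenation.

test_that("causal delay correction matches the printed rule", {
  expect_identical(causal_filter_shift(0.3, 30), 100L)
  expect_identical(causal_filter_shift(0.5, 30), 60L)
  expect_error(causal_filter_shift(20, 30), "parameter error")
})

test_that("constant traces pass both low-pass modes unchanged", {
  x <- rep(2, 600)
  expect_equal(lowpass_filter(x, 0.3, 30, "zero_phase"), x, tolerance = 1e-8)
  expect_equal(lowpass_filter(x, 0.3, 30, "causal"), x, tolerance = 1e-8)
  expect_equal(max(abs(bandpass_filter(rep(3, 1200), fps = 30))), 0,
               tolerance = 1e-8)
})

test_that("corrected causal output leads the zero-phase output by the
           overcorrection of the printed shift rule", {
  # fps/fc = 100 samples vs ~43 samples of true 4th-order group delay:
  # the oracle (cross-correlation against the zero-phase output) measures
  # a constant lead of 57 samples
  fps <- 30; tt <- seq(0, 400, by = 1 / fps)
  x <- sin(2 * pi * 0.1 * tt)
  zp <- lowpass_filter(x, 0.3, fps, "zero_phase")
  ca <- lowpass_filter(x, 0.3, fps, "causal")
  cc <- stats::ccf(ca[2000:10000], zp[2000:10000], lag.max = 200, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], -57, tolerance = 1)
})

test_that("band-pass respects its pass and stop bands", {
  fps <- 30; tt <- seq(0, 200, by = 1 / fps)
  inband <- bandpass_filter(sin(2 * pi * 1 * tt), 0.1, 6, fps)
  expect_gt(max(abs(inband[2000:4000])), 0.95)       # < 5% attenuation
  stop10 <- bandpass_filter(sin(2 * pi * 10 * tt), 0.1, 6, fps)
  expect_lt(max(abs(stop10[2000:4000])), 0.10)       # > 90% attenuation
  expect_error(bandpass_filter(tt, 6, 0.1, fps), "parameter error")
})

test_that("filtering is linear", {
  set.seed(8)
  x <- rnorm(400); y <- rnorm(400)
  for (flt in list(function(v) bandpass_filter(v, fps = 30),
                   function(v) lowpass_filter(v, 0.3, 30),
                   function(v) lowpass_filter(v, 0.3, 30, "causal"))) {
    expect_equal(flt(2 * x - 5 * y), 2 * flt(x) - 5 * flt(y),
                 tolerance = 1e-8)
  }
})

test_that("dF/F0 uses the immediately preceding same-length baseline", {
  fps <- 30
  # +/-3 s analysis window: baseline is the -6..-3 s span
  tr <- rep(2, 20 * fps)
  tr[(10 * fps + 1):(13 * fps)] <- 3  # value 3 over [10, 13) s
  d <- compute_dff(tr, fps, event_time_s = 13, half_window_s = 3)
  # baseline [7, 10) s has value 2; first half of the analysis window is 3
  expect_equal(d$dff[d$times_s < 0], rep(0.5, 3 * fps), ignore_attr = TRUE)
  expect_equal(d$dff[d$times_s >= 0], rep(0, 3 * fps), ignore_attr = TRUE)
  expect_equal(compute_dff(rep(5, 600), fps, 10)$dff, rep(0, 180))
  expect_error(compute_dff(rep(0, 600), fps, 10), "F0 = 0")
  expect_error(compute_dff(rep(1, 600), fps, 3), "insufficient history")
})

test_that("trial extraction drops underflowing events and aligns t = 0", {
  s <- toy_session()
  ts <- suppressMessages(extract_trials(s, "lever_rewarded", c(-15, 15)))
  expect_equal(n_trials(ts), 3L)
  expect_true(any(abs(ts$times_s) < 1e-9))
  # alignment identity: trial value at t = 0 equals the session frame
  i0 <- which(abs(ts$times_s) < 1e-9)
  for (k in seq_len(3))
    expect_equal(ts$data[k, , i0],
                 unname(s$neural[, round(ts$provenance$event_time[k] * 30) + 1]))
  # event at 10 s cannot host a (-15, 15) window
  s2 <- toy_session(event_times_s = c(10, 60, 90))
  expect_message(ts2 <- extract_trials(s2, "lever_rewarded", c(-15, 15)),
                 "dropped")
  expect_equal(n_trials(ts2), 2L)
  expect_error(extract_trials(s2, "lick", c(-15, 15)), "empty-set")
  # provenance reproduces the surviving event times exactly
  expect_identical(ts2$provenance$event_time, c(60, 90))
})

test_that("control triggers respect the lever gap and are seeded", {
  s <- short_session(seed = 2, duration_s = 600)
  lever <- sort(c(event_times(s$events, "lever_rewarded"),
                  event_times(s$events, "lever_unrewarded")))
  tr1 <- sample_control_triggers(s, 25, min_gap_s = 3, window_s = c(-10, 10),
                                 seed = 5)
  expect_length(tr1, 25)
  expect_true(all(vapply(tr1, function(x) min(abs(x - lever)) >= 3, TRUE)))
  expect_true(all(tr1 >= 10 & tr1 <= 590))
  expect_identical(tr1, sample_control_triggers(s, 25, 3, c(-10, 10), seed = 5))
})

test_that("control triggers are uniform in an event-free session", {
  s <- session(matrix(rnorm(2000), 2, 1000), fps_neural = 10,
               area_labels = c("a", "b"))
  pvals <- vapply(1:100, function(i) {
    x <- sample_control_triggers(s, 40, 3, c(-5, 5), seed = i)
    stats::ks.test((x - 5) / 90, "punif")$p.value
  }, 1)
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("PCA denoising recovers exact low rank and orthonormal bases", {
  set.seed(4)
  lat <- matrix(rnorm(60 * 3), 60, 3)
  W <- matrix(rnorm(3 * 8), 3, 8)
  X <- lat %*% W  # rank 3 in 8 features
  arr <- aperm(array(X, c(20, 3, 8)), c(2, 3, 1))  # 3 trials x 8 feat x 20 fr
  ts <- trial_set(arr, times_s = seq(-1, 0.9, by = 0.1), label = "behavior",
                  feature_desc = paste0("f", 1:8),
                  provenance = data.frame(session_id = "x", event_time = 1:3),
                  fps = 10)
  pd <- pca_denoise(ts, var_target = 0.95)
  expect_equal(pd$basis$k, 3L)
  expect_gte(pd$basis$var_explained, 0.95)
  B <- pd$basis$rotation
  expect_equal(t(B) %*% B, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  # explained variance is non-decreasing in k
  cumvar <- cumsum(pd$basis$sdev^2) / sum(pd$basis$sdev^2)
  expect_true(all(diff(cumvar) >= -1e-12))
  # reconstruction from 3 components is exact for rank-3 data
  S <- premove:::trialset_to_samples(pd$trialset)
  rec <- S %*% t(B)
  ctr <- sweep(premove:::trialset_to_samples(ts), 2, pd$basis$center)
  expect_equal(rec, ctr, tolerance = 1e-8)
  expect_error(pca_denoise(trial_set(array(0, c(3, 2, 20)),
                                     seq(-1, 0.9, by = 0.1), "behavior",
                                     c("a", "b"),
                                     data.frame(session_id = "x", event_time = 1:3),
                                     10)),
               "degenerate")
})

test_that("a shared basis rejects mismatched feature dimensions", {
  s <- short_session(seed = 2, duration_s = 600)
  ts <- suppressMessages(extract_trials(s, "lever_rewarded", c(-5, 2)))
  pd <- pca_denoise(ts)
  bad <- trial_set(ts$data[, 1:4, , drop = FALSE], ts$times_s, "control",
                   ts$feature_desc[1:4], ts$provenance, ts$fps)
  expect_error(apply_pca_basis(bad, pd$basis), "mismatched feature bases")
})

test_that("concatenation pools trials in a fixed shared basis", {
  cfg <- synth_config(duration_s = 700, n_areas = 22, event_rate_hz = 0.06)
  sess <- lapply(1:3, function(i) generate_session(cfg, seed = 40 + i))
  ct <- suppressMessages(concat_sessions(sess, window_s = c(-5, 2),
                                         min_trials = 60, fixed_k = 20,
                                         seed = 9))
  expect_s3_class(ct$behavior, "trial_set")
  expect_equal(dim(ct$behavior$data)[2], 20L)       # fixed 20 components
  expect_equal(n_trials(ct$behavior), n_trials(ct$control))
  expect_gte(n_trials(ct$behavior), 60)
  ct2 <- suppressMessages(concat_sessions(sess, window_s = c(-5, 2),
                                          min_trials = 60, fixed_k = 20,
                                          seed = 9))
  expect_identical(ct$behavior$data, ct2$behavior$data)  # seeded determinism
  expect_error(suppressMessages(concat_sessions(sess[1], window_s = c(-5, 2),
                                                min_trials = 500)),
               "insufficient-trials")
})
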