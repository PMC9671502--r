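# Sinusoid fits, circular statistics, inter-area phase correlation, Welch
# spectra and longitudinal trends.

test_that("sinusoid fits recover exact and wrapped parameters", {
  tt <- seq(-6, 1, by = 1 / 30)
  f <- fit_sinusoid(2 * sin(2 * pi * 0.3 * tt + 1.0), tt)
  expect_equal(f$amplitude, 2, tolerance = 1e-3)
  expect_equal(f$freq, 0.3, tolerance = 1e-3)
  expect_equal(f$phase_at_zero, 1.0, tolerance = 1e-3)
  # phase wrapping convention: (-pi, pi]
  f2 <- fit_sinusoid(2 * sin(2 * pi * 0.3 * tt + pi + 0.1), tt)
  expect_equal(f2$phase_at_zero, -pi + 0.1, tolerance = 1e-3)
  expect_equal(wrap_angle(pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  expect_equal(wrap_angle(pi + 0.1), -pi + 0.1)
})

test_that("fitted phases of noisy sinusoids concentrate around the truth", {
  set.seed(14)
  tt <- seq(-6, 1, by = 1 / 30)
  phases <- vapply(1:100, function(i) {
    y <- 1 * sin(2 * pi * 0.35 * tt + 0.8) + stats::rnorm(length(tt), 0, 0.2)
    suppressWarnings(fit_sinusoid(y, tt))$phase_at_zero
  }, 1)
  st <- phase_stats(phases)
  expect_lt(abs(st$circ_mean - 0.8), 0.2)
  expect_gt(st$resultant_length, 0.9)
})

test_that("circular summary statistics match closed-form cases", {
  st <- phase_stats(rep(1.2, 10))
  expect_equal(st$resultant_length, 1)
  expect_equal(st$circ_mean, 1.2)
  anti <- phase_stats(rep(c(0, pi), 20))
  expect_equal(anti$resultant_length, 0, tolerance = 1e-12)
  expect_gt(anti$rayleigh_p, 0.9)
  expect_error(phase_stats(c(0, 1, 2)), "at least 5")
  # rotation invariance: mean shifts by delta, R and p unchanged
  set.seed(5)
  x <- rvonmises(200, 0.3, 3)
  a <- phase_stats(x); b <- phase_stats(wrap_angle(x + 1.1))
  expect_equal(wrap_angle(b$circ_mean - a$circ_mean), 1.1, tolerance = 1e-9)
  expect_equal(b$resultant_length, a$resultant_length)
  expect_equal(b$rayleigh_p, a$rayleigh_p)
})

test_that("Rayleigh p values separate uniform from concentrated samples", {
  set.seed(6)
  expect_gt(phase_stats(stats::runif(1000, -pi, pi))$rayleigh_p, 1e-3)
  expect_lt(phase_stats(rvonmises(100, 0, 5))$rayleigh_p, 1e-10)
})

test_that("inter-area phase correlation is symmetric with unit diagonal", {
  set.seed(7)
  a <- stats::runif(300, -pi, pi)
  m <- cbind(A = a, B = a, C = stats::runif(300, -pi, pi))
  cc <- interarea_phase_corr(m)
  expect_equal(diag(cc), c(A = 1, B = 1, C = 1))
  expect_equal(cc, t(cc))
  expect_equal(cc["A", "B"], 1, tolerance = 1e-12)
  expect_lt(abs(cc["A", "C"]), 0.15)
  # independent phases give near-zero correlation in most replicates
  offs <- vapply(1:20, function(i) {
    mm <- cbind(stats::runif(500, -pi, pi), stats::runif(500, -pi, pi))
    interarea_phase_corr(mm)[1, 2]
  }, 1)
  expect_gte(mean(abs(offs) < 0.1), 0.95)
  expect_error(interarea_phase_corr(m[1:3, ]), "at least 5")
})

test_that("Welch spectra localize peaks and scale as amplitude squared", {
  fps <- 30
  tt <- seq(0, 120, by = 1 / fps)
  x <- sin(2 * pi * 0.4 * tt)
  pk <- psd_peak(x, fps)
  expect_equal(pk$peak_freq, 0.4, tolerance = fps / 512 + 1e-9)  # one bin
  pk2 <- psd_peak(2 * x, fps)
  expect_equal(pk2$peak_power / pk$peak_power, 4, tolerance = 1e-6)
  # DC-offset invariance
  pk3 <- psd_peak(x + 5, fps)
  expect_equal(pk3$peak_freq, pk$peak_freq)
  expect_equal(pk3$peak_power, pk$peak_power, tolerance = 1e-6)
  # total one-sided power integrates to the signal variance
  ps <- psd_welch(stats::rnorm(4096), fps)
  expect_equal(sum(ps$psd) * fps / 512, 1, tolerance = 0.15)
  expect_error(psd_peak(x[1:100], fps), "too short")
})

test_that("generated sessions show slow-oscillation peaks at the implanted
           frequency", {
  cfg <- synth_config(duration_s = 1330, osc_freq_hz = 0.3)
  s <- generate_session(cfg, seed = 15)
  ts <- suppressMessages(extract_trials(s, "lever_rewarded", c(-15, 0.03)))
  hits <- vapply(seq_len(n_trials(ts)), function(i) {
    pk <- psd_peak(ts$data[i, match("limb_L", ts$feature_desc), ],
                   s$fps_neural, band = c(0.15, 1), nperseg = 450)
    pk$peak_freq >= 0.2 && pk$peak_freq <= 0.4
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  # the trial-average is phase-locked only over the final seconds, so its
  # peak is broadened but stays inside the slow band
  avg <- colMeans(ts$data[, match("limb_L", ts$feature_desc), ])
  pk <- psd_peak(avg, s$fps_neural, band = c(0.15, 1), nperseg = 450)
  expect_gte(pk$peak_freq, 0.15)
  expect_lte(pk$peak_freq, 0.5)
})

test_that("longitudinal trends recover exact and null correlations", {
  expect_equal(longitudinal_trend(1:20, 1:20)$pearson_r, 1)
  expect_equal(longitudinal_trend(1:20, 20:1)$pearson_r, -1)
  tr <- longitudinal_trend(1:40, c(rep(7, 7), 8:40), burn_in = 7)
  expect_equal(tr$n, 33)
  expect_true(longitudinal_trend(1:10, rep(2, 10))$degenerate)
  expect_error(longitudinal_trend(1:3, 1:3, burn_in = 7), "at least 3")
  set.seed(16)
  rs <- vapply(1:200, function(i)
    longitudinal_trend(1:40, stats::rnorm(40))$pearson_r, 1)
  expect_gte(mean(abs(rs) < 0.4), 0.95)
})
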