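# Sliding-window decoding, curve smoothing, significance, and the EDT
# backward walk.

fake_curve <- function(acc_mat, times, fps = 30) {
  structure(list(times_s = times, fold_acc = acc_mat,
                 params = list(), smoothed = TRUE, fps = fps),
            class = "accuracy_curve")
}

test_that("moving-average smoothing behaves at the edges and on impulses", {
  x <- c(rep(0, 50), 1, rep(0, 50))
  sm <- moving_average(x, 30)
  expect_equal(max(sm), 1 / 30)
  expect_equal(sum(sm > 1e-12), 30)          # interior plateau of width k
  expect_equal(moving_average(x, 1), x)       # k = 1 is the identity
  expect_equal(moving_average(rep(0.7, 40), 15), rep(0.7, 40))
  expect_error(moving_average(x, 200), "exceeds")
  cv <- fake_curve(matrix(0.5, 20, 10), seq(-1, 0.9, by = 0.1))
  cv$smoothed <- FALSE
  sm2 <- smooth_curve(cv, 5)
  expect_true(sm2$smoothed)
  expect_equal(sm2$fold_acc, matrix(0.5, 20, 10))
})

test_that("curve significance handles chance-level and degenerate folds", {
  times <- seq(-1, 0.9, by = 0.1)
  sig <- curve_significance(fake_curve(matrix(0.5, 20, 10), times))
  expect_false(any(sig$mask))
  # zero fold variance: p = 0 away from chance, p = 1 at chance
  m <- matrix(0.5, 20, 10); m[3, ] <- 0.9
  sig2 <- curve_significance(fake_curve(m, times))
  expect_equal(sig2$p_raw[3], 0)
  expect_equal(sig2$p_raw[4], 1)
  expect_true(sig2$mask[3])
})

test_that("adjustment across the curve matches a hand-rolled BH step-up", {
  # independent oracle: textbook step-up, p_(i) * m / i with a running
  # minimum from the largest p downward
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m); out[o] <- pmin(adj, 1)
    out
  }
  set.seed(31)
  m <- matrix(stats::rnorm(24 * 10, mean = 0.52, sd = 0.05), 24, 10)
  sig <- curve_significance(fake_curve(m, seq(-2, 0.3, by = 0.1)))
  expect_equal(sig$p_adj, bh_oracle(sig$p_raw))
  # ties get identical adjusted values
  mt <- rbind(matrix(0.55, 2, 10), matrix(0.5, 3, 10))
  sigt <- curve_significance(fake_curve(mt + 0, seq(-0.4, 0, by = 0.1)))
  expect_equal(sigt$p_adj[1], sigt$p_adj[2])
})

test_that("the EDT is the start of the contiguous significant run at t = 0", {
  times <- seq(-10, 2, by = 0.5)
  p <- rep(0.5, length(times))
  p[times >= -2 & times <= 0] <- 0.001   # significant [-2, 0]
  p[times == -9] <- 0.001                # isolated early island: ignored
  r <- compute_edt(p, times, alpha = 0.05)
  expect_equal(r$edt_s, -2)
  # not significant at t = 0: not predicted
  p0 <- rep(0.001, length(times)); p0[times == 0] <- 0.9
  expect_equal(compute_edt(p0, times)$edt_s, 0)
  # EDT is never positive
  expect_lte(compute_edt(rep(0.001, length(times)), times)$edt_s, 0)
  for (i in 1:20) {
    pr <- stats::runif(length(times))
    rr <- compute_edt(pr, times)
    expect_lte(rr$edt_s, 0)
    if (rr$edt_s < 0) {
      inrun <- times >= rr$edt_s & times <= 0
      expect_true(all(pr[inrun] < 0.05))
    }
  }
})

test_that("the training loop evaluates one classifier per full feature window", {
  s <- toy_session(duration_s = 200, event_times_s = c(50, 80, 110, 140, 170))
  beh <- extract_trials(s, "lever_rewarded", c(-3, 2))
  ctl <- extract_trials(s, sample_control_triggers(s, 5, 3, c(-3, 2), seed = 1),
                        c(-3, 2))
  cv <- train_accuracy_curve(beh, ctl, feature_window_s = 1, folds = 2,
                             seed = 1)
  # 5-s trial window at 30 fps: 150 frames, 120 full 1-s windows
  expect_equal(length(cv$times_s), 120L)
  expect_equal(min(cv$times_s), -2)           # first full window ends at -2 s
  expect_true(any(abs(cv$times_s) < 1e-9))    # t = 0 always evaluated
  expect_true(all(cv$fold_acc >= 0 & cv$fold_acc <= 1))
  # strided grids stay anchored at t = 0
  cv6 <- train_accuracy_curve(beh, ctl, folds = 2, seed = 1, eval_stride = 6)
  expect_true(any(abs(cv6$times_s) < 1e-9))
  expect_equal(unique(round(diff(cv6$times_s) * 30)), 6)
})

test_that("decoding two identical distributions stays at chance", {
  set.seed(21)
  mk <- function(n) {
    arr <- array(rnorm(n * 3 * 90), c(n, 3, 90))
    trial_set(arr, seq(-2, 0.9666667, by = 1 / 30), "behavior",
              paste0("f", 1:3),
              data.frame(session_id = "x", event_time = seq_len(n)), 30)
  }
  accs <- vapply(1:4, function(i) {
    b <- mk(30); c0 <- mk(30); c0$label <- "control"
    cv <- train_accuracy_curve(b, c0, folds = 5, seed = i, eval_stride = 15)
    mean(cv$fold_acc)
  }, 1)
  expect_equal(mean(accs), 0.5, tolerance = 0.05)
})

test_that("feature-basis and class-size preconditions are enforced", {
  s <- toy_session(duration_s = 200, event_times_s = c(50, 80, 110, 140, 170))
  beh <- extract_trials(s, "lever_rewarded", c(-3, 2))
  ctl <- extract_trials(s, sample_control_triggers(s, 5, 3, c(-3, 2), seed = 1),
                        c(-3, 2))
  bad <- subset_features(ctl, c("area_1", "area_2"))
  expect_error(train_accuracy_curve(beh, bad, folds = 2), "mismatched")
  expect_error(train_accuracy_curve(beh, ctl, folds = 10), "at least")
})

test_that("per-area decoding selects bilateral pairs and KS compares EDTs", {
  s <- short_session(seed = 2, duration_s = 600)
  ts <- suppressMessages(extract_trials(s, "lever_rewarded", c(-4, 1)))
  limb <- subset_features(ts, "limb")
  expect_identical(limb$feature_desc, c("limb_L", "limb_R"))
  expect_error(subset_features(ts, "cerebellum"), "unknown area")
  ks <- compare_edt_distributions(c(-3, -2, 0, -1), c(-3, -2, 0, -1))
  expect_equal(unname(ks$statistic), 0)
})

test_that("more trials never systematically worsen the recovered EDT", {
  edt_at_n <- function(n_tr, seed) {
    cfg <- synth_config(duration_s = 2800, signal_onset_s = -3)
    s <- generate_session(cfg, seed = seed)
    beh <- suppressMessages(extract_trials(s, "lever_rewarded", c(-5, 1)))
    nb <- min(n_tr, n_trials(beh))
    keep <- seq_len(nb)
    beh$data <- beh$data[keep, , , drop = FALSE]
    beh$provenance <- beh$provenance[keep, ]
    ctl <- extract_trials(s, sample_control_triggers(s, nb, 3, c(-5, 1),
                                                     seed = seed), c(-5, 1))
    decode_session(beh, ctl, folds = 10, seed = seed, eval_stride = 10)$edt$edt_s
  }
  small <- vapply(1:2, function(i) edt_at_n(12, 130 + i), 1)
  large <- vapply(1:2, function(i) edt_at_n(70, 130 + i), 1)
  expect_lte(mean(large), mean(small) + 0.35)  # one strided grid step of slack
})
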