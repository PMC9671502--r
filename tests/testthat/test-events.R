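# Movement initiations, lockout filtering, trial pooling, quiescent bouts,
# stereotypy embedding.

make_track <- function(x, y = NULL, fps = 15) {
  y <- y %||% rep(0, length(x))
  body_track(list(left_paw = cbind(x, y)), fps_video = fps)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("initiation detection finds jumps and applies the refractory rule", {
  n <- 1500
  still <- make_track(rep(100, n))
  expect_length(detect_initiations(still, "left_paw"), 0)

  # a single instantaneous jump yields exactly one initiation at the jump
  x <- rep(100, n); x[700:n] <- 160
  t1 <- detect_initiations(make_track(x), "left_paw", k_std = 3)
  expect_length(t1, 1)
  expect_equal(t1, 699 / 15, tolerance = 1.5)  # within smoothing width

  # two bouts 1 s apart with a 3-s refractory keep only the first
  x2 <- rep(100, n); x2[300:n] <- 150; x2[315:n] <- 200
  t2 <- detect_initiations(make_track(x2), "left_paw", k_std = 1,
                           refractory_s = 3)
  t2_no <- detect_initiations(make_track(x2), "left_paw", k_std = 1,
                              refractory_s = 0.1)
  expect_lte(length(t2), length(t2_no))
  expect_error(detect_initiations(still, "right_paw"), "not tracked")
})

test_that("lockout keeps only targets with a quiescent preceding window", {
  ev <- event_table(c(5, 20, 40, 38),
                    c("lever_rewarded", "lever_rewarded", "lever_rewarded",
                      "lever_unrewarded"))
  spec <- lockout_spec(15)
  # 5 underflows; 20 survives (blocker at 5 sits in the allowed first bin);
  # 40 is blocked by the unrewarded pull at 38
  expect_equal(apply_lockout(ev, "lever_rewarded", spec), 20)
  # lockout 0 keeps everything
  expect_equal(apply_lockout(ev, "lever_rewarded", lockout_spec(0)),
               c(5, 20, 40))
  # a blocker in the final 0.250-s bin is tolerated with the edge allowance
  ev2 <- event_table(c(30, 29.9), c("lever_rewarded", "lick"))
  spec_lick <- lockout_spec(15, blocked_kinds = "lick")
  expect_equal(apply_lockout(ev2, "lever_rewarded", spec_lick), 30)
  spec_strict <- lockout_spec(15, edge_allowance = FALSE,
                              blocked_kinds = "lick")
  expect_length(apply_lockout(ev2, "lever_rewarded", spec_strict), 0)
})

test_that("lockout survivors shrink monotonically with lockout duration", {
  s <- short_session(seed = 6, duration_s = 1330)
  counts <- vapply(c(0, 3, 6, 9, 12, 15), function(L)
    length(apply_lockout(s$events, "lever_rewarded", lockout_spec(L))),
    1L)
  expect_true(all(diff(counts) <= 0))
  # survivors are always a subset of the input targets
  surv <- apply_lockout(s$events, "lever_rewarded", lockout_spec(9))
  expect_true(all(surv %in% event_times(s$events, "lever_rewarded")))
})

test_that("lockout pooling reproduces the printed 503-trial enumeration", {
  g <- pool_lockout_trials(503, group_size = 200, stride = 50, min_size = 50)
  expect_length(g, 10)
  expect_equal(g[[1]], 1:200)
  expect_equal(g[[10]], 451:503)
  # n = 200: strided starts keep emitting while >= min_size trials remain
  g200 <- pool_lockout_trials(200)
  expect_length(g200, 4)
  expect_equal(g200[[4]], 151:200)
  expect_error(pool_lockout_trials(49), "insufficient-trials")
  # every trial index is covered at least once
  for (n in c(77, 200, 503, 612)) {
    gg <- pool_lockout_trials(n)
    expect_setequal(sort(unique(unlist(gg))), seq_len(n))
  }
})

test_that("quiescent-bout selection applies both exclusion rules", {
  neural <- matrix(0, 1, 3000)  # 100 s @ 30 Hz
  ini <- list(left_paw = c(20, 50, 80), right_paw = c(48.5), lick = c(78))
  ev <- event_table(c(24, 20, 50, 80, 48.5, 78),
                    c("lever_rewarded", "left_paw", "left_paw", "left_paw",
                      "right_paw", "lick"))
  s <- session(neural, fps_neural = 30, area_labels = "m", events = ev)
  out <- select_quiescent_bouts(s, "left_paw", lever_pre_s = 15,
                                lever_post_s = 5, body_quiescence_s = 5,
                                initiations = ini)
  # 20 is excluded (lever pull at +4 s); 50 is excluded (right-paw move
  # 1.5 s before); 80 is excluded (lick 2 s before)
  expect_equal(nrow(out), 0)
  ini2 <- list(left_paw = c(70), right_paw = numeric(0), lick = numeric(0))
  out2 <- select_quiescent_bouts(s, "left_paw", initiations = ini2)
  expect_equal(out2$time_s, 70)
  expect_gte(out2$quiescence_s, 5)
})

test_that("stereotypy embedding separates distinct movement patterns", {
  fps <- 15; n <- 3000
  mk <- function(bouts) {
    x <- rep(100, n)
    for (b in bouts) x[(b * fps):(b * fps + 10)] <- 140
    x
  }
  # pattern A: movement 8 s before trigger; pattern B: 2 s before
  trk <- body_track(list(left_paw = cbind(mk(c(22, 52, 82, 112)), 0),
                         right_paw = cbind(mk(c(28, 58, 88, 118)), 0)),
                    fps_video = fps)
  triggers <- c(30, 60, 90, 120)
  emb <- stereotypy_embedding(trk, triggers, window_s = c(-10, 0), k_std = 1)
  expect_equal(dim(emb), c(4L, 2L))
  # mean-centered scores
  expect_equal(colSums(emb), c(PC1 = 0, PC2 = 0), tolerance = 1e-8)
  # identical trials coincide
  expect_lt(max(dist(emb)), 1e-6)
  # two alternating patterns form two separated clusters
  trkAB <- body_track(list(left_paw = cbind(mk(c(22, 58, 82, 118)), 0)),
                      fps_video = fps)
  embAB <- stereotypy_embedding(trkAB, triggers, window_s = c(-10, 0), k_std = 1)
  dAB <- as.matrix(dist(embAB))
  expect_lt(dAB[1, 3], 1e-6)            # same-pattern trials coincide
  expect_gt(dAB[1, 2], 0.5)             # cross-pattern trials separate
  expect_error(stereotypy_embedding(trk, c(30, 60)), "at least 3")
})
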