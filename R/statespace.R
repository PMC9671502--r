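# Convex-hull analysis of the pre-movement neural state space: outlier
# triage, shared low-dimensional embedding, hull-ratio curves over the 10 s
# preceding the action, normalized AUC against random triggers, and
# Monte-Carlo hull overlap between behaviors.

#' K-nearest-neighbor outlier triage
#'
#' Removes the `frac` fraction of points with the largest mean distance to
#' their `k` nearest neighbors (hull analysis is sensitive to outliers).
#'
#' @param points matrix `[n x d]`.
#' @param frac fraction to remove (default 0.10); 0 is the identity.
#' @param k neighbor count (default 10).
#' @return the retained points, `ceiling((1 - frac) * n)` rows.
#' @export
knn_triage <- function(points, frac = 0.10, k = 10) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < k + 2) stop("need at least k + 2 points for triage")
  if (frac == 0) return(P)
  # mean distance to the k nearest neighbors, computed in row blocks
  block <- max(1L, min(n, as.integer(2e7 / n)))
  md <- numeric(n)
  sq <- rowSums(P^2)
  for (s0 in seq(1L, n, by = block)) {
    idx <- s0:min(n, s0 + block - 1L)
    D2 <- outer(sq[idx], sq, `+`) - 2 * P[idx, , drop = FALSE] %*% t(P)
    D2[cbind(seq_along(idx), idx)] <- Inf
    D2[D2 < 0] <- 0
    md[idx] <- apply(D2, 1, function(r) mean(sqrt(sort(r, partial = k)[seq_len(k)])))
  }
  n_drop <- n - ceiling((1 - frac) * n)
  if (n_drop <= 0) return(P)
  keep <- sort(order(md, decreasing = TRUE)[-seq_len(n_drop)])
  P[keep, , drop = FALSE]
}

#' Fit the shared low-dimensional embedding of a session
#'
#' PCA basis over all session frame vectors; every hull compared within a
#' session must be computed in this one embedding.
#'
#' @param s a `premove_session`.
#' @param dim embedding dimension, 2 or 3 (default 3).
#' @return list with `center` and `rotation` (class `hull_embedding`).
#' @export
fit_embedding <- function(s, dim = 3) {
  if (!dim %in% 2:3) stop("embedding dimension must be 2 or 3")
  X <- t(s$neural)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(dim), drop = FALSE],
                 dim = dim),
            class = "hull_embedding")
}

#' Project frame vectors into a fitted embedding
#' @param X matrix `[frames x areas]`.
#' @param emb a `hull_embedding`.
#' @return matrix `[frames x dim]`.
#' @export
embed_points <- function(X, emb) {
  sweep(as.matrix(X), 2, emb$center) %*% emb$rotation
}

#' Hull-ratio curve of pre-event neural activity
#'
#' For each offset, the 1-s segment ending at that offset contributes all
#' its frames from every trial; the ratio is the hull volume of those
#' vectors over the hull volume of the whole session's vectors, both after
#' k-nearest-neighbor triage and in the shared embedding. Contraction of
#' the ratio toward t = 0 indicates stereotyped pre-movement activity.
#'
#' @param s a `premove_session`.
#' @param triggers event kind (character) or trigger times in seconds.
#' @param offsets segment end offsets in seconds (default `-10:0`).
#' @param emb a `hull_embedding` (fit on `s` if `NULL`).
#' @param frac,k triage parameters.
#' @param max_session_points cap on session frames used for the
#'   denominator hull (seeded subsample; default 4000).
#' @param min_points minimum segment points per offset (else NA).
#' @param seed RNG seed for the subsample.
#' @param volume_all optional precomputed session hull volume, reused
#'   across repeated calls sharing the same embedding and subsample.
#' @return list of class `hull_ratio_curve`: `offsets`, `ratio` (in
#'   [0, 1]), `volume_all`, `n_trials`.
#' @export
hull_ratio_curve <- function(s, triggers = "lever_rewarded",
                             offsets = -10:0, emb = NULL,
                             frac = 0.10, k = 10,
                             max_session_points = 4000,
                             min_points = 20, seed = 1L,
                             volume_all = NULL) {
  fps <- s$fps_neural
  times <- if (is.character(triggers)) event_times(s$events, triggers)
           else as.numeric(triggers)
  if (!length(times)) stop("no trigger events")
  emb <- emb %||% fit_embedding(s)
  allX <- embed_points(t(s$neural), emb)
  vol_all <- volume_all %||% {
    sel <- with_seed(seed, {
      if (nrow(allX) > max_session_points)
        sort(sample.int(nrow(allX), max_session_points))
      else seq_len(nrow(allX))
    })
    convex_hull(knn_triage(allX[sel, , drop = FALSE], frac, k))$volume
  }
  if (vol_all <= 0) stop("degenerate session hull")

  nfr <- ncol(s$neural)
  ratio <- rep(NA_real_, length(offsets))
  for (i in seq_along(offsets)) {
    o <- offsets[i]
    segs <- lapply(times, function(T) {
      i0 <- time_to_index(T + o - 1, fps)
      i1 <- time_to_index(T + o, fps) - 1L
      if (i0 < 1 || i1 > nfr) return(NULL)
      allX[i0:i1, , drop = FALSE]
    })
    seg <- do.call(rbind, segs)
    if (is.null(seg) || nrow(seg) < max(min_points, k + 2)) next
    ratio[i] <- convex_hull(knn_triage(seg, frac, k))$volume / vol_all
  }
  ratio <- pmin(pmax(ratio, 0), 1)
  structure(list(offsets = offsets, ratio = ratio, volume_all = vol_all,
                 n_trials = length(times)),
            class = "hull_ratio_curve")
}

#' Normalized area under the hull-ratio curve
#'
#' Trapezoidal AUC of the event-locked ratio curve divided by the AUC of a
#' random-trigger ratio curve (triggers at least 3 s from any rewarded
#' pull). Values below 1 indicate pre-event contraction of the occupied
#' neural space relative to random periods.
#'
#' @param ratio_pull,ratio_random `hull_ratio_curve` objects (or numeric
#'   ratio vectors) over the same offsets.
#' @param offsets offsets (taken from the curve objects if omitted).
#' @return scalar normalized AUC.
#' @export
auc_ratio <- function(ratio_pull, ratio_random, offsets = NULL) {
  get_r <- function(x) if (inherits(x, "hull_ratio_curve")) x$ratio else as.numeric(x)
  get_o <- function(x) if (inherits(x, "hull_ratio_curve")) x$offsets else offsets
  rp <- get_r(ratio_pull); rr <- get_r(ratio_random)
  op <- get_o(ratio_pull); or <- get_o(ratio_random)
  if (is.null(op) || is.null(or) || length(rp) != length(rr) ||
      !isTRUE(all.equal(op, or)))
    stop("curves must share the same offsets")
  ok <- is.finite(rp) & is.finite(rr)
  if (sum(ok) < 2) stop("not enough finite curve points")
  a_r <- trapz(or[ok], rr[ok])
  if (a_r == 0) stop("zero random-trigger AUC")
  trapz(op[ok], rp[ok]) / a_r
}

#' Event-locked versus random-trigger hull AUC for one session
#'
#' Convenience wrapper computing the event-locked ratio curve and
#' `n_reps` random-trigger curves (re-sampled each repetition, at least
#' `min_gap_s` from any rewarded pull), with their normalized AUC.
#'
#' @inheritParams hull_ratio_curve
#' @param n_reps random-trigger repetitions (default 10).
#' @param min_gap_s trigger distance to rewarded pulls (default 3).
#' @return list with `pull` curve, `random` ratio matrix
#'   `[n_reps x offsets]`, `auc` (normalized, against the mean random
#'   curve) and `auc_sd` (over repetitions).
#' @export
hull_auc_analysis <- function(s, triggers = "lever_rewarded", offsets = -10:0,
                              n_reps = 10, min_gap_s = 3, emb = NULL,
                              frac = 0.10, k = 10,
                              max_session_points = 4000, seed = 1L) {
  emb <- emb %||% fit_embedding(s)
  pull <- hull_ratio_curve(s, triggers, offsets, emb, frac, k,
                           max_session_points, seed = seed)
  n_ev <- pull$n_trials
  rnd <- matrix(NA_real_, n_reps, length(offsets))
  aucs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    trig <- sample_control_triggers(s, n_ev, min_gap_s = min_gap_s,
                                    window_s = c(min(offsets) - 1, 1),
                                    seed = seed + 1000L * r)
    rc <- hull_ratio_curve(s, trig, offsets, emb, frac, k,
                           max_session_points, seed = seed,
                           volume_all = pull$volume_all)
    rnd[r, ] <- rc$ratio
    aucs[r] <- auc_ratio(pull, rc)
  }
  mean_rnd <- colMeans(rnd)
  list(pull = pull, random = rnd,
       auc = auc_ratio(pull$ratio, mean_rnd, offsets = offsets),
       auc_sd = stats::sd(aucs))
}

#' Monte-Carlo overlap between two hulls
#'
#' Samples uniformly inside hull(A) by rejection from its bounding box;
#' the A-to-B overlap is the fraction of samples inside hull(B). Both
#' directions and the symmetrized mean are reported.
#'
#' @param points_a,points_b point sets `[n x d]` (same d, 2 or 3), in a
#'   common embedding.
#' @param n_mc Monte-Carlo samples per direction (default 1e5).
#' @param seed RNG seed.
#' @return list with `a_in_b`, `b_in_a`, `mean` (all in [0, 1]).
#' @export
hull_overlap <- function(points_a, points_b, n_mc = 1e5, seed = 1L) {
  ha <- convex_hull(points_a)
  hb <- convex_hull(points_b)
  if (ha$degenerate || hb$degenerate) stop("degenerate hull")
  one_way <- function(h_from, h_to, sd_offset) {
    lo <- apply(h_from$vertices, 2, min)
    hi <- apply(h_from$vertices, 2, max)
    got <- 0L; inside_to <- 0L; tries <- 0L
    while (got < n_mc && tries < 200) {
      m <- min(5e4, (n_mc - got) * 4)
      X <- matrix(stats::runif(m * h_from$dim), m) %*% diag(hi - lo, h_from$dim) +
        matrix(lo, m, h_from$dim, byrow = TRUE)
      inA <- hull_contains(h_from, X)
      X <- X[inA, , drop = FALSE]
      if (nrow(X) > n_mc - got) X <- X[seq_len(n_mc - got), , drop = FALSE]
      got <- got + nrow(X)
      if (nrow(X)) inside_to <- inside_to + sum(hull_contains(h_to, X))
      tries <- tries + 1L
    }
    if (got == 0) stop("could not sample inside the hull")
    inside_to / got
  }
  with_seed(seed, {
    ab <- one_way(ha, hb)
    ba <- one_way(hb, ha)
    list(a_in_b = ab, b_in_a = ba, mean = (ab + ba) / 2)
  })
}
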