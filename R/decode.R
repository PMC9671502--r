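# Sliding-window two-class decoding and the earliest-decoding-time (EDT)
# statistic.
#
# For every evaluation time t, a support vector machine is trained on the
# flattened [components x feature-window frames] preceding t (half-open
# window [t - feature_window_s, t)), with the accuracy assigned to the
# window's last time point. Fold partitions are stratified, seeded, and
# shared across time points so fold accuracies are paired in time.
# Significance per time point is a one-sample t-test of the fold accuracies
# against chance, Benjamini-Hochberg corrected across the whole curve; the
# EDT is the start of the contiguous run of significant time points ending
# at t = 0 (isolated earlier significant islands are ignored), with 0
# meaning "not predicted".

#' Train a sliding-window cross-validated accuracy curve
#'
#' @param behavior,control `trial_set` objects of the two classes, with
#'   identical shape, features and time axis (mismatched feature bases are
#'   an error). Class sizes should be matched (sample exactly
#'   `n_trials(behavior)` control triggers).
#' @param feature_window_s feature window length in seconds (default 1).
#' @param folds number of stratified cross-validation folds (default 10,
#'   i.e. a 0.9:0.1 train:validate split).
#' @param kernel SVM kernel (default `"sigmoid"`).
#' @param cost SVM regularization constant (default 1).
#' @param seed RNG seed for the fold partition.
#' @param eval_stride evaluate every `eval_stride`-th frame (grid anchored
#'   so that t = 0 is always evaluated; default 1 = every frame).
#' @return object of class `accuracy_curve`: `times_s`, `fold_acc`
#'   (`[n_timepoints x folds]`), `params`, `smoothed = FALSE`.
#' @export
train_accuracy_curve <- function(behavior, control, feature_window_s = 1,
                                 folds = 10, kernel = "sigmoid", cost = 1,
                                 seed = 1L, eval_stride = 1L) {
  if (!identical(behavior$feature_desc, control$feature_desc))
    stop("mismatched feature bases between behavior and control sets")
  if (!isTRUE(all.equal(behavior$times_s, control$times_s)))
    stop("behavior and control sets must share the time axis")
  nb <- n_trials(behavior); nc <- n_trials(control)
  if (nb < folds || nc < folds)
    stop("each class needs at least `folds` trials (", folds, ")")
  fps <- behavior$fps
  fw <- as.integer(round(feature_window_s * fps))
  nfr <- length(behavior$times_s)
  if (fw >= nfr) stop("feature window longer than the trial window")

  # evaluation grid: ends of full feature windows, anchored at t = 0
  j_all <- (fw + 1L):nfr
  j_zero <- which(abs(behavior$times_s) < 1e-9)
  j_eval <- j_all[(j_all - j_zero) %% eval_stride == 0]
  y <- factor(rep(c("behavior", "control"), c(nb, nc)))

  fold_of <- with_seed(seed, {
    c(sample(rep_len(seq_len(folds), nb)), sample(rep_len(seq_len(folds), nc)))
  })

  acc <- matrix(NA_real_, length(j_eval), folds)
  for (q in seq_along(j_eval)) {
    j <- j_eval[q]
    win <- (j - fw):(j - 1L)
    X <- rbind(matrix(behavior$data[, , win], nrow = nb),
               matrix(control$data[, , win], nrow = nc))
    g <- 1 / (ncol(X) * max(stats::var(as.vector(X)), .Machine$double.eps))
    for (f in seq_len(folds)) {
      te <- fold_of == f
      fit <- e1071::svm(X[!te, , drop = FALSE], y[!te], kernel = kernel,
                        cost = cost, gamma = g, scale = FALSE)
      acc[q, f] <- mean(predict(fit, X[te, , drop = FALSE]) == y[te])
    }
  }
  structure(list(times_s = behavior$times_s[j_eval], fold_acc = acc,
                 params = list(feature_window_s = feature_window_s,
                               folds = folds, kernel = kernel, cost = cost,
                               seed = seed, eval_stride = eval_stride),
                 smoothed = FALSE, fps = fps / eval_stride),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("<accuracy_curve> %d timepoints (%.2f..%.2f s), %d folds%s\n",
              length(x$times_s), min(x$times_s), max(x$times_s),
              ncol(x$fold_acc), if (x$smoothed) ", smoothed" else ""))
  cat(sprintf("  grand mean accuracy %.3f, max %.3f at %.2f s\n",
              mean(x$fold_acc), max(rowMeans(x$fold_acc)),
              x$times_s[which.max(rowMeans(x$fold_acc))]))
  invisible(x)
}

#' Smooth an accuracy curve with a moving average
#'
#' Centered moving average applied per fold trace; edge windows shrink.
#'
#' @param curve an `accuracy_curve`.
#' @param k window length in curve samples (default 30, i.e. 1 s on a
#'   30 Hz evaluation grid).
#' @return the curve with smoothed fold traces and `smoothed = TRUE`.
#' @export
smooth_curve <- function(curve, k = 30L) {
  curve$fold_acc <- apply(curve$fold_acc, 2, moving_average, k = k)
  curve$smoothed <- TRUE
  curve
}

#' Per-timepoint significance of an accuracy curve
#'
#' One-sample t-test of the fold accuracies against chance at every time
#' point, Benjamini-Hochberg adjusted across all time points of the curve.
#' A time point with zero fold variance gets p = 0 if its mean differs
#' from chance and p = 1 otherwise.
#'
#' @param curve a (smoothed) `accuracy_curve`.
#' @param chance chance level (default 0.5).
#' @param alpha significance level (default 0.05).
#' @return list with `p_raw`, `p_adj`, `mask` (`p_adj < alpha`),
#'   `times_s`, `alpha`.
#' @export
curve_significance <- function(curve, chance = 0.5, alpha = 0.05) {
  p_raw <- apply(curve$fold_acc, 1, function(a) {
    if (stats::sd(a) == 0) return(if (mean(a) == chance) 1 else 0)
    stats::t.test(a, mu = chance)$p.value
  })
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  list(p_raw = p_raw, p_adj = p_adj, mask = p_adj < alpha,
       times_s = curve$times_s, alpha = alpha)
}

#' Earliest decoding time from adjusted p values
#'
#' Starting at t = 0 and walking backwards, the EDT is the most negative
#' time t* such that every evaluated time point in `[t*, 0]` is
#' significant. If t = 0 itself is not significant the EDT is 0 (the
#' action was not predicted). EDT is always <= 0.
#'
#' @param p_adj adjusted p values per time point.
#' @param times_s matching time axis (must cover t <= 0).
#' @param alpha significance level (default 0.05).
#' @return object of class `edt_result` with fields `edt_s`, `p_adj`,
#'   `significant_mask`, `alpha`, `times_s`.
#' @export
compute_edt <- function(p_adj, times_s, alpha = 0.05) {
  pre <- which(times_s <= 1e-9)
  if (!length(pre)) stop("`times_s` must cover t <= 0")
  ord <- pre[order(times_s[pre], decreasing = TRUE)]  # 0, then backwards
  mask <- p_adj < alpha
  edt <- 0
  for (i in ord) {
    if (!mask[i]) break
    edt <- times_s[i]
  }
  edt <- min(edt, 0)
  structure(list(edt_s = edt, p_adj = p_adj, significant_mask = mask,
                 alpha = alpha, times_s = times_s),
            class = "edt_result")
}

#' @export
print.edt_result <- function(x, ...) {
  cat(sprintf("<edt_result> EDT = %.3f s%s\n", x$edt_s,
              if (x$edt_s == 0) " (not predicted)" else ""))
  invisible(x)
}

#' Decode a behavior/control pair end to end
#'
#' Convenience wrapper: accuracy curve, moving-average smoothing,
#' per-timepoint t-tests with BH correction, and the EDT backward walk.
#'
#' @inheritParams train_accuracy_curve
#' @param smooth_k smoothing window in curve samples; default matches 1 s
#'   on the evaluation grid.
#' @param chance,alpha significance parameters.
#' @return list with `curve` (smoothed), `significance`, `edt`.
#' @export
decode_session <- function(behavior, control, feature_window_s = 1,
                           folds = 10, kernel = "sigmoid", cost = 1,
                           seed = 1L, eval_stride = 1L,
                           smooth_k = NULL, chance = 0.5, alpha = 0.05) {
  curve <- train_accuracy_curve(behavior, control, feature_window_s,
                                folds, kernel, cost, seed, eval_stride)
  k <- smooth_k %||% max(1L, round(behavior$fps / eval_stride))
  curve <- smooth_curve(curve, k = min(k, length(curve$times_s)))
  sig <- curve_significance(curve, chance = chance, alpha = alpha)
  list(curve = curve, significance = sig,
       edt = compute_edt(sig$p_adj, sig$times_s, alpha))
}

#' Decode restricted to one cortical area (or area pair)
#'
#' Runs the identical pipeline on the trial features matching the
#' requested area(s); by default a stem like `"limb"` selects the
#' bilateral pair.
#'
#' @inheritParams decode_session
#' @param areas area labels or stems (see [subset_features()]).
#' @return as [decode_session()].
#' @export
decode_per_area <- function(behavior, control, areas, ...) {
  decode_session(subset_features(behavior, areas),
                 subset_features(control, areas), ...)
}

#' Compare two EDT distributions
#'
#' Two-sample Kolmogorov-Smirnov test between EDT samples, e.g. all-areas
#' versus single-area decoding.
#'
#' @param edt_a,edt_b numeric vectors of EDTs in seconds.
#' @return `htest` object from [stats::ks.test()].
#' @export
compare_edt_distributions <- function(edt_a, edt_b) {
  suppressWarnings(stats::ks.test(edt_a, edt_b))
}
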