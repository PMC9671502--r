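# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(pi + 0.1)  # -> -pi + 0.1
#' @export
wrap_angle <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# 0-based frame/time convention: frame index i (0-based) <-> time i / fps.
# R storage is 1-based, so time t maps to storage index round(t * fps) + 1.
time_to_index <- function(t, fps) as.integer(round(t * fps)) + 1L
index_to_time <- function(i, fps) (i - 1L) / fps

#' Centered moving average with shrinking edge windows
#'
#' Window of nominal length `k` centered on each sample
#' (`floor((k-1)/2)` samples to the left, `ceiling((k-1)/2)` to the right);
#' at the edges the window shrinks to the available samples.
#'
#' @param x numeric vector.
#' @param k window length in samples (`k = 1` is the identity).
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, k) {
  n <- length(x)
  if (k < 1) stop("`k` must be >= 1")
  if (k > n) stop("`k` (", k, ") exceeds series length (", n, ")")
  if (k == 1) return(x)
  lo <- pmax(seq_len(n) - floor((k - 1) / 2), 1L)
  hi <- pmin(seq_len(n) + ceiling((k - 1) / 2), n)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
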