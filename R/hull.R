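# Convex hulls in 2 and 3 dimensions.
#
# 2-D: grDevices::chull + shoelace area. 3-D: incremental quickhull with an
# exact interior-point pre-filter (points inside the hull of directional
# extremes can never be hull vertices and are discarded before insertion).
# Hulls are stored as half-space intersections (outward facet normals and
# offsets), which makes volume, membership tests and Monte-Carlo overlap
# estimates straightforward.

#' Convex hull of a 2-D or 3-D point set
#'
#' @param points numeric matrix `[n x d]`, d = 2 or 3.
#' @return object of class `convex_hull` with fields `dim`, `volume`
#'   (area in 2-D, volume in 3-D), `vertices` (hull vertex coordinates),
#'   `normals`/`offsets` (outward half-space representation) and
#'   `degenerate` (TRUE for affinely dependent input, with zero volume).
#' @export
convex_hull <- function(points) {
  P <- unique(as.matrix(points))
  storage.mode(P) <- "double"
  d <- ncol(P)
  if (!d %in% c(2L, 3L)) stop("convex hulls are supported in 2 or 3 dimensions")
  scale <- max(apply(P, 2, function(v) diff(range(v))), 1e-12)
  tol <- 1e-9 * scale
  if (d == 2L) hull2_fit(P, tol) else hull3_fit(P, tol)
}

hull_degenerate <- function(P, d) {
  structure(list(dim = d, volume = 0, vertices = P,
                 normals = NULL, offsets = NULL, degenerate = TRUE),
            class = "convex_hull")
}

hull2_fit <- function(P, tol) {
  if (nrow(P) < 3) return(hull_degenerate(P, 2L))
  idx <- grDevices::chull(P)
  V <- P[idx, , drop = FALSE]
  nv <- nrow(V)
  if (nv < 3) return(hull_degenerate(P, 2L))
  x <- V[, 1]; y <- V[, 2]
  area <- abs(sum(x * y[c(2:nv, 1)] - x[c(2:nv, 1)] * y)) / 2
  if (area < tol^2) return(hull_degenerate(P, 2L))
  ctr <- colMeans(V)
  nxt <- c(2:nv, 1)
  ex <- V[nxt, 1] - x; ey <- V[nxt, 2] - y
  N <- cbind(ey, -ex)  # edge normal, orientation fixed against the centroid
  len <- sqrt(rowSums(N^2))
  N <- N / len
  off <- rowSums(N * V)
  flip <- (N %*% ctr) > off
  N[flip, ] <- -N[flip, , drop = FALSE]
  off[flip] <- -off[flip]
  structure(list(dim = 2L, volume = area, vertices = V,
                 normals = N, offsets = as.numeric(off), degenerate = FALSE),
            class = "convex_hull")
}

# -- 3-D quickhull ----------------------------------------------------------

facet_geom <- function(tri, P, interior) {
  v1 <- P[tri[1], ]; v2 <- P[tri[2], ]; v3 <- P[tri[3], ]
  n <- c((v2[2] - v1[2]) * (v3[3] - v1[3]) - (v2[3] - v1[3]) * (v3[2] - v1[2]),
         (v2[3] - v1[3]) * (v3[1] - v1[1]) - (v2[1] - v1[1]) * (v3[3] - v1[3]),
         (v2[1] - v1[1]) * (v3[2] - v1[2]) - (v2[2] - v1[2]) * (v3[1] - v1[1]))
  len <- sqrt(sum(n^2))
  if (len < 1e-300) return(NULL)
  n <- n / len
  if (sum(n * interior) > sum(n * v1)) { n <- -n; tri <- tri[c(1, 3, 2)] }
  list(tri = tri, n = n, d = sum(n * v1))
}

hull3_core <- function(P, cand, tol) {
  # initial simplex from the candidate indices
  i1 <- cand[which.min(P[cand, 1])]
  dd <- rowSums(sweep(P[cand, , drop = FALSE], 2, P[i1, ])^2)
  i2 <- cand[which.max(dd)]
  ab <- P[i2, ] - P[i1, ]
  rel <- sweep(P[cand, , drop = FALSE], 2, P[i1, ])
  crossm <- cbind(rel[, 2] * ab[3] - rel[, 3] * ab[2],
                  rel[, 3] * ab[1] - rel[, 1] * ab[3],
                  rel[, 1] * ab[2] - rel[, 2] * ab[1])
  dl <- sqrt(rowSums(crossm^2))
  i3 <- cand[which.max(dl)]
  if (max(dl) < tol * sqrt(sum(ab^2))) return(NULL)  # collinear
  n0 <- pracma_cross(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  n0 <- n0 / sqrt(sum(n0^2))
  dp <- abs(as.numeric(sweep(P[cand, , drop = FALSE], 2, P[i1, ]) %*% n0))
  i4 <- cand[which.max(dp)]
  if (max(dp) < tol) return(NULL)  # coplanar
  interior <- colMeans(P[c(i1, i2, i3, i4), ])
  facets <- list()
  for (tri in list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))) {
    fg <- facet_geom(tri, P, interior)
    if (is.null(fg)) return(NULL)
    facets[[length(facets) + 1L]] <- fg
  }
  todo <- setdiff(cand, c(i1, i2, i3, i4))
  for (p in todo) {
    pt <- P[p, ]
    vis <- vapply(facets, function(f) sum(f$n * pt) - f$d > tol, TRUE)
    if (!any(vis)) next
    vis_f <- facets[vis]
    edges <- do.call(rbind, lapply(vis_f, function(f)
      rbind(sort(f$tri[c(1, 2)]), sort(f$tri[c(2, 3)]), sort(f$tri[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    facets <- facets[!vis]
    ok <- TRUE
    for (r in seq_len(nrow(horizon))) {
      fg <- facet_geom(c(horizon[r, ], p), P, interior)
      if (is.null(fg)) next
      facets[[length(facets) + 1L]] <- fg
    }
    if (!ok || !length(facets)) return(NULL)
  }
  facets
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

hull3_fit <- function(P, tol) {
  n <- nrow(P)
  if (n < 4) return(hull_degenerate(P, 3L))
  cand <- seq_len(n)
  if (n > 400) {
    # exact pre-filter: points inside the hull of directional extremes are
    # interior to the full hull and can be dropped before insertion
    dirs <- rbind(diag(3), -diag(3),
                  as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
                  matrix(stats::rnorm(3 * 60), ncol = 3))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    proj <- P %*% t(dirs)
    ext <- unique(apply(proj, 2, which.max))
    efac <- hull3_core(P, ext, tol)
    if (!is.null(efac)) {
      N <- t(vapply(efac, `[[`, numeric(3), "n"))
      d0 <- vapply(efac, `[[`, 1, "d")
      outside <- rowSums(P %*% t(N) > matrix(d0 + tol, n, length(d0), byrow = TRUE)) > 0
      cand <- union(ext, which(outside))
    }
  }
  facets <- hull3_core(P, cand, tol)
  if (is.null(facets)) return(hull_degenerate(P, 3L))
  vid <- sort(unique(unlist(lapply(facets, `[[`, "tri"))))
  interior <- colMeans(P[vid, , drop = FALSE])
  vol <- sum(vapply(facets, function(f) {
    a <- P[f$tri[1], ] - interior
    b <- P[f$tri[2], ] - interior
    cc <- P[f$tri[3], ] - interior
    abs(sum(a * pracma_cross(b, cc))) / 6
  }, 1))
  structure(list(dim = 3L, volume = vol, vertices = P[vid, , drop = FALSE],
                 normals = t(vapply(facets, `[[`, numeric(3), "n")),
                 offsets = vapply(facets, `[[`, 1, "d"),
                 degenerate = FALSE),
            class = "convex_hull")
}

#' @export
print.convex_hull <- function(x, ...) {
  cat(sprintf("<convex_hull> %d-D, %s, volume %.6g, %d vertices\n", x$dim,
              if (x$degenerate) "degenerate" else "non-degenerate",
              x$volume, nrow(x$vertices)))
  invisible(x)
}

#' Test points for hull membership
#'
#' @param hull a `convex_hull`.
#' @param X points `[m x d]`.
#' @param tol boundary tolerance.
#' @return logical vector; all `FALSE` for a degenerate hull.
#' @export
hull_contains <- function(hull, X, tol = 1e-9) {
  X <- matrix(X, ncol = hull$dim)
  if (hull$degenerate) return(rep(FALSE, nrow(X)))
  S <- X %*% t(hull$normals)
  lim <- matrix(hull$offsets + tol * max(abs(hull$offsets), 1),
                nrow(X), length(hull$offsets), byrow = TRUE)
  rowSums(S > lim) == 0
}

#' Convex-hull hypervolume of a point set
#'
#' @param points matrix `[n x d]`, d = 2 or 3, already expressed in the
#'   shared session embedding (volumes are basis-dependent; only compare
#'   volumes computed in one common basis).
#' @return the hull volume (area in 2-D); 0 with a warning for a
#'   degenerate (affinely dependent) set.
#' @export
hull_volume <- function(points) {
  h <- convex_hull(points)
  if (h$degenerate) warning("degenerate point set: zero hull volume")
  h$volume
}
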