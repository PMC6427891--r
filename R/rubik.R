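#' Largest-gap split of a one-dimensional projection
#'
#' The 1-D cut primitive behind [rubikSplit()]. Projections are sorted and
#' the largest inter-point gap with at least `minGapPoints` samples on each
#' side is located. The candidate gap `g` is accepted as a split when it
#' dominates the spread of the data in either of two senses:
#'
#' * `g > gapFactor x IQR(larger side)` (the larger side needs >= 5
#'   points): the gap is several times the core spread of the bulk of the
#'   points, as when a compact cluster or a few outlying individuals sit
#'   far from a unimodal main body;
#' * `g > dominanceFactor x (range - g)` (both sides need >= 4 points): the
#'   gap is large relative to everything that is not the gap, which also
#'   fires when *both* sides are themselves wide multi-cluster regions
#'   (e.g. three collinear groups).
#'
#' The side-size guards keep either test from shaving the sparse tail of a
#' single unimodal cluster, where the rotation search would otherwise pick
#' up spuriously large extreme-value spacings.
#'
#' Both tests are unit-free; increasing either factor can only ever merge,
#' never create, splits.
#'
#' @param x numeric vector of projections (length >= 2).
#' @param gapFactor positive threshold on the gap as a multiple of the
#'   larger side's interquartile range (default 3).
#' @param minGapPoints minimum number of samples on each side of the cut.
#' @param dominanceFactor positive threshold on the gap as a multiple of
#'   the non-gap spread (default 0.5).
#' @return the threshold (numeric scalar) or `NULL` if no dominant gap.
#' @export
axisGapSplit <- function(x, gapFactor = 3, minGapPoints = 1L,
                         dominanceFactor = 0.5) {
  n <- length(x)
  if (n < 2L * minGapPoints || n < 2L) return(NULL)
  xs <- sort(x)
  rng <- xs[n] - xs[1L]
  if (rng <= 0) return(NULL)
  gaps <- diff(xs)
  idx <- seq_len(n - 1L)
  ok <- idx >= minGapPoints & (n - idx) >= minGapPoints
  if (!any(ok)) return(NULL)
  cand <- idx[ok]
  i <- cand[which.max(gaps[cand])]
  g <- gaps[i]
  big <- if (i >= n - i) xs[seq_len(i)] else xs[(i + 1L):n]
  fire <- (length(big) >= 5L && g > gapFactor * stats::IQR(big)) ||
    (i >= 4L && (n - i) >= 4L && g > dominanceFactor * (rng - g))
  if (fire) (xs[i] + xs[i + 1L]) / 2 else NULL
}

# rotation about coordinate axis `axis` (1, 2 or 3) by `theta` radians
.rotMat3 <- function(axis, theta) {
  R <- diag(3)
  ij <- switch(axis, c(2L, 3L), c(1L, 3L), c(1L, 2L))
  R[ij[1L], ij[1L]] <- cos(theta)
  R[ij[2L], ij[2L]] <- cos(theta)
  R[ij[1L], ij[2L]] <- -sin(theta)
  R[ij[2L], ij[1L]] <- sin(theta)
  R
}

#' Rotation-search clustering in the space of the first three PCs
#'
#' First-stage splitter of the iterative engine. The 3-D point cloud is
#' rotated through a grid of composed rotations about PC1, then PC2, then
#' PC3 (angles `0, angleStep, ...` below 90 degrees, scanned in
#' lexicographic order) and after each rotation every rotated coordinate is
#' tested with [axisGapSplit()]. The first successful cut in scan order is
#' applied and the procedure recurses on each side, up to `maxGroups`
#' groups. Because a cut happens in an empty gap, well-separated groups are
#' partitioned exactly, and a handful of points far from the bulk of the
#' data (outlying individuals) are shaved off rapidly. The procedure is
#' fully deterministic.
#'
#' @param scores numeric matrix with >= 3 columns (PC1-PC3 are used).
#' @param angleStep grid resolution in degrees (0 < angleStep <= 90).
#' @param gapFactor,minGapPoints see [axisGapSplit()].
#' @param maxGroups recursion cap on the number of groups per invocation.
#' @return integer vector of group labels `1..m` (m = 1 means no split was
#'   found), in order of first appearance.
#' @export
rubikSplit <- function(scores, angleStep = 10, gapFactor = 3,
                       minGapPoints = 1L, maxGroups = 5L) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 3L) .argError("rubikSplit needs at least 3 score columns")
  if (!all(is.finite(scores[, 1:3]))) .valueError("scores must be finite")
  if (angleStep <= 0 || angleStep > 90) .argError("angleStep must be in (0, 90]")
  pts <- scores[, 1:3, drop = FALSE]
  n <- nrow(pts)
  labels <- rep(1L, n)
  if (n < 3L) return(labels)
  angles <- seq(0, 90 - angleStep, by = angleStep) * pi / 180
  queue <- list(seq_len(n))
  nGroups <- 1L
  done <- list()
  while (length(queue) && nGroups < maxGroups) {
    idx <- queue[[1L]]
    queue <- queue[-1L]
    cut <- if (length(idx) >= 2L) {
      .rubikFindCut(pts[idx, , drop = FALSE], angles, gapFactor, minGapPoints)
    } else NULL
    if (is.null(cut)) {
      done[[length(done) + 1L]] <- idx
    } else {
      queue <- c(queue, list(idx[cut], idx[!cut]))
      nGroups <- nGroups + 1L
    }
  }
  done <- c(done, queue)
  for (g in seq_along(done)) labels[done[[g]]] <- g
  # relabel in order of first appearance for determinism
  first <- order(vapply(done, min, 1L))
  relab <- integer(length(done))
  relab[first] <- seq_along(done)
  relab[labels]
}

# scan rotations; return logical side vector for the first successful cut
.rubikFindCut <- function(pts, angles, gapFactor, minGapPoints) {
  for (a1 in angles) {
    R1 <- .rotMat3(1L, a1)
    for (a2 in angles) {
      R21 <- .rotMat3(2L, a2) %*% R1
      for (a3 in angles) {
        R <- .rotMat3(3L, a3) %*% R21
        rot <- pts %*% t(R)
        for (ax in 1:3) {
          thr <- axisGapSplit(rot[, ax], gapFactor, minGapPoints)
          if (!is.null(thr)) return(rot[, ax] <= thr)
        }
      }
    }
  }
  NULL
}
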