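#' @include transforms.R
NULL

#' Rigid best-fit alignment (point-to-plane ICP)
#'
#' Aligns a moving mesh to a reference by iterative closest point with
#' point-to-plane error, restricted to an operator-selected stable region of
#' the moving mesh (areas unaffected by bonding/debonding). Correspondences
#' farther than 3x the median distance are rejected each iteration, which
#' makes the fit robust to moderate unmasked deviations. Iteration stops
#' when the point-to-plane RMS improves by less than \code{tol} or after
#' \code{maxIter} iterations; the RMS never increases across accepted
#' iterations (a worsening step is discarded and iteration stops).
#'
#' The expected use is scan sessions sharing a common rack frame, i.e.
#' initial misalignment below about 1 mm / 5 degrees.
#'
#' @param moving,reference \linkS4class{TriangleMesh} objects.
#' @param mask stable-region selector on the moving mesh: an integer vector
#'   of vertex indices, a list \code{list(center = c(x, y, z),
#'   minDistance = r)} selecting all vertices farther than \code{r} mm from
#'   \code{center}, or NULL for all vertices.
#' @param tol convergence tolerance on the RMS improvement (mm),
#'   default 1e-6.
#' @param maxIter maximum ICP iterations, default 50.
#' @param searchRadius correspondence search radius (mm), default 0.5; it
#'   is temporarily enlarged when an iteration finds no matches.
#' @param maxPoints masked vertices are subsampled (deterministic stride) to
#'   at most this many for speed, default 3000.
#' @return A \linkS4class{RigidTransform} with attributes \code{rms}
#'   (point-to-plane RMS after alignment, mm), \code{iterations}, and
#'   \code{converged}. A final RMS above 0.2 mm triggers a divergence
#'   warning (likely wrong tooth pairing).
#' @export
bestFitAlign <- function(moving, reference, mask = NULL, tol = 1e-6,
                         maxIter = 50L, searchRadius = 0.5,
                         maxPoints = 3000L) {
  pts <- moving@vertices
  idx <- .resolveMask(mask, pts)
  if (length(idx) < 100L)
    stop("mask error: stable region selects ", length(idx),
         " vertices; at least 100 are required for a 6-DOF fit")
  if (length(idx) > maxPoints)
    idx <- idx[seq(1L, length(idx), length.out = maxPoints)]
  P <- pts[idx, , drop = FALSE]
  V <- reference@vertices
  F <- reference@faces - 1L
  # smoothed per-face normals (mean of vertex normals): facet normals of a
  # noisy scan are too noisy for stable point-to-plane residuals
  vn <- .vertexNormals(reference)
  fn <- (vn[reference@faces[, 1], , drop = FALSE] +
           vn[reference@faces[, 2], , drop = FALSE] +
           vn[reference@faces[, 3], , drop = FALSE])
  fn <- fn / sqrt(rowSums(fn^2))
  cur <- identityTransform()
  rms_prev <- Inf
  rms_hist <- numeric(0)
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    Q <- applyTransform(P, cur)
    cl <- cpp_closest_points(Q, V, F, searchRadius)
    ok <- !is.na(cl$distance)
    if (!any(ok)) {
      cl <- cpp_closest_points(Q, V, F, searchRadius * 4)
      ok <- !is.na(cl$distance)
      if (!any(ok))
        stop("divergence: no correspondences within ", searchRadius * 4,
             " mm; surfaces appear disjoint")
    }
    d <- cl$distance[ok]
    keep_rel <- d <= 3 * stats::median(d) + 1e-12
    sel <- which(ok)[keep_rel]
    q <- Q[sel, , drop = FALSE]
    cp <- cl$points[sel, , drop = FALSE]
    n <- fn[cl$face[sel], , drop = FALSE]
    e <- rowSums((q - cp) * n)  # point-to-plane residuals
    rms <- sqrt(mean(e^2))
    if (rms_prev - rms < tol && it > 1L) {
      converged <- TRUE
      if (rms > rms_prev) rms <- rms_prev  # discard worsening step
      break
    }
    rms_prev <- rms
    rms_hist <- c(rms_hist, rms)
    iters <- it
    # linearized point-to-plane solve: unknowns (w, t), residual
    # n . (q + w x q + t - cp)
    A <- cbind(q[, 2] * n[, 3] - q[, 3] * n[, 2],
               q[, 3] * n[, 1] - q[, 1] * n[, 3],
               q[, 1] * n[, 2] - q[, 2] * n[, 1],
               n)
    rhs <- -e
    x <- tryCatch(solve(crossprod(A), crossprod(A, rhs)),
                  error = function(err)
                    stop("divergence: singular point-to-plane system ",
                         "(degenerate stable region)"))
    delta <- rigidTransform(rotationFromVector(x[1:3]), x[4:6])
    cur <- composeTransforms(delta, cur)
  }
  if (rms_prev > 0.2)
    warning(sprintf(
      "divergence warning: post-alignment RMS %.3f mm exceeds 0.2 mm (wrong tooth pairing?)",
      rms_prev))
  structure(cur, rms = min(rms_prev, rms), iterations = iters,
            converged = converged, rmsHistory = rms_hist)
}

.resolveMask <- function(mask, pts) {
  if (is.null(mask)) return(seq_len(nrow(pts)))
  if (is.numeric(mask)) {
    idx <- as.integer(mask)
    if (any(idx < 1L | idx > nrow(pts)))
      stop("mask error: vertex indices out of range")
    return(idx)
  }
  if (is.list(mask) && !is.null(mask$center)) {
    d2 <- rowSums(sweep(pts, 2, as.numeric(mask$center))^2)
    return(which(d2 > as.numeric(mask$minDistance)^2))
  }
  stop("mask error: unsupported mask specification")
}

#' Read a stable-region mask file
#'
#' Supports the two interchange mask formats: a plain text file of
#' newline-separated 0-based vertex indices, or a JSON geometric predicate
#' \code{\{"center": [x, y, z], "min_distance_mm": r\}}.
#'
#' @param path mask file path.
#' @return A mask usable by \code{\link{bestFitAlign}} (1-based indices or
#'   a predicate list).
#' @export
readMaskFile <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::fromJSON(path)
    return(list(center = as.numeric(spec$center),
                minDistance = as.numeric(spec$min_distance_mm)))
  }
  idx <- scan(path, what = integer(), quiet = TRUE)
  idx + 1L  # file is 0-based
}

#' Signed deviation map between aligned surfaces
#'
#' For every vertex of the test mesh, the signed distance (mm) to the
#' reference surface: positive when the test point lies outside the
#' reference along the reference's outward normal (material above, e.g.
#' adhesive), negative below (material loss). Vertices with no reference
#' surface within \code{searchRadius} are flagged unmatched and excluded
#' from summaries.
#'
#' @param test,reference \linkS4class{TriangleMesh} objects in a common
#'   frame.
#' @param searchRadius correspondence search radius (mm), default 0.5.
#' @return A \linkS4class{DeviationMap}.
#' @export
signedDeviation <- function(test, reference, searchRadius = 0.5) {
  Q <- test@vertices
  cl <- cpp_closest_points(Q, reference@vertices, reference@faces - 1L,
                           searchRadius)
  matched <- !is.na(cl$distance)
  if (!any(matched))
    stop("disjoint surfaces: no test vertex finds the reference within ",
         searchRadius, " mm")
  sgn <- sign(rowSums((Q - cl$points) * cl$normals))
  sgn[sgn == 0] <- 1
  dist <- cl$distance * sgn
  new("DeviationMap", points = Q, distance = dist, matched = matched,
      refNormals = cl$normals, searchRadius = searchRadius)
}

#' Summary statistics of a deviation map
#'
#' @param devmap a \linkS4class{DeviationMap}.
#' @return A list with \code{rms}, \code{max}, \code{min}, \code{nMatched}.
#' @export
deviationSummary <- function(devmap) {
  d <- devmap@distance[devmap@matched]
  list(rms = sqrt(mean(d^2)), max = max(d), min = min(d),
       nMatched = length(d))
}
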