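#' @include registration.R
NULL

#' Construct an ROIBox
#'
#' @param center ROI center in the tooth frame (mm).
#' @param side side length (mm), default 5.
#' @param frame 3 x 3 orthonormal matrix (columns = local axes); +z is the
#'   outward viewing direction.
#' @param bottomZ,topZ vertical extent in the local frame (mm).
#' @param id provenance tag; autogenerated when empty.
#' @return An \linkS4class{ROIBox}.
#' @export
roiBox <- function(center, side = 5, frame = diag(3), bottomZ = -5,
                   topZ = 5, id = "") {
  if (!nzchar(id))
    id <- sprintf("roi(%.6f,%.6f,%.6f|%g)", center[1], center[2],
                  center[3], side)
  new("ROIBox", center = as.numeric(center), side = side, frame = frame,
      bottomZ = bottomZ, topZ = topZ, id = id)
}

#' Position the analysis ROI over the bonding zone
#'
#' Automates the ad-hoc square placement: the ROI center is the
#' deviation-weighted centroid of deviation-map vertices exceeding the
#' clearance (the adhesive signal of T1 vs T0); the local +z axis is the
#' mean outward reference normal of the patch under the square; the
#' vertical extent encloses the observed surface with a margin. A manual
#' override is echoed exactly.
#'
#' @param devmap \linkS4class{DeviationMap} of T1 against the T0 reference.
#' @param side ROI side length (mm), default 5.
#' @param clearance deviation threshold for the adhesive signal (mm),
#'   default 0.020.
#' @param margin vertical margin beyond the observed surface (mm),
#'   default 0.5.
#' @param override optional list with \code{center} (and optionally
#'   \code{frame}, \code{side}, \code{bottomZ}, \code{topZ}) taking
#'   precedence over automatic placement.
#' @return An \linkS4class{ROIBox}.
#' @export
placeROI <- function(devmap, side = 5, clearance = 0.020, margin = 0.5,
                     override = NULL) {
  if (!is.null(override)) {
    return(roiBox(center = override$center,
                  side = override$side %||% side,
                  frame = override$frame %||% diag(3),
                  bottomZ = override$bottomZ %||% -5,
                  topZ = override$topZ %||% 5))
  }
  ok <- devmap@matched & !is.na(devmap@distance) &
    devmap@distance > clearance
  if (!any(ok))
    stop("placement error: no deviation exceeds the clearance (",
         clearance, " mm); no adhesive detected and no override supplied")
  w <- devmap@distance[ok]
  pts <- devmap@points[ok, , drop = FALSE]
  center <- colSums(pts * w) / sum(w)
  # patch under the square: matched points within the covering disc
  all_pts <- devmap@points[devmap@matched, , drop = FALSE]
  all_nrm <- devmap@refNormals[devmap@matched, , drop = FALSE]
  d2 <- rowSums(sweep(all_pts, 2, center)^2)
  under <- d2 <= (side / sqrt(2))^2
  if (!any(under)) under <- rep(TRUE, nrow(all_pts))
  zax <- colMeans(all_nrm[under, , drop = FALSE])
  zax <- zax / sqrt(sum(zax^2))
  xax <- c(1, 0, 0)
  xax <- xax - sum(xax * zax) * zax
  if (sqrt(sum(xax^2)) < 1e-6) {
    xax <- c(0, 1, 0)
    xax <- xax - sum(xax * zax) * zax
  }
  xax <- xax / sqrt(sum(xax^2))
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],  # z cross x
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  frame <- cbind(xax, yax, zax)
  colnames(frame) <- NULL
  zloc <- as.vector(sweep(all_pts[under, , drop = FALSE], 2, center) %*%
                      frame[, 3])
  roiBox(center = center, side = side, frame = frame,
         bottomZ = min(zloc) - margin, topZ = max(zloc) + margin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tooth frame -> ROI-local coordinates
.toROIFrame <- function(pts, roi)
  sweep(pts, 2, roi@center) %*% roi@frame

#' Clip a mesh to the lateral faces of the ROI prism
#'
#' The four lateral faces of the ROI prism act as cutting planes: the
#' result is exactly the surface inside the side x side prism, with
#' triangles crossing a face split at the plane (new boundary vertices lie
#' on the planes to within 1e-9 mm). The returned patch is expressed in the
#' ROI-local frame (origin at the ROI center, +z outward).
#'
#' @param mesh a \linkS4class{TriangleMesh} in the tooth frame.
#' @param roi an \linkS4class{ROIBox}.
#' @return An open surface patch (\linkS4class{TriangleMesh}) in ROI-local
#'   coordinates.
#' @export
clipToROI <- function(mesh, roi) {
  v <- .toROIFrame(mesh@vertices, roi)
  f <- mesh@faces
  s2 <- roi@side / 2
  # half-spaces a . (x, y) <= s2
  planes <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (pl in planes) {
    res <- .clipHalfspace(v, f, pl, s2)
    v <- res$v
    f <- res$f
    if (nrow(f) == 0L)
      stop("clip error: mesh '", mesh@provenance,
           "' does not intersect the ROI prism")
  }
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  f[] <- remap[f]
  new("TriangleMesh", vertices = v[used, , drop = FALSE], faces = f,
      provenance = mesh@provenance)
}

# Sutherland-Hodgman clip of a triangle list against a.(x,y) <= c.
# Edge-intersection vertices are cached per undirected edge so adjacent
# triangles share them exactly (keeps the patch topological without a
# merge pass).
.clipHalfspace <- function(v, f, a, cval) {
  d <- v[, 1] * a[1] + v[, 2] * a[2] - cval
  inside <- d <= 1e-12
  nin <- inside[f[, 1]] + inside[f[, 2]] + inside[f[, 3]]
  keep <- f[nin == 3L, , drop = FALSE]
  crossing <- f[nin == 1L | nin == 2L, , drop = FALSE]
  if (nrow(crossing) == 0L)
    return(list(v = v, f = keep))
  newv <- list()
  cache <- new.env(hash = TRUE, parent = emptyenv())
  nv <- nrow(v)
  edge_point <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    # interpolate deterministically from the lower index endpoint
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    nv <<- nv + 1L
    newv[[length(newv) + 1L]] <<- p
    cache[[key]] <- nv
    nv
  }
  outf <- vector("list", nrow(crossing))
  for (k in seq_len(nrow(crossing))) {
    tri <- crossing[k, ]
    poly <- integer(0)
    for (e in 1:3) {
      i <- tri[e]
      j <- tri[if (e == 3L) 1L else e + 1L]
      if (inside[i]) poly <- c(poly, i)
      if (inside[i] != inside[j]) poly <- c(poly, edge_point(i, j))
    }
    if (length(poly) >= 3L) {
      fans <- cbind(poly[1L], poly[2:(length(poly) - 1L)],
                    poly[3:length(poly)])
      outf[[k]] <- fans
    }
  }
  v2 <- rbind(v, do.call(rbind, newv))
  list(v = v2, f = rbind(keep, do.call(rbind, outf)))
}

#' Close a clipped patch into a watertight shell
#'
#' Builds the closed shell of the analysis area: the clipped surface patch
#' is the top, its boundary is extruded down to the ROI bottom plane to
#' form the side walls, and a flat square at \code{bottomZ} closes the
#' solid. Requires the patch boundary to lie on the ROI lateral faces and
#' the patch to be a height field over the ROI square (no fold-over).
#'
#' @param patch clipped surface patch in ROI-local coordinates (from
#'   \code{\link{clipToROI}}).
#' @param roi the \linkS4class{ROIBox} the patch was clipped with.
#' @return A \linkS4class{ClosedShell} (outward-oriented, volume cached).
#' @export
#' @examples
#' # a flat plate at z = 0.5 over a 5 mm ROI closes to a 12.5 mm^3 prism
closeShell <- function(patch, roi) {
  v <- patch@vertices
  f <- patch@faces
  # orientation up
  a <- v[f[, 1], , drop = FALSE]
  nrmz <- (v[f[, 2], 1] - a[, 1]) * (v[f[, 3], 2] - a[, 2]) -
    (v[f[, 2], 2] - a[, 2]) * (v[f[, 3], 1] - a[, 1])
  if (mean(nrmz) < 0) {
    f <- f[, c(1L, 3L, 2L), drop = FALSE]
    nrmz <- -nrmz
  }
  if (any(nrmz < -1e-9 * pmax(1, abs(nrmz))) && min(nrmz) < -1e-9)
    stop("geometry error: patch is not a height field over the ROI ",
         "square (fold-over detected)")
  # directed boundary edges (appear once)
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to <- c(f[, 2], f[, 3], f[, 1])
  ukey <- paste(pmin(he_from, he_to), pmax(he_from, he_to))
  cnt <- table(ukey)
  bnd <- cnt[ukey] == 1L
  bf <- he_from[bnd]
  bt <- he_to[bnd]
  if (length(bf) == 0L)
    stop("geometry error: patch has no boundary (already closed?)")
  s2 <- roi@side / 2
  bverts <- unique(c(bf, bt))
  onplane <- abs(abs(v[bverts, 1]) - s2) < 1e-6 |
    abs(abs(v[bverts, 2]) - s2) < 1e-6
  if (!all(onplane))
    stop("geometry error: ", sum(!onplane),
         " patch boundary vertices do not lie on the ROI lateral faces")
  # walk the single boundary loop
  nxt <- integer(max(bf, bt))
  if (anyDuplicated(bf))
    stop("geometry error: non-manifold patch boundary")
  nxt[bf] <- bt
  loop <- integer(length(bf))
  loop[1L] <- bf[1L]
  for (k in 2:length(bf)) {
    loop[k] <- nxt[loop[k - 1L]]
    if (loop[k] == 0L)
      stop("geometry error: open boundary chain (patch not watertight ",
           "along the clip planes)")
  }
  if (nxt[loop[length(loop)]] != loop[1L] ||
      length(unique(loop)) != length(loop))
    stop("geometry error: patch boundary is not a single closed loop")
  bz <- roi@bottomZ
  if (min(v[, 3]) < bz - 1e-9)
    stop("geometry error: patch dips below the ROI bottom plane")
  nv <- nrow(v)
  ring <- cbind(v[loop, 1], v[loop, 2], bz)
  centroid <- c(mean(ring[, 1]), mean(ring[, 2]), bz)
  v2 <- rbind(v, ring, centroid)
  ridx <- nv + seq_along(loop)
  cidx <- nv + length(loop) + 1L
  nxt_i <- c(seq_along(loop)[-1L], 1L)
  # walls: boundary edge a->b with bottom copies a', b'
  walls <- rbind(cbind(loop, ridx, ridx[nxt_i]),
                 cbind(loop, ridx[nxt_i], loop[nxt_i]))
  bottom <- cbind(cidx, ridx[nxt_i], ridx)
  mesh <- new("TriangleMesh", vertices = v2,
              faces = rbind(f, walls, bottom),
              provenance = patch@provenance)
  closedShell(mesh, roiId = roi@id)
}
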