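#' @include roi.R
NULL

#' Construct a VolumetryConfig
#'
#' @param clearance deviation tolerance absorbed by the Boolean difference
#'   (mm), default 0.020 — the scanner's maximum measuring error.
#' @param clearanceMode \code{"offset"} (default; only the excess of
#'   material beyond the clearance is counted) or \code{"threshold"} (full
#'   deviation counted wherever it exceeds the clearance).
#' @param integrationStep lateral grid step of the height-field integrator
#'   (mm), default 0.010.
#' @param oracleStep voxel size of the independent voxel-counting oracle
#'   (mm), default 0.005.
#' @return A \linkS4class{VolumetryConfig}.
#' @export
volumetryConfig <- function(clearance = 0.020,
                            clearanceMode = c("offset", "threshold"),
                            integrationStep = 0.010, oracleStep = 0.005) {
  new("VolumetryConfig", clearance = clearance,
      clearanceMode = match.arg(clearanceMode),
      integrationStep = integrationStep, oracleStep = oracleStep)
}

# common grid of two ROI shells; errors when they do not share the ROI
.sharedGrid <- function(a, b, step) {
  if (!identical(a@roiId, b@roiId) || !nzchar(a@roiId))
    stop("contract error: shells were not built from the same ROIBox (",
         "'", a@roiId, "' vs '", b@roiId, "')")
  va <- a@mesh@vertices
  vb <- b@mesh@vertices
  bba <- c(min(va[, 1]), max(va[, 1]), min(va[, 2]), max(va[, 2]))
  bbb <- c(min(vb[, 1]), max(vb[, 1]), min(vb[, 2]), max(vb[, 2]))
  if (max(abs(bba - bbb)) > 1e-6)
    stop("contract error: shell footprints differ")
  nx <- max(1L, as.integer(round((bba[2] - bba[1]) / step)))
  ny <- max(1L, as.integer(round((bba[4] - bba[3]) / step)))
  list(ox = bba[1], oy = bba[3], nx = nx, ny = ny, step = step,
       zmin = min(va[, 3], vb[, 3]), zmax = max(va[, 3], vb[, 3]))
}

#' Clearance-aware Boolean difference volume
#'
#' Volume (mm^3) of the region inside shell \code{a} but outside shell
#' \code{b}, discounted by the clearance according to the configured mode.
#' Both shells must originate from the same \linkS4class{ROIBox} (shared
#' bottom and side surfaces), so the difference reduces to a height-field
#' integral over the ROI square: heights are sampled by vertical ray
#' casting at cell centers on a regular grid (half-open ROI interval per
#' axis) and the positive part of \eqn{h_a - h_b - clearance} (offset mode)
#' or the full \eqn{h_a - h_b} where it exceeds the clearance (threshold
#' mode) is integrated.
#'
#' @param a,b \linkS4class{ClosedShell} objects built from the same ROI.
#' @param cfg a \linkS4class{VolumetryConfig}.
#' @return Volume in mm^3 (>= 0).
#' @seealso \code{\link{voxelOracleVolume}} for the independent
#'   voxel-counting cross-check.
#' @export
booleanDifferenceVolume <- function(a, b, cfg = volumetryConfig()) {
  g <- .sharedGrid(a, b, cfg@integrationStep)
  Ha <- cpp_raster_heights(a@mesh@vertices, a@mesh@faces - 1L,
                           g$ox, g$oy, g$step, g$nx, g$ny)
  Hb <- cpp_raster_heights(b@mesh@vertices, b@mesh@faces - 1L,
                           g$ox, g$oy, g$step, g$nx, g$ny)
  d <- Ha - Hb
  d[is.na(d)] <- 0
  if (cfg@clearanceMode == "offset") {
    excess <- pmax(d - cfg@clearance, 0)
  } else {
    excess <- d * (d > cfg@clearance)
  }
  sum(excess) * g$step^2
}

#' Voxel-counting oracle for the Boolean difference
#'
#' Independent cross-check of \code{\link{booleanDifferenceVolume}}: both
#' shells are rasterized into voxel columns at \code{oracleStep} (default
#' 5 um) and voxel centers inside \code{a} but not inside \code{b} (dilated
#' upward by the clearance in offset mode) are counted. In threshold mode a
#' column's voxels count only when the column's difference thickness
#' exceeds the clearance.
#'
#' @inheritParams booleanDifferenceVolume
#' @return Volume in mm^3.
#' @export
voxelOracleVolume <- function(a, b, cfg = volumetryConfig()) {
  g <- .sharedGrid(a, b, cfg@oracleStep)
  zstep <- cfg@oracleStep
  zmin <- g$zmin - zstep
  nz <- as.integer(ceiling((g$zmax + cfg@clearance - zmin) / zstep)) + 2L
  cpp_voxel_diff_volume(a@mesh@vertices, a@mesh@faces - 1L,
                        b@mesh@vertices, b@mesh@faces - 1L,
                        g$ox, g$oy, g$step, g$nx, g$ny,
                        zmin, zstep, nz, cfg@clearance,
                        if (cfg@clearanceMode == "offset") 0L else 1L)
}

#' Per-tooth volume report
#'
#' The three clearance-aware Boolean differences of one registered scan
#' triplet inside its ROI: adhesive volume AV = vol(T1 minus T0), residual
#' adhesive volume RAV = vol(T2 minus T0), enamel volume loss
#' EVL = vol(T0 minus T2), and the relative residual adhesive fraction
#' dAV = RAV / AV (NA, flagged undefined, when AV is below 1e-6 mm^3).
#'
#' @param triplet a \linkS4class{ScanTriplet} with T1/T2 already best-fit
#'   aligned to T0 (see \code{\link{alignTriplet}}).
#' @param roi the \linkS4class{ROIBox} (see \code{\link{placeROI}}). Its
#'   bottom plane is lowered automatically if a clipped surface dips below
#'   it; volume differences are insensitive to the bottom plane.
#' @param cfg a \linkS4class{VolumetryConfig}.
#' @param alignmentRMS optional per-tooth registration RMS to carry into
#'   the report row.
#' @return A one-row data.frame with columns \code{tooth_id}, \code{group},
#'   \code{AV_mm3}, \code{RAV_mm3}, \code{dAV}, \code{EVL_mm3},
#'   \code{clearance_mm}, \code{clearance_mode}, \code{alignment_RMS_mm}.
#' @export
computeVolumeReport <- function(triplet, roi, cfg = volumetryConfig(),
                                alignmentRMS = NA_real_) {
  res <- tryCatch({
    p0 <- clipToROI(triplet@t0, roi)
    p1 <- clipToROI(triplet@t1, roi)
    p2 <- clipToROI(triplet@t2, roi)
    zmin <- min(p0@vertices[, 3], p1@vertices[, 3], p2@vertices[, 3])
    if (zmin - 0.5 < roi@bottomZ) roi@bottomZ <- zmin - 0.5
    s0 <- closeShell(p0, roi)
    s1 <- closeShell(p1, roi)
    s2 <- closeShell(p2, roi)
    av <- booleanDifferenceVolume(s1, s0, cfg)
    rav <- booleanDifferenceVolume(s2, s0, cfg)
    evl <- booleanDifferenceVolume(s0, s2, cfg)
    list(av = av, rav = rav, evl = evl)
  }, error = function(e)
    stop("tooth '", triplet@toothId, "': ", conditionMessage(e),
         call. = FALSE))
  dav <- if (res$av > 1e-6) res$rav / res$av else NA_real_
  data.frame(tooth_id = triplet@toothId, group = triplet@group,
             AV_mm3 = res$av, RAV_mm3 = res$rav, dAV = dav,
             EVL_mm3 = res$evl, clearance_mm = cfg@clearance,
             clearance_mode = cfg@clearanceMode,
             alignment_RMS_mm = alignmentRMS,
             stringsAsFactors = FALSE)
}

#' Register a scan triplet to its T0 baseline
#'
#' Aligns T1 and T2 to T0 by best-fit ICP over the stable region. When no
#' explicit mask is given, a two-pass scheme reproduces the manual
#' selection of unaffected areas: a first robust full-surface fit (the 3x
#' median correspondence rejection suppresses the adhesive zone), then a
#' deviation map locates the bonded zone and the fit is repeated using only
#' vertices farther than \code{excludeRadius} from its deviation-weighted
#' centroid.
#'
#' @param triplet a \linkS4class{ScanTriplet} (T1/T2 in approximately the
#'   T0 frame, e.g. scan sessions sharing a rack).
#' @param mask optional explicit stable-region mask (see
#'   \code{\link{bestFitAlign}}) applied to both T1 and T2.
#' @param excludeRadius auto-mask exclusion radius around the bonded zone
#'   (mm), default 1.
#' @param clearance deviation threshold locating the bonded zone (mm),
#'   default 0.020.
#' @param ... passed to \code{\link{bestFitAlign}}.
#' @return The triplet with T1/T2 replaced by their aligned versions, with
#'   attributes \code{rmsT1}, \code{rmsT2} (post-alignment RMS, mm).
#' @export
alignTriplet <- function(triplet, mask = NULL, excludeRadius = 1,
                         clearance = 0.020, ...) {
  alignOne <- function(moving) {
    if (!is.null(mask)) {
      tr <- bestFitAlign(moving, triplet@t0, mask = mask, ...)
      return(list(mesh = applyTransform(moving, tr),
                  rms = attr(tr, "rms"), transform = tr))
    }
    tr1 <- bestFitAlign(moving, triplet@t0, mask = NULL, ...)
    m1 <- applyTransform(moving, tr1)
    dev <- signedDeviation(m1, triplet@t0)
    hot <- dev@matched & !is.na(dev@distance) &
      abs(dev@distance) > clearance
    if (any(hot)) {
      w <- abs(dev@distance[hot])
      ctr <- colSums(dev@points[hot, , drop = FALSE] * w) / sum(w)
      automask <- list(center = ctr, minDistance = excludeRadius)
      tr2 <- tryCatch(
        bestFitAlign(m1, triplet@t0, mask = automask, ...),
        error = function(e) identityTransform())
      m2 <- applyTransform(m1, tr2)
      return(list(mesh = m2,
                  rms = attr(tr2, "rms") %||% attr(tr1, "rms"),
                  transform = composeTransforms(tr2, tr1)))
    }
    list(mesh = m1, rms = attr(tr1, "rms"), transform = tr1)
  }
  a1 <- alignOne(triplet@t1)
  a2 <- alignOne(triplet@t2)
  triplet@t1 <- a1$mesh
  triplet@t2 <- a2$mesh
  attr(triplet, "rmsT1") <- a1$rms
  attr(triplet, "rmsT2") <- a2$rms
  attr(triplet, "transformT1") <- a1$transform
  attr(triplet, "transformT2") <- a2$transform
  triplet
}
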