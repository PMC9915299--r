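#' @include AllGenerics.R
NULL

#' Triangulated surface mesh
#'
#' The atomic geometric object of the package: a triangulated surface in mm
#' units. Vertices are an n x 3 numeric matrix; faces an m x 3 integer matrix
#' of 1-based vertex indices with consistent winding (outward normals for
#' closed surfaces). \code{provenance} is a free-text label, conventionally
#' \code{"<tooth_id>_<T0|T1|T2>"}.
#'
#' Use \code{\link{triangleMesh}} to construct (it validates, merges
#' duplicate vertices and drops degenerate faces), and
#' \code{\link{readSTL}}/\code{\link{writeSTL}} for STL interchange.
#'
#' @slot vertices numeric matrix, n x 3 (mm).
#' @slot faces integer matrix, m x 3, 1-based.
#' @slot provenance character label.
#' @aliases TriangleMesh
#' @export
setClass("TriangleMesh",
         representation(vertices = "matrix", faces = "matrix",
                        provenance = "character"),
         prototype(provenance = ""))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  if (ncol(v) != 3L) return("vertices must be an n x 3 matrix")
  if (ncol(f) != 3L) return("faces must be an m x 3 matrix")
  if (!all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v))
      return("face indices must reference existing vertices")
  }
  TRUE
})

#' Watertight closed shell
#'
#' A \linkS4class{TriangleMesh} known to be watertight (every edge shared by
#' exactly two faces) and outward-oriented, with its enclosed volume (mm^3,
#' computed by the divergence theorem) cached. Built with
#' \code{\link{closeShell}} (extrusion of a clipped surface patch to the ROI
#' bottom plane) or \code{\link{closedShell}} from any watertight mesh.
#'
#' @slot mesh the underlying \linkS4class{TriangleMesh}.
#' @slot isWatertight logical flag (always TRUE for a valid object).
#' @slot enclosedVolume cached volume in mm^3, >= 0.
#' @slot roiId provenance tag of the \linkS4class{ROIBox} the shell was
#'   built from (empty when not ROI-derived); Boolean volumetry requires
#'   both operands to share it.
#' @aliases ClosedShell
#' @export
setClass("ClosedShell",
         representation(mesh = "TriangleMesh", isWatertight = "logical",
                        enclosedVolume = "numeric", roiId = "character"),
         prototype(roiId = ""))

setValidity("ClosedShell", function(object) {
  if (!isTRUE(object@isWatertight)) return("shell is not watertight")
  if (length(object@enclosedVolume) != 1L || object@enclosedVolume < 0)
    return("enclosedVolume must be a single non-negative number")
  TRUE
})

#' Rigid roto-translation
#'
#' A proper rigid motion \eqn{x' = R x + t} with \eqn{R} orthonormal,
#' \eqn{det(R) = +1} (checked to 1e-9) and translation in mm. Construct with
#' \code{\link{rigidTransform}}; compose with \code{\link{composeTransforms}};
#' invert with \code{\link{invertTransform}}.
#'
#' @slot rotation 3 x 3 rotation matrix.
#' @slot translation length-3 numeric (mm).
#' @aliases RigidTransform
#' @export
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (length(object@translation) != 3L)
    return("translation must have length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation is not orthonormal (tolerance 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper (det = +1)")
  TRUE
})

#' Scan triplet for one tooth
#'
#' The three surface scans of one tooth: \code{t0} (intact baseline),
#' \code{t1} (post-debond, adhesive present), \code{t2} (post-clean-up),
#' plus tooth identity and treatment group (1, 2 or 3). Before registration
#' the meshes may differ by a small rigid motion; \code{\link{alignTriplet}}
#' brings T1/T2 into the T0 frame.
#'
#' @slot toothId character identifier.
#' @slot group integer treatment group label.
#' @slot t0,t1,t2 \linkS4class{TriangleMesh} objects.
#' @aliases ScanTriplet
#' @export
setClass("ScanTriplet",
         representation(toothId = "character", group = "integer",
                        t0 = "TriangleMesh", t1 = "TriangleMesh",
                        t2 = "TriangleMesh"))

setValidity("ScanTriplet", function(object) {
  if (length(object@toothId) != 1L) return("toothId must be a single string")
  if (length(object@group) != 1L || is.na(object@group))
    return("group must be a single integer")
  TRUE
})

#' Signed surface deviation map
#'
#' Per-vertex signed distances (mm) from a test surface to a reference
#' surface: positive when the test point lies outside the reference along
#' the reference's outward normal (material above the reference, e.g.
#' adhesive), negative below (material loss). Vertices with no reference
#' surface within the search radius are flagged unmatched and excluded from
#' the summaries. Produced by \code{\link{signedDeviation}}.
#'
#' @slot points n x 3 matrix of test vertex coordinates.
#' @slot distance signed distances (mm), NA where unmatched.
#' @slot matched logical vector.
#' @slot refNormals n x 3 outward normals of the matched reference faces.
#' @slot searchRadius the correspondence search radius used (mm).
#' @aliases DeviationMap
#' @export
setClass("DeviationMap",
         representation(points = "matrix", distance = "numeric",
                        matched = "logical", refNormals = "matrix",
                        searchRadius = "numeric"))

setValidity("DeviationMap", function(object) {
  n <- nrow(object@points)
  if (length(object@distance) != n || length(object@matched) != n)
    return("distance/matched must match the number of points")
  d <- object@distance[object@matched]
  if (length(d) && any(abs(d) > object@searchRadius + 1e-9))
    return("matched deviations exceed the search radius")
  TRUE
})

#' Region-of-interest box
#'
#' The square analysis region ("5 mm cube") positioned over the bonding
#' zone: a local orthonormal frame whose +z axis is the outward viewing
#' direction (top view), a center, a side length, and the vertical extent
#' [bottomZ, topZ] in the local frame enclosing all three surfaces. Lateral
#' faces of the prism are the cutting planes for \code{\link{clipToROI}};
#' bottomZ is the closing plane for \code{\link{closeShell}}.
#'
#' @slot center length-3 numeric, ROI center in the tooth frame (mm).
#' @slot side side length (mm), default 5.
#' @slot frame 3 x 3 orthonormal matrix; columns are the local x, y, z axes
#'   expressed in the tooth frame.
#' @slot bottomZ,topZ vertical extent in the local frame (mm).
#' @slot id provenance tag used to guard Boolean volumetry contracts.
#' @aliases ROIBox
#' @export
setClass("ROIBox",
         representation(center = "numeric", side = "numeric",
                        frame = "matrix", bottomZ = "numeric",
                        topZ = "numeric", id = "character"))

setValidity("ROIBox", function(object) {
  if (length(object@center) != 3L) return("center must have length 3")
  if (object@side <= 0) return("side must be positive")
  if (max(abs(crossprod(object@frame) - diag(3))) > 1e-6)
    return("frame must be orthonormal")
  if (object@bottomZ >= object@topZ) return("bottomZ must be below topZ")
  TRUE
})

#' Volumetry configuration
#'
#' Parameters of the clearance-aware Boolean difference volumetry.
#' \code{clearance} (mm, default 0.020) absorbs the scanner's maximum
#' measuring error; \code{clearanceMode} selects its semantics:
#' \code{"offset"} (default) offsets the reference surface by +clearance so
#' only the excess of material beyond the clearance is counted;
#' \code{"threshold"} counts the full deviation wherever it exceeds the
#' clearance. \code{integrationStep} is the lateral grid step of the
#' height-field integrator; \code{oracleStep} the (finer) voxel size of the
#' independent voxel-counting oracle.
#'
#' @slot clearance mm, >= 0.
#' @slot clearanceMode "offset" or "threshold".
#' @slot integrationStep mm, default 0.010.
#' @slot oracleStep mm, default 0.005.
#' @aliases VolumetryConfig
#' @export
setClass("VolumetryConfig",
         representation(clearance = "numeric", clearanceMode = "character",
                        integrationStep = "numeric", oracleStep = "numeric"))

setValidity("VolumetryConfig", function(object) {
  if (object@clearance < 0) return("clearance must be >= 0")
  if (!object@clearanceMode %in% c("offset", "threshold"))
    return("clearanceMode must be 'offset' or 'threshold'")
  if (object@integrationStep <= 0 || object@oracleStep <= 0)
    return("integration/oracle steps must be positive")
  TRUE
})

#' One-way ANOVA result
#'
#' @slot F the F statistic (>= 0).
#' @slot dfBetween,dfWithin degrees of freedom (k - 1 and N - k).
#' @slot p upper-tail probability from the F distribution.
#' @aliases AnovaResult
#' @export
setClass("AnovaResult",
         representation(F = "numeric", dfBetween = "integer",
                        dfWithin = "integer", p = "numeric"))

setValidity("AnovaResult", function(object) {
  if (object@F < 0) return("F must be >= 0")
  if (object@p <= 0 || object@p > 1) return("p must be in (0, 1]")
  TRUE
})

#' Tukey HSD result
#'
#' All-pairs post-hoc comparison on the transformed scale: for each group
#' pair the difference of means and the adjusted p-value from the
#' studentized range distribution.
#'
#' @slot pairs data.frame with columns \code{group1}, \code{group2},
#'   \code{difference}, \code{p_adj}.
#' @slot alpha the family-wise level used for flagging.
#' @aliases TukeyResult
#' @export
setClass("TukeyResult",
         representation(pairs = "data.frame", alpha = "numeric"))

# ---- show methods ----

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh '%s': %d vertices, %d faces (mm)\n",
              object@provenance, nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "ClosedShell", function(object) {
  cat(sprintf("ClosedShell '%s': %d faces, enclosed volume %.6f mm^3\n",
              object@mesh@provenance, nrow(object@mesh@faces),
              object@enclosedVolume))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object)
  cat(sprintf(
    "RigidTransform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
    ang * 180 / pi, object@translation[1], object@translation[2],
    object@translation[3]))
})

setMethod("show", "ScanTriplet", function(object) {
  cat(sprintf("ScanTriplet '%s' (group %d): T0 %d / T1 %d / T2 %d vertices\n",
              object@toothId, object@group, nrow(object@t0@vertices),
              nrow(object@t1@vertices), nrow(object@t2@vertices)))
})

setMethod("show", "DeviationMap", function(object) {
  d <- object@distance[object@matched]
  cat(sprintf(
    "DeviationMap: %d/%d matched, RMS %.4f mm, range [%.4f, %.4f] mm\n",
    sum(object@matched), length(object@matched),
    if (length(d)) sqrt(mean(d^2)) else NA_real_,
    if (length(d)) min(d) else NA_real_,
    if (length(d)) max(d) else NA_real_))
})

setMethod("show", "ROIBox", function(object) {
  cat(sprintf(
    "ROIBox '%s': side %.2f mm at (%.3f, %.3f, %.3f), z in [%.3f, %.3f]\n",
    object@id, object@side, object@center[1], object@center[2],
    object@center[3], object@bottomZ, object@topZ))
})

setMethod("show", "VolumetryConfig", function(object) {
  cat(sprintf(
    "VolumetryConfig: clearance %.3f mm (%s), step %.3f mm, oracle %.3f mm\n",
    object@clearance, object@clearanceMode, object@integrationStep,
    object@oracleStep))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("One-way ANOVA: F[%d, %d] = %.3f, p = %.4g\n",
              object@dfBetween, object@dfWithin, object@F, object@p))
})

setMethod("show", "TukeyResult", function(object) {
  cat(sprintf("Tukey HSD (alpha = %.3g):\n", object@alpha))
  print(object@pairs, row.names = FALSE)
})

# ---- accessors ----

#' @rdname mesh-accessors
#' @export
setMethod("vertices", "TriangleMesh", function(x) x@vertices)
#' @rdname mesh-accessors
#' @export
setMethod("faces", "TriangleMesh", function(x) x@faces)
#' @rdname mesh-accessors
#' @export
setMethod("provenance", "TriangleMesh", function(x) x@provenance)
#' @rdname mesh-accessors
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
#' @rdname mesh-accessors
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))
#' @rdname mesh-accessors
#' @export
setMethod("vertices", "ClosedShell", function(x) x@mesh@vertices)
#' @rdname mesh-accessors
#' @export
setMethod("faces", "ClosedShell", function(x) x@mesh@faces)
#' @rdname mesh-accessors
#' @export
setMethod("isWatertight", "ClosedShell", function(object) object@isWatertight)
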