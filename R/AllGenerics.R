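#' @include RcppExports.R
NULL

#' Accessor generics for mesh-based classes
#'
#' Accessors for the geometric data model: \code{vertices} and \code{faces}
#' return the vertex coordinate matrix (n x 3, mm) and the face index matrix
#' (m x 3, 1-based); \code{provenance} the free-text label carried by a mesh;
#' \code{nVertices}/\code{nFaces} the corresponding counts;
#' \code{enclosedVolume} the volume (mm^3) enclosed by a watertight,
#' outward-oriented surface; \code{isWatertight} the cached watertightness
#' flag of a closed shell.
#'
#' @param x an object of a class defined in this package.
#' @param object an object of a class defined in this package.
#' @return See the individual methods.
#' @name mesh-accessors
#' @aliases vertices faces provenance nVertices nFaces enclosedVolume
#'   isWatertight
#' @examples
#' m <- unitCubeMesh()
#' nVertices(m)
#' nFaces(m)
NULL

#' @rdname mesh-accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname mesh-accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname mesh-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname mesh-accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname mesh-accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname mesh-accessors
#' @export
setGeneric("enclosedVolume", function(object) standardGeneric("enclosedVolume"))

#' @rdname mesh-accessors
#' @export
setGeneric("isWatertight", function(object) standardGeneric("isWatertight"))

#' Apply a rigid transform
#'
#' Maps an object (mesh or point matrix) through a rigid roto-translation
#' \eqn{x' = R x + t}. Faces are unchanged; enclosed volumes of closed
#' shells are preserved.
#'
#' @param x a \linkS4class{TriangleMesh} or an n x 3 numeric matrix.
#' @param transform a \linkS4class{RigidTransform}.
#' @return An object of the same class as \code{x}.
#' @export
#' @examples
#' t <- rigidTransform(rotationAboutZ(pi / 8), c(1, 0, 0))
#' applyTransform(unitCubeMesh(), t)
setGeneric("applyTransform",
           function(x, transform) standardGeneric("applyTransform"))
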