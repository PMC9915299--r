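#' @include geometry-io.R
NULL

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation (mm).
#' @return A \linkS4class{RigidTransform}.
#' @export
#' @examples
#' rigidTransform(diag(3), c(1, 2, 3))
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' @rdname rigidTransform
#' @export
identityTransform <- function() rigidTransform()

#' Elementary rotations and axis-angle construction
#'
#' \code{rotationAboutZ} (and x/y) build elementary rotation matrices;
#' \code{rotationFromVector} exponentiates a rotation vector (Rodrigues);
#' \code{rotationAngle} returns the rotation angle (rad) of a transform.
#'
#' @param theta angle in radians.
#' @param w length-3 rotation vector (axis times angle, rad).
#' @param transform a \linkS4class{RigidTransform}.
#' @return A 3 x 3 matrix, or the angle in radians.
#' @name rotations
NULL

#' @rdname rotations
#' @export
rotationAboutZ <- function(theta)
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))

#' @rdname rotations
#' @export
rotationAboutX <- function(theta)
  rbind(c(1, 0, 0),
        c(0, cos(theta), -sin(theta)),
        c(0, sin(theta), cos(theta)))

#' @rdname rotations
#' @export
rotationAboutY <- function(theta)
  rbind(c(cos(theta), 0, sin(theta)),
        c(0, 1, 0),
        c(-sin(theta), 0, cos(theta)))

#' @rdname rotations
#' @export
rotationFromVector <- function(w) {
  theta <- sqrt(sum(w^2))
  if (theta < 1e-300) return(diag(3))
  k <- w / theta
  K <- rbind(c(0, -k[3], k[2]),
             c(k[3], 0, -k[1]),
             c(-k[2], k[1], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' @rdname rotations
#' @export
rotationAngle <- function(transform) {
  tr <- sum(diag(transform@rotation))
  acos(min(1, max(-1, (tr - 1) / 2)))
}

#' Compose and invert rigid transforms
#'
#' \code{composeTransforms(b, a)} returns the transform applying \code{a}
#' first, then \code{b} (function composition b o a).
#'
#' @param a,b,transform \linkS4class{RigidTransform} objects.
#' @return A \linkS4class{RigidTransform}.
#' @export
composeTransforms <- function(b, a) {
  rigidTransform(b@rotation %*% a@rotation,
                 as.vector(b@rotation %*% a@translation) + b@translation)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, as.vector(-Rt %*% transform@translation))
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("matrix", "RigidTransform"),
          function(x, transform) {
            t(transform@rotation %*% t(x)) +
              matrix(transform@translation, nrow(x), 3, byrow = TRUE)
          })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("TriangleMesh", "RigidTransform"),
          function(x, transform) {
            x@vertices <- applyTransform(x@vertices, transform)
            x
          })
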