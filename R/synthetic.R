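#' @include stats.R
NULL

#' Generate a smooth synthetic tooth crown surface
#'
#' Builds the intact buccal-surface emulation used by the synthetic study:
#' a single-valued height field \eqn{z(x, y)} combining a smooth dome
#' (crown curvature) and fine perikymata-like ripples, triangulated on a
#' regular grid at the scanner's point spacing. Deterministic for a given
#' seed (the seed only randomizes the ripple phase).
#'
#' @param extent patch extent in mm (length 2), default \code{c(8, 8)} —
#'   comfortably larger than the 5 mm analysis square.
#' @param domeRadii dome curvature radii (mm) along x and y, default
#'   \code{c(9, 11)} (typical molar crown curvature); \code{Inf} gives a
#'   flat plate.
#' @param rippleAmplitude perikymata ripple amplitude (mm), default 0.005.
#' @param rippleWavelength ripple wavelength (mm), default 0.1.
#' @param undulationAmplitude total amplitude (mm) of the larger-scale
#'   anatomical undulations (cusp slopes, developmental grooves, lobes),
#'   default 0.25. These features are what makes rigid registration
#'   well-posed: a smooth dome alone can slide tangentially under a best
#'   fit.
#' @param undulationWavelengths wavelengths (mm) of the undulation
#'   harmonics, default \code{c(3, 1.5, 0.8)}; per-harmonic amplitudes are
#'   proportional to wavelength and orientations/phases are drawn from
#'   the seed.
#' @param spacing mesh point spacing (mm), default 0.075 (the scanner's
#'   nominal point spacing).
#' @param seed integer seed for the ripple phase, default 1.
#' @param provenance mesh label.
#' @return A \linkS4class{TriangleMesh} height field with attribute
#'   \code{spacing}.
#' @export
generateBaseSurface <- function(extent = c(8, 8), domeRadii = c(9, 11),
                                rippleAmplitude = 0.005,
                                rippleWavelength = 0.1,
                                undulationAmplitude = 0.25,
                                undulationWavelengths = c(3, 1.5, 0.8),
                                spacing = 0.075,
                                seed = 1L, provenance = "base") {
  stopifnot(spacing > 0, all(extent > 0))
  # phases/orientations from the seed, without disturbing the caller's
  # RNG stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  phase <- stats::runif(1, 0, max(rippleWavelength, 1e-9))
  nu <- length(undulationWavelengths)
  uphi <- stats::runif(2 * nu, 0, 2 * pi)
  uang <- stats::runif(nu, 0, pi)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
  xs <- seq(-extent[1] / 2, extent[1] / 2, by = spacing)
  ys <- seq(-extent[2] / 2, extent[2] / 2, by = spacing)
  g <- expand.grid(x = xs, y = ys)
  z <- -(g$x^2 / (2 * domeRadii[1]) + g$y^2 / (2 * domeRadii[2]))
  if (rippleAmplitude > 0)
    z <- z + rippleAmplitude * sin(2 * pi * (g$y + phase) /
                                     rippleWavelength)
  if (undulationAmplitude > 0 && nu > 0) {
    # 1/f-like spectrum: amplitude proportional to wavelength, so the
    # coarse scales dominate capture and the fine scales add precision
    amps <- undulationAmplitude * undulationWavelengths /
      sum(undulationWavelengths)
    for (k in seq_len(nu)) {
      u <- g$x * cos(uang[k]) + g$y * sin(uang[k])
      w <- -g$x * sin(uang[k]) + g$y * cos(uang[k])
      z <- z + amps[k] *
        sin(2 * pi * u / undulationWavelengths[k] + uphi[2 * k - 1]) *
        sin(2 * pi * w / (1.7 * undulationWavelengths[k]) + uphi[2 * k])
    }
  }
  nx <- length(xs)
  ny <- length(ys)
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- (j - 1) * nx + i
  b <- a + 1L
  cc <- a + nx
  d <- cc + 1L
  # alternate the cell diagonal (checkerboard) so the triangulation has no
  # preferred direction; a uniform split biases closest-point queries on
  # noisy scans
  even <- (i + j) %% 2L == 0L
  f <- rbind(cbind(a[even], b[even], d[even]),
             cbind(a[even], d[even], cc[even]),
             cbind(a[!even], b[!even], cc[!even]),
             cbind(b[!even], d[!even], cc[!even]))
  verts <- cbind(g$x, g$y, z)
  dimnames(verts) <- NULL
  m <- new("TriangleMesh", vertices = verts,
           faces = matrix(as.integer(f), ncol = 3),
           provenance = provenance)
  attr(m, "spacing") <- spacing
  m
}

# closed-form profiles added to / carved from a height field
.capProfile <- function(x, y, center, r, h) {
  d2 <- (x - center[1])^2 + (y - center[2])^2
  a2 <- h * (2 * r - h)
  p <- numeric(length(x))
  inside <- d2 < a2
  p[inside] <- sqrt(pmax(r^2 - d2[inside], 0)) - (r - h)
  pmax(p, 0)
}

#' Deposit an adhesive patch on a surface
#'
#' Raises the height field of \code{base} by the chosen profile and
#' returns the closed-form true volume of the added material:
#' spherical cap \eqn{\pi h^2 (3r - h) / 3}; flat pad
#' \eqn{l_x l_y h}; Gaussian bump \eqn{2 \pi A \sigma^2} (over the
#' infinite plane; the truncation error at the patch extent is reported as
#' an attribute).
#'
#' @param base a height-field \linkS4class{TriangleMesh}.
#' @param center footprint center \code{c(x, y)} (mm).
#' @param shape \code{"spherical_cap"}, \code{"flat_pad"} or
#'   \code{"gaussian_bump"}.
#' @param dim shape dimensions: cap \code{c(r, h)} (sphere radius, cap
#'   height); pad \code{c(lx, ly, height)}; bump \code{c(A, sigma)}.
#' @return A list with \code{mesh} and \code{trueVolume} (mm^3).
#' @export
addAdhesive <- function(base, center = c(0, 0),
                        shape = c("spherical_cap", "flat_pad",
                                  "gaussian_bump"),
                        dim) {
  shape <- match.arg(shape)
  v <- base@vertices
  x <- v[, 1]; y <- v[, 2]
  ext <- c(max(x) - min(x), max(y) - min(y))
  if (shape == "spherical_cap") {
    r <- dim[1]; h <- dim[2]
    if (h < 0 || 2 * r <= h) stop("parameter error: need 0 <= h < 2r")
    if (h == 0) return(list(mesh = base, trueVolume = 0))
    a <- sqrt(h * (2 * r - h))
    if (any(abs(center) + a > ext / 2))
      stop("parameter error: cap footprint extends outside the surface")
    p <- .capProfile(x, y, center, r, h)
    vol <- pi * h^2 * (3 * r - h) / 3
    trunc_err <- 0
  } else if (shape == "flat_pad") {
    lx <- dim[1]; ly <- dim[2]; h <- dim[3]
    if (any(abs(center) + c(lx, ly) / 2 > ext / 2))
      stop("parameter error: pad footprint extends outside the surface")
    p <- ifelse(abs(x - center[1]) <= lx / 2 &
                  abs(y - center[2]) <= ly / 2, h, 0)
    vol <- lx * ly * h
    trunc_err <- 0
  } else {
    A <- dim[1]; sg <- dim[2]
    d2 <- (x - center[1])^2 + (y - center[2])^2
    p <- A * exp(-d2 / (2 * sg^2))
    vol <- 2 * pi * A * sg^2
    rmin <- min(ext / 2 - abs(center))
    trunc_err <- vol * exp(-rmin^2 / (2 * sg^2))
  }
  v[, 3] <- v[, 3] + p
  base@vertices <- v
  structure(list(mesh = base, trueVolume = vol),
            truncationError = trunc_err)
}

#' Simulate a clean-up procedure
#'
#' Produces the post-clean-up surface T2 from the bonded surface T1 and
#' its baseline T0: the adhesive height (T1 minus T0) is scaled toward the
#' baseline by \code{removalFraction}, and enamel-loss dents (inverted
#' spherical caps with closed-form volumes) are carved below the baseline.
#' Dent footprints must not overlap the adhesive footprint for the
#' recorded ground truth to be exact; the study generator guarantees this.
#'
#' @param bonded T1 height-field mesh (same vertex grid as \code{base}).
#' @param base T0 height-field mesh.
#' @param removalFraction fraction of the adhesive height removed, in
#'   [0, 1].
#' @param dents list of dents, each \code{list(center = c(x, y), r, depth)}
#'   (sphere radius and cap depth, mm).
#' @param maxDepth physical bound on dent depth (mm), default 0.5.
#' @return A list with \code{mesh} (T2), \code{trueEVL} (mm^3, closed
#'   form), and \code{removalFraction}.
#' @export
simulateCleanup <- function(bonded, base, removalFraction, dents = list(),
                            maxDepth = 0.5) {
  if (removalFraction < 0 || removalFraction > 1)
    stop("parameter error: removalFraction must be in [0, 1]")
  if (!isTRUE(all.equal(dim(bonded@vertices), dim(base@vertices))))
    stop("bonded mesh must share the base vertex grid")
  v <- bonded@vertices
  zb <- base@vertices[, 3]
  adh <- v[, 3] - zb
  z2 <- zb + (1 - removalFraction) * adh
  evl <- 0
  for (dn in dents) {
    if (dn$depth > maxDepth)
      stop("parameter error: dent depth ", dn$depth,
           " mm exceeds the physical bound ", maxDepth, " mm")
    p <- .capProfile(v[, 1], v[, 2], dn$center, dn$r, dn$depth)
    z2 <- z2 - p
    evl <- evl + pi * dn$depth^2 * (3 * dn$r - dn$depth) / 3
  }
  out <- bonded
  out@vertices[, 3] <- z2
  list(mesh = out, trueEVL = evl, removalFraction = removalFraction)
}

# area-weighted vertex normals of a mesh
.vertexNormals <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  # accumulate face normals onto vertices
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) for (d in 1:3) {
    acc <- rowsum(fn[, d], f[, k])
    n[as.integer(rownames(acc)), d] <- n[as.integer(rownames(acc)), d] +
      acc[, 1]
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Apply scanner noise and a session pose offset
#'
#' Emulates a structured-light scan of a surface: every vertex is
#' displaced along its normal by \eqn{N(0, \sigma^2)} (default
#' \eqn{\sigma} = 0.007 mm, so 3\eqn{\sigma} stays under the 0.020 mm
#' maximum measuring error), then the mesh is moved by a small random
#' rigid pose drawn uniformly within the given ranges (a new scan session
#' never reproduces the previous frame exactly). Uses the current RNG
#' state; seed via \code{set.seed} for reproducibility.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param sigma per-vertex Gaussian noise SD along the normal (mm).
#' @param poseAngleDeg per-axis rotation range (degrees), default 2.
#' @param poseTransMm per-axis translation range (mm), default 0.5.
#' @return A list with \code{mesh} and \code{pose} (the applied
#'   \linkS4class{RigidTransform}).
#' @export
applyScanNoise <- function(mesh, sigma = 0.007, poseAngleDeg = 2,
                           poseTransMm = 0.5) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma > 0) {
    n <- .vertexNormals(mesh)
    disp <- stats::rnorm(nrow(mesh@vertices), 0, sigma)
    mesh@vertices <- mesh@vertices + n * disp
  }
  ang <- stats::runif(3, -poseAngleDeg, poseAngleDeg) * pi / 180
  tr <- stats::runif(3, -poseTransMm, poseTransMm)
  R <- rotationAboutZ(ang[3]) %*% rotationAboutY(ang[2]) %*%
    rotationAboutX(ang[1])
  pose <- rigidTransform(R, tr)
  if (poseAngleDeg == 0 && poseTransMm == 0) pose <- identityTransform()
  list(mesh = applyTransform(mesh, pose), pose = pose)
}

#' Default synthetic study parameters
#'
#' The study conditions emulated by \code{\link{generateStudy}}: 3
#' treatment groups of 25 teeth; adhesive volumes drawn lognormal within
#' 0.1-1.5 mm^3; group-specific residual fractions (Beta families) and
#' enamel-loss volumes (right-skewed lognormal families within
#' 0.001-1.1 mm^3) whose group means approximate the published treatment
#' contrasts (RAV about 0.24/0.07/0.12 mm^3, EVL about
#' 0.18/0.19/0.29 mm^3); scanner noise sigma = 0.007 mm and session pose
#' offsets within +/-2 degrees / +/-0.5 mm.
#'
#' @return A named list of parameters accepted by
#'   \code{\link{generateStudy}}.
#' @export
defaultStudyParams <- function() {
  list(nPerGroup = 25L,
       extent = c(8, 8),
       spacing = 0.075,
       domeRadii = c(9, 11),
       rippleAmplitude = 0.005,
       rippleWavelength = 0.1,
       undulationAmplitude = 0.25,
       undulationWavelengths = c(3, 1.5, 0.8),
       sigma = 0.007,
       poseAngleDeg = 2,
       poseTransMm = 0.5,
       avMeanlog = log(0.55), avSdlog = 0.5, avRange = c(0.1, 1.5),
       davShape1 = 1.5, davMean = c(0.40, 0.115, 0.20),
       evlMean = c(0.180, 0.187, 0.290), evlSdlog = 0.8,
       evlRange = c(0.001, 1.104),
       maxDentVolume = 0.22)
}

# geometry of a spherical cap of volume V and height h:
# r = V / (pi h^2) + h / 3, footprint radius a with a^2 = 2V/(pi h) - h^2/3
.capForVolume <- function(V, h) {
  h <- min(h, 0.95 * (6 * V / pi)^(1 / 3))  # keep footprint real
  r <- V / (pi * h^2) + h / 3
  list(r = r, h = h, a = sqrt(max(2 * V / (pi * h) - h^2 / 3, 1e-12)))
}

#' Generate the synthetic clean-up study
#'
#' Builds ground-truth-annotated T0/T1/T2 triplets for a full study: per
#' tooth a fresh crown surface, a spherical-cap adhesive patch (T1), a
#' group-specific clean-up with enamel-loss dents (T2), then scanner noise
#' on every condition and a random session pose on T1/T2 (T0 is the
#' reference frame). Fully reproducible from the seed.
#'
#' @param seed integer seed governing all randomness.
#' @param params study parameters, see \code{\link{defaultStudyParams}};
#'   supplied entries override the defaults.
#' @param dir optional output directory: when given, writes
#'   \code{<tooth_id>_<T0|T1|T2>.stl} per tooth plus
#'   \code{ground_truth.csv} and \code{groups.csv}.
#' @return Invisibly (visibly when \code{dir} is NULL) a list with
#'   \code{triplets} (list of \linkS4class{ScanTriplet}),
#'   \code{groundTruth} (data.frame: tooth_id, group, true_AV, true_RAV,
#'   true_dAV, true_EVL, pose_angle_deg_t1, pose_trans_mm_t1, sigma),
#'   \code{poses} (applied T1/T2 \linkS4class{RigidTransform}s per tooth),
#'   and \code{params}.
#' @export
generateStudy <- function(seed = 1L, params = list(), dir = NULL) {
  p <- utils::modifyList(defaultStudyParams(), params)
  set.seed(seed)
  triplets <- list()
  poses <- list()
  gt <- list()
  for (g in 1:3) {
    for (i in seq_len(p$nPerGroup)) {
      id <- sprintf("G%d_T%02d", g, i)
      base <- generateBaseSurface(
        extent = p$extent, domeRadii = p$domeRadii,
        rippleAmplitude = p$rippleAmplitude,
        rippleWavelength = p$rippleWavelength,
        undulationAmplitude = p$undulationAmplitude,
        undulationWavelengths = p$undulationWavelengths,
        spacing = p$spacing,
        seed = as.integer((as.double(seed) * 7919 + g * 100 + i) %%
                            2147483647),
        provenance = paste0(id, "_T0"))
      # adhesive patch
      av <- exp(stats::rnorm(1, p$avMeanlog, p$avSdlog))
      av <- min(max(av, p$avRange[1]), p$avRange[2])
      cap <- .capForVolume(av, 0.45 + 0.3 * av)
      ctr <- stats::runif(2, -0.4, 0.4)
      bonded <- addAdhesive(base, center = ctr, shape = "spherical_cap",
                            dim = c(cap$r, cap$h))
      bonded$mesh@provenance <- paste0(id, "_T1")
      # clean-up: residual fraction and dents
      dav <- stats::rbeta(1, p$davShape1,
                          p$davShape1 * (1 / p$davMean[g] - 1))
      mu <- log(p$evlMean[g]) - p$evlSdlog^2 / 2
      evl <- exp(stats::rnorm(1, mu, p$evlSdlog))
      evl <- min(max(evl, p$evlRange[1]), p$evlRange[2])
      k <- max(1L, ceiling(evl / p$maxDentVolume))
      vd <- evl / k
      # bur gouges are deep relative to their width; depth capped under
      # the 0.5 mm physical bound
      dgeom <- .capForVolume(vd, min(0.38 + 0.4 * vd, 0.48))
      ring <- max(cap$a + dgeom$a + 0.12,
                  if (k > 1) dgeom$a / sin(pi / k) + 0.02 else 0)
      ang0 <- stats::runif(1, 0, 2 * pi)
      dents <- lapply(seq_len(k), function(j) {
        th <- ang0 + 2 * pi * (j - 1) / k
        list(center = ctr + ring * c(cos(th), sin(th)),
             r = dgeom$r, depth = dgeom$h)
      })
      cleaned <- simulateCleanup(bonded$mesh, base,
                                 removalFraction = 1 - dav,
                                 dents = dents)
      cleaned$mesh@provenance <- paste0(id, "_T2")
      # scanning: noise on every condition, pose offset on T1/T2
      s0 <- applyScanNoise(base, sigma = p$sigma, poseAngleDeg = 0,
                           poseTransMm = 0)
      s1 <- applyScanNoise(bonded$mesh, sigma = p$sigma,
                           poseAngleDeg = p$poseAngleDeg,
                           poseTransMm = p$poseTransMm)
      s2 <- applyScanNoise(cleaned$mesh, sigma = p$sigma,
                           poseAngleDeg = p$poseAngleDeg,
                           poseTransMm = p$poseTransMm)
      triplets[[id]] <- new("ScanTriplet", toothId = id,
                            group = as.integer(g), t0 = s0$mesh,
                            t1 = s1$mesh, t2 = s2$mesh)
      poses[[id]] <- list(t1 = s1$pose, t2 = s2$pose)
      gt[[id]] <- data.frame(
        tooth_id = id, group = g, true_AV = bonded$trueVolume,
        true_RAV = dav * bonded$trueVolume, true_dAV = dav,
        true_EVL = cleaned$trueEVL,
        pose_angle_deg_t1 = rotationAngle(s1$pose) * 180 / pi,
        pose_trans_mm_t1 = sqrt(sum(s1$pose@translation^2)),
        sigma = p$sigma, stringsAsFactors = FALSE)
    }
  }
  gt <- do.call(rbind, gt)
  rownames(gt) <- NULL
  out <- list(triplets = triplets, groundTruth = gt, poses = poses,
              params = p, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (tp in triplets) {
      writeSTL(tp@t0, file.path(dir, paste0(tp@toothId, "_T0.stl")))
      writeSTL(tp@t1, file.path(dir, paste0(tp@toothId, "_T1.stl")))
      writeSTL(tp@t2, file.path(dir, paste0(tp@toothId, "_T2.stl")))
    }
    gtw <- gt
    for (cl in names(gtw)) if (is.numeric(gtw[[cl]]))
      gtw[[cl]] <- sprintf("%.9g", gtw[[cl]])
    utils::write.csv(gtw, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(gt[, c("tooth_id", "group")],
                     file.path(dir, "groups.csv"), row.names = FALSE,
                     quote = FALSE)
    return(invisible(out))
  }
  out
}
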