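# Geometry fixtures built in code.

# rectilinear height-field mesh over explicit coordinate vectors
gridSurface <- function(xs, ys, z, provenance = "fixture") {
  g <- expand.grid(x = xs, y = ys)
  zz <- if (is.function(z)) z(g$x, g$y) else rep(z, nrow(g))
  nx <- length(xs)
  ny <- length(ys)
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- (j - 1) * nx + i
  f <- rbind(cbind(a, a + 1L, a + nx + 1L),
             cbind(a, a + nx + 1L, a + nx))
  v <- cbind(g$x, g$y, zz)
  dimnames(v) <- NULL
  new("TriangleMesh", vertices = v,
      faces = matrix(as.integer(f), ncol = 3), provenance = provenance)
}

# flat plate of given height
flatPlate <- function(z = 0, ext = 10, sp = 0.25, provenance = "plate") {
  s <- seq(-ext / 2, ext / 2, by = sp)
  gridSurface(s, s, z, provenance)
}

# height field with a raised/recessed rectangle bounded by near-vertical
# walls (ramp width `eps`), for analytic Boolean fixtures
stepPlate <- function(base = 0.5, height = 0.5, half = 0.5, ext = 10,
                      sp = 0.05, eps = 1e-6, provenance = "step") {
  s <- sort(unique(c(seq(-ext / 2, ext / 2, by = sp),
                     -half, half, -half - eps, half + eps)))
  zf <- function(x, y)
    base + ifelse(abs(x) <= half & abs(y) <= half, height, 0)
  gridSurface(s, s, zf, provenance)
}

# icosphere by subdivision of an icosahedron, radius 1
icosphere <- function(subdiv = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    env <- new.env(hash = TRUE, parent = emptyenv())
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- env[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      env[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 4 * nf, 3)
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      newf[4 * k - 3, ] <- c(a, ab, ca)
      newf[4 * k - 2, ] <- c(b, bc, ab)
      newf[4 * k - 1, ] <- c(cc, ca, bc)
      newf[4 * k, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  new("TriangleMesh", vertices = v, faces = f, provenance = "icosphere")
}

# total triangle area of a mesh
meshArea <- function(mesh) {
  v <- vertices(mesh)
  f <- faces(mesh)
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# compact registration fixture: textured surface, quick to align
testSurface <- function(seed = 1, ext = 5, sp = 0.12)
  generateBaseSurface(extent = c(ext, ext), spacing = sp, seed = seed,
                      provenance = "ref")

# small synthetic study parameters for pipeline tests
miniStudyParams <- function()
  list(nPerGroup = 3L, extent = c(6, 6), spacing = 0.1)

# spherical-cap (radius, height) for a target volume, from the closed form
.capForVolume2 <- function(V, h) {
  r <- V / (pi * h^2) + h / 3
  c(r, h)
}

# shared cache for expensive fixtures within one test run
.fixtureCache <- new.env(parent = emptyenv())
cachedStudy <- function(key, ...) {
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateStudy(...)
  .fixtureCache[[key]]
}
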