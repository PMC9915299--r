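#' @include AllClasses.R
NULL

# STL stores triangle soup: identical coordinates repeated per facet.
# Vertices within this distance are merged on construction so shared
# edges become topological.
.MERGE_TOL <- 1e-6

#' Construct a validated TriangleMesh
#'
#' Builds a \linkS4class{TriangleMesh} from raw vertex/face arrays. Duplicate
#' vertices within \code{mergeTol} (default 1e-6 mm) are merged so that
#' shared edges are topological, and degenerate (zero-area) faces are
#' dropped with a message rather than an error — scanner meshes routinely
#' contain slivers.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 matrix of vertex indices (1-based).
#' @param provenance free-text label, conventionally
#'   \code{"<tooth_id>_<T0|T1|T2>"}.
#' @param mergeTol vertex merge tolerance in mm.
#' @param merge merge duplicate vertices (default TRUE).
#' @return A \linkS4class{TriangleMesh}.
#' @export
#' @examples
#' m <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   rbind(c(1, 2, 3)))
#' nFaces(m)
triangleMesh <- function(vertices, faces, provenance = "",
                         mergeTol = .MERGE_TOL, merge = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(vertices) == 0L || nrow(faces) == 0L)
    stop("empty mesh: a TriangleMesh needs at least one face")
  if (merge) {
    key <- paste(round(vertices[, 1] / mergeTol),
                 round(vertices[, 2] / mergeTol),
                 round(vertices[, 3] / mergeTol))
    first <- !duplicated(key)
    remap <- match(key, key[first])
    vertices <- vertices[first, , drop = FALSE]
    faces[] <- remap[faces]
  }
  # drop degenerate faces: repeated indices or (near) zero area
  rep_idx <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  a <- vertices[faces[, 1], , drop = FALSE]
  ab <- vertices[faces[, 2], , drop = FALSE] - a
  ac <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area2 <- sqrt(rowSums(cr^2))
  degen <- rep_idx | area2 < 1e-14
  if (any(degen)) {
    message(sprintf("triangleMesh: dropped %d degenerate face(s)",
                    sum(degen)))
    faces <- faces[!degen, , drop = FALSE]
  }
  if (nrow(faces) == 0L)
    stop("empty mesh: all faces were degenerate")
  new("TriangleMesh", vertices = vertices, faces = faces,
      provenance = as.character(provenance))
}

#' Read a mesh from an STL file
#'
#' Reads binary or ASCII STL (auto-detected). Coordinates are taken as mm.
#' Duplicate vertices within 1e-6 mm are merged so shared edges become
#' topological; degenerate facets are dropped.
#'
#' @param path path to an \code{.stl} file.
#' @param provenance label for the mesh; defaults to the file base name.
#' @return A \linkS4class{TriangleMesh}.
#' @seealso \code{\link{writeSTL}}
#' @export
readSTL <- function(path, provenance = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(provenance))
    provenance <- sub("\\.stl$", "", basename(path), ignore.case = TRUE)
  size <- file.info(path)$size
  if (size < 15) stop("format error in '", path, "': file too short (",
                      size, " bytes)")
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(size, 512))
  txt <- rawToChar(head[head >= as.raw(9) & head <= as.raw(126)])
  is_ascii <- grepl("^\\s*solid", txt) && grepl("facet", txt)
  if (is_ascii) {
    close(con)
    on.exit()
    return(.readSTLascii(path, provenance))
  }
  if (size < 84)
    stop("format error in '", path, "': binary STL shorter than the ",
         "84-byte header (", size, " bytes)")
  seek(con, 80)
  nfac <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(nfac)
  if (expected != size)
    stop(sprintf(
      "format error in '%s': header declares %d facets (%d bytes) but file has %d bytes (mismatch at byte offset 80)",
      path, nfac, expected, size))
  if (nfac == 0L) stop("empty mesh in '", path, "'")
  body <- readBin(con, "raw", n = 50 * nfac)
  rec <- matrix(body, nrow = 50)
  floats <- readBin(as.vector(rec[1:48, ]), "double", size = 4,
                    n = 12 * nfac, endian = "little")
  fm <- matrix(floats, nrow = 12)  # rows 1:3 normal, 4:12 vertices
  verts <- matrix(as.vector(fm[4:12, ]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3 * nfac), ncol = 3, byrow = TRUE)
  triangleMesh(verts, faces, provenance = provenance)
}

.readSTLascii <- function(path, provenance) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L) stop("empty mesh in '", path, "'")
  if (length(vl) %% 3 != 0L)
    stop("format error in '", path, "': vertex count ", length(vl),
         " is not a multiple of 3")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  if (any(!is.finite(verts)))
    stop("format error in '", path, "': non-numeric vertex coordinates")
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  triangleMesh(verts, faces, provenance = provenance)
}

#' Write a mesh to binary STL
#'
#' Writes little-endian binary STL (84-byte header + 50 bytes per facet),
#' mm units. \code{readSTL(writeSTL(m))} reproduces the mesh up to vertex
#' merging.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeSTL <- function(mesh, path) {
  stopifnot(is(mesh, "TriangleMesh"))
  v <- mesh@vertices
  f <- mesh@faces
  if (nrow(f) == 0L) stop("empty mesh: nothing to write")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  ab <- b - a; ac <- cc - a
  n <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
             ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
             ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  dat <- cbind(n, a, b, cc)  # 12 floats per facet in record order
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "binary STL (mm)"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  fraw <- writeBin(as.vector(t(dat)), raw(), size = 4, endian = "little")
  rec <- matrix(as.raw(0), nrow = 50, ncol = nrow(f))
  rec[1:48, ] <- matrix(fraw, nrow = 48)
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' Mesh validity report
#'
#' Single-pass edge audit of a mesh: watertightness (every edge shared by
#' exactly two faces), boundary edge count, non-manifold edge count, and
#' orientation consistency (the two directed half-edges of every interior
#' edge run in opposite directions).
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return A list with \code{watertight}, \code{boundaryEdges},
#'   \code{nonManifoldEdges}, \code{orientationConsistent}, \code{nEdges}.
#' @export
#' @examples
#' validateMesh(unitCubeMesh())
validateMesh <- function(mesh) {
  stopifnot(is(mesh, "TriangleMesh"))
  f <- mesh@faces
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(he_from, he_to)
  hi <- pmax(he_from, he_to)
  key <- paste(lo, hi)
  cnt <- table(key)
  boundary <- sum(cnt == 1L)
  nonmanifold <- sum(cnt > 2L)
  # orientation: for interior edges the directed edge must appear once in
  # each direction, i.e. no directed duplicate
  dkey <- paste(he_from, he_to)
  consistent <- !anyDuplicated(dkey) && nonmanifold == 0L
  list(watertight = boundary == 0L && nonmanifold == 0L,
       boundaryEdges = as.integer(boundary),
       nonManifoldEdges = as.integer(nonmanifold),
       orientationConsistent = consistent,
       nEdges = length(cnt))
}

# signed divergence-theorem volume (positive for outward orientation)
.signedVolume <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Promote a watertight mesh to a ClosedShell
#'
#' Checks watertightness (erroring with the boundary edge count otherwise),
#' flips the orientation if the signed divergence-theorem volume is
#' negative, and caches the enclosed volume.
#'
#' @param mesh a watertight \linkS4class{TriangleMesh}.
#' @param roiId optional ROI provenance tag (see \linkS4class{ClosedShell}).
#' @return A \linkS4class{ClosedShell}.
#' @export
#' @examples
#' enclosedVolume(closedShell(unitCubeMesh()))
closedShell <- function(mesh, roiId = "") {
  rep <- validateMesh(mesh)
  if (!rep$watertight)
    stop(sprintf(
      "topology error: mesh '%s' is not watertight (%d boundary edges, %d non-manifold edges)",
      mesh@provenance, rep$boundaryEdges, rep$nonManifoldEdges))
  vol <- .signedVolume(mesh)
  if (vol < 0) {
    mesh@faces <- mesh@faces[, c(1L, 3L, 2L), drop = FALSE]
    vol <- -vol
  }
  new("ClosedShell", mesh = mesh, isWatertight = TRUE,
      enclosedVolume = vol, roiId = as.character(roiId))
}

#' @rdname mesh-accessors
#' @export
setMethod("enclosedVolume", "ClosedShell", function(object)
  object@enclosedVolume)

#' @rdname mesh-accessors
#' @export
setMethod("enclosedVolume", "TriangleMesh", function(object)
  enclosedVolume(closedShell(object)))

#' Axis-aligned unit cube mesh
#'
#' A 12-face watertight unit cube with outward orientation; the standard
#' tiny fixture for I/O and volumetry checks.
#'
#' @param origin corner of the cube (length 3), default the origin.
#' @param side side length in mm, default 1.
#' @return A \linkS4class{TriangleMesh}.
#' @export
unitCubeMesh <- function(origin = c(0, 0, 0), side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  v <- sweep(v, 2, origin, "+")
  colnames(v) <- NULL
  # vertex order from expand.grid: index = 1 + x + 2y + 4z (x fastest)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),    # bottom (z = 0), normal -z
    c(5, 6, 7), c(6, 8, 7),    # top, normal +z
    c(1, 2, 5), c(2, 6, 5),    # y = 0, normal -y
    c(3, 7, 4), c(4, 7, 8),    # y = side, normal +y
    c(1, 5, 3), c(3, 5, 7),    # x = 0, normal -x
    c(2, 4, 6), c(4, 8, 6))    # x = side, normal +x
  triangleMesh(v, f, provenance = "unit_cube", merge = FALSE)
}
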