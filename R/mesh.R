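## Triangle-mesh data structures and geometry primitives: projection, edge
## lengths, corner angles, areas, interpolation, field sign.  Angles are
## radians internally; file interfaces use degrees.

#' Signed areas of 2D faces
#'
#' Positive for counter-clockwise faces.
#'
#' @param coords n x 2 coordinates.
#' @param faces m x 3 vertex-index matrix.
#' @return numeric vector of signed areas.
#' @export
signedFaceAreas <- function(coords, faces) {
  x1 <- coords[faces[, 1], 1]; y1 <- coords[faces[, 1], 2]
  0.5 * ((coords[faces[, 2], 1] - x1) * (coords[faces[, 3], 2] - y1) -
         (coords[faces[, 3], 1] - x1) * (coords[faces[, 2], 2] - y1))
}

#' Construct a Mesh3D
#'
#' @param coords n x 3 vertex coordinates (mm).
#' @param faces m x 3 vertex-index matrix (1-based).
#' @param vertexData optional named list of per-vertex scalar fields.
#' @return a [Mesh3D-class].
#' @export
mesh3D <- function(coords, faces, vertexData = list()) {
  new("Mesh3D", coords = as.matrix(coords),
      faces = matrix(as.integer(as.matrix(faces)), ncol = 3),
      vertexData = vertexData)
}

#' Construct a FlatMap from 2D coordinates and faces
#'
#' Faces are reoriented counter-clockwise; degenerate faces (absolute signed
#' area below \code{degenerateTol}) are excluded from the corner-angle set
#' and the field-sign computation with a warning.  The undirected edge set,
#' the perimeter (vertices on edges belonging to exactly one face) and the
#' mean edge length are derived here.
#'
#' @param coords n x 2 coordinates.
#' @param faces m x 3 vertex-index matrix.
#' @param metadata free-form list carried along (projection parameters, ...).
#' @param degenerateTol signed-area threshold below which a face is treated
#'   as degenerate.
#' @return a [FlatMap-class].
#' @export
flatMap <- function(coords, faces, metadata = list(), degenerateTol = 1e-12) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  a <- signedFaceAreas(coords, faces)
  flip <- a < 0
  if (any(flip)) faces[flip, ] <- faces[flip, c(1, 3, 2), drop = FALSE]
  a <- abs(a)
  degen <- a <= degenerateTol
  if (any(degen))
    warning(sprintf("%d degenerate face(s) excluded from corner angles", sum(degen)))
  good <- faces[!degen, , drop = FALSE]
  triples <- rbind(good[, c(1, 2, 3)], good[, c(2, 3, 1)], good[, c(3, 1, 2)])

  n <- nrow(coords)
  eAll <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  lo <- pmin(eAll[, 1], eAll[, 2]); hi <- pmax(eAll[, 1], eAll[, 2])
  key <- (as.double(lo) - 1) * n + hi
  first <- !duplicated(key)
  E <- cbind(lo[first], hi[first])
  counts <- table(key)
  boundaryKey <- as.numeric(names(counts)[counts == 1L])
  bLo <- floor((boundaryKey - 1) / n) + 1
  bHi <- boundaryKey - (bLo - 1) * n
  perim <- sort(unique(as.integer(c(bLo, bHi))))

  len <- edgeLengths(coords, E)
  new("FlatMap", coords = coords, faces = faces,
      edges = matrix(as.integer(E), ncol = 2),
      angleTriples = matrix(as.integer(triples), ncol = 3),
      perimeter = perim, meanEdgeLength = mean(len), metadata = metadata)
}

#' Construct a MapProjection
#'
#' Defaults describe an occipital-pole-centered orthographic projection of
#' the cortical sphere; the exact center and orientation are configuration
#' values, documented rather than claimed canonical.
#'
#' @param center projection axis (normalized internally).
#' @param orientation in-plane rotation, degrees.
#' @param radius angular extent, degrees, in (0, 90].
#' @param chirality "lh" or "rh".
#' @return a [MapProjection-class].
#' @export
mapProjection <- function(center = c(-1, -0.4, -0.2), orientation = 0,
                          radius = 60, chirality = "lh") {
  center <- center / sqrt(sum(center^2))
  new("MapProjection", center = as.numeric(center),
      orientation = as.numeric(orientation), radius = as.numeric(radius),
      chirality = chirality)
}

#' Orthographic projection of a spherical mesh to a flat map
#'
#' Vertices within the angular radius of the projection center are retained;
#' their 2D coordinates are the in-plane components after rotating the center
#' to the pole (so distances are in the units of the sphere radius).  Faces
#' are kept only if wholly inside.  For right-hemisphere projections the x
#' axis is mirrored so both hemispheres share one orientation convention.
#'
#' @param mesh a [Mesh3D-class] whose vertices lie on a sphere.
#' @param proj a [MapProjection-class].
#' @param tolerance allowed relative radial deviation from a sphere.
#' @return a [FlatMap-class]; its metadata records the projection, the sphere
#'   radius and the original vertex indices (\code{sourceVertex}).
#' @export
orthographicProject <- function(mesh, proj, tolerance = 1e-3) {
  xyz <- coords(mesh)
  r <- sqrt(rowSums(xyz^2))
  R <- mean(r)
  if (R <= 0 || max(abs(r - R)) / R > tolerance)
    stop("mesh vertices do not lie on a sphere (radial deviation above tolerance)")
  unit <- xyz / r

  cz <- proj@center
  up <- if (abs(cz[3]) < 0.99) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(up[2] * cz[3] - up[3] * cz[2],
          up[3] * cz[1] - up[1] * cz[3],
          up[1] * cz[2] - up[2] * cz[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(cz[2] * e1[3] - cz[3] * e1[2],
          cz[3] * e1[1] - cz[1] * e1[3],
          cz[1] * e1[2] - cz[2] * e1[1])
  ang <- proj@orientation * pi / 180
  f1 <- cos(ang) * e1 + sin(ang) * e2
  f2 <- -sin(ang) * e1 + cos(ang) * e2

  polar <- acos(pmin(1, pmax(-1, unit %*% cz)))
  keep <- which(polar <= proj@radius * pi / 180 + 1e-12)
  if (!length(keep)) stop("empty map: no vertex within the projection radius")

  xy <- cbind(xyz[keep, , drop = FALSE] %*% f1,
              xyz[keep, , drop = FALSE] %*% f2)
  if (proj@chirality == "rh") xy[, 1] <- -xy[, 1]

  idx <- integer(nrow(xyz)); idx[keep] <- seq_along(keep)
  f <- faces(mesh)
  inside <- idx[f[, 1]] > 0L & idx[f[, 2]] > 0L & idx[f[, 3]] > 0L
  f2d <- cbind(idx[f[inside, 1]], idx[f[inside, 2]], idx[f[inside, 3]])
  if (!nrow(f2d)) stop("empty map: no face lies wholly inside the projection")

  flatMap(xy, f2d, metadata = list(projection = proj, sphereRadius = R,
                                   sourceVertex = keep))
}

#' Euclidean edge lengths
#'
#' @param coords n x 2 (or n x 3) coordinates.
#' @param E edge matrix, one (u, v) row per edge.
#' @return numeric vector of lengths.
#' @export
edgeLengths <- function(coords, E) {
  d <- coords[E[, 1], , drop = FALSE] - coords[E[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Counter-clockwise corner angles
#'
#' For a triple (a, b, c) the angle at a from edge (a,b) to edge (a,c),
#' measured counter-clockwise, in radians within [0, 2*pi).  Interior
#' corners of positively oriented non-degenerate triangles lie in (0, pi).
#'
#' @param coords n x 2 coordinates.
#' @param triples corner-triple matrix (a, b, c).
#' @return numeric vector of angles (radians).
#' @export
cornerAngles <- function(coords, triples) {
  u <- coords[triples[, 2], , drop = FALSE] - coords[triples[, 1], , drop = FALSE]
  v <- coords[triples[, 3], , drop = FALSE] - coords[triples[, 1], , drop = FALSE]
  if (any(rowSums(u^2) == 0 | rowSums(v^2) == 0))
    stop("degenerate geometry: zero-length edge incident to a corner")
  a <- atan2(u[, 1] * v[, 2] - u[, 2] * v[, 1],
             u[, 1] * v[, 1] + u[, 2] * v[, 2])
  a %% (2 * pi)
}

#' Field sign of mesh triangles
#'
#' The orientation of each face's image in the visual field times its
#' orientation on the flat map: +1 for non-mirror, -1 for mirror
#' representations (adjacent visual areas alternate).  Faces with a missing
#' visual-field coordinate or a degenerate image yield NA / 0 respectively.
#'
#' @param flatCoords n x 2 map coordinates.
#' @param vfCoords n x 2 visual-field Cartesian coordinates (degrees).
#' @param faces m x 3 face matrix.
#' @return integer vector in \{-1, 0, +1\} with NA for excluded faces.
#' @export
triangleFieldSign <- function(flatCoords, vfCoords, faces) {
  sMap <- sign(signedFaceAreas(flatCoords, faces))
  sVf <- sign(signedFaceAreas(vfCoords, faces))
  out <- as.integer(sMap * sVf)
  miss <- !is.finite(vfCoords[faces[, 1], 1]) | !is.finite(vfCoords[faces[, 1], 2]) |
          !is.finite(vfCoords[faces[, 2], 1]) | !is.finite(vfCoords[faces[, 2], 2]) |
          !is.finite(vfCoords[faces[, 3], 1]) | !is.finite(vfCoords[faces[, 3], 2])
  out[miss] <- NA_integer_
  out
}

#' Per-vertex surface areas of a 3D mesh
#'
#' Each face's area is split equally (one third) among its vertices, so the
#' vertex areas sum exactly to the total mesh area.
#'
#' @param mesh a [Mesh3D-class].
#' @return numeric vector of vertex areas (mm^2).
#' @export
vertexSurfaceAreas <- function(mesh) {
  xyz <- coords(mesh); f <- faces(mesh)
  u <- xyz[f[, 2], , drop = FALSE] - xyz[f[, 1], , drop = FALSE]
  v <- xyz[f[, 3], , drop = FALSE] - xyz[f[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  fa <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  out <- numeric(nrow(xyz))
  for (k in 1:3) {
    s <- tapply(fa / 3, f[, k], sum)
    idx <- as.integer(names(s))
    out[idx] <- out[idx] + as.numeric(s)
  }
  out
}

#' Locate points in a 2D triangulation
#'
#' Point-in-triangle search with barycentric coordinates.  A query on a
#' shared edge resolves to the lowest face index (deterministic).
#'
#' @param map a [FlatMap-class], or an n x 2 coordinate matrix.
#' @param points p x 2 query points.
#' @param faces face matrix (only when \code{map} is a coordinate matrix).
#' @param tol barycentric tolerance for boundary inclusion.
#' @return list with \code{face} (0 where the point is outside every face)
#'   and \code{bary} (p x 3 barycentric weights, NA outside).
#' @export
locatePoints <- function(map, points, faces = NULL, tol = 1e-9) {
  if (is(map, "FlatMap")) {
    co <- map@coords; f <- map@faces
  } else {
    co <- as.matrix(map); f <- faces
  }
  points <- matrix(as.numeric(points), ncol = 2)
  cpp_locate(co, matrix(as.integer(f), ncol = 3), points, tol)
}

#' Barycentric interpolation of per-vertex fields
#'
#' Linear interpolation inside the containing face; points outside every face
#' receive NA.  Interpolation reproduces affine fields exactly.  Angular
#' fields must be interpolated via their visual-field Cartesian embedding
#' (see [interpolateRetinotopy()]), never as raw angle numbers.
#'
#' @param source a [FlatMap-class].
#' @param fields numeric vector or n x k matrix of per-vertex values.
#' @param points p x 2 query points.
#' @param tol boundary-inclusion tolerance passed to [locatePoints()].
#' @return interpolated values (vector or p x k matrix), NA outside.
#' @export
barycentricInterpolate <- function(source, fields, points, tol = 1e-9) {
  loc <- locatePoints(source, points, tol = tol)
  onecol <- is.null(dim(fields))
  fields <- as.matrix(fields)
  out <- matrix(NA_real_, nrow(loc$bary), ncol(fields))
  hit <- loc$face > 0L
  if (any(hit)) {
    fv <- source@faces[loc$face[hit], , drop = FALSE]
    b <- loc$bary[hit, , drop = FALSE]
    for (k in seq_len(ncol(fields))) {
      out[hit, k] <- b[, 1] * fields[fv[, 1], k] +
                     b[, 2] * fields[fv[, 2], k] +
                     b[, 3] * fields[fv[, 3], k]
    }
  }
  colnames(out) <- colnames(fields)
  if (onecol) out[, 1] else out
}

#' Interpolate retinotopic (angle, eccentricity) fields
#'
#' Embeds polar angle and eccentricity as visual-field Cartesian coordinates,
#' interpolates linearly, and converts back; this avoids angular wrap
#' artifacts.
#'
#' @param source a [FlatMap-class].
#' @param angleDeg,eccenDeg per-vertex polar angle and eccentricity (deg).
#' @param points p x 2 query points.
#' @param hemisphere "lh" or "rh".
#' @return list with \code{polarAngle} and \code{eccentricity} at the points.
#' @export
interpolateRetinotopy <- function(source, angleDeg, eccenDeg, points,
                                  hemisphere = "rh") {
  xy <- visualFieldCoords(angleDeg, eccenDeg, hemisphere)
  v <- barycentricInterpolate(source, xy, points)
  visualFieldAngles(v[, 1], v[, 2], hemisphere)
}

#' Regular triangular lattice over a rectangle
#'
#' Rows are spaced \code{resolution * sqrt(3) / 2} apart with alternate rows
#' offset by half a step, giving near-equilateral triangles of edge
#' \code{resolution}.
#'
#' @param xlim,ylim extents.
#' @param resolution target edge length.
#' @return list with \code{coords} and \code{faces}.
#' @export
makeTriangularLattice <- function(xlim, ylim, resolution) {
  h <- resolution * sqrt(3) / 2
  nx <- floor((xlim[2] - xlim[1]) / resolution + 1e-9) + 1L
  ny <- floor((ylim[2] - ylim[1]) / h + 1e-9) + 1L
  if (nx < 2L || ny < 2L)
    stop("empty map: resolution larger than the map extent")
  xs <- xlim[1] + (seq_len(nx) - 1L) * resolution
  co <- matrix(0, nx * ny, 2)
  for (j in seq_len(ny)) {
    off <- if (j %% 2 == 0) resolution / 2 else 0
    rows <- (j - 1L) * nx + seq_len(nx)
    co[rows, 1] <- xs + off
    co[rows, 2] <- ylim[1] + (j - 1L) * h
  }
  fl <- vector("list", ny - 1L)
  for (j in seq_len(ny - 1L)) {
    b <- (j - 1L) * nx          # base of row j
    t <- j * nx                 # base of row j + 1
    i <- seq_len(nx - 1L)
    if (j %% 2 == 1) {          # row j unshifted, row j+1 shifted right
      f1 <- cbind(b + i, b + i + 1L, t + i)
      f2 <- cbind(b + i + 1L, t + i + 1L, t + i)
    } else {                    # row j shifted, row j+1 unshifted
      f1 <- cbind(b + i, b + i + 1L, t + i + 1L)
      f2 <- cbind(b + i, t + i + 1L, t + i)
    }
    fl[[j]] <- rbind(f1, f2)
  }
  list(coords = co, faces = do.call(rbind, fl))
}

#' Resample a flat map onto a uniform triangular lattice
#'
#' Builds an equilateral lattice of the requested edge length over the source
#' map's bounding box, keeps the lattice vertices that fall inside the source
#' triangulation, and transfers fields by barycentric interpolation.
#'
#' @param source a [FlatMap-class].
#' @param fields per-vertex vector or matrix to transfer (optional).
#' @param resolution target edge length; defaults to the source's mean edge
#'   length.
#' @return list with \code{map} (the uniform [FlatMap-class]) and
#'   \code{fields} (interpolated values at its vertices, or NULL).
#' @export
uniformResample <- function(source, fields = NULL,
                            resolution = meanEdgeLength(source)) {
  if (resolution <= 0) stop("resolution must be positive")
  co <- source@coords
  lat <- makeTriangularLattice(range(co[, 1]), range(co[, 2]), resolution)
  loc <- locatePoints(source, lat$coords)
  inside <- loc$face > 0L
  idx <- integer(nrow(lat$coords)); idx[inside] <- seq_len(sum(inside))
  f <- lat$faces
  keep <- idx[f[, 1]] > 0L & idx[f[, 2]] > 0L & idx[f[, 3]] > 0L
  if (!any(keep)) stop("empty map: resolution larger than the map extent")
  f2 <- cbind(idx[f[keep, 1]], idx[f[keep, 2]], idx[f[keep, 3]])
  ptsIn <- lat$coords[inside, , drop = FALSE]
  used <- sort(unique(as.integer(f2)))
  remap <- integer(nrow(ptsIn)); remap[used] <- seq_along(used)
  map <- flatMap(ptsIn[used, , drop = FALSE],
                 cbind(remap[f2[, 1]], remap[f2[, 2]], remap[f2[, 3]]),
                 metadata = list(resampledFrom = source@metadata,
                                 resolution = resolution))
  out <- NULL
  if (!is.null(fields))
    out <- barycentricInterpolate(source, fields, map@coords)
  list(map = map, fields = out)
}
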