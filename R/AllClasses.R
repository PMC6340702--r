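## S4 class definitions.  Validity methods encode the structural invariants
## that the rest of the package relies on; constructors live next to the
## module code (mesh.R, model.R, registration.R, ...).

#' Mesh3D: a triangle mesh embedded in 3D
#'
#' Vertex coordinates in mm, faces as ordered vertex-index triples, plus
#' optional per-vertex scalar fields (e.g. curvature, surface area).
#'
#' @slot coords numeric matrix, n x 3 vertex positions (mm).
#' @slot faces integer matrix, m x 3 vertex indices (1-based).
#' @slot vertexData named list of per-vertex numeric vectors.
#' @export
setClass("Mesh3D", representation(
  coords = "matrix", faces = "matrix", vertexData = "list"))

setValidity("Mesh3D", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  n <- nrow(object@coords)
  f <- object@faces
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > n)
      msg <- c(msg, "face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
      msg <- c(msg, "faces must have three distinct vertices")
    ek <- edgeKeys3(f, n)
    if (any(table(ek) > 2L))
      msg <- c(msg, "non-manifold: an edge is shared by more than two faces")
  }
  bad <- vapply(object@vertexData, function(v) length(v) != n, logical(1))
  if (any(bad)) msg <- c(msg, "vertexData entries must have one value per vertex")
  if (length(msg)) msg else TRUE
})

# undirected edge keys of a face matrix (helper shared with FlatMap validity)
edgeKeys3 <- function(faces, n) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  (lo - 1) * as.double(n) + hi
}

#' MapProjection: parameters of an orthographic flattening
#'
#' @slot center unit 3-vector, the projection axis.
#' @slot orientation in-plane rotation applied after projection, degrees.
#' @slot radius angular extent retained around the center, degrees, in (0, 90].
#' @slot chirality "lh" or "rh"; the "rh" map is mirrored at projection time
#'   so both hemispheres share one in-map orientation convention.
#' @export
setClass("MapProjection", representation(
  center = "numeric", orientation = "numeric", radius = "numeric",
  chirality = "character"))

setValidity("MapProjection", function(object) {
  msg <- character()
  if (length(object@center) != 3L ||
      abs(sqrt(sum(object@center^2)) - 1) > 1e-6)
    msg <- c(msg, "center must be a unit 3-vector")
  if (length(object@radius) != 1L || object@radius <= 0 || object@radius > 90)
    msg <- c(msg, "radius must be in (0, 90] degrees")
  if (!object@chirality %in% c("lh", "rh"))
    msg <- c(msg, "chirality must be 'lh' or 'rh'")
  if (length(msg)) msg else TRUE
})

#' FlatMap: a 2D-projected triangle mesh
#'
#' Houses everything the registration potential needs: 2D vertex coordinates,
#' counter-clockwise faces, the undirected edge set, corner-angle triples,
#' the perimeter vertex set and the mean edge length.
#'
#' @slot coords numeric matrix, n x 2.
#' @slot faces integer matrix, m x 3, all counter-clockwise.
#' @slot edges integer matrix, one row per undirected edge (u < v).
#' @slot angleTriples integer matrix, rows (a, b, c): the corner at a between
#'   edges (a,b) and (a,c); degenerate faces are excluded.
#' @slot perimeter integer vector of boundary vertex indices.
#' @slot meanEdgeLength mean Euclidean edge length (the epsilon used for
#'   step-size and anchor-width defaults).
#' @slot metadata list (projection parameters, source vertex ids, ...).
#' @export
setClass("FlatMap", representation(
  coords = "matrix", faces = "matrix", edges = "matrix",
  angleTriples = "matrix", perimeter = "integer",
  meanEdgeLength = "numeric", metadata = "list"))

setValidity("FlatMap", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must be n x 2")
  f <- object@faces
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > n) msg <- c(msg, "face indices out of range")
    a <- signedFaceAreas(object@coords, f)
    if (any(a < 0)) msg <- c(msg, "all faces must be counter-clockwise")
  }
  e <- object@edges
  if (nrow(e) > 0) {
    key <- (pmin(e[, 1], e[, 2]) - 1) * as.double(n) + pmax(e[, 1], e[, 2])
    if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edge in E")
  }
  if (length(object@meanEdgeLength) != 1L || !(object@meanEdgeLength > 0))
    msg <- c(msg, "meanEdgeLength must be a single positive number")
  if (length(object@perimeter) && (min(object@perimeter) < 1L ||
                                   max(object@perimeter) > n))
    msg <- c(msg, "perimeter indices out of range")
  if (length(msg)) msg else TRUE
})

#' RetinotopyModel: a queryable 2D template of retinotopy
#'
#' Assigns polar angle (degrees, 0 at the upper vertical meridian through 90
#' at the horizontal to 180 at the lower vertical meridian), eccentricity
#' (degrees, 0-90) and a visual-area label to every point of the model
#' region.
#'
#' @slot mesh the model [FlatMap-class].
#' @slot polarAngle,eccentricity per-vertex fields, degrees.
#' @slot vertexArea,faceArea per-vertex / per-face area labels ("none" where
#'   unassigned).
#' @slot areas ordered character vector of modeled area names.
#' @slot rescale list with the angle linear map and the fitted exponential
#'   eccentricity map (a, b, targets).
#' @slot sizeFun data.frame (area, slope, intercept): the model's linear
#'   pRF-size-vs-eccentricity function per area.
#' @slot version schema version string.
#' @export
setClass("RetinotopyModel", representation(
  mesh = "FlatMap", polarAngle = "numeric", eccentricity = "numeric",
  vertexArea = "character", faceArea = "character", areas = "character",
  rescale = "list", sizeFun = "data.frame", version = "character"))

setValidity("RetinotopyModel", function(object) {
  msg <- character()
  n <- nrow(object@mesh@coords)
  if (length(object@polarAngle) != n || length(object@eccentricity) != n ||
      length(object@vertexArea) != n)
    msg <- c(msg, "per-vertex fields must match the mesh vertex count")
  if (length(object@faceArea) != nrow(object@mesh@faces))
    msg <- c(msg, "faceArea must match the face count")
  ok <- is.finite(object@polarAngle)
  if (any(object@polarAngle[ok] < -1e-9 | object@polarAngle[ok] > 180 + 1e-9))
    msg <- c(msg, "polar angle must lie in [0, 180] degrees")
  ok <- is.finite(object@eccentricity)
  if (any(object@eccentricity[ok] < -1e-9 | object@eccentricity[ok] > 90 + 1e-9))
    msg <- c(msg, "eccentricity must lie in [0, 90] degrees")
  if (length(msg)) msg else TRUE
})

#' RetinotopyData: per-vertex pRF measurements
#'
#' @slot vertexId integer vertex ids (keys into a mesh; preserved through the
#'   whole pipeline so predictions transfer to native space).
#' @slot polarAngle,eccentricity,prfSize measured values, degrees.
#' @slot varianceExplained fraction of BOLD variance explained, in [0, 1];
#'   used as the data-quality weight.  Vertices below the analysis threshold
#'   are *marked* (excluded from anchors), never dropped from indexing.
#' @slot hemisphere "lh" or "rh".
#' @export
setClass("RetinotopyData", representation(
  vertexId = "integer", polarAngle = "numeric", eccentricity = "numeric",
  prfSize = "numeric", varianceExplained = "numeric", hemisphere = "character"))

setValidity("RetinotopyData", function(object) {
  msg <- character()
  n <- length(object@vertexId)
  if (length(object@polarAngle) != n || length(object@eccentricity) != n ||
      length(object@prfSize) != n || length(object@varianceExplained) != n)
    msg <- c(msg, "all per-vertex fields must have equal length")
  w <- object@varianceExplained
  if (any(w < -1e-12 | w > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "varianceExplained must lie in [0, 1]")
  if (any(object@eccentricity < 0, na.rm = TRUE))
    msg <- c(msg, "eccentricity must be non-negative")
  if (!object@hemisphere %in% c("lh", "rh"))
    msg <- c(msg, "hemisphere must be 'lh' or 'rh'")
  if (length(msg)) msg else TRUE
})

#' AnchorSet: the Gaussian potential wells linking data to the model
#'
#' One anchor per (retinotopic vertex x modeled area): the vertex index, the
#' model point where that area represents the vertex's measured coordinates,
#' the well width sigma, and a non-negative weight.
#'
#' @slot vertex integer vertex indices into the registration mesh.
#' @slot target numeric matrix, one 2D model point per anchor.
#' @slot sigma Gaussian well widths, map units; positive, capped at 20 times
#'   the mean edge length.
#' @slot weight anchor weights (variance explained, possibly reduced by the
#'   field-sign and pRF-size factors).
#' @slot area the modeled area each anchor points into.
#' @export
setClass("AnchorSet", representation(
  vertex = "integer", target = "matrix", sigma = "numeric",
  weight = "numeric", area = "character"))

setValidity("AnchorSet", function(object) {
  msg <- character()
  n <- length(object@vertex)
  if (nrow(object@target) != n || length(object@sigma) != n ||
      length(object@weight) != n || length(object@area) != n)
    msg <- c(msg, "anchor slots must have equal length")
  if (any(object@sigma <= 0)) msg <- c(msg, "sigma must be positive")
  if (any(object@weight < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RegistrationSystem: the reference configuration of the potential
#'
#' @slot x0 reference 2D coordinates.
#' @slot edges,refLengths undirected edges and their reference lengths.
#' @slot q0 minimum allowable edge length (scalar).
#' @slot q1 maximum allowable edge length, per edge (may be Inf).
#' @slot angleTriples,refAngles corner triples and reference angles (radians).
#' @slot perimeter boundary vertex indices.
#' @slot faces the mesh faces (needed for per-vertex field-sign lookups).
#' @slot meanEdgeLength epsilon of the projection.
#' @export
setClass("RegistrationSystem", representation(
  x0 = "matrix", edges = "matrix", refLengths = "numeric", q0 = "numeric",
  q1 = "numeric", angleTriples = "matrix", refAngles = "numeric",
  perimeter = "integer", faces = "matrix", meanEdgeLength = "numeric"))

setValidity("RegistrationSystem", function(object) {
  msg <- character()
  if (any(object@refLengths <= object@q0) || any(object@refLengths >= object@q1))
    msg <- c(msg, "reference edge lengths must lie strictly inside (q0, q1)")
  if (any(object@refAngles <= 0 | object@refAngles >= pi))
    msg <- c(msg, "reference angles must lie strictly inside (0, pi)")
  if (length(msg)) msg else TRUE
})

#' MinimizerConfig: settings for the registration minimizer
#'
#' @slot steps iteration count (default 2500).
#' @slot maxStep per-vertex displacement cap per step; NA means 1/50 of the
#'   mean edge length, resolved at registration time.
#' @slot noiseScale scale of the exponential multiplicative gradient noise
#'   (0 disables it; the default makes the median magnitude factor 1.7).
#' @slot backtrackFactor step shrink factor on a rejected step, in (0, 1).
#' @slot maxRetries bounded retries per step before the step is skipped.
#' @slot seed RNG seed (NA: leave the RNG state alone).
#' @slot gradTol optional early-stop gradient tolerance (0: run all steps).
#' @slot fluctTol relative potential increase tolerated per accepted step
#'   when gradient noise is enabled (the injected-noise tolerance); with
#'   noiseScale = 0 descent is strictly monotone regardless.
#' @export
setClass("MinimizerConfig", representation(
  steps = "integer", maxStep = "numeric", noiseScale = "numeric",
  backtrackFactor = "numeric", maxRetries = "integer", seed = "numeric",
  gradTol = "numeric", fluctTol = "numeric"))

setValidity("MinimizerConfig", function(object) {
  msg <- character()
  if (object@steps < 1L) msg <- c(msg, "steps must be >= 1")
  if (!is.na(object@maxStep) && object@maxStep <= 0)
    msg <- c(msg, "maxStep must be positive")
  if (object@backtrackFactor <= 0 || object@backtrackFactor >= 1)
    msg <- c(msg, "backtrackFactor must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' RegistrationResult: output of the potential minimization
#'
#' @slot coords registered vertex coordinates (same vertex order as x0, so
#'   predictions transfer to native space without inverting anything).
#' @slot potential the per-step potential trajectory (length steps + 1).
#' @slot backtracks,skipped backtrack and skipped-step counts.
#' @slot finalGradNorm Euclidean norm of the final gradient.
#' @slot diagnostics list: extreme corner angles and edge-length margins seen
#'   across all accepted configurations (topology-preservation evidence).
#' @slot seed the seed used (NA if none was set).
#' @export
setClass("RegistrationResult", representation(
  coords = "matrix", potential = "numeric", backtracks = "integer",
  skipped = "integer", finalGradNorm = "numeric", diagnostics = "list",
  seed = "numeric"))

#' InferredMaps: full-field per-vertex predictions
#'
#' @slot vertexId native vertex ids.
#' @slot polarAngle,eccentricity predicted values, degrees (NA outside every
#'   modeled area).
#' @slot area predicted visual-area label ("none" outside).
#' @slot prfSize predicted pRF size, degrees (NA where no per-area size fit
#'   was possible).
#' @slot provenance list: model version, configuration hash, seed.
#' @export
setClass("InferredMaps", representation(
  vertexId = "integer", polarAngle = "numeric", eccentricity = "numeric",
  area = "character", prfSize = "numeric", provenance = "list"))

#' SyntheticDataset: a generated ground-truth subject
#'
#' @slot model the ground-truth [RetinotopyModel-class].
#' @slot subjectMap the subject's flat map (warped model mesh); its
#'   coordinates play the role of the prior-aligned starting position.
#' @slot truePositions the unwarped model-space position of every subject
#'   vertex (the inverse correspondence of the warp).
#' @slot truth data.frame: per-vertex ground-truth polarAngle, eccentricity,
#'   prfSize, area.
#' @slot scans list of [RetinotopyData-class], one per simulated scan.
#' @slot validation a held-out averaged-scan [RetinotopyData-class].
#' @slot config,seed provenance.
#' @export
setClass("SyntheticDataset", representation(
  model = "RetinotopyModel", subjectMap = "FlatMap", truePositions = "matrix",
  truth = "data.frame", scans = "list", validation = "RetinotopyData",
  config = "list", seed = "numeric"))
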