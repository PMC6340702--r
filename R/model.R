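## 2D models of retinotopy: fill polar-angle and eccentricity fields between
## labeled boundary contours by minimizing the orthogonality + smoothness
## objective, rescale to degrees, answer point lookups, serialize to JSON.

.boundaryLabels <- c("foveal", "peripheral", "upper_vertical_meridian",
                     "lower_vertical_meridian", "horizontal_meridian")
.visualAreas <- c("V1", "V2", "V3", "hV4", "VO1", "VO2", "V3a", "V3b",
                  "LO1", "LO2", "TO1", "TO2", "none")

# scaled field value implied by a boundary label; NA where the label does not
# constrain that field
.labelTheta <- c(upper_vertical_meridian = -1, lower_vertical_meridian = 1,
                 horizontal_meridian = 0)
.labelRho <- c(foveal = -1, peripheral = 1)

#' Specify labeled boundary contours for a retinotopy model
#'
#' @param contours list; each element a list with \code{points} (k x 2
#'   polyline), \code{label} (one of foveal, peripheral,
#'   upper_vertical_meridian, lower_vertical_meridian, horizontal_meridian)
#'   and \code{areas} (the visual-area pair the contour separates).
#' @param areaPolygons list of \code{list(name =, polygon =)} entries; a
#'   vertex is labeled with the first polygon that contains it.
#' @return a classed list usable by [buildModel()].
#' @export
boundarySpec <- function(contours, areaPolygons) {
  for (ct in contours) {
    if (!ct$label %in% .boundaryLabels)
      stop("unknown boundary label: ", ct$label)
    if (!is.matrix(ct$points) || ncol(ct$points) != 2)
      stop("contour points must be a k x 2 matrix")
  }
  for (ap in areaPolygons)
    if (!ap$name %in% .visualAreas)
      stop("unknown visual area: ", ap$name)
  structure(list(contours = contours, areaPolygons = areaPolygons),
            class = "boundarySpec")
}

# even-odd ray-crossing point-in-polygon test (no closing vertex required)
pointInPolygon <- function(points, poly) {
  px <- points[, 1]; py <- points[, 2]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Orthogonality + smoothness objective of the field fill-in
#'
#' \eqn{f(\theta,\rho) = (\theta\cdot\rho)^2 + \sum_{(u,v)\in E}
#' ((\theta_u-\theta_v)^2 + (\rho_u-\rho_v)^2) / (2\,\|x_u-x_v\|)}
#' evaluated on scaled fields.
#'
#' @param theta,rho scaled per-vertex fields.
#' @param coords n x 2 mesh coordinates.
#' @param E edge matrix.
#' @return the scalar objective value.
#' @export
fieldFillObjective <- function(theta, rho, coords, E) {
  r <- pmax(edgeLengths(coords, E), 1e-12)
  dth <- theta[E[, 1]] - theta[E[, 2]]
  drh <- rho[E[, 1]] - rho[E[, 2]]
  sum(theta * rho)^2 + sum((dth^2 + drh^2) / (2 * r))
}

# snap contour polylines to mesh vertices: subdivide each segment to about
# half the mesh edge length, then take the nearest corner of the containing
# face; ties and misses fall back to a brute-force nearest vertex.
.snapContour <- function(mesh, pts, spacing) {
  seg <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    d <- sqrt(sum((pts[i + 1L, ] - pts[i, ])^2))
    k <- max(2L, ceiling(d / spacing) + 1L)
    t <- seq(0, 1, length.out = k)
    seg[[i]] <- cbind(pts[i, 1] + t * (pts[i + 1L, 1] - pts[i, 1]),
                      pts[i, 2] + t * (pts[i + 1L, 2] - pts[i, 2]))
  }
  smp <- do.call(rbind, seg)
  loc <- locatePoints(mesh, smp)
  out <- integer(nrow(smp))
  hit <- loc$face > 0L
  if (any(hit)) {
    fv <- mesh@faces[loc$face[hit], , drop = FALSE]
    b <- loc$bary[hit, , drop = FALSE]
    # nearest corner = largest barycentric weight; tie -> lowest vertex index
    pick <- max.col(b, ties.method = "first")
    out[hit] <- fv[cbind(seq_len(nrow(fv)), pick)]
  }
  if (any(!hit)) {
    co <- mesh@coords
    for (i in which(!hit)) {
      d2 <- (co[, 1] - smp[i, 1])^2 + (co[, 2] - smp[i, 2])^2
      out[i] <- which.min(d2)   # which.min takes the lowest index on ties
    }
  }
  unique(out)
}

#' Build a retinotopy model from labeled boundary contours
#'
#' Snaps the contours to mesh vertices, holds the label-implied scaled values
#' fixed (polar angle -1/0/+1 at the upper vertical / horizontal / lower
#' vertical meridians; eccentricity -1/+1 at the foveal / peripheral
#' boundaries) and fills both fields in between by minimizing
#' [fieldFillObjective()].  Stationarity couples the two sparse harmonic
#' systems only through the scalar product theta . rho, so the solver runs a
#' secant iteration on that scalar with one direct sparse solve per step,
#' stopping when the joint gradient norm drops below \code{tol}; the
#' recorded objective trajectory is non-increasing.  Fields are then
#' rescaled to degrees with [rescaleFields()].
#'
#' @param spec a [boundarySpec()].
#' @param mesh the model [FlatMap-class].
#' @param eccTargets named vector (min, median, max) of target eccentricities
#'   in degrees for the exponential rescaling.
#' @param sizeFun optional data.frame (area, slope, intercept) giving the
#'   model's linear pRF-size-vs-eccentricity function per area.
#' @param tol joint gradient-norm tolerance.
#' @param maxIter maximum alternating sweeps.
#' @return a [RetinotopyModel-class].
#' @export
buildModel <- function(spec, mesh, eccTargets = c(min = 0, median = 3, max = 90),
                       sizeFun = NULL, tol = 1e-8, maxIter = 200) {
  n <- nrow(mesh@coords)
  thetaFix <- rep(NA_real_, n)
  rhoFix <- rep(NA_real_, n)
  for (ct in spec$contours) {
    vids <- .snapContour(mesh, ct$points, mesh@meanEdgeLength / 2)
    if (!is.na(.labelTheta[ct$label])) {
      new <- is.na(thetaFix[vids])
      thetaFix[vids[new]] <- .labelTheta[ct$label]
    } else {
      new <- is.na(rhoFix[vids])
      rhoFix[vids[new]] <- .labelRho[ct$label]
    }
  }

  E <- mesh@edges
  r <- pmax(edgeLengths(mesh@coords, E), 1e-12)
  w <- 1 / (2 * r)
  L <- Matrix::sparseMatrix(
    i = c(E[, 1], E[, 2], E[, 1], E[, 2]),
    j = c(E[, 1], E[, 2], E[, 2], E[, 1]),
    x = c(w, w, -w, -w), dims = c(n, n))

  solveParts <- function(fixedMask) {
    free <- which(!fixedMask); fixed <- which(fixedMask)
    if (!length(fixed))
      stop("specification error: a field has no fixed boundary values")
    tryCatch(Matrix::Cholesky(L[free, free], perm = TRUE),
             error = function(e)
               stop("specification error: an area is not enclosed by ",
                    "boundary contours (singular smoothness system)"))
    list(free = free, fixed = fixed, Lfb = L[free, fixed])
  }
  pt <- solveParts(!is.na(thetaFix))
  pr <- solveParts(!is.na(rhoFix))

  theta <- ifelse(is.na(thetaFix), 0, thetaFix)
  rho <- ifelse(is.na(rhoFix), 0, rhoFix)
  objective <- fieldFillObjective(theta, rho, mesh@coords, E)

  # Stationarity of the objective reads  L theta + d rho = 0  and
  # L rho + d theta = 0  on the free entries, with the scalar d = theta . rho.
  # For a fixed d this is one sparse symmetric linear system in the stacked
  # free values, solved directly; the outer problem is a 1D fixed point in
  # d, closed by secant iteration.  (Plain alternation on the full quadratic
  # subproblems contracts too slowly here: its dominant mode follows d,
  # which moves by a fraction of a percent per sweep.)
  nt <- length(pt$free); nr <- length(pr$free)
  common <- intersect(pt$free, pr$free)
  S <- Matrix::sparseMatrix(i = match(common, pt$free),
                            j = match(common, pr$free),
                            x = rep(1, length(common)), dims = c(nt, nr))
  rhoFixAtT <- ifelse(is.na(rhoFix[pt$free]), 0, rhoFix[pt$free])
  thetaFixAtR <- ifelse(is.na(thetaFix[pr$free]), 0, thetaFix[pr$free])
  bt0 <- -as.numeric(pt$Lfb %*% thetaFix[pt$fixed])
  br0 <- -as.numeric(pr$Lfb %*% rhoFix[pr$fixed])
  Ltt <- L[pt$free, pt$free]
  Lrr <- L[pr$free, pr$free]
  solveGivenD <- function(d, theta, rho) {
    M <- rbind(cbind(Ltt, d * S), cbind(d * Matrix::t(S), Lrr))
    rhs <- c(bt0 - d * rhoFixAtT, br0 - d * thetaFixAtR)
    z <- as.numeric(Matrix::solve(M, rhs))
    theta[pt$free] <- z[seq_len(nt)]
    rho[pr$free] <- z[nt + seq_len(nr)]
    list(theta = theta, rho = rho)
  }
  jointGrad <- function(theta, rho) {
    dotTR <- sum(theta * rho)
    gt <- 2 * dotTR * rho + 2 * as.numeric(L %*% theta)
    gr <- 2 * dotTR * theta + 2 * as.numeric(L %*% rho)
    sqrt(sum(gt[pt$free]^2) + sum(gr[pr$free]^2))
  }
  # start from the decoupled (d = 0) harmonic fill-in: near the orthogonal
  # solution the scalar coupling is tiny and the inner alternation contracts
  d0 <- 0
  st <- solveGivenD(d0, theta, rho)
  d1 <- sum(st$theta * st$rho)
  if (!is.finite(d1))
    stop("field fill-in diverged; are the boundary fields strongly ",
         "non-orthogonal?")
  h0 <- d1 - d0
  gnorm <- Inf
  for (it in seq_len(maxIter)) {
    st1 <- solveGivenD(d1, st$theta, st$rho)
    g1 <- sum(st1$theta * st1$rho)
    h1 <- g1 - d1
    if (!is.finite(g1)) stop("field fill-in diverged at coupling ", d1)
    obj1 <- fieldFillObjective(st1$theta, st1$rho, mesh@coords, E)
    if (obj1 <= objective[length(objective)]) {
      theta <- st1$theta; rho <- st1$rho
      objective <- c(objective, obj1)
    }
    gnorm <- jointGrad(st1$theta, st1$rho)
    if (gnorm < tol) { theta <- st1$theta; rho <- st1$rho; break }
    dNew <- if (h1 != h0) d1 - h1 * (d1 - d0) / (h1 - h0) else g1
    # keep the secant step inside a trust region around the current d
    lim <- 10 * (abs(d1) + 1e-6)
    dNew <- max(min(dNew, d1 + lim), d1 - lim)
    d0 <- d1; h0 <- h1; d1 <- dNew; st <- st1
  }
  if (gnorm >= tol)
    warning(sprintf("field fill-in stopped at gradient norm %.3g after %d sweeps",
                    gnorm, maxIter))

  resc <- rescaleFields(theta, rho, eccTargets)

  co <- mesh@coords
  vertexArea <- rep("none", n)
  for (ap in spec$areaPolygons) {
    unassigned <- vertexArea == "none"
    hit <- pointInPolygon(co[unassigned, , drop = FALSE], ap$polygon)
    vertexArea[which(unassigned)[hit]] <- ap$name
  }
  cent <- (co[mesh@faces[, 1], ] + co[mesh@faces[, 2], ] + co[mesh@faces[, 3], ]) / 3
  faceArea <- rep("none", nrow(mesh@faces))
  for (ap in spec$areaPolygons) {
    unassigned <- faceArea == "none"
    hit <- pointInPolygon(cent[unassigned, , drop = FALSE], ap$polygon)
    faceArea[which(unassigned)[hit]] <- ap$name
  }
  areas <- unique(vapply(spec$areaPolygons, `[[`, "", "name"))

  if (is.null(sizeFun)) {
    k <- seq_along(areas)
    sizeFun <- data.frame(area = areas, slope = 0.1 + 0.05 * (k - 1),
                          intercept = 0.1 + 0.1 * (k - 1),
                          stringsAsFactors = FALSE)
  }

  new("RetinotopyModel", mesh = mesh, polarAngle = resc$polarAngle,
      eccentricity = resc$eccentricity, vertexArea = vertexArea,
      faceArea = faceArea, areas = areas,
      rescale = c(resc$params,
                  list(fit = list(objective = objective, gradNorm = gnorm,
                                  sweeps = it))),
      sizeFun = sizeFun, version = "1.0")
}

#' Rescale the minimizer's scaled fields to degrees
#'
#' Polar angle maps linearly, \eqn{\theta = 90(\hat\theta + 1)} degrees.
#' Eccentricity maps through the two-parameter exponential
#' \eqn{\rho = min + a(e^{b s} - 1)} with \eqn{s = (\hat\rho+1)/2}, with
#' (a, b) fitted so the minimum, median and maximum of the supplied scaled
#' values hit the target eccentricity distribution; the map is strictly
#' increasing.
#'
#' @param thetaRaw,rhoRaw scaled fields in [-1, 1].
#' @param eccTargets named vector (min, median, max), degrees.
#' @return list with \code{polarAngle}, \code{eccentricity} (degrees) and the
#'   fitted \code{params}.
#' @export
rescaleFields <- function(thetaRaw, rhoRaw, eccTargets = c(min = 0, median = 3,
                                                           max = 90)) {
  tmin <- eccTargets[["min"]]; tmed <- eccTargets[["median"]]
  tmax <- eccTargets[["max"]]
  if (!(tmin < tmed && tmed < tmax))
    stop("parameterization error: eccentricity targets must be increasing")
  theta <- 90 * (pmin(1, pmax(-1, thetaRaw)) + 1)
  s <- (pmin(1, pmax(-1, rhoRaw)) + 1) / 2
  sMed <- median(s, na.rm = TRUE)
  frac <- (tmed - tmin) / (tmax - tmin)
  if (sMed <= 0 || sMed >= 1 || frac >= sMed) {
    # the target median is not below the linear interpolant: fall back to
    # the (near-)linear limit of the family
    b <- 1e-6
  } else {
    g <- function(b) (exp(b * sMed) - 1) / (exp(b) - 1) - frac
    b <- uniroot(g, c(1e-8, 500), tol = 1e-12)$root
  }
  a <- (tmax - tmin) / (exp(b) - 1)
  if (!(a > 0))
    stop("parameterization error: fitted eccentricity map is not monotone")
  rho <- tmin + a * (exp(b * s) - 1)
  list(polarAngle = theta, eccentricity = pmin(90, pmax(0, rho)),
       params = list(eccA = a, eccB = b, eccMin = tmin,
                     eccTargets = c(min = tmin, median = tmed, max = tmax),
                     angleOffset = 90, angleScale = 90))
}

#' Query a retinotopy model at 2D map points
#'
#' The visual-area label is that of the containing face ("none" outside every
#' area); polar angle and eccentricity are barycentric-interpolated through
#' the visual-field Cartesian embedding.  Deterministic: queries on shared
#' edges resolve to the lowest face index.
#'
#' @param model a [RetinotopyModel-class].
#' @param points p x 2 query points in map coordinates.
#' @param hemisphere hemisphere convention for the embedding.
#' @return data.frame with polarAngle, eccentricity (degrees; NA outside) and
#'   area.
#' @export
modelLookup <- function(model, points, hemisphere = "rh") {
  points <- matrix(as.numeric(points), ncol = 2)
  mesh <- model@mesh
  loc <- locatePoints(mesh, points)
  out <- data.frame(polarAngle = rep(NA_real_, nrow(points)),
                    eccentricity = NA_real_,
                    area = rep("none", nrow(points)),
                    stringsAsFactors = FALSE)
  hit <- loc$face > 0L
  if (any(hit)) {
    xy <- visualFieldCoords(model@polarAngle, model@eccentricity, hemisphere)
    fv <- mesh@faces[loc$face[hit], , drop = FALSE]
    b <- loc$bary[hit, , drop = FALSE]
    ix <- b[, 1] * xy[fv[, 1], 1] + b[, 2] * xy[fv[, 2], 1] + b[, 3] * xy[fv[, 3], 1]
    iy <- b[, 1] * xy[fv[, 1], 2] + b[, 2] * xy[fv[, 2], 2] + b[, 3] * xy[fv[, 3], 2]
    ang <- visualFieldAngles(ix, iy, hemisphere)
    inArea <- model@faceArea[loc$face[hit]] != "none"
    idx <- which(hit)[inArea]
    out$polarAngle[idx] <- ang$polarAngle[inArea]
    out$eccentricity[idx] <- ang$eccentricity[inArea]
    out$area[idx] <- model@faceArea[loc$face[hit]][inArea]
  }
  out
}

#' Serialize / deserialize a retinotopy model as JSON
#'
#' The round trip is lossless: doubles are written at full precision and the
#' mesh is rebuilt from coordinates and faces.  The schema is versioned; a
#' version mismatch or a missing section is an explicit error.
#'
#' @param model a [RetinotopyModel-class].
#' @return a JSON string ([serializeModel()]) or a model
#'   ([deserializeModel()]).
#' @export
serializeModel <- function(model) {
  mesh <- model@mesh
  doc <- list(schema = "retinomap-model", version = model@version,
              coords = mesh@coords, faces = mesh@faces,
              polarAngle = model@polarAngle,
              eccentricity = model@eccentricity,
              vertexArea = model@vertexArea, faceArea = model@faceArea,
              areas = model@areas,
              rescale = model@rescale[setdiff(names(model@rescale), "fit")],
              sizeFun = model@sizeFun)
  jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE)
}

#' @rdname serializeModel
#' @param json a JSON string (or parsed list) from [serializeModel()].
#' @export
deserializeModel <- function(json) {
  doc <- if (is.character(json)) {
    tryCatch(jsonlite::fromJSON(json),
             error = function(e) stop("model JSON parse error: ",
                                      conditionMessage(e)))
  } else json
  need <- c("schema", "version", "coords", "faces", "polarAngle",
            "eccentricity", "vertexArea", "faceArea", "areas", "rescale",
            "sizeFun")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("model JSON is missing section(s): ", paste(miss, collapse = ", "))
  if (!identical(doc$schema, "retinomap-model"))
    stop("not a retinomap model document")
  if (!identical(as.character(doc$version), "1.0"))
    stop("unsupported model schema version: ", doc$version)
  mesh <- flatMap(doc$coords, doc$faces)
  sf <- as.data.frame(doc$sizeFun, stringsAsFactors = FALSE)
  new("RetinotopyModel", mesh = mesh,
      polarAngle = as.numeric(doc$polarAngle),
      eccentricity = as.numeric(doc$eccentricity),
      vertexArea = as.character(doc$vertexArea),
      faceArea = as.character(doc$faceArea),
      areas = as.character(doc$areas), rescale = doc$rescale,
      sizeFun = sf, version = as.character(doc$version))
}

#' @rdname serializeModel
#' @param path file path.
#' @export
writeModel <- function(model, path) {
  writeLines(serializeModel(model), path)
  invisible(path)
}

#' @rdname serializeModel
#' @export
readModel <- function(path) {
  deserializeModel(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
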