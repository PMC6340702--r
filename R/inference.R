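## The user-facing pipeline: visual-field coordinate conventions, subject
## preparation (threshold + uniform resampling), Bayesian map inference, and
## the per-area linear pRF-size fit.

#' Visual-field Cartesian embedding of retinotopic coordinates
#'
#' Polar angle is measured from the upper vertical meridian (0 deg) through
#' the horizontal (90) to the lower vertical meridian (180) within one
#' hemifield; the contralateral sign of x is carried by the hemisphere flag
#' ("lh" cortex sees the right visual field, x > 0; "rh" the left, x < 0).
#' \code{x = sgn * rho * sin(theta)}, \code{y = rho * cos(theta)}.
#'
#' @param angleDeg polar angle, degrees.
#' @param eccenDeg eccentricity, degrees.
#' @param hemisphere "lh" or "rh".
#' @return n x 2 matrix of visual-field coordinates (degrees).
#' @export
visualFieldCoords <- function(angleDeg, eccenDeg, hemisphere = "rh") {
  sgn <- if (hemisphere == "rh") -1 else 1
  th <- angleDeg * pi / 180
  cbind(x = sgn * eccenDeg * sin(th), y = eccenDeg * cos(th))
}

#' @rdname visualFieldCoords
#' @param x,y visual-field Cartesian coordinates (degrees).
#' @return \code{visualFieldAngles}: list with \code{polarAngle} and
#'   \code{eccentricity}; the round trip with [visualFieldCoords()] is exact
#'   to machine precision for angles in (-180, 180].
#' @export
visualFieldAngles <- function(x, y, hemisphere = "rh") {
  sgn <- if (hemisphere == "rh") -1 else 1
  list(polarAngle = atan2(sgn * x, y) * 180 / pi,
       eccentricity = sqrt(x^2 + y^2))
}

#' Construct a RetinotopyData object
#'
#' @param vertexId integer vertex ids.
#' @param polarAngle,eccentricity,prfSize measurements, degrees.
#' @param varianceExplained pRF-model variance explained, in [0, 1].
#' @param hemisphere "lh" or "rh".
#' @return a [RetinotopyData-class].
#' @export
retinotopyData <- function(vertexId, polarAngle, eccentricity,
                           prfSize = rep(NA_real_, length(vertexId)),
                           varianceExplained = rep(1, length(vertexId)),
                           hemisphere = "rh") {
  new("RetinotopyData", vertexId = as.integer(vertexId),
      polarAngle = as.numeric(polarAngle),
      eccentricity = as.numeric(eccentricity),
      prfSize = as.numeric(prfSize),
      varianceExplained = as.numeric(varianceExplained),
      hemisphere = hemisphere)
}

#' Threshold and resample subject data onto a uniform mesh
#'
#' Vertices with variance explained strictly below the threshold are
#' excluded from anchor generation (exactly at the threshold is retained).
#' The map and data are resampled onto a uniform triangular lattice;
#' retinotopic fields travel through their visual-field embedding weighted by
#' variance explained, so unmeasured vertices do not pollute their
#' neighbors, and the weights themselves are interpolated and re-thresholded.
#'
#' @param map the subject's [FlatMap-class] (prior-aligned coordinates).
#' @param data a [RetinotopyData-class] keyed to the map's vertices.
#' @param threshold variance-explained threshold.
#' @param resolution lattice edge length (default: the map's mean edge
#'   length).
#' @return list with \code{map} (uniform mesh), \code{data} (resampled
#'   measurements) and \code{sourceMap}.
#' @export
prepareSubject <- function(map, data, threshold = 0.1,
                           resolution = meanEdgeLength(map)) {
  n <- nrow(map@coords)
  if (any(data@vertexId < 1L | data@vertexId > n))
    stop("data vertex ids do not index the map")
  omega <- rep(0, n)
  emb <- matrix(0, n, 2)
  size <- rep(0, n)
  good <- is.finite(data@polarAngle) & is.finite(data@eccentricity) &
    !is.na(data@varianceExplained)
  vid <- data@vertexId[good]
  omega[vid] <- data@varianceExplained[good]
  emb[vid, ] <- visualFieldCoords(data@polarAngle[good],
                                  data@eccentricity[good], data@hemisphere)
  size[vid] <- ifelse(is.finite(data@prfSize[good]), data@prfSize[good], 0)
  if (sum(omega >= threshold) < 10L)
    stop("insufficient data: fewer than 10 vertices at or above the ",
         "variance-explained threshold")

  fields <- cbind(wx = omega * emb[, 1], wy = omega * emb[, 2],
                  ws = omega * size, w = omega)
  rs <- uniformResample(map, fields, resolution)
  w <- rs$fields[, "w"]
  ok <- is.finite(w) & w > 1e-12
  ang <- rep(NA_real_, nrow(rs$fields))
  ecc <- rep(NA_real_, nrow(rs$fields))
  sz <- rep(NA_real_, nrow(rs$fields))
  if (any(ok)) {
    va <- visualFieldAngles(rs$fields[ok, "wx"] / w[ok],
                            rs$fields[ok, "wy"] / w[ok], data@hemisphere)
    ang[ok] <- va$polarAngle
    ecc[ok] <- va$eccentricity
    sz[ok] <- rs$fields[ok, "ws"] / w[ok]
  }
  w[!is.finite(w)] <- 0
  newData <- retinotopyData(seq_len(nrow(rs$map@coords)), ang, ecc, sz, w,
                            data@hemisphere)
  if (sum(w >= threshold) < 10L)
    stop("insufficient data: fewer than 10 resampled vertices at or above ",
         "the variance-explained threshold")
  list(map = rs$map, data = newData, sourceMap = map)
}

#' Prior-alone prediction: look the model up at the current coordinates
#'
#' @param map the subject's [FlatMap-class] in prior-aligned coordinates.
#' @param model a [RetinotopyModel-class].
#' @param hemisphere "lh" or "rh".
#' @return an [InferredMaps-class].
#' @export
priorMaps <- function(map, model, hemisphere = "rh") {
  .lookupToMaps(model, map@coords, hemisphere,
                provenance = list(mode = "prior", model = model@version))
}

.lookupToMaps <- function(model, pts, hemisphere, provenance,
                          sizes = NULL) {
  lk <- modelLookup(model, pts, hemisphere)
  if (is.null(sizes)) {
    # without a data-driven fit, sizes come from the model's own linear
    # size-vs-eccentricity function
    sizes <- rep(NA_real_, nrow(lk))
    for (i in seq_len(nrow(model@sizeFun))) {
      idx <- lk$area == model@sizeFun$area[i]
      sizes[idx] <- pmax(model@sizeFun$slope[i] * lk$eccentricity[idx] +
                           model@sizeFun$intercept[i], 0.01)
    }
  }
  new("InferredMaps", vertexId = seq_len(nrow(lk)),
      polarAngle = lk$polarAngle, eccentricity = lk$eccentricity,
      area = lk$area, prfSize = sizes, provenance = provenance)
}

#' Bayesian inference of a subject's retinotopic maps
#'
#' Thresholds and resamples the data, builds anchors against the model, runs
#' the topology-preserving registration, and reads the model values at every
#' native vertex's registered position.  Vertex identity is preserved
#' throughout: the displacement field fitted on the uniform mesh is
#' interpolated back to the native vertex positions, so no registration
#' inversion is needed.  With no above-threshold measurements the prior
#' remains the prediction: the output is identical to [priorMaps()].
#'
#' @param map the subject's [FlatMap-class] in prior-aligned coordinates.
#' @param data a [RetinotopyData-class] (or NULL for prior-alone).
#' @param model a [RetinotopyModel-class].
#' @param config a [MinimizerConfig-class].
#' @param threshold variance-explained threshold.
#' @param resolution resampling lattice edge length.
#' @param fieldSignFactor,sizeSigma anchor weight factors (see
#'   [buildAnchors()]).
#' @param fitSizes fit per-area linear pRF-size functions from the data
#'   (areas with a degenerate design are left NA).
#' @return list with \code{maps} (an [InferredMaps-class]),
#'   \code{registration} (NULL for prior-alone), \code{anchors},
#'   \code{system} and \code{resampled}.
#' @export
inferMaps <- function(map, data, model, config = minimizerConfig(),
                      threshold = 0.1, resolution = meanEdgeLength(map),
                      fieldSignFactor = 0.25, sizeSigma = log(2),
                      fitSizes = TRUE) {
  hemi <- if (is.null(data)) "rh" else data@hemisphere
  nAbove <- if (is.null(data)) 0L else
    sum(data@varianceExplained >= threshold & is.finite(data@polarAngle) &
          is.finite(data@eccentricity), na.rm = TRUE)
  if (nAbove == 0L) {
    return(list(maps = priorMaps(map, model, hemi), registration = NULL,
                anchors = NULL, system = NULL, resampled = NULL,
                registeredPositions = map@coords))
  }
  prep <- prepareSubject(map, data, threshold, resolution)
  sys <- registrationSystem(prep$map)
  anchors <- buildAnchors(prep$data, model, sys, threshold,
                          fieldSignFactor, sizeSigma)
  reg <- registerMap(sys, anchors, config)
  disp <- reg@coords - sys@x0
  dNative <- barycentricInterpolate(prep$map, disp, map@coords)
  dNative[!is.finite(dNative)] <- 0
  xReg <- map@coords + dNative

  lk <- modelLookup(model, xReg, hemi)
  sizes <- NULL
  if (fitSizes) {
    sizes <- rep(NA_real_, nrow(lk))
    szFit <- .fitSizesByArea(data, lk, model@areas)
    for (area in names(szFit)) {
      f <- szFit[[area]]
      idx <- lk$area == area & is.finite(lk$eccentricity)
      sizes[idx] <- pmax(f["slope"] * lk$eccentricity[idx] + f["intercept"],
                         0.01)
    }
  }
  maps <- new("InferredMaps", vertexId = seq_len(nrow(lk)),
              polarAngle = lk$polarAngle, eccentricity = lk$eccentricity,
              area = lk$area, prfSize = if (is.null(sizes))
                rep(NA_real_, nrow(lk)) else sizes,
              provenance = list(mode = "bayesian", model = model@version,
                                seed = config@seed,
                                configHash = configHash(list(
                                  steps = config@steps,
                                  noiseScale = config@noiseScale,
                                  threshold = threshold,
                                  resolution = resolution))))
  list(maps = maps, registration = reg, anchors = anchors, system = sys,
       resampled = prep, registeredPositions = xReg)
}

# per-area weighted size fits from native measurements vs inferred
# eccentricity; degenerate areas are skipped (their size stays NA)
.fitSizesByArea <- function(data, lk, areas) {
  out <- list()
  for (area in areas) {
    idx <- which(lk$area[data@vertexId] == area &
                   is.finite(data@prfSize) & data@prfSize > 0 &
                   data@varianceExplained > 0 &
                   is.finite(lk$eccentricity[data@vertexId]))
    if (length(idx) < 2L) next
    fit <- tryCatch(
      fitPrfSize(data@prfSize[idx], lk$eccentricity[data@vertexId[idx]],
                 data@varianceExplained[idx]),
      error = function(e) NULL)
    if (!is.null(fit))
      out[[area]] <- c(slope = fit$slope, intercept = fit$intercept)
  }
  out
}

#' Weighted linear fit of pRF size against eccentricity
#'
#' Weighted least squares of measured pRF size on (inferred) eccentricity;
#' the fitted line predicts a size for every vertex, floored at a small
#' positive constant.
#'
#' @param sObs measured pRF sizes.
#' @param eccen (inferred) eccentricities, same length.
#' @param weights non-negative weights (variance explained).
#' @param predictEccen eccentricities at which to predict (default: the fit
#'   inputs).
#' @param floor lower bound for predicted sizes, degrees.
#' @return list with \code{slope}, \code{intercept} and \code{prfSize}.
#' @export
fitPrfSize <- function(sObs, eccen, weights = rep(1, length(sObs)),
                       predictEccen = eccen, floor = 0.01) {
  ok <- is.finite(sObs) & is.finite(eccen) & is.finite(weights) & weights > 0
  if (sum(ok) < 2L || length(unique(eccen[ok])) < 2L)
    stop("degenerate design: need at least two distinct eccentricities ",
         "with positive weight")
  fit <- lm(sObs[ok] ~ eccen[ok], weights = weights[ok])
  m <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  list(slope = m, intercept = b,
       prfSize = pmax(m * predictEccen + b, floor))
}
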