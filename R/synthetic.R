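## Synthetic fixtures: a banded ground-truth retinotopy model, smoothly
## warped "subjects", and noisy pRF measurements with the failure modes the
## method is designed to survive (meridian dropout, coherent artifact blobs,
## a limited stimulus aperture).  Everything is seeded and deterministic.

#' Configuration of the synthetic generator
#'
#' The model is a quarterfield band stack: V1 (a full hemifield, scaled
#' polar angle -1..1) flanked by mirror-image quarterfield bands for V2 and
#' V3 ventrally and dorsally, plus an outer band on each side (hV4
#' ventrally, V3a dorsally) so that anchors from non-target areas exert
#' realistic pull.  The quarterfield band height is 1 map unit; the lattice
#' edge length defaults to 1/40 of it so that the 20-epsilon cap on anchor
#' widths stays well below the band height (the regime the method assumes).
#'
#' @param resolution lattice edge length, map units.
#' @param fieldWidth eccentricity extent of the strip, map units.
#' @param eccTargets eccentricity rescale targets (min, median, max), deg.
#' @param warpAmplitude mean vertex displacement of the subject warp, map
#'   units (default 5 * resolution).
#' @param warpScale Gaussian bump width of the warp field, map units.
#' @param warpBumps number of random bumps.
#' @param warpTaper c(x, y) boundary taper widths of the warp field, map
#'   units (see [warpSubject()]).
#' @param warpAxisWeights relative (x, y) amplitudes of the warp: individual
#'   variation in these maps is dominated by polar-angle-axis boundary
#'   shifts, with milder eccentricity-axis compression.
#' @param noiseSdAngle per-scan polar-angle noise sd, degrees.
#' @param noiseSdEccen per-scan log-eccentricity noise sd (multiplicative).
#' @param noiseSdSize per-scan pRF-size noise sd, degrees.
#' @param omegaShape Beta shape parameters of the variance-explained draw.
#' @param dropoutHalfWidth half-width of the vertical-meridian dropout band,
#'   degrees of polar angle.
#' @param blobCount,blobRadius artifact blobs: count and radius (map units);
#'   blob positions and offsets are subject-level (shared across scans).
#' @param blobAngleOffset coherent polar-angle offset inside blobs, degrees.
#' @param aperture stimulus aperture, degrees of eccentricity; vertices
#'   beyond it are effectively unmeasured.
#' @param lowOmega multiplier applied to variance explained in dropout
#'   bands, blobs and beyond the aperture.
#' @param nScans number of training scans.
#' @param nValidationScans number of held-out scans averaged into the
#'   validation dataset.
#' @param seed RNG seed.
#' @return a classed list of settings.
#' @export
syntheticConfig <- function(resolution = 0.025, fieldWidth = 1,
                            eccTargets = c(min = 0, median = 3, max = 90),
                            warpAmplitude = NULL, warpScale = 2.5,
                            warpBumps = 12, warpTaper = c(0.3, 0.8),
                            warpAxisWeights = c(0.15, 1),
                            noiseSdAngle = 20, noiseSdEccen = 0.1,
                            noiseSdSize = 0.2, omegaShape = c(2.5, 3),
                            dropoutHalfWidth = 10, blobCount = 3,
                            blobRadius = 0.08, blobAngleOffset = 25,
                            aperture = 12, lowOmega = 0.01,
                            nScans = 6, nValidationScans = 6, seed = 1) {
  if (is.null(warpAmplitude)) warpAmplitude <- 5 * resolution
  cfg <- list(resolution = resolution, fieldWidth = fieldWidth,
              eccTargets = eccTargets, warpAmplitude = warpAmplitude,
              warpScale = warpScale, warpBumps = warpBumps,
              warpTaper = warpTaper, warpAxisWeights = warpAxisWeights,
              noiseSdAngle = noiseSdAngle, noiseSdEccen = noiseSdEccen,
              noiseSdSize = noiseSdSize, omegaShape = omegaShape,
              dropoutHalfWidth = dropoutHalfWidth, blobCount = blobCount,
              blobRadius = blobRadius, blobAngleOffset = blobAngleOffset,
              aperture = aperture, lowOmega = lowOmega, nScans = nScans,
              nValidationScans = nValidationScans, seed = seed)
  stopifnot(all(vapply(cfg[c("noiseSdAngle", "noiseSdEccen", "noiseSdSize",
                             "warpAmplitude")], function(v) v >= 0,
                       logical(1))))
  structure(cfg, class = "syntheticConfig")
}

.modelCache <- new.env(parent = emptyenv())

#' Build the banded ground-truth retinotopy model
#'
#' Deterministic given the configuration (no RNG is consumed); built via
#' [buildModel()] from a generated [boundarySpec()], so it exercises the
#' same field fill-in machinery as a hand-drawn model would.  Adjacent
#' bands are mirror images, so their face-wise field signs alternate.
#'
#' @param cfg a [syntheticConfig()].
#' @param cache reuse a previously built model for an identical geometry.
#' @return a [RetinotopyModel-class].
#' @export
makeSyntheticModel <- function(cfg = syntheticConfig(), cache = TRUE) {
  key <- configHash(cfg[c("resolution", "fieldWidth", "eccTargets")])
  if (cache && !is.null(.modelCache[[key]])) return(.modelCache[[key]])

  xw <- cfg$fieldWidth
  lat <- makeTriangularLattice(c(0, xw), c(-4, 4), cfg$resolution)
  mesh <- flatMap(lat$coords, lat$faces,
                  metadata = list(generator = "syntheticBandModel",
                                  resolution = cfg$resolution))
  xs <- range(mesh@coords[, 1])
  line <- function(y) cbind(c(xs[1], xs[2]), c(y, y))
  contours <- list(
    list(points = cbind(c(0, 0), c(-4, 4)), label = "foveal",
         areas = c("none", "none")),
    list(points = cbind(c(xw, xw), c(-4, 4)), label = "peripheral",
         areas = c("none", "none")),
    list(points = line(-1), label = "upper_vertical_meridian",
         areas = c("V1", "V2")),
    list(points = line(1), label = "lower_vertical_meridian",
         areas = c("V1", "V2")),
    list(points = line(-2), label = "horizontal_meridian",
         areas = c("V2", "V3")),
    list(points = line(2), label = "horizontal_meridian",
         areas = c("V2", "V3")),
    list(points = line(-3), label = "upper_vertical_meridian",
         areas = c("V3", "hV4")),
    list(points = line(3), label = "lower_vertical_meridian",
         areas = c("V3", "V3a")),
    list(points = line(-4), label = "horizontal_meridian",
         areas = c("hV4", "none")),
    list(points = line(4), label = "horizontal_meridian",
         areas = c("V3a", "none")))
  pad <- cfg$resolution
  rect <- function(y0, y1) cbind(c(xs[1] - pad, xs[2] + pad, xs[2] + pad,
                                   xs[1] - pad),
                                 c(y0, y0, y1, y1))
  areaPolygons <- list(
    list(name = "V1", polygon = rect(-1, 1)),
    list(name = "V2", polygon = rect(-2, -1)),
    list(name = "V2", polygon = rect(1, 2)),
    list(name = "V3", polygon = rect(-3, -2)),
    list(name = "V3", polygon = rect(2, 3)),
    list(name = "hV4", polygon = rect(-4 - pad, -3)),
    list(name = "V3a", polygon = rect(3, 4 + pad)))
  spec <- boundarySpec(contours, areaPolygons)
  model <- buildModel(spec, mesh, cfg$eccTargets)
  if (cache) .modelCache[[key]] <- model
  model
}

#' Warp a model mesh into a synthetic subject
#'
#' Adds a smooth displacement field (a sum of random Gaussian bumps of width
#' \code{scale}) rescaled so the mean vertex displacement equals
#' \code{amplitude}, then shrunk if necessary until the warped mesh stays
#' admissible (no corner angle outside (0, pi)).  Amplitude 0 is the
#' identity.
#'
#' @param mesh the model [FlatMap-class].
#' @param amplitude target mean vertex displacement, map units.
#' @param scale Gaussian bump width, map units.
#' @param nBumps number of bumps.
#' @param seed RNG seed.
#' @param taper c(x, y) widths of the smooth boundary tapers, map units.
#'   Each displacement component fades to zero toward the map edges along
#'   its own axis: the foveal and peripheral columns and the outer map rim
#'   are anatomically anchored, so a realistic structure-function warp is
#'   interior along the axis it displaces.
#' @param axisWeights relative amplitude of the (x, y) displacement
#'   components; individual variation in these maps is predominantly along
#'   the polar-angle axis (boundary shifts), with milder eccentricity-axis
#'   compression.
#' @param maxStrain admissibility bound: after the warp every edge must keep
#'   a length ratio in [1 - maxStrain, 1 + maxStrain] and every corner angle
#'   a comfortable margin, so both the warp and its inverse stay strictly
#'   inside the registration's edge-length wells.
#' @return list: \code{map} (warped [FlatMap-class]),
#'   \code{truePositions} (the unwarped coordinates, i.e. the inverse
#'   correspondence), \code{displacement}.
#' @export
warpSubject <- function(mesh, amplitude, scale = 2.5, nBumps = 12, seed = 1,
                        taper = c(0.3, 0.8), axisWeights = c(0.15, 1),
                        maxStrain = 0.45) {
  set.seed(as.integer(seed))
  co <- mesh@coords
  n <- nrow(co)
  D <- matrix(0, n, 2)
  if (amplitude > 0) {
    cx <- runif(nBumps, min(co[, 1]), max(co[, 1]))
    cy <- runif(nBumps, min(co[, 2]), max(co[, 2]))
    coefX <- rnorm(nBumps)
    coefY <- rnorm(nBumps)
    for (k in seq_len(nBumps)) {
      g <- exp(-((co[, 1] - cx[k])^2 + (co[, 2] - cy[k])^2) /
                 (2 * scale^2))
      D[, 1] <- D[, 1] + coefX[k] * g
      D[, 2] <- D[, 2] + coefY[k] * g
    }
    # normalize each component to its axis weight before the joint rescale,
    # so chance cancellation in one axis cannot inflate the other
    for (ax in 1:2) {
      r <- sqrt(mean(D[, ax]^2))
      if (r > 0) D[, ax] <- D[, ax] * axisWeights[ax] / r
    }
    smoothstep <- function(d, w) {
      t <- pmin(1, pmax(0, d / w))
      t * t * (3 - 2 * t)
    }
    if (taper[1] > 0)
      D[, 1] <- D[, 1] * smoothstep(pmin(co[, 1] - min(co[, 1]),
                                         max(co[, 1]) - co[, 1]), taper[1])
    if (taper[2] > 0)
      D[, 2] <- D[, 2] * smoothstep(pmin(co[, 2] - min(co[, 2]),
                                         max(co[, 2]) - co[, 2]), taper[2])
    # soft-saturate local peaks (smooth tanh limiter at ~1.75x the mean) and
    # restore the requested mean: keeps the deformation in the low-amplitude
    # regime the elastic terms tolerate, with no rare extreme displacements
    for (pass in 1:2) {
      mbar <- mean(sqrt(rowSums(D^2)))
      if (mbar > 0) D <- D * (amplitude / mbar)
      mag <- sqrt(rowSums(D^2))
      cap <- 1.75 * amplitude
      fac <- ifelse(mag > 1e-12, tanh(mag / cap) * cap / mag, 1)
      D <- D * fac
    }
    mbar <- mean(sqrt(rowSums(D^2)))
    if (mbar > 0) D <- D * (amplitude / mbar)
    r0 <- edgeLengths(co, mesh@edges)
    margin <- 0.05
    shrink <- 1
    admissible <- FALSE
    for (i in 1:25) {
      xw <- co + shrink * D
      a <- cornerAngles(xw, mesh@angleTriples)
      ratio <- edgeLengths(xw, mesh@edges) / r0
      admissible <- all(a > margin & a < pi - margin) &&
        all(ratio > 1 - maxStrain & ratio < 1 + maxStrain)
      if (admissible) break
      shrink <- shrink * 0.8
    }
    if (!admissible)
      stop("warp admissibility unreachable after rescaling")
    if (shrink < 0.5)
      stop("warp admissibility required shrinking below half the requested ",
           "amplitude")
    D <- shrink * D
  }
  warped <- flatMap(co + D, mesh@faces,
                    metadata = c(mesh@metadata,
                                 list(warpSeed = seed, warpAmplitude = amplitude)))
  list(map = warped, truePositions = co, displacement = D)
}

#' Simulate noisy pRF measurements from ground truth
#'
#' Per scan: Gaussian noise on polar angle, log-normal on eccentricity
#' (keeping it positive), Gaussian on pRF size floored at 0.01 deg; variance
#' explained is Beta-distributed, crushed toward zero within the
#' vertical-meridian dropout bands, inside subject-level artifact blobs
#' (which also carry a coherent polar-angle offset), and beyond the stimulus
#' aperture.  When all noise sds are zero the simulation is fully
#' deterministic: observations equal truth and variance explained sits at
#' the Beta mean.
#'
#' @param truth data.frame with polarAngle, eccentricity, prfSize.
#' @param map the subject [FlatMap-class] (for blob geometry).
#' @param cfg a [syntheticConfig()].
#' @param nScans number of scans to simulate.
#' @param seed RNG seed.
#' @return list of [RetinotopyData-class], one per scan.
#' @export
simulatePrfData <- function(truth, map, cfg = syntheticConfig(), nScans = 1,
                            seed = 1) {
  set.seed(as.integer(seed))
  n <- nrow(truth)
  noiseFree <- cfg$noiseSdAngle == 0 && cfg$noiseSdEccen == 0 &&
    cfg$noiseSdSize == 0
  co <- map@coords

  inBlob <- rep(FALSE, n)
  if (cfg$blobCount > 0 && !noiseFree) {
    bx <- runif(cfg$blobCount, min(co[, 1]), max(co[, 1]))
    by <- runif(cfg$blobCount, min(co[, 2]), max(co[, 2]))
    for (k in seq_len(cfg$blobCount))
      inBlob <- inBlob | ((co[, 1] - bx[k])^2 + (co[, 2] - by[k])^2 <=
                            cfg$blobRadius^2)
  }
  nearMeridian <- truth$polarAngle < cfg$dropoutHalfWidth |
    truth$polarAngle > 180 - cfg$dropoutHalfWidth
  beyondAperture <- truth$eccentricity > cfg$aperture
  lowQ <- nearMeridian | inBlob | beyondAperture

  lapply(seq_len(nScans), function(s) {
    ang <- truth$polarAngle
    ecc <- truth$eccentricity
    siz <- truth$prfSize
    if (!noiseFree) {
      ang <- ang + rnorm(n, 0, cfg$noiseSdAngle)
      ecc <- ecc * exp(rnorm(n, 0, cfg$noiseSdEccen))
      siz <- pmax(siz + rnorm(n, 0, cfg$noiseSdSize), 0.01)
      ang[inBlob] <- ang[inBlob] + cfg$blobAngleOffset
      omega <- rbeta(n, cfg$omegaShape[1], cfg$omegaShape[2])
    } else {
      omega <- rep(cfg$omegaShape[1] / sum(cfg$omegaShape), n)
    }
    omega[lowQ] <- omega[lowQ] * cfg$lowOmega
    retinotopyData(seq_len(n), ang, ecc, siz, omega, "rh")
  })
}

#' Average several scans into one dataset
#'
#' Arithmetic averaging of all measured quantities, emulating a longer scan
#' (per-vertex noise sd shrinks as 1/sqrt(k)).
#'
#' @param scans list of [RetinotopyData-class] on identical vertices.
#' @return a [RetinotopyData-class].
#' @export
averageScans <- function(scans) {
  stopifnot(length(scans) >= 1)
  acc <- function(get) Reduce(`+`, lapply(scans, get)) / length(scans)
  retinotopyData(scans[[1]]@vertexId,
                 acc(polarAngle), acc(eccentricity), acc(prfSize),
                 acc(varianceExplained), scans[[1]]@hemisphere)
}

#' Generate a complete synthetic dataset
#'
#' Composes the model builder, the subject warp and the pRF simulator.  The
#' subject's flat-map coordinates are the warped model coordinates (playing
#' the prior-aligned starting position); the ground truth of vertex u is the
#' model evaluated at its unwarped position, which by construction equals the
#' model's stored per-vertex values.  Training scans and a held-out
#' validation average are generated from one seeded stream.
#'
#' @param cfg a [syntheticConfig()].
#' @param dir if non-NULL, fixture files (model JSON, subject mesh OFF,
#'   truth/scan/validation TSVs, manifest JSON) are written there.
#' @param model optionally a prebuilt model for this cfg (skips rebuilding).
#' @return a [SyntheticDataset-class].
#' @export
makeDataset <- function(cfg = syntheticConfig(), dir = NULL, model = NULL) {
  if (is.null(model)) model <- makeSyntheticModel(cfg)
  wp <- warpSubject(model@mesh, cfg$warpAmplitude, cfg$warpScale,
                    cfg$warpBumps, seed = cfg$seed, taper = cfg$warpTaper,
                    axisWeights = cfg$warpAxisWeights)
  sf <- model@sizeFun
  sTrue <- rep(NA_real_, length(model@polarAngle))
  for (i in seq_len(nrow(sf))) {
    idx <- model@vertexArea == sf$area[i]
    sTrue[idx] <- sf$slope[i] * model@eccentricity[idx] + sf$intercept[i]
  }
  truth <- data.frame(polarAngle = model@polarAngle,
                      eccentricity = model@eccentricity,
                      prfSize = sTrue, area = model@vertexArea,
                      stringsAsFactors = FALSE)
  all <- simulatePrfData(truth, wp$map, cfg,
                         cfg$nScans + cfg$nValidationScans,
                         seed = cfg$seed + 1)
  scans <- all[seq_len(cfg$nScans)]
  validation <- averageScans(all[cfg$nScans + seq_len(cfg$nValidationScans)])

  ds <- new("SyntheticDataset", model = model, subjectMap = wp$map,
            truePositions = wp$truePositions, truth = truth, scans = scans,
            validation = validation, config = unclass(cfg), seed = cfg$seed)
  if (!is.null(dir)) writeDataset(ds, dir)
  ds
}

#' @rdname makeDataset
#' @param ds a [SyntheticDataset-class].
#' @return \code{writeDataset}: the directory, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hash <- configHash(ds@config)
  prov <- list(configHash = hash, seed = ds@seed)
  writeModel(ds@model, file.path(dir, "model.json"))
  writeOff(ds@subjectMap@coords, ds@subjectMap@faces,
           file.path(dir, "subject_mesh.off"))
  truthData <- retinotopyData(seq_len(nrow(ds@truth)), ds@truth$polarAngle,
                              ds@truth$eccentricity, ds@truth$prfSize,
                              rep(1, nrow(ds@truth)), "rh")
  writePrfTable(truthData, file.path(dir, "truth.tsv"), prov,
                extra = data.frame(visual_area = ds@truth$area))
  files <- c("model.json", "subject_mesh.off", "truth.tsv")
  for (i in seq_along(ds@scans)) {
    fn <- sprintf("scan_%02d.tsv", i)
    writePrfTable(ds@scans[[i]], file.path(dir, fn), prov)
    files <- c(files, fn)
  }
  writePrfTable(ds@validation, file.path(dir, "validation.tsv"), prov)
  files <- c(files, "validation.tsv")
  manifest <- list(tool = "retinomap", configHash = hash, seed = ds@seed,
                   config = ds@config, files = files)
  writeLines(jsonlite::toJSON(manifest, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
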