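# Shared fixtures: small meshes built in code, an icosphere, memoised heavy
# objects (the full-size synthetic model and the multi-seed recovery study)
# shared across test files.

# triangulated lattice as a FlatMap, optionally jittered (seeded)
makeGridMap <- function(nx = 5, ny = 5, spacing = 1, jitter = 0, seed = 1) {
  lat <- makeTriangularLattice(c(0, (nx - 1) * spacing),
                               c(0, (ny - 1) * spacing * sqrt(3) / 2),
                               spacing)
  co <- lat$coords
  if (jitter > 0) {
    set.seed(seed)
    co <- co + matrix(rnorm(length(co), 0, jitter), ncol = 2)
  }
  flatMap(co, lat$faces)
}

# icosphere: subdivided icosahedron projected to the unit sphere
makeIcosphere <- function(subdiv = 2) {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env(parent = emptyenv())
    getMid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[key]])) return(mid[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, c); ca <- getMid(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  mesh3D(v, f)
}

# unit-square grid split with alternating (union-jack) diagonals: linear
# fields are exactly graph-harmonic on it and the vertex set is a full
# rectangular grid, so boundary-value fill-in tests have exact references
crossGridMesh <- function(n = 13) {
  xs <- seq(0, 1, length.out = n)
  co <- cbind(rep(xs, times = n), rep(xs, each = n))
  id <- function(i, j) (j - 1L) * n + i
  faces <- matrix(0L, 0, 3)
  for (j in seq_len(n - 1L)) for (i in seq_len(n - 1L)) {
    a <- id(i, j); b <- id(i + 1L, j); c <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
    if ((i + j) %% 2 == 0) {
      faces <- rbind(faces, c(a, b, c), c(a, c, d))
    } else {
      faces <- rbind(faces, c(a, b, d), c(b, c, d))
    }
  }
  flatMap(co, faces)
}

# single-term registration systems for hand-evaluable potential cases
edgeOnlySystem <- function(x0, edges, r0, q0 = 0, q1 = Inf) {
  new("RegistrationSystem", x0 = x0, edges = matrix(as.integer(edges), ncol = 2),
      refLengths = r0, q0 = q0, q1 = rep_len(q1, length(r0)),
      angleTriples = matrix(integer(), ncol = 3), refAngles = numeric(),
      perimeter = integer(), faces = matrix(integer(), ncol = 3),
      meanEdgeLength = mean(r0))
}

angleOnlySystem <- function(x0, triples, a0) {
  new("RegistrationSystem", x0 = x0, edges = matrix(integer(), ncol = 2),
      refLengths = numeric(), q0 = 0, q1 = numeric(),
      angleTriples = matrix(as.integer(triples), ncol = 3), refAngles = a0,
      perimeter = integer(), faces = matrix(integer(), ncol = 3),
      meanEdgeLength = 1)
}

perimeterOnlySystem <- function(x0, perim) {
  new("RegistrationSystem", x0 = x0, edges = matrix(integer(), ncol = 2),
      refLengths = numeric(), q0 = 0, q1 = numeric(),
      angleTriples = matrix(integer(), ncol = 3), refAngles = numeric(),
      perimeter = as.integer(perim), faces = matrix(integer(), ncol = 3),
      meanEdgeLength = 1)
}

# small, fast synthetic configuration for unit tests (coarse lattice; the
# warp amplitude is kept at a sane absolute size rather than 5x the coarse
# edge length)
tinyConfig <- function(...) {
  syntheticConfig(resolution = 0.1, warpAmplitude = 0.15, ...)
}

# memoised heavy objects, shared across test files within one run
.fixtureCache <- new.env(parent = emptyenv())

getDefaultModel <- function() {
  if (is.null(.fixtureCache$model))
    .fixtureCache$model <- makeSyntheticModel(syntheticConfig())
  .fixtureCache$model
}

getTinyModel <- function() {
  if (is.null(.fixtureCache$tiny))
    .fixtureCache$tiny <- makeSyntheticModel(tinyConfig())
  .fixtureCache$tiny
}

# the scaled-down recovery study at the stated conditions: warp amplitude
# 5x mean edge length, single-scan noise sd 20 deg / 0.1 log-ecc, 10 deg
# meridian dropout.  One full 2500-step registration per seed; per-seed
# weighted scaled MSE on the V1-V3 (0, 12] deg ROI against ground truth,
# weighted by held-out validation variance explained.
runRecoveryStudy <- function(seeds) {
  model <- getDefaultModel()
  rows <- list()
  diags <- list()
  for (seed in seeds) {
    cfg <- syntheticConfig(seed = seed)
    ds <- makeDataset(cfg, model = model)
    truth <- ds@truth
    roi <- truth$area %in% c("V1", "V2", "V3") &
      truth$eccentricity > 0 & truth$eccentricity <= 12
    wts <- varianceExplained(ds@validation)
    mse <- function(pa, pe)
      weightedMSE(scaledError(pa[roi], pe[roi], truth$polarAngle[roi],
                              truth$eccentricity[roi]), wts[roi])
    res <- suppressWarnings(
      inferMaps(ds@subjectMap, ds@scans[[1]], model,
                minimizerConfig(seed = seed + 500)))
    prior <- priorMaps(ds@subjectMap, model)
    d6 <- averageScans(ds@scans)
    rows[[as.character(seed)]] <- c(
      bayes = mse(polarAngle(res$maps), eccentricity(res$maps)),
      prior = mse(polarAngle(prior), eccentricity(prior)),
      data1 = mse(polarAngle(ds@scans[[1]]), eccentricity(ds@scans[[1]])),
      data6 = mse(polarAngle(d6), eccentricity(d6)))
    reg <- res$registration
    diags[[as.character(seed)]] <- c(
      minAngle = reg@diagnostics$minAngle,
      maxAngle = reg@diagnostics$maxAngle,
      minEdge = reg@diagnostics$minEdge,
      maxEdgeFrac = reg@diagnostics$maxEdgeFrac,
      skipped = reg@skipped,
      steps = length(reg@potential) - 1L)
  }
  list(errors = do.call(rbind, rows), diagnostics = do.call(rbind, diags))
}

getRecoveryStudy <- function() {
  if (is.null(.fixtureCache$study))
    .fixtureCache$study <- runRecoveryStudy(1:10)
  .fixtureCache$study
}
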