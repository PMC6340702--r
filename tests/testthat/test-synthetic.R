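# The synthetic generator: banded model, subject warp, noisy pRF scans,
# dataset composition.

test_that("adjacent areas of the banded model have opposite field signs", {
  model <- getTinyModel()
  mesh <- model@mesh
  xy <- visualFieldCoords(model@polarAngle, model@eccentricity, "rh")
  fs <- triangleFieldSign(mesh@coords, xy, mesh@faces)
  signOf <- function(area) sign(mean(fs[model@faceArea == area], na.rm = TRUE))
  expect_equal(signOf("V1"), -signOf("V2"))
  expect_equal(signOf("V2"), -signOf("V3"))
  expect_equal(signOf("V3"), -signOf("hV4"))
  expect_equal(signOf("V3"), -signOf("V3a"))
  # within-area face signs are constant away from boundary snapping noise
  for (a in areaNames(model)) {
    s <- fs[model@faceArea == a]
    expect_gt(abs(mean(s, na.rm = TRUE)), 0.8)
  }
})

test_that("V1/V2 boundary vertices carry exactly the meridian angles", {
  model <- getTinyModel()
  co <- model@mesh@coords
  rowStep <- 0.1 * sqrt(3) / 2
  onBoundary <- abs(co[, 2] - 1) < rowStep / 2   # the lower-vertical line
  expect_gt(sum(onBoundary), 5)
  expect_true(all(abs(model@polarAngle[onBoundary] - 180) < 1e-9))
  onUpper <- abs(co[, 2] + 1) < rowStep / 2
  expect_true(all(abs(model@polarAngle[onUpper] - 0) < 1e-9))
})

test_that("the model builder is deterministic", {
  m1 <- makeSyntheticModel(tinyConfig(), cache = FALSE)
  m2 <- makeSyntheticModel(tinyConfig(), cache = FALSE)
  expect_identical(m1@polarAngle, m2@polarAngle)
  expect_identical(m1@eccentricity, m2@eccentricity)
  expect_identical(m1@mesh@coords, m2@mesh@coords)
})

test_that("subject warps are identity at amplitude zero and admissible otherwise", {
  model <- getTinyModel()
  wp0 <- warpSubject(model@mesh, 0, seed = 2)
  expect_identical(wp0$map@coords, model@mesh@coords)

  amps <- numeric(5)
  for (s in 1:5) {
    wp <- warpSubject(model@mesh, 0.15, seed = s)
    expect_true(all(signedFaceAreas(wp$map@coords, wp$map@faces) > 0))
    expect_identical(wp$truePositions, model@mesh@coords)
    amps[s] <- mean(sqrt(rowSums(wp$displacement^2)))
  }
  # Monte-Carlo over seeds: mean displacement within 10% of the requested
  # amplitude (individual seeds may be shrunk by the admissibility guard)
  expect_lt(abs(mean(amps) - 0.15) / 0.15, 0.1)
})

test_that("noise-free simulation returns truth with variance explained at the Beta mean", {
  model <- getTinyModel()
  cfg <- tinyConfig(noiseSdAngle = 0, noiseSdEccen = 0, noiseSdSize = 0,
                    dropoutHalfWidth = 0, blobCount = 0, aperture = 1e6)
  truth <- data.frame(polarAngle = model@polarAngle,
                      eccentricity = model@eccentricity,
                      prfSize = 0.1 * model@eccentricity + 0.2)
  scans <- simulatePrfData(truth, model@mesh, cfg, nScans = 2, seed = 3)
  expect_identical(polarAngle(scans[[1]]), truth$polarAngle)
  expect_identical(eccentricity(scans[[1]]), truth$eccentricity)
  expect_equal(unique(varianceExplained(scans[[1]])),
               cfg$omegaShape[1] / sum(cfg$omegaShape))
})

test_that("meridian dropout crushes variance explained near the vertical meridians", {
  model <- getTinyModel()
  cfg <- tinyConfig(dropoutHalfWidth = 10, aperture = 1e6, blobCount = 0)
  truth <- data.frame(polarAngle = model@polarAngle,
                      eccentricity = model@eccentricity,
                      prfSize = 0.1 * model@eccentricity + 0.2)
  sc <- simulatePrfData(truth, model@mesh, cfg, nScans = 1, seed = 4)[[1]]
  near <- truth$polarAngle < 10 | truth$polarAngle > 170
  expect_gt(mean(varianceExplained(sc)[near] < 0.1), 0.9)
  expect_lt(mean(varianceExplained(sc)[!near] < 0.1), 0.2)
})

test_that("simulated noise has the configured magnitude and averaging shrinks it", {
  model <- getTinyModel()
  cfg <- tinyConfig(dropoutHalfWidth = 0, blobCount = 0, aperture = 1e6)
  truth <- data.frame(polarAngle = model@polarAngle,
                      eccentricity = model@eccentricity,
                      prfSize = 0.1 * model@eccentricity + 0.2)
  scans <- simulatePrfData(truth, model@mesh, cfg, nScans = 16, seed = 5)
  resid <- polarAngle(scans[[1]]) - truth$polarAngle
  expect_lt(abs(sd(resid) - cfg$noiseSdAngle) / cfg$noiseSdAngle, 0.05)
  # log-normal eccentricity noise
  lr <- log(eccentricity(scans[[1]]) / truth$eccentricity)
  lr <- lr[is.finite(lr)]
  expect_lt(abs(sd(lr) - cfg$noiseSdEccen) / cfg$noiseSdEccen, 0.06)
  # averaging k scans shrinks the sd roughly as 1/sqrt(k)
  avg <- averageScans(scans)
  residAvg <- polarAngle(avg) - truth$polarAngle
  expect_lt(abs(sd(residAvg) - cfg$noiseSdAngle / 4) / (cfg$noiseSdAngle / 4),
            0.15)
})

test_that("datasets are reproducible and internally consistent", {
  cfg <- tinyConfig(seed = 7)
  ds1 <- makeDataset(cfg)
  ds2 <- makeDataset(cfg)
  expect_identical(ds1@subjectMap@coords, ds2@subjectMap@coords)
  expect_identical(polarAngle(ds1@scans[[1]]), polarAngle(ds2@scans[[1]]))

  # ground truth equals the model looked up at the inverse-warped positions
  lk <- modelLookup(ds1@model, ds1@truePositions)
  ok <- lk$area != "none" & ds1@truth$eccentricity > 1e-6
  expect_lt(max(abs(lk$polarAngle[ok] - ds1@truth$polarAngle[ok])), 1e-9)
  expect_lt(max(abs(lk$eccentricity[ok] - ds1@truth$eccentricity[ok])), 1e-9)

  # warped subject map admissible
  expect_true(all(signedFaceAreas(ds1@subjectMap@coords,
                                  ds1@subjectMap@faces) > 0))
})

test_that("written fixture directories are byte-identical for the same config and seed", {
  cfg <- tinyConfig(seed = 9, nScans = 2, nValidationScans = 2)
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  unlink(c(d1, d2), recursive = TRUE)
  makeDataset(cfg, dir = d1)
  makeDataset(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  expect_true(all(c("model.json", "subject_mesh.off", "truth.tsv",
                    "scan_01.tsv", "validation.tsv", "manifest.json") %in%
                    list.files(d1)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the default configuration yields ample above-threshold retinotopic vertices", {
  ds <- makeDataset(syntheticConfig(seed = 1), model = getDefaultModel())
  expect_gte(sum(varianceExplained(ds@scans[[1]]) >= 0.1), 3000)
})
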