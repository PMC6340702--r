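# Model building: boundary-constrained field fill-in, rescaling, lookup,
# serialization.

# a unit-square strip with field values fixed on its four edges
squareSpec <- function(thetaLeft = "upper_vertical_meridian",
                       thetaRight = "lower_vertical_meridian") {
  contours <- list(
    list(points = cbind(c(0, 0), c(0, 1)), label = thetaLeft,
         areas = c("V1", "none")),
    list(points = cbind(c(1, 1), c(0, 1)), label = thetaRight,
         areas = c("V1", "none")),
    list(points = cbind(c(0, 1), c(0, 0)), label = "foveal",
         areas = c("V1", "none")),
    list(points = cbind(c(0, 1), c(1, 1)), label = "peripheral",
         areas = c("V1", "none")))
  boundarySpec(contours, list(list(name = "V1",
                                   polygon = rbind(c(-0.1, -0.1), c(1.1, -0.1),
                                                   c(1.1, 1.1), c(-0.1, 1.1)))))
}

squareMesh <- function(n = 13) crossGridMesh(n)

rawFields <- function(model) {
  p <- model@rescale
  s <- log(pmax(model@eccentricity - p$eccMin, 0) / p$eccA + 1) / p$eccB
  list(theta = model@polarAngle / 90 - 1, rho = 2 * s - 1)
}

test_that("boundary-constrained fill-in matches an independent harmonic solve", {
  mesh <- squareMesh()
  model <- buildModel(squareSpec(), mesh)
  raw <- rawFields(model)
  co <- mesh@coords

  # independent oracle: dense graph-harmonic solve with the same 1/(2r)
  # edge weights, no orthogonality term, base-R solve()
  harmonicOracle <- function(fixedVal) {
    n <- nrow(co)
    E <- mesh@edges
    w <- 1 / (2 * edgeLengths(co, E))
    L <- matrix(0, n, n)
    for (i in seq_len(nrow(E))) {
      u <- E[i, 1]; v <- E[i, 2]
      L[u, v] <- L[u, v] - w[i]; L[v, u] <- L[v, u] - w[i]
      L[u, u] <- L[u, u] + w[i]; L[v, v] <- L[v, v] + w[i]
    }
    free <- which(is.na(fixedVal)); fixed <- which(!is.na(fixedVal))
    sol <- fixedVal
    sol[free] <- solve(L[free, free],
                       -L[free, fixed, drop = FALSE] %*% fixedVal[fixed])
    sol
  }
  tol <- 1e-6
  thetaFix <- rep(NA_real_, nrow(co))
  thetaFix[co[, 1] < tol] <- -1; thetaFix[co[, 1] > 1 - tol] <- 1
  rhoFix <- rep(NA_real_, nrow(co))
  rhoFix[co[, 2] < tol] <- -1; rhoFix[co[, 2] > 1 - tol] <- 1

  expect_lt(max(abs(raw$theta - harmonicOracle(thetaFix))), 1e-3)
  expect_lt(max(abs(raw$rho - harmonicOracle(rhoFix))), 1e-3)

  # the solution is essentially bilinear: linear-in-x theta, linear-in-y rho
  expect_lt(max(abs(raw$theta - (2 * co[, 1] - 1))), 1e-3)
  expect_lt(max(abs(raw$rho - (2 * co[, 2] - 1))), 1e-3)
  # orthogonality term is tiny by symmetry
  expect_lt(sum(raw$theta * raw$rho)^2, 1e-6)

  # objective non-increasing across recorded minimizer iterations
  expect_true(all(diff(model@rescale$fit$objective) <= 1e-9))
  # maximum principle: interior scaled values within the boundary range
  expect_true(all(raw$theta >= -1 - 1e-6 & raw$theta <= 1 + 1e-6))
  expect_true(all(raw$rho >= -1 - 1e-6 & raw$rho <= 1 + 1e-6))
})

test_that("equal boundary values force a constant interior field", {
  mesh <- squareMesh(9)
  model <- buildModel(squareSpec("horizontal_meridian", "horizontal_meridian"),
                      mesh)
  raw <- rawFields(model)
  expect_lt(max(abs(raw$theta - 0)), 1e-6)   # both edges fixed at 0
})

test_that("doubling all edge lengths halves each smoothness summand", {
  fm <- makeGridMap(4, 4, jitter = 0.05, seed = 5)
  set.seed(6)
  th <- rnorm(nrow(fm@coords)); rh <- rnorm(nrow(fm@coords))
  f1 <- fieldFillObjective(th, rh, fm@coords, fm@edges)
  f2 <- fieldFillObjective(th, rh, 2 * fm@coords, fm@edges)
  dot2 <- sum(th * rh)^2
  expect_equal(f2 - dot2, (f1 - dot2) / 2, tolerance = 1e-12)
})

test_that("rescaling maps scaled fields to the configured degree ranges", {
  r <- rescaleFields(c(-1, 0, 1), c(-1, 0, 1))
  expect_equal(r$polarAngle, c(0, 90, 180))
  expect_equal(r$eccentricity[1], 0)

  set.seed(8)
  rho <- c(runif(1999, -1, 1), -1, 1)
  r2 <- rescaleFields(rep(0, 2001), rho,
                      c(min = 0, median = 3, max = 90))
  # fitted exponential maps the median scaled value to the target median
  expect_equal(unname(r2$eccentricity[which(rho == median(rho))]), 3,
               tolerance = 0.03)
  expect_equal(max(r2$eccentricity), 90, tolerance = 1e-6)
  # strictly increasing in the scaled field
  ord <- order(rho)
  expect_true(all(diff(r2$eccentricity[ord]) >= 0))
  expect_error(rescaleFields(0, 0, c(min = 5, median = 3, max = 90)),
               "parameterization")
})

test_that("model lookup is self-consistent at vertices and labels points correctly", {
  model <- getTinyModel()
  mesh <- model@mesh
  inside <- which(model@vertexArea != "none" & model@eccentricity > 0.01)
  idx <- inside[seq(1, length(inside), length.out = 200)]
  lk <- modelLookup(model, mesh@coords[idx, ])
  hit <- lk$area != "none"
  expect_gt(mean(hit), 0.95)
  expect_equal(lk$polarAngle[hit], model@polarAngle[idx][hit], tolerance = 1e-9)
  expect_equal(lk$eccentricity[hit], model@eccentricity[idx][hit],
               tolerance = 1e-9)

  out <- modelLookup(model, cbind(50, 50))
  expect_equal(out$area, "none")
  expect_true(is.na(out$polarAngle))

  # every returned label is consistent with the face partition: looking up
  # face centroids returns that face's own label
  f <- sample(which(model@faceArea != "none"), 50)
  cent <- (mesh@coords[mesh@faces[f, 1], ] + mesh@coords[mesh@faces[f, 2], ] +
             mesh@coords[mesh@faces[f, 3], ]) / 3
  lk2 <- modelLookup(model, cent)
  expect_equal(lk2$area, model@faceArea[f])
})

test_that("model JSON round-trips losslessly and validates its schema", {
  model <- getTinyModel()
  json <- serializeModel(model)
  back <- deserializeModel(json)
  expect_identical(back@polarAngle, model@polarAngle)
  expect_identical(back@eccentricity, model@eccentricity)
  expect_identical(back@vertexArea, model@vertexArea)
  expect_identical(back@mesh@coords, model@mesh@coords)
  expect_identical(back@areas, model@areas)

  # truncation names the missing section
  doc <- jsonlite::fromJSON(json)
  doc$eccentricity <- NULL
  expect_error(deserializeModel(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "eccentricity")
  expect_error(deserializeModel("{\"schema\": \"other\"}"), "missing")

  # a model declaring 12 areas serializes 12 area entries
  m12 <- model
  m12@areas <- c("V1", "V2", "V3", "hV4", "VO1", "VO2", "V3a", "V3b",
                 "LO1", "LO2", "TO1", "TO2")
  parsed <- jsonlite::fromJSON(serializeModel(m12))
  expect_length(parsed$areas, 12)
})

test_that("file round trip through writeModel/readModel preserves the model", {
  model <- getTinyModel()
  path <- tempfile(fileext = ".json")
  writeModel(model, path)
  back <- readModel(path)
  expect_identical(back@polarAngle, model@polarAngle)
  expect_identical(back@sizeFun$slope, model@sizeFun$slope)
  unlink(path)
})
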