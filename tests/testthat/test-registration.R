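# Potential terms, gradients, anchors, and the topology-preserving
# minimizer.

test_that("edge potential matches hand-evaluated harmonic and well cases", {
  x0 <- rbind(c(0, 0), c(1, 0))
  sys <- edgeOnlySystem(x0, rbind(c(1L, 2L)), r0 = 1, q0 = 0, q1 = Inf)
  p <- edgePotential(rbind(c(0, 0), c(2, 0)), sys)
  expect_equal(p$He, 0.5)            # (1/2)(2-1)^2
  expect_equal(edgePotential(x0, sys)$value, 0)
  expect_equal(edgePotential(x0, sys)$grad, matrix(0, 2, 2))

  sys2 <- edgeOnlySystem(x0, rbind(c(1L, 2L)), r0 = 1, q0 = 0, q1 = 2)
  p2 <- edgePotential(rbind(c(0, 0), c(1.5, 0)), sys2)
  expect_equal(p2$Ge, 5 / 9, tolerance = 1e-12)  # (1/2)[(1/1.5-1)^2+((2-1)/(2-1.5)-1)^2]
  expect_error(edgePotential(rbind(c(0, 0), c(2.5, 0)), sys2), "singularity")
  expect_error(edgePotential(rbind(c(0, 0), c(0, 0)), sys2), "singularity")
})

test_that("angle potential matches hand-evaluated harmonic and well cases", {
  x0 <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  sys <- angleOnlySystem(x0, rbind(c(1L, 2L, 3L)), a0 = pi / 3)
  xr <- rbind(c(0, 0), c(1, 0), c(0, 1))   # corner at pi/2
  p <- anglePotential(xr, sys)
  expect_equal(p$Htheta, 0.5 * (pi / 6)^2, tolerance = 1e-12)  # ~0.13708
  expect_equal(p$Gtheta, 1 / 9, tolerance = 1e-12)             # ~0.11111
  expect_equal(anglePotential(x0, sys)$value, 0)
  # a reflected (inverted) corner crosses the singularity
  expect_error(anglePotential(rbind(c(0, 0), c(1, 0), c(0.5, -0.5)), sys),
               "singularity")
})

test_that("perimeter potential penalizes only perimeter displacements", {
  x0 <- rbind(c(0, 0), c(1, 0))
  sys <- perimeterOnlySystem(x0, 1L)
  expect_equal(perimeterPotential(x0, sys)$value, 0)
  p <- perimeterPotential(rbind(c(0.3, 0.4), c(1, 0)), sys)
  expect_equal(p$value, 0.125)   # (1/2) * 0.5^2
  # displacing a non-perimeter vertex leaves Fp unchanged
  p2 <- perimeterPotential(rbind(c(0, 0), c(7, 7)), sys)
  expect_equal(p2$value, 0)
})

test_that("anchors are inverted-Gaussian wells", {
  an <- anchorSet(1L, rbind(c(1, 0)), sigma = 1, weight = 1)
  expect_equal(anchorPotential(rbind(c(1, 0), c(9, 9)), an)$value, -1)
  expect_equal(anchorPotential(rbind(c(0, 0), c(9, 9)), an)$value, -exp(-1),
               tolerance = 1e-12)
  far <- anchorPotential(rbind(c(100, 0), c(9, 9)), an)$value
  expect_gt(far, -1e-6); expect_lte(far, 0)
})

test_that("the total potential is the exact sum of its four terms", {
  fm <- makeGridMap(4, 4, jitter = 0.04, seed = 12)
  sys <- registrationSystem(fm)
  an <- anchorSet(c(2L, 5L), rbind(c(0.5, 0.5), c(1.5, 1)), c(0.3, 0.4),
                  c(1, 0.7))
  x <- sys@x0 + matrix(rnorm(length(sys@x0), 0, 0.02), ncol = 2)
  tot <- totalPotential(x, sys, an)
  fe <- edgePotential(x, sys)$value
  fth <- anglePotential(x, sys)$value
  fp <- perimeterPotential(x, sys)$value
  fphi <- anchorPotential(x, an)$value
  expect_equal(tot$value, fe + fth + fp + fphi, tolerance = 1e-12)
  expect_equal(totalPotential(sys@x0, sys)$value, 0)  # reference, no anchors
  expect_equal(posteriorDensity(sys@x0, sys), 1)
  g <- totalGradient(x, sys, an)
  expect_equal(g, edgePotential(x, sys)$grad + anglePotential(x, sys)$grad +
                 perimeterPotential(x, sys)$grad + anchorPotential(x, an)$grad,
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences on random meshes", {
  set.seed(99)
  worst <- 0
  for (k in 1:30) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    fm <- makeGridMap(nx, ny, jitter = 0.08, seed = 1000 + k)
    sys <- registrationSystem(fm)
    nv <- nrow(sys@x0)
    nan <- sample(1:4, 1)
    an <- anchorSet(sample(nv, nan),
                    sys@x0[sample(nv, nan), , drop = FALSE] +
                      matrix(rnorm(2 * nan, 0, 0.3), ncol = 2),
                    runif(nan, 0.2, 0.6), runif(nan, 0.3, 1))
    x <- sys@x0 + matrix(rnorm(2 * nv, 0, 0.015), ncol = 2)
    g <- totalGradient(x, sys, an)
    h <- 1e-6
    fd <- matrix(0, nv, 2)
    for (i in seq_len(nv)) for (d in 1:2) {
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      fd[i, d] <- (totalPotential(xp, sys, an)$value -
                     totalPotential(xm, sys, an)$value) / (2 * h)
    }
    worst <- max(worst, max(abs(g - fd)) / max(abs(g)))
  }
  expect_lt(worst, 1e-5)
})

test_that("the minimizer is stationary with no anchors and deterministic under a seed", {
  fm <- makeGridMap(5, 5, jitter = 0.05, seed = 21)
  sys <- registrationSystem(fm)
  res <- registerMap(sys, NULL, minimizerConfig(steps = 50, noiseScale = 0))
  expect_equal(res@coords, sys@x0)
  expect_equal(res@potential, rep(0, 51))

  an <- anchorSet(c(7L, 12L), sys@x0[c(7L, 12L), ] + 0.2, c(0.3, 0.3), c(1, 1))
  r1 <- registerMap(sys, an, minimizerConfig(steps = 120, seed = 42))
  r2 <- registerMap(sys, an, minimizerConfig(steps = 120, seed = 42))
  expect_identical(r1@coords, r2@coords)
  expect_identical(r1@potential, r2@potential)
  r3 <- registerMap(sys, an, minimizerConfig(steps = 120, seed = 43))
  expect_false(identical(r3@coords, r1@coords))
})

test_that("noise-free descent has a non-increasing potential and preserves topology", {
  fm <- makeGridMap(6, 6, jitter = 0.05, seed = 31)
  sys <- registrationSystem(fm)
  nv <- nrow(sys@x0)
  set.seed(5)
  idx <- sample(nv, 8)
  an <- anchorSet(idx, sys@x0[idx, ] + matrix(rnorm(16, 0, 0.4), ncol = 2),
                  rep(0.4, 8), rep(1, 8))
  res <- registerMap(sys, an, minimizerConfig(steps = 400, noiseScale = 0))
  expect_true(all(diff(res@potential) <= 1e-14))
  expect_gt(res@diagnostics$minAngle, 0)
  expect_lt(res@diagnostics$maxAngle, pi)
  expect_gt(res@diagnostics$minEdge, 0)
  expect_lt(res@diagnostics$maxEdgeFrac, 1)
  # final configuration admissible: no inverted face
  expect_true(all(signedFaceAreas(res@coords, fm@faces) > 0))
})

test_that("with noise the potential fluctuates only within the stated tolerance", {
  fm <- makeGridMap(6, 6, jitter = 0.05, seed = 33)
  sys <- registrationSystem(fm)
  set.seed(6)
  idx <- sample(nrow(sys@x0), 6)
  an <- anchorSet(idx, sys@x0[idx, ] + matrix(rnorm(12, 0, 0.3), ncol = 2),
                  rep(0.35, 6), rep(1, 6))
  cfg <- minimizerConfig(steps = 300, seed = 9)
  res <- registerMap(sys, an, cfg)
  inc <- diff(res@potential)
  slack <- cfg@fluctTol * (1 + abs(res@potential[-length(res@potential)]))
  expect_true(all(inc <= slack + 1e-14))
  # the returned configuration is the best one visited
  expect_lte(totalPotential(res@coords, sys, an)$value, min(res@potential) + 1e-12)
})

test_that("a single free vertex settles into its anchor well", {
  # one interior vertex, tiny deformation weights via wide wells and a
  # strong anchor: final position close to the anchor point
  fm <- makeGridMap(3, 3, spacing = 1)
  sys <- registrationSystem(fm)
  inner <- setdiff(seq_len(nrow(sys@x0)), fm@perimeter)[1]
  target <- sys@x0[inner, ] + c(0.05, 0.03)
  an <- anchorSet(inner, rbind(target), sigma = 0.2, weight = 50)
  res <- registerMap(sys, an, minimizerConfig(steps = 2000, noiseScale = 0))
  expect_lt(sqrt(sum((res@coords[inner, ] - target)^2)), 1e-3)

  # anchor monotonicity: larger weight ends (weakly) closer to the anchor
  dists <- vapply(c(0.5, 2, 8, 32), function(w) {
    r <- registerMap(sys, anchorSet(inner, rbind(target), 0.2, w),
                     minimizerConfig(steps = 500, noiseScale = 0))
    sqrt(sum((r@coords[inner, ] - target)^2))
  }, numeric(1))
  expect_true(all(diff(dists) <= 1e-6))
})

test_that("He scales quadratically under uniform displacement of one edge", {
  x0 <- rbind(c(0, 0), c(1, 0))
  sys <- edgeOnlySystem(x0, rbind(c(1L, 2L)), r0 = 1, q0 = 0, q1 = Inf)
  d1 <- edgePotential(rbind(c(0, 0), c(1.1, 0)), sys)$He
  d2 <- edgePotential(rbind(c(0, 0), c(1.2, 0)), sys)$He
  expect_equal(d2 / d1, 4, tolerance = 1e-9)
})

test_that("anchors are built one-per-area with capped widths and thresholded weights", {
  model <- getTinyModel()
  mesh <- model@mesh
  sys <- registrationSystem(mesh)
  n <- nrow(mesh@coords)
  # three vertices: one well-measured inside V1, one below threshold, one
  # with an eccentricity beyond the model's range
  v1mid <- which(model@vertexArea == "V1" & abs(model@polarAngle - 45) < 10 &
                   model@eccentricity > 2 & model@eccentricity < 6)[1]
  data <- retinotopyData(
    vertexId = c(v1mid, 1L, 2L),
    polarAngle = c(model@polarAngle[v1mid], 90, 90),
    eccentricity = c(model@eccentricity[v1mid], 3, 3000),
    prfSize = c(0.5, 0.5, 0.5),
    varianceExplained = c(0.8, 0.05, 0.8))
  an <- suppressWarnings(buildAnchors(data, model, sys,
                                      fieldSignFactor = NULL, sizeSigma = NULL))
  # the sub-threshold vertex contributes zero anchors
  expect_false(1L %in% an@vertex)
  # the out-of-range vertex contributes zero anchors (skipped with warning)
  expect_warning(buildAnchors(retinotopyData(2L, 90, 3000, 0.5, 0.8),
                              model, sys), "no anchor")
  # theta = 45 deg exists in V1 and in the dorsal halves of V2/V3 and the
  # dorsal outer band: one anchor per representing area
  mine <- an@vertex == v1mid
  expect_equal(sort(unique(an@area[mine])), sort(c("V1", "V2", "V3", "hV4")))
  expect_equal(sum(mine), 4L)
  # widths positive and capped at 20 epsilon
  expect_true(all(an@sigma > 0))
  expect_true(all(an@sigma <= 20 * sys@meanEdgeLength + 1e-12))
  # base weight is the variance explained
  expect_equal(unique(an@weight[mine]), 0.8)
  # exactly at threshold is retained
  atThr <- retinotopyData(v1mid, model@polarAngle[v1mid],
                          model@eccentricity[v1mid], 0.5, 0.1)
  expect_gt(length(suppressWarnings(
    buildAnchors(atThr, model, sys))@vertex), 0)
})

test_that("a single-area toy model caps sigma at 20 epsilon", {
  # one-area square model: each vertex has exactly one anchor, so the width
  # takes its maximum value
  lat <- makeTriangularLattice(c(0, 1), c(0, 1), 0.25)
  mesh <- flatMap(lat$coords, lat$faces)
  contours <- list(
    list(points = cbind(c(0, 0), c(0, 1)), label = "upper_vertical_meridian",
         areas = c("V1", "none")),
    list(points = cbind(c(1, 1), c(0, 1)), label = "lower_vertical_meridian",
         areas = c("V1", "none")),
    list(points = cbind(c(0, 1), c(0, 0)), label = "foveal", areas = c("V1", "none")),
    list(points = cbind(c(0, 1), c(1, 1)), label = "peripheral", areas = c("V1", "none")))
  spec <- boundarySpec(contours, list(list(
    name = "V1", polygon = rbind(c(-1, -1), c(2, -1), c(2, 2), c(-1, 2)))))
  model <- buildModel(spec, mesh)
  sys <- registrationSystem(mesh)
  data <- retinotopyData(1:3, c(45, 90, 120), c(2, 3, 5), c(0.4, 0.5, 0.6),
                         c(0.5, 0.6, 0.7))
  an <- suppressWarnings(buildAnchors(data, model, sys, fieldSignFactor = NULL,
                                      sizeSigma = NULL))
  expect_true(all(an@sigma == 20 * sys@meanEdgeLength))
})
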