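# Mesh geometry primitives: projection, lengths, angles, areas,
# interpolation, field sign, resampling.

test_that("orthographic projection maps the center to the origin and the rim to radius 1", {
  ico <- makeIcosphere(3)
  expect_equal(nrow(coords(ico)), 642L)

  # put a vertex exactly at the projection center
  v1 <- coords(ico)[1, ]
  proj <- mapProjection(center = v1, radius = 90, chirality = "lh")
  fm <- orthographicProject(ico, proj)
  src <- fm@metadata$sourceVertex
  i1 <- which(src == 1L)
  expect_equal(unname(fm@coords[i1, ]), c(0, 0), tolerance = 1e-12)

  # a vertex 90 degrees from the center projects to norm 1 on the unit sphere
  ang <- acos(pmin(1, pmax(-1, coords(ico) %*% v1)))
  far <- which.min(abs(ang - pi / 2))
  co <- coords(ico)
  co[far, ] <- co[far, ] - c(co[far, ] %*% v1) * v1
  co[far, ] <- co[far, ] / sqrt(sum(co[far, ]^2))
  ico2 <- mesh3D(co, faces(ico))
  fm2 <- orthographicProject(ico2, proj)
  ifar <- which(fm2@metadata$sourceVertex == far)
  expect_equal(sqrt(sum(fm2@coords[ifar, ]^2)), 1, tolerance = 1e-9)
})

test_that("projection retains exactly the vertices within the angular radius", {
  ico <- makeIcosphere(3)
  proj <- mapProjection(center = c(0, 0, 1), radius = 60, chirality = "lh")
  fm <- orthographicProject(ico, proj)
  # independent oracle: direct angle test per vertex
  ang <- acos(pmin(1, pmax(-1, coords(ico)[, 3])))
  expect_equal(nrow(fm@coords), sum(ang <= 60 * pi / 180 + 1e-12))
})

test_that("projection rejects non-spherical input and empty selections", {
  bad <- mesh3D(rbind(c(1, 0, 0), c(0, 3, 0), c(0, 0, 1), c(0.5, 0.5, 0.5)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_error(orthographicProject(bad, mapProjection(center = c(0, 0, 1))),
               "sphere")
  ico <- makeIcosphere(1)
  expect_error(orthographicProject(ico, mapProjection(center = c(0, 0, 1),
                                                      radius = 1e-4)),
               "empty")
})

test_that("projection is a near-isometry close to the center", {
  # a small polar cap of points within 1 degree of the projection axis
  th <- c(0.1, 0.4, 0.7, 0.9, 0.5, 0.3) * pi / 180
  ph <- c(0, 1.1, 2.4, 3.9, 5.1, 0.6)
  pts <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  cap <- mesh3D(pts, rbind(c(1, 2, 6), c(2, 3, 6), c(3, 4, 5)))
  fm <- orthographicProject(cap, mapProjection(center = c(0, 0, 1),
                                               radius = 5, chirality = "lh"))
  for (i in 1:5) for (j in (i + 1):6) {
    arc <- acos(pmin(1, sum(pts[i, ] * pts[j, ])))
    flat <- sqrt(sum((fm@coords[i, ] - fm@coords[j, ])^2))
    expect_equal(flat, arc, tolerance = 2e-4)  # 0.02% relative
  }
})

test_that("edge lengths are Euclidean and match an element-wise oracle", {
  expect_equal(edgeLengths(rbind(c(0, 0), c(3, 4)), rbind(c(1, 2))), 5)
  expect_equal(edgeLengths(rbind(c(1, 1), c(1, 1)), rbind(c(1, 2))), 0)
  set.seed(7)
  co <- matrix(rnorm(40), ncol = 2)
  E <- cbind(sample(20, 50, TRUE), sample(20, 50, TRUE))
  oracle <- vapply(seq_len(50), function(i)
    sqrt(sum((co[E[i, 1], ] - co[E[i, 2], ])^2)), numeric(1))
  expect_equal(edgeLengths(co, E), oracle, tolerance = 1e-12)
})

test_that("corner angles recover known triangles and sum to pi", {
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  a <- cornerAngles(eq, rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)))
  expect_equal(a, rep(pi / 3, 3), tolerance = 1e-12)
  rt <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(cornerAngles(rt, rbind(c(1, 2, 3))), pi / 2, tolerance = 1e-12)
  set.seed(11)
  for (k in 1:20) {
    tri <- matrix(rnorm(6), ncol = 2)
    if (abs(signedFaceAreas(tri, rbind(c(1, 2, 3)))) < 1e-3) next
    f <- if (signedFaceAreas(tri, rbind(c(1, 2, 3))) > 0) c(1, 2, 3) else c(1, 3, 2)
    a <- cornerAngles(tri, rbind(f, f[c(2, 3, 1)], f[c(3, 1, 2)]))
    expect_equal(sum(a), pi, tolerance = 1e-9)
    expect_true(all(a > 0 & a < pi))
  }
  expect_error(cornerAngles(rbind(c(0, 0), c(0, 0), c(1, 1)),
                            rbind(c(1, 2, 3))), "degenerate")
})

test_that("field sign is +1 for identity, -1 for mirror, NA for missing values", {
  fm <- makeGridMap(4, 4)
  co <- fm@coords
  expect_true(all(triangleFieldSign(co, co, fm@faces) == 1L))
  mir <- co; mir[, 1] <- -mir[, 1]
  expect_true(all(triangleFieldSign(co, mir, fm@faces) == -1L))
  vf <- co; vf[1, 1] <- NA
  fs <- triangleFieldSign(co, vf, fm@faces)
  touching <- apply(fm@faces == 1L, 1, any)
  expect_true(all(is.na(fs[touching])))
  expect_true(all(!is.na(fs[!touching])))
})

test_that("vertex surface areas split faces into thirds and conserve total area", {
  tri <- mesh3D(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_equal(vertexSurfaceAreas(tri), rep(1 / 6, 3), tolerance = 1e-12)

  ico <- makeIcosphere(0)
  va <- vertexSurfaceAreas(ico)
  xyz <- coords(ico); f <- faces(ico)
  u <- xyz[f[, 2], ] - xyz[f[, 1], ]; v <- xyz[f[, 3], ] - xyz[f[, 1], ]
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  expect_equal(sum(va), sum(sqrt(rowSums(cr^2)) / 2), tolerance = 1e-9)

  degen <- mesh3D(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), rbind(c(1, 2, 3)))
  expect_equal(sum(vertexSurfaceAreas(degen)), 0)
})

test_that("barycentric interpolation reproduces affine fields and flags outside points", {
  fm <- makeGridMap(5, 5, jitter = 0.1, seed = 3)
  co <- fm@coords
  field <- 2 * co[, 1] - 3 * co[, 2] + 0.5
  set.seed(4)
  inside <- cbind(runif(50, 1, 3), runif(50, 1, 2.5))
  vals <- barycentricInterpolate(fm, field, inside)
  expect_equal(vals, 2 * inside[, 1] - 3 * inside[, 2] + 0.5, tolerance = 1e-12)

  # query at a vertex returns that vertex's value
  expect_equal(barycentricInterpolate(fm, field, co[7, , drop = FALSE]),
               field[7], tolerance = 1e-12)
  # point far outside the hull is missing
  expect_true(is.na(barycentricInterpolate(fm, field, cbind(100, 100))))
})

test_that("uniform resampling is exact for identity, constants and affine fields", {
  fm <- makeGridMap(6, 6, spacing = 0.5)
  co <- fm@coords
  field <- cbind(const = rep(2.5, nrow(co)), lin = 1.2 * co[, 1] - 0.7 * co[, 2])
  rs <- uniformResample(fm, field, resolution = 0.5)
  expect_equal(rs$fields[, "const"], rep(2.5, nrow(rs$map@coords)),
               tolerance = 1e-9)
  expect_equal(rs$fields[, "lin"],
               1.2 * rs$map@coords[, 1] - 0.7 * rs$map@coords[, 2],
               tolerance = 1e-9)

  # irregular source, linear field, different resolution
  fj <- makeGridMap(7, 7, jitter = 0.12, seed = 9)
  lin <- 3 * fj@coords[, 1] + 2 * fj@coords[, 2]
  rs2 <- uniformResample(fj, lin, resolution = 0.8)
  expect_equal(rs2$fields,
               3 * rs2$map@coords[, 1] + 2 * rs2$map@coords[, 2],
               tolerance = 1e-9)

  expect_error(uniformResample(fm, resolution = 100), "empty map")
})

test_that("flat maps store each undirected edge once, CCW faces, and a positive mean edge length", {
  fm <- makeGridMap(5, 4, jitter = 0.05, seed = 2)
  E <- fm@edges
  key <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(signedFaceAreas(fm@coords, fm@faces) > 0))
  expect_gt(fm@meanEdgeLength, 0)
  expect_equal(fm@meanEdgeLength, mean(edgeLengths(fm@coords, fm@edges)))
  # perimeter vertices all lie on a boundary edge of the lattice
  expect_true(all(fm@perimeter %in% seq_len(nrow(fm@coords))))
  # total vertex-area conservation in 2D via the 3D routine with z = 0
  m3 <- mesh3D(cbind(fm@coords, 0), fm@faces)
  expect_equal(sum(vertexSurfaceAreas(m3)),
               sum(signedFaceAreas(fm@coords, fm@faces)), tolerance = 1e-9)
})
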