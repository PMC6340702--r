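## The registration engine: anchor construction, the four potential terms
## with analytic gradients (edge, angle, perimeter, anchor), and the
## topology-preserving, backtracking, noise-assisted gradient descent.

#' Build a RegistrationSystem from a flat map
#'
#' Freezes the reference configuration of the registration potential: the
#' reference coordinates x0, edge set with reference lengths, corner triples
#' with reference angles, perimeter set, and the admissible edge-length well
#' (q0, q1).  By default q0 = 0 and q1 = 2 times each reference length, so
#' edges may shrink toward zero and at most double.
#'
#' @param map a [FlatMap-class].
#' @param q0 minimum allowable edge length.
#' @param q1 maximum allowable edge lengths; a scalar or per-edge vector, or
#'   NULL for 2 * reference length (Inf disables the upper well).
#' @return a [RegistrationSystem-class].
#' @export
registrationSystem <- function(map, q0 = 0, q1 = NULL) {
  r0 <- edgeLengths(map@coords, map@edges)
  if (is.null(q1)) q1 <- 2 * r0
  q1 <- rep_len(q1, length(r0))
  new("RegistrationSystem", x0 = map@coords, edges = map@edges,
      refLengths = r0, q0 = q0, q1 = q1,
      angleTriples = map@angleTriples,
      refAngles = cornerAngles(map@coords, map@angleTriples),
      perimeter = map@perimeter, faces = map@faces,
      meanEdgeLength = map@meanEdgeLength)
}

#' Construct an AnchorSet directly
#'
#' Usually produced by [buildAnchors()]; this constructor exists for tests
#' and custom pipelines.
#'
#' @param vertex integer vertex indices.
#' @param target anchor points (k x 2).
#' @param sigma Gaussian well widths.
#' @param weight anchor weights.
#' @param area area labels (optional).
#' @return an [AnchorSet-class].
#' @export
anchorSet <- function(vertex, target, sigma, weight,
                      area = rep("none", length(vertex))) {
  new("AnchorSet", vertex = as.integer(vertex),
      target = matrix(as.numeric(target), ncol = 2),
      sigma = as.numeric(sigma), weight = as.numeric(weight),
      area = as.character(area))
}

.emptyAnchors <- function() {
  new("AnchorSet", vertex = integer(), target = matrix(numeric(), ncol = 2),
      sigma = numeric(), weight = numeric(), area = character())
}

# shared argument marshalling for the C++ evaluator; empty components switch
# the corresponding term off so each term can be evaluated in isolation
.cppArgs <- function(x, sys = NULL, anchors = NULL,
                     useEdges = TRUE, useAngles = TRUE, usePerimeter = TRUE) {
  x <- matrix(as.numeric(x), ncol = 2)
  if (is.null(anchors)) anchors <- .emptyAnchors()
  e0 <- matrix(integer(), ncol = 2)
  if (is.null(sys)) {
    list(x = x, E = e0, r0 = numeric(), q0 = 0, q1 = numeric(),
         Th = matrix(integer(), ncol = 3), a0 = numeric(), P = integer(),
         x0 = x, av = anchors@vertex, ay = anchors@target,
         asig = anchors@sigma, aw = anchors@weight)
  } else {
    list(x = x,
         E = if (useEdges) sys@edges else e0,
         r0 = if (useEdges) sys@refLengths else numeric(),
         q0 = sys@q0,
         q1 = if (useEdges) sys@q1 else numeric(),
         Th = if (useAngles) sys@angleTriples else matrix(integer(), ncol = 3),
         a0 = if (useAngles) sys@refAngles else numeric(),
         P = if (usePerimeter) sys@perimeter else integer(),
         x0 = sys@x0, av = anchors@vertex, ay = anchors@target,
         asig = anchors@sigma, aw = anchors@weight)
  }
}

.callPotential <- function(a, wantGrad) {
  cpp_potential(a$x, a$E, a$r0, a$q0, a$q1, a$Th, a$a0, a$P, a$x0,
                a$av, a$ay, a$asig, a$aw, wantGrad)
}

.singularityStop <- function() {
  stop(errorCondition(
    paste("singularity: an edge length or corner angle lies outside the",
          "admissible region"),
    class = c("retinomap_singularity", "error")))
}

#' Edge-length deformation potential Fe
#'
#' \code{Fe = (He + Ge) / |E|}: the harmonic penalty
#' \code{He = 1/2 * sum (r - r0)^2} plus the infinite-well barrier Ge that
#' diverges as any edge length approaches q0 or q1.
#'
#' @param x current 2D coordinates.
#' @param sys a [RegistrationSystem-class].
#' @return list with \code{value}, the unnormalized components \code{He} and
#'   \code{Ge}, and the analytic \code{grad} (n x 2).
#' @export
edgePotential <- function(x, sys) {
  p <- .callPotential(.cppArgs(x, sys, useAngles = FALSE, usePerimeter = FALSE),
                      TRUE)
  if (!p$admissible) .singularityStop()
  list(value = p$fe, He = p$he, Ge = p$ge, grad = p$grad)
}

#' Corner-angle deformation potential Ftheta
#'
#' \code{Ftheta = (Htheta + Gtheta) / |Theta|}: the harmonic angle penalty
#' plus the barrier diverging as any corner angle approaches 0 or pi.
#'
#' @inheritParams edgePotential
#' @return list with \code{value}, \code{Htheta}, \code{Gtheta}, \code{grad}.
#' @export
anglePotential <- function(x, sys) {
  p <- .callPotential(.cppArgs(x, sys, useEdges = FALSE, usePerimeter = FALSE),
                      TRUE)
  if (!p$admissible) .singularityStop()
  list(value = p$ftheta, Htheta = p$htheta, Gtheta = p$gtheta, grad = p$grad)
}

#' Perimeter potential Fp
#'
#' \code{Fp = 1/2 * sum over perimeter vertices of |x_u - x0_u|^2}.
#'
#' @inheritParams edgePotential
#' @return list with \code{value} and \code{grad}.
#' @export
perimeterPotential <- function(x, sys) {
  p <- .callPotential(.cppArgs(x, sys, useEdges = FALSE, useAngles = FALSE),
                      TRUE)
  list(value = p$fp, grad = p$grad)
}

#' Anchor potential Fphi (inverted-Gaussian wells)
#'
#' \code{Fphi = -(1/|Phi|) * sum w * exp(-|x_u - y|^2 / sigma^2)}.  The
#' negative sign makes each anchor a potential well: the term decreases as a
#' retinotopic vertex approaches its anchor point.
#'
#' @param x current 2D coordinates.
#' @param anchors an [AnchorSet-class] (empty set gives 0).
#' @return list with \code{value} and \code{grad}.
#' @export
anchorPotential <- function(x, anchors) {
  p <- .callPotential(.cppArgs(x, NULL, anchors), TRUE)
  list(value = p$fphi, grad = p$grad)
}

#' Total registration potential and gradient
#'
#' \code{F = Fe + Ftheta + Fp + Fphi} exactly; the gradient is the sum of the
#' term gradients.  \code{exp(-F)} is the unnormalized posterior density of
#' the configuration (deformation terms play the prior, anchors the
#' likelihood).
#'
#' @param x current 2D coordinates.
#' @param sys a [RegistrationSystem-class].
#' @param anchors an [AnchorSet-class] or NULL.
#' @return \code{totalPotential}: list with \code{value} and the four term
#'   values; \code{totalGradient}: the n x 2 gradient matrix.
#' @export
totalPotential <- function(x, sys, anchors = NULL) {
  p <- .callPotential(.cppArgs(x, sys, anchors), FALSE)
  if (!p$admissible) .singularityStop()
  list(value = p$f, Fe = p$fe, Ftheta = p$ftheta, Fp = p$fp, Fphi = p$fphi)
}

#' @rdname totalPotential
#' @export
totalGradient <- function(x, sys, anchors = NULL) {
  p <- .callPotential(.cppArgs(x, sys, anchors), TRUE)
  if (!p$admissible) .singularityStop()
  p$grad
}

#' @rdname totalPotential
#' @export
posteriorDensity <- function(x, sys, anchors = NULL) {
  exp(-totalPotential(x, sys, anchors)$value)
}

#' Minimizer settings
#'
#' @param steps iteration count; the default follows the at-least-2500-step
#'   schedule.
#' @param maxStep per-vertex displacement cap per step; NA resolves to
#'   1/50 of the mean edge length at registration time.
#' @param noiseScale scale of the multiplicative exponential gradient noise;
#'   the default 0.7 / ln 2 makes the median per-vertex magnitude factor 1.7.
#'   Zero disables noise, making descent strictly monotone.
#' @param backtrackFactor step shrink on a rejected step.
#' @param maxRetries bounded retries per step.
#' @param seed RNG seed (NA leaves the RNG state alone).
#' @param gradTol optional early-stop gradient tolerance (0 = run all steps).
#' @param fluctTol relative potential increase tolerated per accepted step
#'   while noise is enabled.  The noise (and the slack that admits its
#'   fluctuations) lets the descent keep per-vertex steps near the
#'   displacement cap instead of collapsing to the stiff barrier curvature,
#'   which speeds convergence dramatically without changing the minimum.
#' @return a [MinimizerConfig-class].
#' @export
minimizerConfig <- function(steps = 2500, maxStep = NA_real_,
                            noiseScale = 0.7 / log(2), backtrackFactor = 0.5,
                            maxRetries = 50, seed = NA_real_, gradTol = 0,
                            fluctTol = 1e-3) {
  new("MinimizerConfig", steps = as.integer(steps),
      maxStep = as.numeric(maxStep), noiseScale = as.numeric(noiseScale),
      backtrackFactor = as.numeric(backtrackFactor),
      maxRetries = as.integer(maxRetries), seed = as.numeric(seed),
      gradTol = as.numeric(gradTol), fluctTol = as.numeric(fluctTol))
}

#' Register a map to its anchors by potential minimization
#'
#' Gradient descent on the total potential with: a per-vertex displacement
#' cap per step; optional per-vertex multiplicative exponential gradient
#' noise (direction preserved); and backtracking whenever a proposed step
#' would cross an edge-length or angle singularity or fail to decrease the
#' potential.  No face can invert at any accepted step, so the mesh topology
#' is preserved along the whole trajectory.
#'
#' @param sys a [RegistrationSystem-class].
#' @param anchors an [AnchorSet-class] (or NULL for no data; the reference
#'   configuration is then already the minimum).
#' @param config a [MinimizerConfig-class].
#' @return a [RegistrationResult-class].
#' @export
registerMap <- function(sys, anchors = NULL, config = minimizerConfig()) {
  if (is.null(anchors)) anchors <- .emptyAnchors()
  maxStep <- if (is.na(config@maxStep)) sys@meanEdgeLength / 50 else config@maxStep
  if (!is.na(config@seed)) set.seed(as.integer(config@seed))
  a <- .cppArgs(sys@x0, sys, anchors)
  res <- cpp_minimize(a$x, a$E, a$r0, a$q0, a$q1, a$Th, a$a0, a$P, a$x0,
                      a$av, a$ay, a$asig, a$aw,
                      config@steps, maxStep, config@noiseScale,
                      config@backtrackFactor, config@maxRetries,
                      config@gradTol, config@fluctTol)
  if (res$skipped > 0 && res$skipped >= config@steps)
    warning("registration stagnated: every step was rejected")
  new("RegistrationResult", coords = res$x, potential = res$potential,
      backtracks = as.integer(res$backtracks),
      skipped = as.integer(res$skipped),
      finalGradNorm = res$finalGradNorm,
      diagnostics = list(minAngle = res$minAngle, maxAngle = res$maxAngle,
                         minEdge = res$minEdge, maxEdgeFrac = res$maxEdgeFrac,
                         stalled = res$stalled),
      seed = config@seed)
}

#' Construct anchors linking measured vertices to the model
#'
#' For every retinotopic vertex with variance explained at or above the
#' threshold, one anchor is placed per modeled area, at the model point
#' where that area represents the vertex's measured (polar angle,
#' eccentricity).  The well width sigma is the minimum distance from the
#' anchor point to any other anchor point of the same vertex, capped at 20
#' times the mean edge length.  The base weight is the variance explained,
#' reduced by a field-sign factor when the data's local field sign mismatches
#' the target area's sign, and by a log-normal pRF-size factor comparing the
#' measured size with the model's linear size-vs-eccentricity function.
#'
#' @param data a [RetinotopyData-class] whose vertexId indexes the vertices
#'   of the registration mesh.
#' @param model a [RetinotopyModel-class].
#' @param sys the [RegistrationSystem-class] of the data mesh.
#' @param threshold variance-explained threshold (vertices strictly below it
#'   get no anchors).
#' @param fieldSignFactor multiplicative weight reduction on field-sign
#'   mismatch (NULL disables the factor).
#' @param sizeSigma log-scale width of the pRF-size factor (NULL disables).
#' @return an [AnchorSet-class].
#' @export
buildAnchors <- function(data, model, sys, threshold = 0.1,
                         fieldSignFactor = 0.25, sizeSigma = log(2)) {
  hemi <- data@hemisphere
  omega <- data@varianceExplained
  ok <- !is.na(omega) & omega >= threshold &
    is.finite(data@polarAngle) & is.finite(data@eccentricity)
  sel <- which(ok)
  if (!length(sel))
    return(.emptyAnchors())
  vid <- data@vertexId[sel]
  vfObs <- visualFieldCoords(data@polarAngle[sel], data@eccentricity[sel], hemi)

  mesh <- model@mesh
  xyModel <- visualFieldCoords(model@polarAngle, model@eccentricity, hemi)
  xyModel[!is.finite(xyModel)] <- 1e9   # unassigned model vertices never match

  # data-side field sign per selected vertex (mean sign of adjacent faces)
  vSign <- rep(0, length(sel))
  if (!is.null(fieldSignFactor) && nrow(sys@faces)) {
    vfAll <- matrix(NA_real_, nrow(sys@x0), 2)
    okAll <- which(ok)
    vfAll[data@vertexId[okAll], ] <-
      visualFieldCoords(data@polarAngle[okAll], data@eccentricity[okAll], hemi)
    fSign <- triangleFieldSign(sys@x0, vfAll, sys@faces)
    acc <- numeric(nrow(sys@x0))
    for (k in 1:3) {
      s <- tapply(ifelse(is.na(fSign), 0, fSign), sys@faces[, k], sum)
      idx <- as.integer(names(s))
      acc[idx] <- acc[idx] + as.numeric(s)
    }
    vSign <- sign(acc[vid])
  }

  parts <- vector("list", length(model@areas))
  nSkipped <- 0L
  for (ai in seq_along(model@areas)) {
    area <- model@areas[ai]
    fIdx <- which(model@faceArea == area)
    if (!length(fIdx)) next
    fc <- mesh@faces[fIdx, , drop = FALSE]
    loc <- cpp_locate(xyModel, matrix(as.integer(fc), ncol = 3), vfObs, 1e-9)
    hit <- loc$face > 0L
    nSkipped <- nSkipped + sum(!hit)
    if (!any(hit)) next
    fv <- fc[loc$face[hit], , drop = FALSE]
    b <- loc$bary[hit, , drop = FALSE]
    y <- cbind(
      b[, 1] * mesh@coords[fv[, 1], 1] + b[, 2] * mesh@coords[fv[, 2], 1] +
        b[, 3] * mesh@coords[fv[, 3], 1],
      b[, 1] * mesh@coords[fv[, 1], 2] + b[, 2] * mesh@coords[fv[, 2], 2] +
        b[, 3] * mesh@coords[fv[, 3], 2])

    w <- omega[sel][hit]
    if (!is.null(fieldSignFactor)) {
      aSign <- sign(sum(triangleFieldSign(mesh@coords, xyModel, fc), na.rm = TRUE))
      mism <- vSign[hit] != 0 & aSign != 0 & vSign[hit] != aSign
      w[mism] <- w[mism] * fieldSignFactor
    }
    if (!is.null(sizeSigma)) {
      sf <- model@sizeFun
      row <- match(area, sf$area)
      if (!is.na(row)) {
        sModel <- sf$slope[row] * data@eccentricity[sel][hit] + sf$intercept[row]
        sObs <- data@prfSize[sel][hit]
        fac <- ifelse(is.finite(sObs) & sObs > 0 & sModel > 0,
                      exp(-log(sObs / sModel)^2 / (2 * sizeSigma^2)), 1)
        w <- w * fac
      }
    }
    parts[[ai]] <- data.frame(vertex = vid[hit], x = y[, 1], y = y[, 2],
                              weight = w, area = area,
                              stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, parts)
  if (is.null(all) || !nrow(all)) {
    warning("no anchors could be placed (all measurements outside the model)")
    return(.emptyAnchors())
  }
  lost <- setdiff(vid, all$vertex)
  if (length(lost))
    warning(sprintf(paste("%d measured vertex(es) received no anchor:",
                          "coordinates outside every modeled area's",
                          "represented field"), length(lost)))

  ord <- order(all$vertex, match(all$area, model@areas))
  all <- all[ord, , drop = FALSE]
  cap <- 20 * sys@meanEdgeLength
  sigma <- rep(cap, nrow(all))
  grp <- split(seq_len(nrow(all)), all$vertex)
  for (g in grp) {
    if (length(g) < 2L) next
    pts <- cbind(all$x[g], all$y[g])
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    sigma[g] <- pmin(apply(d, 1, min), cap)
  }
  # a well narrower than half an edge length cannot be resolved by the mesh
  # and its near-singular gradient would throttle the global step size
  sigma <- pmax(sigma, sys@meanEdgeLength / 2)
  anchorSet(all$vertex, cbind(all$x, all$y), sigma, all$weight, all$area)
}
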