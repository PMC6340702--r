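## Quantitative evaluation: eccentricity-scaled errors, weighted MSE,
## cortical magnification, and deformation summaries (mean 3x3 distance
## matrix, planar metric embedding, RMSD).

#' Eccentricity-scaled prediction error
#'
#' The Euclidean distance in the visual field between predicted and
#' validation pRF centers, divided by the validation eccentricity.  Vertices
#' with zero validation eccentricity are excluded (NA) and counted.
#'
#' @param predAngle,predEccen predicted polar angle / eccentricity (deg).
#' @param validAngle,validEccen validation values (deg).
#' @param hemisphere hemisphere convention for the embedding.
#' @return numeric vector of scaled errors with attribute
#'   \code{excludedZeroEccen} (count of excluded vertices).
#' @export
scaledError <- function(predAngle, predEccen, validAngle, validEccen,
                        hemisphere = "rh") {
  p <- visualFieldCoords(predAngle, predEccen, hemisphere)
  v <- visualFieldCoords(validAngle, validEccen, hemisphere)
  d <- sqrt(rowSums((p - v)^2))
  out <- ifelse(validEccen > 0, d / validEccen, NA_real_)
  attr(out, "excludedZeroEccen") <- sum(validEccen <= 0, na.rm = TRUE)
  out
}

#' Variance-explained-weighted mean squared error
#'
#' \code{sum(w * e^2) / sum(w)} over vertices with finite errors and
#' weights.
#'
#' @param errors per-vertex errors.
#' @param weights validation variance explained.
#' @return scalar weighted MSE.
#' @export
weightedMSE <- function(errors, weights) {
  if (length(errors) != length(weights))
    stop("errors and weights must have equal length")
  ok <- is.finite(errors) & is.finite(weights)
  w <- weights[ok]
  if (sum(w) <= 0) stop("all weights are zero")
  sum(w * errors[ok]^2) / sum(w)
}

#' Full error report comparing predicted and validation maps
#'
#' @param pred,valid lists or data.frames with \code{polarAngle} and
#'   \code{eccentricity} per common vertex (degrees).
#' @param weights validation variance explained per vertex.
#' @param hemisphere hemisphere convention.
#' @param eccBands break points (deg) for eccentricity-band breakdowns of the
#'   weighted MSE.
#' @return list: per-vertex \code{scaledError}, \code{weightedMSE},
#'   \code{medianAbsAngleError} and \code{meanAbsAngleError} (deg),
#'   \code{medianAbsEccenError} and \code{meanAbsEccenError} (deg), a
#'   \code{bands} data.frame, and the excluded-vertex count.
#' @export
evaluatePrediction <- function(pred, valid, weights = rep(1, length(valid$polarAngle)),
                               hemisphere = "rh", eccBands = c(0, 3, 12)) {
  e <- scaledError(pred$polarAngle, pred$eccentricity,
                   valid$polarAngle, valid$eccentricity, hemisphere)
  dAng <- abs(pred$polarAngle - valid$polarAngle)
  dEcc <- abs(pred$eccentricity - valid$eccentricity)
  bands <- data.frame(lo = eccBands[-length(eccBands)], hi = eccBands[-1],
                      weightedMSE = NA_real_, n = NA_integer_)
  for (i in seq_len(nrow(bands))) {
    idx <- which(valid$eccentricity >= bands$lo[i] &
                   valid$eccentricity < bands$hi[i] & is.finite(e))
    bands$n[i] <- length(idx)
    if (length(idx) && sum(weights[idx], na.rm = TRUE) > 0)
      bands$weightedMSE[i] <- weightedMSE(e[idx], weights[idx])
  }
  list(scaledError = e,
       weightedMSE = weightedMSE(e, weights),
       medianAbsAngleError = median(dAng, na.rm = TRUE),
       meanAbsAngleError = mean(dAng, na.rm = TRUE),
       medianAbsEccenError = median(dEcc, na.rm = TRUE),
       meanAbsEccenError = mean(dEcc, na.rm = TRUE),
       bands = bands,
       excludedZeroEccen = attr(e, "excludedZeroEccen"))
}

#' Cortical magnification from pRF centers and vertex areas
#'
#' At each query eccentricity rho (on the horizontal meridian by default)
#' the magnification is the summed surface area of all vertices whose pRF
#' center falls within a disk of radius \code{rho * diskRatio} around the
#' query point, divided by the disk area (mm^2 per deg^2).  Disk membership
#' is inclusive (distance <= radius).
#'
#' @param prfCenters n x 2 visual-field Cartesian pRF centers (deg).
#' @param vertexAreas per-vertex surface areas (mm^2), e.g. from
#'   [vertexSurfaceAreas()] of the white surface.
#' @param queryEccen eccentricities at which to sample (deg, > 0).
#' @param queryAngle polar angle of the sampling ray (deg; 90 = horizontal
#'   meridian).
#' @param diskRatio disk radius as a fraction of eccentricity (alpha =
#'   rho / 3 by default).
#' @param hemisphere hemisphere convention for the query ray.
#' @return data.frame with \code{eccentricity} and \code{magnification}
#'   (NA where the disk contains no pRF center).
#' @export
corticalMagnification <- function(prfCenters, vertexAreas, queryEccen,
                                  queryAngle = 90, diskRatio = 1 / 3,
                                  hemisphere = "rh") {
  stopifnot(nrow(prfCenters) == length(vertexAreas))
  out <- data.frame(eccentricity = queryEccen, magnification = NA_real_)
  for (i in seq_along(queryEccen)) {
    rho <- queryEccen[i]
    if (!(rho > 0)) next
    q <- visualFieldCoords(queryAngle, rho, hemisphere)
    alpha <- rho * diskRatio
    d2 <- (prfCenters[, 1] - q[1])^2 + (prfCenters[, 2] - q[2])^2
    inside <- which(d2 <= alpha^2)
    if (length(inside))
      out$magnification[i] <- sum(vertexAreas[inside]) / (pi * alpha^2)
  }
  out
}

#' Summarize the anatomical and retinotopic deformation steps
#'
#' Computes per-vertex pairwise distances among three positions of the same
#' vertices (native, anatomically aligned, retinotopically aligned), their
#' mean 3x3 distance matrix over an ROI, a classical planar metric embedding
#' of the three mean points, the two step lengths with the interior angle at
#' the anatomical position, and the per-stage RMSD.
#'
#' @param native,anatomical,retinotopic n x 2 (or n x 3) positions sharing
#'   vertex order.
#' @param roi logical or integer vertex subset (default: all).
#' @return list: \code{meanDist} (3x3 matrix), \code{embedding} (3 x 2
#'   coordinates reproducing the mean distances exactly),
#'   \code{anatomicalStep}, \code{retinotopicStep}, \code{stepAngle}
#'   (degrees, NA when a step is zero), \code{rmsdAnatomical},
#'   \code{rmsdRetinotopic}.
#' @export
deformationSummary <- function(native, anatomical, retinotopic, roi = NULL) {
  if (!is.null(roi)) {
    native <- native[roi, , drop = FALSE]
    anatomical <- anatomical[roi, , drop = FALSE]
    retinotopic <- retinotopic[roi, , drop = FALSE]
  }
  dNA <- sqrt(rowSums((anatomical - native)^2))
  dAR <- sqrt(rowSums((retinotopic - anatomical)^2))
  dNR <- sqrt(rowSums((retinotopic - native)^2))
  m <- matrix(0, 3, 3, dimnames = list(c("native", "anatomical", "retinotopic"),
                                       c("native", "anatomical", "retinotopic")))
  m["native", "anatomical"] <- m["anatomical", "native"] <- mean(dNA)
  m["anatomical", "retinotopic"] <- m["retinotopic", "anatomical"] <- mean(dAR)
  m["native", "retinotopic"] <- m["retinotopic", "native"] <- mean(dNR)

  # classical embedding of three points: N at origin, A on the x-axis,
  # R placed by the law of cosines (three points always embed in the plane)
  a <- m["native", "anatomical"]
  emb <- matrix(0, 3, 2, dimnames = list(rownames(m), c("x", "y")))
  emb[2, 1] <- a
  if (a > 0) {
    rx <- (a^2 + m["native", "retinotopic"]^2 -
             m["anatomical", "retinotopic"]^2) / (2 * a)
    ry2 <- m["native", "retinotopic"]^2 - rx^2
    emb[3, ] <- c(rx, sqrt(max(0, ry2)))
  } else {
    emb[3, ] <- c(m["native", "retinotopic"], 0)
  }

  stepA <- m["native", "anatomical"]
  stepR <- m["anatomical", "retinotopic"]
  angle <- NA_real_
  if (stepA > 0 && stepR > 0) {
    cosang <- (stepA^2 + stepR^2 - m["native", "retinotopic"]^2) /
      (2 * stepA * stepR)
    angle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }
  list(meanDist = m, embedding = emb,
       anatomicalStep = stepA, retinotopicStep = stepR, stepAngle = angle,
       rmsdAnatomical = sqrt(mean(dNA^2)),
       rmsdRetinotopic = sqrt(mean(dAR^2)))
}
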