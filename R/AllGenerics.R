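## Generics and accessors.  Slot access outside the package goes through
## these, as in the Bioconductor convention.

#' @rdname FlatMap-class
#' @param object,x an object.
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname FlatMap-class
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))
#' @rdname FlatMap-class
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))
#' @rdname FlatMap-class
#' @export
setGeneric("angleTriples", function(object) standardGeneric("angleTriples"))
#' @rdname FlatMap-class
#' @export
setGeneric("perimeter", function(object) standardGeneric("perimeter"))
#' @rdname FlatMap-class
#' @export
setGeneric("meanEdgeLength", function(object) standardGeneric("meanEdgeLength"))
#' @rdname FlatMap-class
#' @export
setGeneric("nVertices", function(object) standardGeneric("nVertices"))

#' @rdname RetinotopyData-class
#' @export
setGeneric("polarAngle", function(object) standardGeneric("polarAngle"))
#' @rdname RetinotopyData-class
#' @export
setGeneric("eccentricity", function(object) standardGeneric("eccentricity"))
#' @rdname RetinotopyData-class
#' @export
setGeneric("prfSize", function(object) standardGeneric("prfSize"))
#' @rdname RetinotopyData-class
#' @export
setGeneric("varianceExplained",
           function(object) standardGeneric("varianceExplained"))
#' @rdname RetinotopyData-class
#' @export
setGeneric("hemisphere", function(object) standardGeneric("hemisphere"))
#' @rdname RetinotopyData-class
#' @export
setGeneric("vertexIds", function(object) standardGeneric("vertexIds"))

#' @rdname RetinotopyModel-class
#' @param what "vertex" or "face" labels.
#' @export
setGeneric("areaLabels",
           function(object, what = c("vertex", "face")) standardGeneric("areaLabels"))
#' @rdname RetinotopyModel-class
#' @export
setGeneric("areaNames", function(object) standardGeneric("areaNames"))
#' @rdname RetinotopyModel-class
#' @export
setGeneric("modelMesh", function(object) standardGeneric("modelMesh"))

#' @rdname RegistrationResult-class
#' @export
setGeneric("registeredCoords",
           function(object) standardGeneric("registeredCoords"))
#' @rdname RegistrationResult-class
#' @export
setGeneric("potentialTrace", function(object) standardGeneric("potentialTrace"))

## ---- methods -------------------------------------------------------------

#' @rdname FlatMap-class
setMethod("coords", "FlatMap", function(object) object@coords)
#' @rdname FlatMap-class
setMethod("faces", "FlatMap", function(object) object@faces)
#' @rdname FlatMap-class
setMethod("edges", "FlatMap", function(object) object@edges)
#' @rdname FlatMap-class
setMethod("angleTriples", "FlatMap", function(object) object@angleTriples)
#' @rdname FlatMap-class
setMethod("perimeter", "FlatMap", function(object) object@perimeter)
#' @rdname FlatMap-class
setMethod("meanEdgeLength", "FlatMap", function(object) object@meanEdgeLength)
#' @rdname FlatMap-class
setMethod("nVertices", "FlatMap", function(object) nrow(object@coords))

#' @rdname Mesh3D-class
#' @param object a Mesh3D.
setMethod("coords", "Mesh3D", function(object) object@coords)
#' @rdname Mesh3D-class
setMethod("faces", "Mesh3D", function(object) object@faces)
#' @rdname Mesh3D-class
setMethod("nVertices", "Mesh3D", function(object) nrow(object@coords))

#' @rdname RetinotopyData-class
setMethod("polarAngle", "RetinotopyData", function(object) object@polarAngle)
#' @rdname RetinotopyData-class
setMethod("eccentricity", "RetinotopyData", function(object) object@eccentricity)
#' @rdname RetinotopyData-class
setMethod("prfSize", "RetinotopyData", function(object) object@prfSize)
#' @rdname RetinotopyData-class
setMethod("varianceExplained", "RetinotopyData",
          function(object) object@varianceExplained)
#' @rdname RetinotopyData-class
setMethod("hemisphere", "RetinotopyData", function(object) object@hemisphere)
#' @rdname RetinotopyData-class
setMethod("vertexIds", "RetinotopyData", function(object) object@vertexId)

#' @rdname RetinotopyModel-class
setMethod("polarAngle", "RetinotopyModel", function(object) object@polarAngle)
#' @rdname RetinotopyModel-class
setMethod("eccentricity", "RetinotopyModel", function(object) object@eccentricity)
#' @rdname RetinotopyModel-class
setMethod("areaLabels", "RetinotopyModel", function(object, what = c("vertex", "face")) {
  what <- match.arg(what)
  if (what == "vertex") object@vertexArea else object@faceArea
})
#' @rdname RetinotopyModel-class
setMethod("areaNames", "RetinotopyModel", function(object) object@areas)
#' @rdname RetinotopyModel-class
setMethod("modelMesh", "RetinotopyModel", function(object) object@mesh)

#' @rdname InferredMaps-class
setMethod("polarAngle", "InferredMaps", function(object) object@polarAngle)
#' @rdname InferredMaps-class
setMethod("eccentricity", "InferredMaps", function(object) object@eccentricity)
#' @rdname InferredMaps-class
setMethod("prfSize", "InferredMaps", function(object) object@prfSize)
#' @rdname InferredMaps-class
setMethod("vertexIds", "InferredMaps", function(object) object@vertexId)
#' @rdname InferredMaps-class
#' @param what unused for InferredMaps.
setMethod("areaLabels", "InferredMaps", function(object, what) object@area)

#' @rdname RegistrationResult-class
setMethod("registeredCoords", "RegistrationResult", function(object) object@coords)
#' @rdname RegistrationResult-class
setMethod("potentialTrace", "RegistrationResult", function(object) object@potential)

## ---- show methods --------------------------------------------------------

setMethod("show", "FlatMap", function(object) {
  cat(sprintf("FlatMap: %d vertices, %d faces, %d edges, %d perimeter vertices\n",
              nrow(object@coords), nrow(object@faces), nrow(object@edges),
              length(object@perimeter)))
  cat(sprintf("  mean edge length: %.4g map units\n", object@meanEdgeLength))
})

setMethod("show", "Mesh3D", function(object) {
  cat(sprintf("Mesh3D: %d vertices, %d faces", nrow(object@coords),
              nrow(object@faces)))
  if (length(object@vertexData))
    cat(sprintf(", fields: %s", paste(names(object@vertexData), collapse = ", ")))
  cat("\n")
})

setMethod("show", "RetinotopyModel", function(object) {
  cat(sprintf("RetinotopyModel (schema %s): %d vertices, %d areas (%s)\n",
              object@version, nrow(object@mesh@coords), length(object@areas),
              paste(object@areas, collapse = ", ")))
  e <- object@eccentricity[is.finite(object@eccentricity)]
  cat(sprintf("  eccentricity range: %.3g - %.3g deg\n",
              min(e), max(e)))
})

setMethod("show", "RetinotopyData", function(object) {
  w <- object@varianceExplained
  cat(sprintf("RetinotopyData (%s): %d vertices, %d with variance explained >= 0.1\n",
              object@hemisphere, length(object@vertexId),
              sum(w >= 0.1, na.rm = TRUE)))
})

setMethod("show", "AnchorSet", function(object) {
  cat(sprintf("AnchorSet: %d anchors on %d vertices, areas: %s\n",
              length(object@vertex), length(unique(object@vertex)),
              paste(unique(object@area), collapse = ", ")))
})

setMethod("show", "RegistrationResult", function(object) {
  p <- object@potential
  cat(sprintf("RegistrationResult: %d steps, potential %.6g -> %.6g\n",
              length(p) - 1L, p[1], p[length(p)]))
  cat(sprintf("  backtracks: %d, skipped steps: %d, |grad| = %.3g\n",
              object@backtracks, object@skipped, object@finalGradNorm))
})

setMethod("show", "InferredMaps", function(object) {
  cat(sprintf("InferredMaps: %d vertices, %d inside modeled areas\n",
              length(object@vertexId), sum(object@area != "none")))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset (seed %s): %d vertices, %d scans\n",
              format(object@seed), nrow(object@subjectMap@coords),
              length(object@scans)))
})
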