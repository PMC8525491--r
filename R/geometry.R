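#' Construct a volume geometry
#'
#' @param nFast,nSlow,nAxial voxel counts (each >= 16)
#' @param dxUm lateral voxel pitch in um (default 1.4)
#' @param dzUm axial voxel pitch in um (default 1.9)
#' @return a \linkS4class{VolumeGeometry}
#' @examples
#' VolumeGeometry(256, 256, 512)
#' @export
VolumeGeometry <- function(nFast, nSlow, nAxial, dxUm = 1.4, dzUm = 1.9) {
  new("VolumeGeometry", nFast = as.integer(nFast), nSlow = as.integer(nSlow),
      nAxial = as.integer(nAxial), dxUm = dxUm, dzUm = dzUm)
}

#' Construct a noise / motion model
#'
#' @param speckleContrast multiplicative speckle coefficient of variation
#' @param backgroundLevel additive background floor
#' @param motionJitterUm per-B-scan translation scale (axial, lateral), um
#' @param projectionTail relative strength of the rendered decorrelation
#'   tail beneath superficial vessels (0 disables)
#' @param seed integer RNG seed
#' @return a \linkS4class{NoiseModel}
#' @export
NoiseModel <- function(speckleContrast = 0.3, backgroundLevel = 0.03,
                       motionJitterUm = c(0, 0), projectionTail = 0.4,
                       seed = 1L) {
  new("NoiseModel", speckleContrast = speckleContrast,
      backgroundLevel = backgroundLevel,
      motionJitterUm = as.numeric(motionJitterUm),
      projectionTail = projectionTail, seed = as.integer(seed))
}

#' @describeIn VolumeGeometry-class accessor generics
#' @param object an object with a geometry
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @export
setMethod("geometry", "OCTVolume", function(object) object@geometry)
#' @export
setMethod("geometry", "SceneGroundTruth", function(object) object@geometry)
#' @export
setMethod("geometry", "VesselnessVolume", function(object) object@geometry)
#' @export
setMethod("geometry", "Angiogram", function(object) object@geometry)
#' @export
setMethod("geometry", "LayerSurfaces", function(object) object@geometry)
#' @export
setMethod("geometry", "Slab", function(object) object@geometry)

#' Intensity array accessor
#' @param object an \linkS4class{OCTVolume}
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @export
setMethod("intensities", "OCTVolume", function(object) object@intensities)

#' Angiogram mask accessor
#' @param object an \linkS4class{Angiogram}
#' @export
setGeneric("angioMask", function(object) standardGeneric("angioMask"))
#' @export
setMethod("angioMask", "Angiogram", function(object) object@mask)

#' Vesselness score accessor
#' @param object a \linkS4class{VesselnessVolume}
#' @export
setGeneric("vesselScores", function(object) standardGeneric("vesselScores"))
#' @export
setMethod("vesselScores", "VesselnessVolume", function(object) object@scores)

#' Surface depth-map accessor
#'
#' @param object a \linkS4class{LayerSurfaces} or
#'   \linkS4class{SceneGroundTruth}
#' @param which optional surface name
#' @export
setGeneric("surfaceMaps",
           function(object, which = NULL) standardGeneric("surfaceMaps"))
#' @export
setMethod("surfaceMaps", "LayerSurfaces", function(object, which = NULL) {
  if (is.null(which)) object@surfaces else object@surfaces[[which]]
})
#' @export
setMethod("surfaceMaps", "SceneGroundTruth", function(object, which = NULL) {
  if (is.null(which)) object@surfaces else object@surfaces[[which]]
})

#' Metadata accessor
#' @param object an \linkS4class{OCTVolume}
#' @export
setGeneric("volumeMetadata",
           function(object) standardGeneric("volumeMetadata"))
#' @export
setMethod("volumeMetadata", "OCTVolume", function(object) object@metadata)

fieldUm <- function(g) c(fast = g@nFast * g@dxUm, slow = g@nSlow * g@dxUm,
                         axial = g@nAxial * g@dzUm)

setMethod("show", "VolumeGeometry", function(object) {
  cat(sprintf("VolumeGeometry: %d x %d A-scans x %d axial, %.2f um lateral / %.2f um axial\n",
              object@nFast, object@nSlow, object@nAxial, object@dxUm,
              object@dzUm))
})

setMethod("show", "OCTVolume", function(object) {
  g <- object@geometry
  t <- object@metadata$timepointDays
  cat(sprintf("OCTVolume [%d x %d x %d] (axial x fast x slow)%s\n",
              g@nAxial, g@nFast, g@nSlow,
              if (!is.null(t)) sprintf(", day %g", t) else ""))
  cat(sprintf("  field: %.0f x %.0f um lateral, %.0f um depth\n",
              g@nFast * g@dxUm, g@nSlow * g@dxUm, g@nAxial * g@dzUm))
})

setMethod("show", "SceneGroundTruth", function(object) {
  cat(sprintf("SceneGroundTruth: condition '%s', %d lesion(s), dimScale %.2f\n",
              object@condition, length(object@lesionSpecs), object@dimScale))
  show(object@geometry)
})

setMethod("show", "Angiogram", function(object) {
  cat(sprintf("Angiogram: %s positive voxels (%.2f%%)%s\n",
              format(sum(object@mask), big.mark = ","),
              100 * mean(object@mask),
              if (isTRUE(object@provenance$shadowRejected))
                ", shadow-rejected" else ""))
})

setMethod("show", "DynamicsTrace", function(object) {
  cat(sprintf("DynamicsTrace (%s): days %s\n", object@dimension,
              paste(object@days, collapse = ", ")))
  cat(sprintf("  percent change: %s\n",
              paste(sprintf("%+.1f", object@percentChange), collapse = " ")))
  cat(sprintf("  steady-state onset: %s (threshold %.1f%%)\n",
              if (is.na(object@steadyOnset)) "none"
              else sprintf("day %g", object@steadyOnset),
              object@significanceThreshold))
})

setMethod("show", "GroupStats", function(object) {
  cat(sprintf("GroupStats (%s): %d cells, pooled CV %.3f\n",
              object@condition, nrow(object@cells), object@pooledCv))
})

setMethod("show", "LesionClassification", function(object) {
  e <- object@evidence
  cat(sprintf("LesionClassification: %s (rupture=%s, void=%s, height=%.0f um, DVP non-perfusion=%s)\n",
              object@label, e$rpeRupture, e$choroidVoid, e$maxHeightUm,
              e$dvpNonperfusion))
})

setMethod("show", "PerfusionTimecourse", function(object) {
  cat(sprintf("PerfusionTimecourse: %d plexus/day cells, drop fraction %.2f\n",
              nrow(object@densities), object@dropFraction))
  if (nrow(object@intervals)) {
    apply(object@intervals, 1, function(r)
      cat(sprintf("  %s: non-perfused (%s, %s)\n", r[["plexus"]],
                  r[["start_day"]], r[["end_day"]])))
  } else cat("  no non-perfusion intervals\n")
})
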