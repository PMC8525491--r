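#' @import methods
#' @importFrom stats approx filter fft mad median quantile rnorm runif rgamma
#'   rexp sd setNames aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

#' Voxel geometry of an OCT data cube
#'
#' Describes the sampling grid of a volume: A-scan counts along the fast and
#' slow lateral axes, axial sample count, and the lateral / axial voxel
#' pitches in micrometres. The defaults correspond to a high-density en-face
#' acquisition with 1.4 um lateral and 1.9 um axial voxels; desk-scale work
#' uses reduced A-scan counts at the same pitches.
#'
#' @slot nFast integer, A-scans per B-scan (fast lateral axis)
#' @slot nSlow integer, number of B-scans (slow axis)
#' @slot nAxial integer, axial samples per A-scan
#' @slot dxUm numeric, lateral voxel pitch (um), both lateral axes
#' @slot dzUm numeric, axial voxel pitch (um)
#' @exportClass VolumeGeometry
setClass("VolumeGeometry",
  representation(nFast = "integer", nSlow = "integer", nAxial = "integer",
                 dxUm = "numeric", dzUm = "numeric"),
  validity = function(object) {
    if (any(c(object@nFast, object@nSlow, object@nAxial) < 16L))
      return("all voxel counts must be >= 16")
    if (object@dxUm <= 0 || object@dzUm <= 0)
      return("voxel pitches must be positive")
    TRUE
  })

#' Acquisition noise and motion model for the simulator
#'
#' @slot speckleContrast numeric, coefficient of variation of the
#'   multiplicative (gamma) speckle; 0 disables speckle
#' @slot backgroundLevel numeric, additive background floor
#' @slot motionJitterUm numeric length-2, per-B-scan translation scale
#'   (axial, lateral) in um; realised jitter is integer-voxel
#' @slot projectionTail numeric, relative strength of the decorrelation-tail
#'   artifact rendered in the deep plexus band beneath superficial vessels
#' @slot seed integer RNG seed; identical seed and parameters give
#'   bit-identical output
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(speckleContrast = "numeric", backgroundLevel = "numeric",
                 motionJitterUm = "numeric", projectionTail = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@speckleContrast < 0) return("speckleContrast must be >= 0")
    if (length(object@motionJitterUm) != 2L || any(object@motionJitterUm < 0))
      return("motionJitterUm must be two non-negative values (axial, lateral)")
    if (object@projectionTail < 0) return("projectionTail must be >= 0")
    TRUE
  })

#' Per-lesion simulation specification
#'
#' Holds the ground-truth time course of one laser lesion: the four defined
#' dimensions (ONL lateral disruption, RPE lateral disruption, maximal
#' OPL-RPE height, ELM-IS/OS protrusion width) per timepoint, the deep-plexus
#' non-perfusion schedule, and the lognormal dispersion used for
#' lesion-to-lesion variability.
#'
#' @slot condition "acute" or "cnv"
#' @slot centerUm numeric length-2 lateral position (fast, slow) in um
#' @slot timepointDays ordered numeric timepoint grid (days)
#' @slot trueDims numeric matrix, one row per timepoint, columns
#'   onl_um, rpe_um, height_um, pr_um
#' @slot nonperfusionSchedule numeric per-timepoint fraction of deep/
#'   intermediate plexus vessel voxels removed inside the lesion cylinder
#' @slot dispersionCv numeric matrix matching trueDims: per-cell coefficient
#'   of variation that generated the lognormal scaling (0 when dispersion off)
#' @slot rpeRupture logical, whether the RPE/Bruch's complex is ruptured
#' @exportClass LesionSpec
setClass("LesionSpec",
  representation(condition = "character", centerUm = "numeric",
                 timepointDays = "numeric", trueDims = "matrix",
                 nonperfusionSchedule = "numeric", dispersionCv = "matrix",
                 rpeRupture = "logical"),
  validity = function(object) {
    if (!object@condition %in% c("acute", "cnv"))
      return("condition must be 'acute' or 'cnv'")
    if (is.unsorted(object@timepointDays, strictly = TRUE))
      return("timepointDays must be strictly increasing")
    if (any(object@trueDims < 0)) return("true dimensions must be >= 0")
    if (any(object@nonperfusionSchedule < 0 | object@nonperfusionSchedule > 1))
      return("nonperfusionSchedule must lie in [0, 1]")
    if (object@condition == "acute" &&
        (any(object@nonperfusionSchedule > 0) || object@rpeRupture))
      return("acute lesions have no non-perfusion and no RPE rupture")
    TRUE
  })

#' Ground truth of a simulated retinal scene
#'
#' The oracle surface for all downstream tests: baseline layer surfaces,
#' vessel centerlines per plexus (superficial, intermediate and deep inner
#' plexuses plus choroid), and the lesion specifications. Voxelised vessel
#' masks and per-timepoint surfaces are derived on demand via
#' \code{\link{plexusMasksAt}} and \code{\link{surfacesAt}}.
#'
#' @slot geometry a \linkS4class{VolumeGeometry}
#' @slot condition "acute", "cnv" or "control"
#' @slot surfaces list of baseline depth maps (um from volume top), matrices
#'   nFast x nSlow, for ILM, ONLtop (OPL/ONL boundary), ELM, ISOS, RPE and
#'   choroidBase
#' @slot vesselCenterlines list per plexus of per-vessel data frames with
#'   columns x_um, y_um and a radius_um attribute
#' @slot lesionSpecs list of \linkS4class{LesionSpec}
#' @slot dimScale numeric, desk-scale factor applied to lesion geometry
#' @slot seed integer seed the scene was built from
#' @slot params list of renderer constants (layer depths, amplitudes)
#' @exportClass SceneGroundTruth
setClass("SceneGroundTruth",
  representation(geometry = "VolumeGeometry", condition = "character",
                 surfaces = "list", vesselCenterlines = "list",
                 lesionSpecs = "list", dimScale = "numeric", seed = "integer",
                 params = "list"),
  validity = function(object) {
    need <- c("ILM", "ONLtop", "ELM", "ISOS", "RPE", "choroidBase")
    if (!all(need %in% names(object@surfaces)))
      return(paste("surfaces must contain", paste(need, collapse = ", ")))
    s <- object@surfaces
    for (i in seq_len(length(need) - 1L))
      if (any(s[[need[i]]] >= s[[need[i + 1L]]]))
        return("surfaces must be strictly depth-ordered at every position")
    TRUE
  })

#' A 3D OCT intensity volume
#'
#' @slot intensities numeric array [z, x, y] (axial, fast, slow),
#'   non-negative and finite
#' @slot geometry a \linkS4class{VolumeGeometry}
#' @slot metadata list: timepointDays, seed, appliedOffsets (nSlow x 2 matrix
#'   of axial/lateral voxel shifts applied by the renderer), and after
#'   registration estimatedOffsets plus per-scan flags
#' @exportClass OCTVolume
setClass("OCTVolume",
  representation(intensities = "array", geometry = "VolumeGeometry",
                 metadata = "list"),
  validity = function(object) {
    g <- object@geometry
    if (!identical(dim(object@intensities),
                   c(g@nAxial, g@nFast, g@nSlow)))
      return("intensity array shape must be (nAxial, nFast, nSlow)")
    if (!all(is.finite(object@intensities)))
      return("intensities must be finite")
    TRUE
  })

#' Segmented retinal layer surfaces
#'
#' Depth maps in um from the volume top for ILM, ONLtop (OPL/ONL boundary),
#' ELM, ISOS and RPE, with a per-position validity mask. Depth ordering
#' ILM < ONLtop < ELM < ISOS < RPE holds wherever valid.
#'
#' @slot surfaces named list of nFast x nSlow depth maps (um)
#' @slot validity logical nFast x nSlow matrix
#' @slot geometry a \linkS4class{VolumeGeometry}
#' @exportClass LayerSurfaces
setClass("LayerSurfaces",
  representation(surfaces = "list", validity = "matrix",
                 geometry = "VolumeGeometry"))

#' A surface-referenced slab
#'
#' A depth band of a volume flattened to a reference surface: every A-scan
#' column is shifted (nearest voxel, no interpolation) so the reference
#' surface is flat, then a band of \code{thicknessUm} starting
#' \code{offsetUm} below the surface is extracted.
#'
#' @slot referenceSurface name of the reference surface
#' @slot offsetUm signed start offset from the reference (um)
#' @slot thicknessUm band height (um), default 60
#' @slot voxels array [band, x, y]
#' @slot geometry source \linkS4class{VolumeGeometry}
#' @slot clipped logical, TRUE when the band exceeded the volume extent
#'   somewhere and was zero-filled
#' @exportClass Slab
setClass("Slab",
  representation(referenceSurface = "character", offsetUm = "numeric",
                 thicknessUm = "numeric", voxels = "array",
                 geometry = "VolumeGeometry", clipped = "logical"),
  validity = function(object) {
    if (object@thicknessUm <= 0) return("thicknessUm must be > 0")
    TRUE
  })

#' Vesselness score volume
#'
#' @slot scores numeric array in [0, 1], co-registered with the source volume
#' @slot geometry a \linkS4class{VolumeGeometry}
#' @slot iteratorLog ordered list of the applied enhancement stages with
#'   their parameters (non-empty)
#' @exportClass VesselnessVolume
setClass("VesselnessVolume",
  representation(scores = "array", geometry = "VolumeGeometry",
                 iteratorLog = "list"),
  validity = function(object) {
    if (length(object@iteratorLog) == 0L)
      return("iteratorLog must record at least one stage")
    rng <- range(object@scores)
    if (rng[1] < 0 || rng[2] > 1) return("scores must lie in [0, 1]")
    TRUE
  })

#' Binary 3D angiogram
#'
#' @slot mask logical array [z, x, y]
#' @slot geometry a \linkS4class{VolumeGeometry}
#' @slot provenance list: threshold parameters, shadow-rejection flag,
#'   source identifier
#' @exportClass Angiogram
setClass("Angiogram",
  representation(mask = "array", geometry = "VolumeGeometry",
                 provenance = "list"))

#' 2D depth-coded or maximum-intensity projection
#'
#' In \code{depth_color} mode each foreground pixel's hue encodes the depth
#' of the brightest angiogram voxel in its column (decodable through the
#' stored decode table to within one voxel pitch) and its value encodes the
#' column maximum.
#'
#' @slot image numeric matrix (max_intensity) or [x, y, 3] RGB array
#'   (depth_color)
#' @slot mode "depth_color" or "max_intensity"
#' @slot depthRangeUm numeric length-2 depth band (um from volume top)
#' @slot colormapName identifier of the hue mapping
#' @slot decode data frame mapping hue to depth (um)
#' @exportClass DepthProjection
setClass("DepthProjection",
  representation(image = "array", mode = "character",
                 depthRangeUm = "numeric", colormapName = "character",
                 decode = "data.frame"))

#' Longitudinal dynamics of one lesion dimension
#'
#' Percent change relative to the first (baseline) measurement, consecutive
#' interval differences normalized by baseline, their second differences,
#' and the detected steady-state onset. Expansion is positive, reduction
#' negative.
#'
#' @slot dimension measured dimension name
#' @slot days timepoints (days), strictly increasing
#' @slot values raw measurements (um)
#' @slot percentChange percent change from baseline per timepoint
#' @slot firstDiff per-interval change, percent of baseline (length n-1)
#' @slot secondDiff consecutive differences of firstDiff (length n-2)
#' @slot significanceThreshold percent threshold for a significant change
#' @slot steadyOnset earliest steady-state onset day, NA when none
#' @slot phaseLabels inflammatory phase per timepoint
#'   (early <= day 3, transition 3-7, late >= day 7)
#' @exportClass DynamicsTrace
setClass("DynamicsTrace",
  representation(dimension = "character", days = "numeric",
                 values = "numeric", percentChange = "numeric",
                 firstDiff = "numeric", secondDiff = "numeric",
                 significanceThreshold = "numeric", steadyOnset = "numeric",
                 phaseLabels = "character"),
  validity = function(object) {
    n <- length(object@days)
    if (length(object@values) != n || length(object@percentChange) != n)
      return("days, values and percentChange must have equal length")
    if (length(object@firstDiff) != n - 1L)
      return("firstDiff must have length n - 1")
    if (length(object@secondDiff) != max(0L, n - 2L))
      return("secondDiff must have length n - 2")
    if (abs(object@percentChange[1]) > 1e-9)
      return("percent change at baseline must be 0")
    TRUE
  })

#' Per-group measurement statistics
#'
#' Per (dimension, day) cell mean, standard deviation (population
#' denominator) and coefficient of variation sigma/mu, plus the pooled CV:
#' the unweighted arithmetic mean of the condition's cell CVs.
#'
#' @slot cells data frame with columns dimension, day, n, mean, sd, cv
#' @slot pooledCv arithmetic mean of the retained cells' CVs
#' @slot condition condition label
#' @slot excluded data frame of cells excluded (zero mean)
#' @exportClass GroupStats
setClass("GroupStats",
  representation(cells = "data.frame", pooledCv = "numeric",
                 condition = "character", excluded = "data.frame"))

#' Plexus-resolved perfusion time course
#'
#' @slot densities data frame: plexus, day, density, nonperfused
#' @slot baselineDensity named numeric baseline density per plexus
#' @slot dropFraction numeric, non-perfusion threshold as a fraction of
#'   baseline
#' @slot intervals data frame: plexus, start_day, end_day (non-overlapping,
#'   ordered)
#' @slot reperfusionDay named numeric, first day density recovers after the
#'   last interval, NA when it never does
#' @exportClass PerfusionTimecourse
setClass("PerfusionTimecourse",
  representation(densities = "data.frame", baselineDensity = "numeric",
                 dropFraction = "numeric", intervals = "data.frame",
                 reperfusionDay = "numeric"))

#' Acute-versus-CNV lesion call
#'
#' @slot label "acute", "cnv" or "indeterminate"
#' @slot evidence list: rpeRupture, choroidVoid, maxHeightUm,
#'   dvpNonperfusion
#' @exportClass LesionClassification
setClass("LesionClassification",
  representation(label = "character", evidence = "list"))
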