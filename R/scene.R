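# Scene construction: layered retina geometry, plexus vessel networks and
# lesion specifications. All depths are um; lateral positions um from the
# volume corner. The reflectivity stack and plexus depths are free model
# constants chosen to give each retinal band the qualitative OCT appearance
# (bright NFL/OPL/ELM/ISOS/RPE, dark INL/ONL) and to keep the plexuses in
# axially disjoint bands.

sceneParams <- function() {
  list(
    # layer interval tops below the ILM and their reflectivities
    layerBreaks = c(0, 8, 60, 75, 85, 153, 157, 165, 171, 185, 195, 260),
    layerRefl = c(0.45, 0.22, 0.12, 0.30, 0.08, 0.50, 0.15, 0.62, 0.15,
                  0.90, 0.28),
    aboveRefl = 0.0, belowRefl = 0.05,
    surfaceDepths = c(ILM = 0, ONLtop = 85, ELM = 155, ISOS = 168,
                      RPE = 190, choroidBase = 260),
    plexusDepth = c(SVP = 15, IVP = 45, DVP = 80, choroid = 225),
    vesselAmp = 0.35, blobAmp = 0.40,
    prDisplaceUm = 25, ruptureRadiusUm = 40,
    onlRpeGapUm = 105,     # normal OPL/ONL boundary to RPE distance
    fillStopUm = 190, fillOnlZoneUm = 158, fillRpeZoneUm = 172,
    domeEdgeUm = 6, lateralEdgeUm = 5,
    shadowMinRadiusUm = 7, shadowAtten = 0.12,
    nonperfusionRemoval = 0.8, nonperfusionHeightUm = 200)
}

#' Simulate a ground-truthed retinal scene
#'
#' Builds the geometric ground truth of a synthetic laser-injury experiment:
#' smoothly undulating layer surfaces, vessel centerlines for the
#' superficial, intermediate and deep inner plexuses plus the choroid, and
#' per-lesion dimension time courses calibrated to the packaged reference
#' table (\code{\link{lesionDimensionTable}}). With dispersion enabled each
#' lesion's dimensions are scaled by per-cell lognormal factors whose CV
#' matches the table's CV cells; with dispersion off the generated
#' dimensions equal the table means exactly at the printed timepoints.
#'
#' CNV lesions carry an RPE rupture and a deep/intermediate-plexus
#' non-perfusion schedule that removes vessel voxels inside the lesion
#' cylinder at the timepoints where the condition's (unscaled) mean height
#' reaches 200 um; acute lesions never remove vessel voxels.
#'
#' @param geometry a \linkS4class{VolumeGeometry}
#' @param condition "acute", "cnv" or "control"
#' @param nLesions number of lesions (0 for control)
#' @param seed integer RNG seed; identical inputs give identical scenes
#' @param timepointDays timepoint grid in days (default 1, 3, 7, 14, 21);
#'   prepend 0.042 for the one-hour point (it takes the day-1 values)
#' @param dispersion logical, enable lesion-to-lesion lognormal variability
#' @param dimScale desk-scale factor applied to lesion geometry only (the
#'   condition-level time courses and non-perfusion schedule are unscaled)
#' @param nonperfusionSchedule optional per-timepoint removal fractions
#'   overriding the default CNV schedule (applied to every lesion)
#' @return a \linkS4class{SceneGroundTruth}
#' @examples
#' g <- VolumeGeometry(96, 96, 256)
#' simulateScene(g, "control", 0, seed = 1)
#' @export
simulateScene <- function(geometry, condition = c("acute", "cnv", "control"),
                          nLesions = 0L, seed = 1L,
                          timepointDays = c(1, 3, 7, 14, 21),
                          dispersion = TRUE, dimScale = 1,
                          nonperfusionSchedule = NULL) {
  condition <- match.arg(condition)
  p <- sceneParams()
  g <- geometry
  if (condition == "control" && nLesions > 0L)
    stop("control scenes have zero lesions")
  if (nLesions < 0L) stop("nLesions must be >= 0")
  set.seed(as.integer(seed))

  # lesion dimension time courses first (they constrain the ILM depth)
  specs <- list()
  if (nLesions > 0L) {
    base <- conditionDimsAt(condition, timepointDays) * dimScale
    cvs <- conditionCvAt(condition, timepointDays)
    sched <- if (!is.null(nonperfusionSchedule)) {
      stopifnot(length(nonperfusionSchedule) == length(timepointDays))
      as.numeric(nonperfusionSchedule)
    } else if (condition == "cnv") {
      hUnscaled <- conditionDimsAt("cnv", timepointDays)[, "height_um"]
      p$nonperfusionRemoval * (hUnscaled >= p$nonperfusionHeightUm)
    } else rep(0, length(timepointDays))
    dims <- vector("list", nLesions)
    for (i in seq_len(nLesions)) {
      if (dispersion) {
        s <- sqrt(log(1 + cvs^2))
        fac <- matrix(exp(rnorm(length(s), -s^2 / 2, s)), nrow = nrow(s))
        dims[[i]] <- base * fac
      } else dims[[i]] <- base
    }
    centers <- placeLesions(g, vapply(dims, function(d)
      max(d[, c("onl_um", "rpe_um", "pr_um")]), numeric(1)))
    specs <- lapply(seq_len(nLesions), function(i)
      new("LesionSpec", condition = condition, centerUm = centers[i, ],
          timepointDays = as.numeric(timepointDays), trueDims = dims[[i]],
          nonperfusionSchedule = sched,
          dispersionCv = if (dispersion) cvs else cvs * 0,
          rpeRupture = condition == "cnv"))
  }

  # axial placement: ILM deep enough for the largest dome plus margin
  extent <- g@nAxial * g@dzUm
  domeMax <- if (length(specs))
    max(0, vapply(specs, function(s)
      max(s@trueDims[, "height_um"]) - p$onlRpeGapUm, numeric(1))) else 0
  ilmBase <- max(70, domeMax + 20, 0.15 * extent)
  if (ilmBase + p$surfaceDepths[["choroidBase"]] + 15 > extent)
    stop("axial extent too small for the retina model (need >= ",
         round(ilmBase + 275), " um)")

  ilm <- ilmBase + undulationField(g, ampUm = 10)
  sd <- p$surfaceDepths
  surfaces <- list(ILM = ilm, ONLtop = ilm + sd[["ONLtop"]],
                   ELM = ilm + sd[["ELM"]], ISOS = ilm + sd[["ISOS"]],
                   RPE = ilm + sd[["RPE"]],
                   choroidBase = ilm + sd[["choroidBase"]])

  centerlines <- makePlexusCenterlines(g)

  new("SceneGroundTruth", geometry = g, condition = condition,
      surfaces = surfaces, vesselCenterlines = centerlines,
      lesionSpecs = specs, dimScale = dimScale, seed = as.integer(seed),
      params = p)
}

# smooth low-frequency lateral field (sum of random sinusoid products)
undulationField <- function(g, ampUm = 10) {
  x <- seq_len(g@nFast) / g@nFast
  y <- seq_len(g@nSlow) / g@nSlow
  f <- matrix(0, g@nFast, g@nSlow)
  amps <- ampUm * c(0.5, 0.3, 0.2)
  for (a in amps) {
    kx <- runif(1, 0.7, 2.5); ky <- runif(1, 0.7, 2.5)
    px <- runif(1, 0, 2 * pi); py <- runif(1, 0, 2 * pi)
    f <- f + a * outer(sin(2 * pi * kx * x + px), cos(2 * pi * ky * y + py))
  }
  f
}

# grid layout with footprint + quarter-diameter margin inside the field and
# 25%-dilated footprints non-overlapping
placeLesions <- function(g, footprintUm) {
  n <- length(footprintUm)
  fx <- g@nFast * g@dxUm
  fy <- g@nSlow * g@dxUm
  k <- ceiling(sqrt(n))
  rows <- ceiling(n / k)
  centers <- cbind(
    fx * ((((seq_len(n) - 1L) %% k) + 0.5) / k),
    fy * ((((seq_len(n) - 1L) %/% k) + 0.5) / rows))
  for (i in seq_len(n)) {
    need <- 0.75 * footprintUm[i]
    m <- min(centers[i, 1], fx - centers[i, 1],
             centers[i, 2], fy - centers[i, 2])
    if (m < need)
      stop("geometry too small for requested lesion (footprint ",
           round(footprintUm[i]), " um needs ", round(need),
           " um clearance, field allows ", round(m), ")")
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (d < 1.25 * (footprintUm[i] + footprintUm[j]) / 2)
        stop("lesion overlap after placement")
    }
  }
  centers
}

makePlexusCenterlines <- function(g) {
  areaScale <- (g@nFast / 256) * (g@nSlow / 256)
  counts <- c(SVP = max(3, round(7 * areaScale)),
              IVP = max(4, round(11 * areaScale)),
              DVP = max(5, round(14 * areaScale)),
              choroid = max(3, round(8 * areaScale)))
  radii <- list(SVP = c(4, 11), IVP = c(2.5, 4.5), DVP = c(2.5, 5),
                choroid = c(6, 13))
  out <- list()
  for (pl in names(counts)) {
    vs <- vector("list", counts[[pl]])
    for (v in seq_len(counts[[pl]])) {
      path <- vesselPath(g@nFast, g@nSlow)
      df <- data.frame(x_um = path[, 1] * g@dxUm, y_um = path[, 2] * g@dxUm)
      attr(df, "radius_um") <- runif(1, radii[[pl]][1], radii[[pl]][2])
      vs[[v]] <- df
    }
    out[[pl]] <- vs
  }
  out
}

# meandering path across the field: AR(1) heading random walk from a random
# edge, unit-pixel steps
vesselPath <- function(nx, ny) {
  edge <- sample(4L, 1L)
  pos <- switch(edge,
    c(1, runif(1, 1, ny)), c(nx, runif(1, 1, ny)),
    c(runif(1, 1, nx), 1), c(runif(1, 1, nx), ny))
  heading <- switch(edge, 0, pi, pi / 2, -pi / 2) + runif(1, -0.5, 0.5)
  maxSteps <- 3L * (nx + ny)
  path <- matrix(NA_real_, maxSteps, 2L)
  for (i in seq_len(maxSteps)) {
    path[i, ] <- pos
    heading <- heading + rnorm(1, 0, 0.06)
    pos <- pos + c(cos(heading), sin(heading))
    if (pos[1] < 1 || pos[1] > nx || pos[2] < 1 || pos[2] > ny) {
      path <- path[seq_len(i), , drop = FALSE]
      break
    }
  }
  path[!is.na(path[, 1]), , drop = FALSE]
}

# per-plexus en-face vessel radius map (um; 0 where no vessel) and the
# plexus depth map following the ILM
plexusEnface <- function(scene, plexus) {
  g <- scene@geometry
  radiusMap <- matrix(0, g@nFast, g@nSlow)
  for (df in scene@vesselCenterlines[[plexus]]) {
    r <- attr(df, "radius_um")
    P <- matrix(1, g@nFast, g@nSlow)
    ix <- pmin(pmax(round(df$x_um / g@dxUm + 0.5), 1L), g@nFast)
    iy <- pmin(pmax(round(df$y_um / g@dxUm + 0.5), 1L), g@nSlow)
    P[cbind(ix, iy)] <- 0
    d <- as.matrix(EBImage::distmap(P)) * g@dxUm
    radiusMap <- pmax(radiusMap, ifelse(d <= r, r, 0))
  }
  depth <- scene@surfaces$ILM + scene@params$plexusDepth[[plexus]]
  list(radiusUm = radiusMap, depthUm = depth)
}

lesionDimsAt <- function(spec, timepoint) {
  if (timepoint == 0) return(setNames(rep(0, 4L), dimNames))
  vapply(dimNames, function(d)
    interpFlat(spec@timepointDays, spec@trueDims[, d], timepoint),
    numeric(1))
}

lesionScheduleAt <- function(spec, timepoint) {
  if (timepoint == 0) return(0)
  interpFlat(spec@timepointDays, spec@nonperfusionSchedule, timepoint)
}

# lateral distance map (um) from a lesion center
lesionRadiusMap <- function(g, centerUm) {
  x <- (seq_len(g@nFast) - 0.5) * g@dxUm
  y <- (seq_len(g@nSlow) - 0.5) * g@dxUm
  sqrt(outer((x - centerUm[1])^2, (y - centerUm[2])^2, "+"))
}

#' Voxelised plexus vessel masks at a timepoint
#'
#' Rasterizes the scene's vessel centerlines into binary 3D masks (one per
#' plexus) and applies the CNV non-perfusion schedule: at timepoints with a
#' non-zero scheduled removal fraction s, the centermost s fraction of
#' deep- and intermediate-plexus vessel voxels inside each lesion cylinder
#' is removed. Timepoint 0 is the pre-lesion state. The masks are mutually
#' disjoint (the plexuses occupy disjoint depth bands) and serve as the
#' oracle for angiography tests.
#'
#' @param scene a \linkS4class{SceneGroundTruth}
#' @param timepoint day on the scene grid, or 0 for pre-lesion
#' @param plexuses which plexus masks to build
#' @return named list of logical [z, x, y] arrays
#' @export
plexusMasksAt <- function(scene, timepoint = 0,
                          plexuses = c("SVP", "IVP", "DVP", "choroid")) {
  g <- scene@geometry
  zUm <- (seq_len(g@nAxial) - 0.5) * g@dzUm
  out <- list()
  for (pl in plexuses) {
    ef <- plexusEnface(scene, pl)
    arr <- array(FALSE, dim = c(g@nAxial, g@nFast, g@nSlow))
    rmax <- max(ef$radiusUm)
    if (rmax > 0) {
      zlo <- max(1L, floor((min(ef$depthUm) - rmax) / g@dzUm))
      zhi <- min(g@nAxial, ceiling((max(ef$depthUm) + rmax) / g@dzUm) + 1L)
      has <- ef$radiusUm > 0
      for (z in zlo:zhi)
        arr[z, , ] <- has & abs(zUm[z] - ef$depthUm) <= ef$radiusUm
    }
    out[[pl]] <- arr
  }
  # scheduled non-perfusion: remove centermost vessel voxels in the cylinder
  for (spec in scene@lesionSpecs) {
    s <- lesionScheduleAt(spec, timepoint)
    if (s <= 0) next
    R <- lesionDimsAt(spec, timepoint)[["onl_um"]] / 2
    r2d <- lesionRadiusMap(g, spec@centerUm)
    for (pl in intersect(c("IVP", "DVP"), names(out))) {
      arr <- out[[pl]]
      inCyl <- r2d <= R
      sel <- arr & rep(inCyl, each = g@nAxial)
      if (!any(sel)) next
      rAll <- rep(r2d, each = g@nAxial)[sel]
      rCut <- as.numeric(quantile(rAll, probs = s, type = 1))
      arr[sel & rep(r2d, each = g@nAxial) <= rCut] <- FALSE
      out[[pl]] <- arr
    }
  }
  out
}

#' Layer surfaces at a timepoint, with lesion perturbations
#'
#' Applies the per-lesion geometry to the baseline surfaces: the swelling
#' dome (height in excess of the normal OPL/ONL-to-RPE distance) displaces
#' the inner retina (ILM and OPL/ONL boundary) upward over the ONL
#' footprint, and the photoreceptor protrusion displaces the ELM and IS/OS
#' surfaces upward over the PR footprint. The RPE and choroid base are
#' never displaced. Also returns the lesion fields used by the renderer.
#'
#' @param scene a \linkS4class{SceneGroundTruth}
#' @param timepoint day on the scene grid, or 0 for pre-lesion
#' @return list: \code{surfaces} (named depth maps, um),
#'   \code{domeUm}, \code{prUm}, \code{rupture} (2D fields),
#'   \code{lesionInfo} (per-lesion dims and footprints)
#' @export
surfacesAt <- function(scene, timepoint) {
  p <- scene@params
  g <- scene@geometry
  s <- scene@surfaces
  dome <- matrix(0, g@nFast, g@nSlow)
  pr <- matrix(0, g@nFast, g@nSlow)
  rupt <- matrix(0, g@nFast, g@nSlow)
  info <- list()
  for (spec in scene@lesionSpecs) {
    d <- lesionDimsAt(spec, timepoint)
    if (all(d == 0)) next
    r <- lesionRadiusMap(g, spec@centerUm)
    domeH <- max(0, d[["height_um"]] - p$onlRpeGapUm)
    if (domeH > 0)
      dome <- pmax(dome, domeH * softDisc(r, d[["onl_um"]] / 2, p$domeEdgeUm))
    pr <- pmax(pr, p$prDisplaceUm * softDisc(r, d[["pr_um"]] / 2,
                                             p$lateralEdgeUm))
    if (spec@rpeRupture) {
      rr <- p$ruptureRadiusUm * scene@dimScale
      rupt <- pmax(rupt, softDisc(r, rr, 4))
    }
    info[[length(info) + 1L]] <- list(centerUm = spec@centerUm, dims = d,
                                      domeH = domeH,
                                      rupture = spec@rpeRupture)
  }
  list(surfaces = list(ILM = s$ILM - dome, ONLtop = s$ONLtop - dome,
                       ELM = s$ELM - pr, ISOS = s$ISOS - pr,
                       RPE = s$RPE, choroidBase = s$choroidBase),
       domeUm = dome, prUm = pr, rupture = rupt, lesionInfo = info,
       geometry = g)
}

#' Ground-truth lesion measurement table
#'
#' The oracle surface for morphometry: one row per lesion per timepoint
#' with the true simulated dimensions.
#'
#' @param scene a \linkS4class{SceneGroundTruth}
#' @return data frame lesion_id, day, onl_um, rpe_um, height_um, pr_um
#' @export
trueMeasurementTable <- function(scene) {
  if (length(scene@lesionSpecs) == 0L)
    return(data.frame(lesion_id = integer(), day = numeric(),
                      onl_um = numeric(), rpe_um = numeric(),
                      height_um = numeric(), pr_um = numeric()))
  do.call(rbind, lapply(seq_along(scene@lesionSpecs), function(i) {
    sp <- scene@lesionSpecs[[i]]
    data.frame(lesion_id = i, day = sp@timepointDays,
               onl_um = sp@trueDims[, "onl_um"],
               rpe_um = sp@trueDims[, "rpe_um"],
               height_um = sp@trueDims[, "height_um"],
               pr_um = sp@trueDims[, "pr_um"], row.names = NULL)
  }))
}
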