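# Volume renderer: layered reflectivity + vessels + lesion perturbations +
# speckle/motion noise. Reflectivity units are arbitrary; the stack is
# normalized so the RPE band (0.9) is the brightest layer.

# Multiplicative speckle with the spatial statistics the angiography
# contrast relies on: static tissue carries a frozen, laterally correlated
# speckle pattern (grain ~1 resolution cell, so adjacent B-scans share it),
# while voxels inside flowing vessels decorrelate voxel-by-voxel
# (erythrocyte motion). cv is the speckle contrast (CV of the
# multiplicative field); mean is 1 everywhere.
speckleField <- function(dims, cv, flowMask = NULL) {
  n <- prod(dims)
  W <- array(rnorm(n), dims)
  # lateral correlation: smooth along x (dim 2) and slow axis y (dim 3)
  kx <- gaussKernel1D(0.7)
  ky <- gaussKernel1D(1.1)
  W <- smoothAlongDim(W, kx, 2L)
  W <- smoothAlongDim(W, ky, 3L)
  W <- W / sqrt(sum(kx^2) * sum(ky^2))
  s <- sqrt(log(1 + cv^2))
  sp <- exp(s * W - s^2 / 2)
  if (!is.null(flowMask) && any(flowMask)) {
    nf <- sum(flowMask)
    sp[flowMask] <- rgamma(nf, shape = 1 / cv^2, scale = cv^2)
  }
  sp
}

layerLookup <- function(d, p) {
  idx <- findInterval(d, p$layerBreaks)
  c(p$aboveRefl, p$layerRefl, p$belowRefl)[idx + 1L]
}

# ELM / outer-segment / IS-OS band reflectivities for redrawn displaced lines
lineLookup <- function(d) {
  ifelse(d < 157, 0.50, ifelse(d < 165, 0.15, 0.62))
}

#' Render a synthetic OCT volume at a timepoint
#'
#' Produces the intensity volume of a scene at one timepoint: layered
#' reflectivity relative to the (lesion-displaced) surfaces, hyperreflective
#' vessels, the lesion body (hyperreflective fill from the disrupted,
#' possibly dome-displaced OPL/ONL boundary down to the RPE contact, its
#' lateral width flaring from the ONL width to the RPE-disruption width),
#' displaced ELM/IS-OS lines over the photoreceptor-protrusion footprint,
#' the RPE-rupture void (suppressed outer-retina and choroid signal beneath
#' ruptured CNV lesions), shadowing below large superficial vessels, an
#' optional decorrelation-tail artifact in the deep-plexus band beneath
#' superficial vessels, multiplicative gamma speckle, an additive background
#' floor, and integer-voxel per-B-scan motion jitter drawn from a bounded
#' autoregressive walk. Applied jitter offsets are recorded in the metadata
#' for oracle use. Identical scene, timepoint and noise model give
#' bit-identical volumes.
#'
#' @param scene a \linkS4class{SceneGroundTruth}
#' @param timepoint day on the scene's grid (0 = pre-lesion baseline)
#' @param noise a \linkS4class{NoiseModel}
#' @return an \linkS4class{OCTVolume}
#' @export
renderVolume <- function(scene, timepoint, noise = NoiseModel()) {
  g <- scene@geometry
  p <- scene@params
  if (length(scene@lesionSpecs)) {
    grid <- c(0, scene@lesionSpecs[[1]]@timepointDays)
    if (!timepoint %in% grid)
      stop("timepoint ", timepoint, " is not on the scene grid (",
           paste(grid, collapse = ", "), ")")
  }
  set.seed(seedAt(noise@seed, timepoint))
  nz <- g@nAxial
  zUm <- (seq_len(nz) - 0.5) * g@dzUm
  D0 <- outer(zUm, as.numeric(scene@surfaces$ILM), "-")
  base <- layerLookup(D0, p)
  dim(D0) <- c(nz, g@nFast, g@nSlow)
  dim(base) <- c(nz, g@nFast, g@nSlow)

  # lesion geometry (before vessels: the dome re-layering overwrites voxels)
  for (spec in scene@lesionSpecs)
    base <- renderLesionBody(base, D0, g, p, spec, timepoint,
                             scene@dimScale)

  masks <- plexusMasksAt(scene, timepoint)
  for (m in masks) base[m] <- base[m] + p$vesselAmp

  for (spec in scene@lesionSpecs)
    base <- renderRuptureVoid(base, D0, g, p, spec, timepoint,
                              scene@dimScale)

  # shadowing below large superficial vessels
  svp <- plexusEnface(scene, "SVP")
  foot <- svp$radiusUm >= p$shadowMinRadiusUm
  if (any(foot)) {
    shade <- rep(1 - p$shadowAtten * foot, each = nz)
    sel <- D0 > 30 & shade < 1
    base[sel] <- base[sel] * shade[sel]
  }

  # decorrelation-tail artifact in the DVP band beneath superficial vessels
  if (noise@projectionTail > 0) {
    tail <- projectionTailMask(scene, masks = masks, svpEnface = svp)
    base[tail] <- base[tail] + noise@projectionTail * p$vesselAmp
    rm(tail)
  }

  rm(D0)
  flow <- Reduce("|", masks)
  rm(masks)
  gc(verbose = FALSE)
  n <- length(base)
  if (noise@speckleContrast > 0) {
    base <- base * speckleField(c(nz, g@nFast, g@nSlow),
                                noise@speckleContrast, flow)
  }
  rm(flow)
  if (noise@backgroundLevel > 0)
    base <- base + noise@backgroundLevel * rexp(n)
  base <- pmax(base, 0)
  dim(base) <- c(nz, g@nFast, g@nSlow)

  # bounded AR(1) integer-voxel motion jitter per B-scan
  off <- matrix(0L, g@nSlow, 2L,
                dimnames = list(NULL, c("axial", "lateral")))
  sVox <- noise@motionJitterUm / c(g@dzUm, g@dxUm)
  if (any(sVox > 0)) {
    for (a in 1:2) {
      if (sVox[a] <= 0) next
      j <- 0
      for (y in seq_len(g@nSlow)) {
        j <- clampv(0.5 * j + rnorm(1, 0, sVox[a]), -6, 6)
        off[y, a] <- as.integer(round(j))
      }
    }
    for (y in seq_len(g@nSlow))
      if (any(off[y, ] != 0L))
        base[, , y] <- circShift2D(base[, , y], off[y, 1L], off[y, 2L])
  }

  new("OCTVolume", intensities = base, geometry = g,
      metadata = list(timepointDays = timepoint, seed = noise@seed,
                      appliedOffsets = off,
                      noise = list(speckleContrast = noise@speckleContrast,
                                   backgroundLevel = noise@backgroundLevel,
                                   projectionTail = noise@projectionTail)))
}

# hyperreflective lesion body, dome re-layering, displaced photoreceptor
# lines and RPE-contact fill, restricted to the lesion bounding box and
# processed in slow-axis chunks to bound temporary memory
renderLesionBody <- function(base, D0, g, p, spec, timepoint, dimScale) {
  d <- lesionDimsAt(spec, timepoint)
  if (all(d == 0)) return(base)
  nz <- dim(base)[1]
  bboxR <- max(d) / 2 + 40
  x <- (seq_len(g@nFast) - 0.5) * g@dxUm
  y <- (seq_len(g@nSlow) - 0.5) * g@dxUm
  xi <- which(abs(x - spec@centerUm[1]) <= bboxR)
  yi <- which(abs(y - spec@centerUm[2]) <= bboxR)
  if (!length(xi) || !length(yi)) return(base)
  domeH <- max(0, d[["height_um"]] - p$onlRpeGapUm)
  topF <- p$fillStopUm - d[["height_um"]]
  edema <- spec@condition == "cnv" && timepoint >= 5

  chunk <- max(8L, ceiling(3e6 / (nz * length(xi))))
  for (y0 in seq(1L, length(yi), by = chunk)) {
    yc <- yi[y0:min(y0 + chunk - 1L, length(yi))]
    rsub <- sqrt(outer((x[xi] - spec@centerUm[1])^2,
                       (y[yc] - spec@centerUm[2])^2, "+"))
    Dsub <- D0[, xi, yc, drop = FALSE]
    bsub <- base[, xi, yc, drop = FALSE]
    nzc <- nz

    prA <- rep(p$prDisplaceUm * softDisc(rsub, d[["pr_um"]] / 2,
                                         p$lateralEdgeUm), each = nzc)
    if (domeH > 0) {
      domeA <- rep(domeH * softDisc(rsub, d[["onl_um"]] / 2, p$domeEdgeUm),
                   each = nzc)
      sel <- domeA > 0.25 & Dsub < 85 & Dsub > -(domeH + 10)
      Din <- Dsub[sel] + domeA[sel]
      bsub[sel] <- layerLookup(ifelse(Din < 85, Din,
                                      pmax(Dsub[sel], 85.01)), p)
      rm(domeA)
    }
    # erase the ELM/OS/IS-OS band, redraw displaced upward (into the ONL)
    selEr <- prA > 0.5 & Dsub >= 153 - prA & Dsub < 171
    bsub[selEr] <- 0.08
    selDr <- prA > 0.5 & Dsub + prA >= 153 & Dsub + prA < 171
    bsub[selDr] <- lineLookup((Dsub + prA)[selDr])
    rm(selEr, selDr)

    # lesion fill: hyperreflective column from the (dome-displaced) top of
    # the disruption down to the RPE interface, with depth-dependent
    # lateral half-width: the ONL width through the nuclear layer, flaring
    # or narrowing to the RPE-disruption width at the RPE contact (the
    # cylinder / hourglass / pyramid morphology), making every defined
    # width geometrically unambiguous.
    Wz <- ifelse(Dsub <= p$fillOnlZoneUm, d[["onl_um"]] / 2,
          ifelse(Dsub >= p$fillRpeZoneUm, d[["rpe_um"]] / 2,
                 d[["onl_um"]] / 2 + (d[["rpe_um"]] - d[["onl_um"]]) / 2 *
                   (Dsub - p$fillOnlZoneUm) /
                   (p$fillRpeZoneUm - p$fillOnlZoneUm)))
    tEdge <- (rep(rsub, each = nzc) - (Wz - p$lateralEdgeUm / 2)) /
      p$lateralEdgeUm
    rm(Wz)
    wFill <- ifelse(tEdge <= 0, 1,
                    ifelse(tEdge >= 1, 0, 0.5 * (1 + cos(pi * tEdge))))
    rm(tEdge)
    selB <- wFill > 0.02 & Dsub >= topF & Dsub <= p$fillStopUm
    amp <- p$blobAmp * wFill
    if (edema) {
      # sub-retinal edema: hyporeflective core within the lesion body
      amp <- amp * (1 - 0.3 * rep(softDisc(rsub, d[["onl_um"]] / 4, 10),
                                  each = nzc))
    }
    bsub[selB] <- bsub[selB] + amp[selB]
    base[, xi, yc] <- bsub
  }
  base
}

# suppressed outer-retina and choroid signal beneath a ruptured RPE
# (applied after vessels so choroid vasculature disappears in the void)
renderRuptureVoid <- function(base, D0, g, p, spec, timepoint, dimScale) {
  if (!spec@rpeRupture) return(base)
  d <- lesionDimsAt(spec, timepoint)
  if (all(d == 0)) return(base)
  nz <- dim(base)[1]
  rr <- p$ruptureRadiusUm * dimScale
  x <- (seq_len(g@nFast) - 0.5) * g@dxUm
  y <- (seq_len(g@nSlow) - 0.5) * g@dxUm
  xi <- which(abs(x - spec@centerUm[1]) <= rr + 15)
  yi <- which(abs(y - spec@centerUm[2]) <= rr + 15)
  if (!length(xi) || !length(yi)) return(base)
  rsub <- sqrt(outer((x[xi] - spec@centerUm[1])^2,
                     (y[yi] - spec@centerUm[2])^2, "+"))
  wR <- rep(softDisc(rsub, rr, 4), each = nz)
  Dsub <- D0[, xi, yi, drop = FALSE]
  bsub <- base[, xi, yi, drop = FALSE]
  sel <- wR > 0.02 & Dsub >= 150 & Dsub < 205
  bsub[sel] <- bsub[sel] * (1 - 0.85 * wR[sel])
  sel <- wR > 0.02 & Dsub >= 195 & Dsub <= 260
  bsub[sel] <- bsub[sel] * (1 - 0.75 * wR[sel])
  base[, xi, yi] <- bsub
  base
}

#' Ground-truth mask of the rendered decorrelation-tail artifact
#'
#' Voxels in the deep-plexus band lying beneath superficial vessels that do
#' not belong to true deep-plexus vessels: the columns where the renderer
#' adds the projection-tail artifact. Oracle for shadow-rejection tests.
#'
#' @param scene a \linkS4class{SceneGroundTruth}
#' @param masks optional precomputed plexus masks
#' @param svpEnface optional precomputed superficial-plexus en-face map
#' @return logical [z, x, y] array
#' @export
projectionTailMask <- function(scene, masks = NULL, svpEnface = NULL) {
  g <- scene@geometry
  p <- scene@params
  nz <- g@nAxial
  if (is.null(svpEnface)) svpEnface <- plexusEnface(scene, "SVP")
  dvp <- if (is.null(masks)) plexusMasksAt(scene, 0, "DVP")$DVP
         else masks$DVP
  zUm <- (seq_len(nz) - 0.5) * g@dzUm
  depth <- rep(as.numeric(svpEnface$depthUm - p$plexusDepth[["SVP"]] +
               p$plexusDepth[["DVP"]]), each = nz)
  foot <- rep(as.vector(svpEnface$radiusUm > 0), each = nz)
  band <- abs(rep(zUm, times = g@nFast * g@nSlow) - depth) <= 8
  out <- foot & band & !as.vector(dvp)
  dim(out) <- c(nz, g@nFast, g@nSlow)
  out
}

#' Simulate a full longitudinal acquisition
#'
#' One volume per timepoint sharing a single scene, plus the ground-truth
#' measurement table (the oracle surface for morphometry).
#'
#' @inheritParams simulateScene
#' @param noise a \linkS4class{NoiseModel}
#' @param includeBaseline prepend a pre-lesion (day 0) volume
#' @param render set FALSE to skip volume rendering (scene and table only)
#' @return list: \code{scene}, \code{volumes} (named by day),
#'   \code{table} (data frame lesion_id, day, onl_um, rpe_um, height_um,
#'   pr_um)
#' @export
simulateTimecourse <- function(condition, nLesions, geometry,
                               noise = NoiseModel(), seed = 1L,
                               timepointDays = c(1, 3, 7, 14, 21),
                               includeBaseline = FALSE, dispersion = TRUE,
                               dimScale = 1, nonperfusionSchedule = NULL,
                               render = TRUE) {
  scene <- simulateScene(geometry, condition, nLesions, seed,
                         timepointDays, dispersion, dimScale,
                         nonperfusionSchedule)
  days <- if (includeBaseline) c(0, timepointDays) else timepointDays
  volumes <- list()
  if (render) {
    volumes <- lapply(days, function(t) renderVolume(scene, t, noise))
    names(volumes) <- as.character(days)
  }
  list(scene = scene, volumes = volumes, table = trueMeasurementTable(scene))
}

#' Capillary tube phantom
#'
#' A minimal resolution phantom: straight tubes of given diameter running
#' along the slow axis at fixed depth in a uniform speckled background,
#' with the ground-truth tube mask.
#'
#' @param geometry a \linkS4class{VolumeGeometry}
#' @param diameterUm tube diameter (um)
#' @param nTubes 1 or 2 parallel tubes
#' @param centerSepUm center-to-center separation when nTubes = 2
#' @param depthUm tube axis depth (um from volume top); default mid-volume
#' @param speckleContrast multiplicative speckle CV
#' @param seed RNG seed
#' @return list: \code{volume} (an \linkS4class{OCTVolume}),
#'   \code{mask} (logical array)
#' @export
tubePhantom <- function(geometry, diameterUm = 5, nTubes = 1L,
                        centerSepUm = 15, depthUm = NULL,
                        speckleContrast = 0.3, seed = 9L) {
  g <- geometry
  if (is.null(depthUm)) depthUm <- g@nAxial * g@dzUm / 2
  set.seed(as.integer(seed))
  zUm <- (seq_len(g@nAxial) - 0.5) * g@dzUm
  xUm <- (seq_len(g@nFast) - 0.5) * g@dxUm
  cx <- g@nFast * g@dxUm / 2 +
    (if (nTubes == 2L) c(-centerSepUm / 2, centerSepUm / 2) else 0)
  r <- diameterUm / 2
  sec <- matrix(FALSE, g@nAxial, g@nFast)
  for (c0 in cx)
    sec <- sec | outer((zUm - depthUm)^2, (xUm - c0)^2, "+") <= r^2
  mask <- array(rep(sec, g@nSlow), dim = c(g@nAxial, g@nFast, g@nSlow))
  base <- 0.15 + 0.5 * mask
  if (speckleContrast > 0)
    base <- base * speckleField(dim(mask), speckleContrast, mask)
  base <- base + 0.02 * rexp(length(base))
  dim(base) <- dim(mask)
  vol <- new("OCTVolume", intensities = base, geometry = g,
             metadata = list(timepointDays = 0, seed = as.integer(seed),
                             appliedOffsets = matrix(0L, g@nSlow, 2L)))
  list(volume = vol, mask = mask)
}
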