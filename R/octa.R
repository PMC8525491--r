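# Angiography core: sequential localized structural enhancement of en-face
# C-scan images, hysteresis segmentation of the vesselness volume,
# projection-artifact (shadow/decorrelation tail) rejection, and color
# depth-coded projections. The enhancement is strictly en-face (2D per
# C-scan): the vessel contrast of a single high-density scan lives in the
# lateral speckle structure, and per-slice processing preserves axial
# localization.

# 2D multiscale ridge (vesselness) filter from the local Hessian
# eigenstructure; bright ridges on a dark background. The structure
# sensitivity c is fixed (the input is already contrast-normalized to unit
# scale) so responses are comparable across slices, including vessel-free
# ones.
frangi2D <- function(img, sigmasPx, beta = 0.5, c = 1) {
  out <- matrix(0, nrow(img), ncol(img))
  for (s in sigmasPx) {
    gxx <- s^2 * gaussFilter2D(img, s, dx = 2L, dy = 0L)
    gyy <- s^2 * gaussFilter2D(img, s, dx = 0L, dy = 2L)
    gxy <- s^2 * gaussFilter2D(img, s, dx = 1L, dy = 1L)
    tmp <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
    m <- (gxx + gyy) / 2
    l1 <- m + tmp   # larger algebraic eigenvalue
    l2 <- m - tmp   # ridge eigenvalue (strongly negative on bright tubes)
    swap <- abs(l1) > abs(l2)
    tt <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tt
    S2 <- l1^2 + l2^2
    v <- exp(-(l1 / pmin(l2, -1e-12))^2 / (2 * beta^2)) *
      (1 - exp(-S2 / (2 * c^2)))
    v[l2 >= 0] <- 0
    out <- pmax(out, as.matrix(v))
  }
  out
}

#' Sequential localized structural enhancement of en-face images
#'
#' The angiography contrast engine: per C-scan, (i) local background
#' removal by moving-median subtraction with a window much larger than the
#' widest vessel, then, repeated \code{nIterations} times, (ii) local
#' contrast normalization (division by a local mean magnitude plus floor)
#' and (iii) multiscale tubular enhancement from the local second-derivative
#' (Hessian) eigenstructure at scales matched to capillary-to-arteriole
#' diameters. Scores are rescaled to [0, 1] over the volume and every stage
#' is recorded in the iterator log.
#'
#' @param volume a registered \linkS4class{OCTVolume}
#' @param surfaces optional \linkS4class{LayerSurfaces}; when supplied the
#'   volume is flattened to the ILM (integer column shifts) before en-face
#'   processing and the scores are shifted back, suppressing the contour
#'   artifacts C-scans pick up where they cut through curved bright layers
#' @param nIterations number of normalization + ridge-enhancement
#'   iterations (default 1; a second pass sharpens centerlines but thins
#'   wide superficial vessels)
#' @param scalesUm vessel diameters to enhance (default 5, 10, 20, 40 um)
#' @param zRangeUm optional axial range to process (um from the volume
#'   top, or um below the ILM when \code{surfaces} is given); outside
#'   slices get zero scores
#' @param bgWindowUm moving-median background window (um); must be well
#'   above the widest vessel diameter
#' @param normWindowUm local contrast-normalization window (um); above the
#'   widest vessel diameter so wide vessels do not normalize themselves
#'   away
#' @return a \linkS4class{VesselnessVolume}
#' @export
enhanceVessels <- function(volume, surfaces = NULL, nIterations = 1L,
                           scalesUm = c(5, 10, 20, 40), zRangeUm = NULL,
                           bgWindowUm = 70, normWindowUm = 84) {
  g <- volume@geometry
  nz <- g@nAxial
  arr <- volume@intensities
  fixIdx <- 0L
  refUm <- NULL
  if (!is.null(surfaces)) {
    refUm <- if (is(surfaces, "LayerSurfaces")) surfaces@surfaces$ILM
             else surfaces$surfaces$ILM
    fixIdx <- round(min(refUm) / g@dzUm)
    arr <- flattenToSurface(arr, refUm, g@dzUm, fixIdx)
  }
  scores <- array(0, dim = dim(arr))
  zUm <- (seq_len(nz) - 0.5) * g@dzUm
  zSel <- if (is.null(zRangeUm)) seq_len(nz)
          else if (is.null(refUm))
            which(zUm >= zRangeUm[1] & zUm <= zRangeUm[2])
          else {
            z0 <- (fixIdx - 0.5) * g@dzUm
            which(zUm >= z0 + zRangeUm[1] & zUm <= z0 + zRangeUm[2])
          }
  bgR <- max(3L, round(bgWindowUm / 2 / g@dxUm))
  nmR <- max(3L, round(normWindowUm / 2 / g@dxUm))
  sigmas <- pmax(scalesUm / 2 / g@dxUm, 0.8)
  log <- list(
    list(stage = "ilm_flattening", applied = !is.null(refUm)),
    list(stage = "background_median_subtraction", windowUm = bgWindowUm),
    list(stage = "local_contrast_normalization", windowUm = normWindowUm,
         iterations = nIterations),
    list(stage = "multiscale_hessian_ridge", scalesUm = scalesUm,
         iterations = nIterations))
  if (diff(range(arr)) < 1e-9) {
    warning("constant volume: vesselness is all zero")
    return(new("VesselnessVolume", scores = scores, geometry = g,
               iteratorLog = log))
  }
  top <- max(arr)
  # volume-global residual scale: the normalization floor, so vessel-free
  # and noise-only slices are not amplified to vessel level
  G <- mean(vapply(zSel[seq(1, length(zSel), by = 8)], function(z) {
    img <- arr[z, , ]
    bg <- as.matrix(EBImage::medianFilter(img / top, bgR)) * top
    mean(abs(img - bg))
  }, numeric(1)))
  for (z in zSel) {
    img <- arr[z, , ]
    bg <- as.matrix(EBImage::medianFilter(img / top, bgR)) * top
    b <- img - bg
    for (it in seq_len(nIterations)) {
      den <- as.matrix(boxBlur2D(abs(b), nmR)) + G + 1e-12
      b <- b / den
      b <- as.matrix(gaussFilter2D(b, 0.8))
      b <- frangi2D(b, sigmas)
    }
    scores[z, , ] <- b
  }
  mx <- max(scores)
  if (mx > 0) scores <- scores / mx
  if (!is.null(refUm))
    scores <- flattenToSurface(scores, refUm, g@dzUm, fixIdx,
                               inverse = TRUE)
  new("VesselnessVolume", scores = scores, geometry = g, iteratorLog = log)
}

#' Segment a binary angiogram from a vesselness volume
#'
#' Hysteresis thresholding per 60 um axial band: the band's strong-response
#' level is taken as a high quantile of its positive scores, and the
#' high/low hysteresis thresholds are fixed fractions of that level (seeds
#' at the high threshold grow into connected regions above the low one).
#' Components smaller than a minimum voxel count (per C-scan) are removed.
#' Deterministic for fixed input; an empty mask is allowed. Setting both
#' fractions equal reduces hysteresis to single-threshold segmentation.
#'
#' @param vesselness a \linkS4class{VesselnessVolume}
#' @param hystFractions high/low threshold pair as fractions of the band
#'   reference level (default 0.35, 0.15)
#' @param refQuantile quantile of the band's positive scores defining its
#'   strong-response reference level
#' @param minVoxels minimum connected-component voxel count
#' @param bandUm axial band height over which thresholds are computed
#' @param floorScore absolute score floor below which a band is considered
#'   empty
#' @return an \linkS4class{Angiogram}
#' @export
segmentAngiogram <- function(vesselness, hystFractions = c(0.35, 0.15),
                             refQuantile = 0.99, minVoxels = 10L,
                             bandUm = 60, floorScore = 0.04) {
  g <- vesselness@geometry
  s <- vesselness@scores
  nz <- g@nAxial
  mask <- array(FALSE, dim = dim(s))
  bandVox <- max(1L, round(bandUm / g@dzUm))
  starts <- seq(1L, nz, by = bandVox)
  for (z0 in starts) {
    zr <- z0:min(z0 + bandVox - 1L, nz)
    sub <- s[zr, , , drop = FALSE]
    pos <- sub[sub > 0.02]
    if (length(pos) < 50L) next
    ref <- as.numeric(quantile(pos, refQuantile))
    hi <- max(hystFractions[1] * ref, floorScore)
    lo <- max(hystFractions[2] * ref, floorScore * 0.6)
    if (hystFractions[1] == hystFractions[2]) lo <- hi
    for (k in seq_along(zr)) {
      sl <- sub[k, , ]
      low <- sl >= lo
      if (!any(low)) next
      lab <- EBImage::bwlabel(low)
      keepSeed <- unique(lab[sl >= hi])
      sz <- tabulate(lab)
      keep <- intersect(keepSeed[keepSeed > 0], which(sz >= minVoxels))
      if (length(keep))
        mask[zr[k], , ] <- matrix(lab %in% keep, g@nFast, g@nSlow)
    }
  }
  new("Angiogram", mask = mask, geometry = g,
      provenance = list(hystFractions = hystFractions,
                        refQuantile = refQuantile,
                        minVoxels = minVoxels, bandUm = bandUm,
                        shadowRejected = FALSE))
}

#' Reject projection (shadow) artifacts below the superficial plexus
#'
#' A voxel below the superficial band is removed when the maximal
#' vesselness in its column's superficial band exceeds its own score by
#' the tail-rejection factor: decorrelation tails echo the superficial
#' vessel above them with weaker scores, while true deep vessels carry
#' comparable scores of their own. Superficial-band voxels are never
#' altered and no voxel is ever added.
#'
#' A candidate voxel (ratio rule satisfied) is removed when either (i) it
#' lies in a connected mask component most of whose voxels satisfy the
#' ratio rule - tail echoes satisfy it throughout, true deep vessels only
#' where they cross beneath a superficial one - or (ii) its slice's local
#' en-face neighbourhood correlates with the superficial-band projection
#' (tails are lateral replicas of the vessel above; crossing deep vessels
#' carry their own orientation and fail the replica test).
#'
#' @param angiogram an \linkS4class{Angiogram}
#' @param vesselness the matching \linkS4class{VesselnessVolume}
#' @param surfaces a \linkS4class{LayerSurfaces} (or \code{surfacesAt}
#'   list) providing the ILM
#' @param tailFactor rejection factor (default 1.5)
#' @param svpBandUm superficial band below the ILM (um)
#' @param compFraction fraction of a component's voxels that must satisfy
#'   the ratio rule for component-level removal
#' @param replicaCorr minimum local correlation with the superficial
#'   projection for voxel-level removal; set to > 1 to disable
#' @return a shadow-rejected \linkS4class{Angiogram}
#' @export
suppressProjectionArtifacts <- function(angiogram, vesselness, surfaces,
                                        tailFactor = 1.5,
                                        svpBandUm = c(0, 40),
                                        compFraction = 0.65,
                                        replicaCorr = 0.25) {
  if (missing(surfaces) || is.null(surfaces))
    stop("layer surfaces are required for shadow rejection")
  g <- angiogram@geometry
  nz <- g@nAxial
  nx <- g@nFast
  ny <- g@nSlow
  maps <- if (is(surfaces, "LayerSurfaces")) surfaces@surfaces
          else surfaces$surfaces
  ilm <- as.numeric(maps$ILM)
  s <- vesselness@scores
  dim(s) <- c(nz, length(ilm))
  zUm <- (seq_len(nz) - 0.5) * g@dzUm
  zcol <- rep(zUm, times = length(ilm))
  ilmRep <- rep(ilm, each = nz)
  inBand <- zcol >= ilmRep + svpBandUm[1] & zcol <= ilmRep + svpBandUm[2]
  sBand <- s
  sBand[!inBand] <- 0
  colMax <- apply(sBand, 2, max)
  below <- array(zcol > ilmRep + svpBandUm[2] + 8, c(nz, nx, ny))
  mask <- angiogram@mask
  scores3 <- vesselness@scores
  cond <- mask & below &
    array(rep(colMax, each = nz) > tailFactor * as.numeric(s), c(nz, nx, ny))
  P <- matrix(colMax, nx, ny)
  bP <- as.matrix(boxBlur2D(P, 3L))
  vP <- pmax(as.matrix(boxBlur2D(P^2, 3L)) - bP^2, 1e-12)
  for (z in which(apply(cond, 1, any))) {
    sl <- mask[z, , ] & below[z, , ]
    cz <- cond[z, , ]
    rmv <- matrix(FALSE, nx, ny)
    lab <- EBImage::bwlabel(sl)
    if (max(lab) > 0) {
      fr <- tapply(cz[lab > 0], lab[lab > 0], mean)
      rmLab <- as.integer(names(fr)[fr >= compFraction])
      if (length(rmLab))
        rmv <- rmv | (matrix(lab %in% rmLab, nx, ny) & cz)
    }
    if (replicaCorr <= 1) {
      Sz <- scores3[z, , ]
      bS <- as.matrix(boxBlur2D(Sz, 3L))
      r <- (as.matrix(boxBlur2D(Sz * P, 3L)) - bS * bP) /
        sqrt(pmax(as.matrix(boxBlur2D(Sz^2, 3L)) - bS^2, 1e-12) * vP)
      rmv <- rmv | (cz & r >= replicaCorr)
    }
    mk <- mask[z, , ]
    mk[rmv] <- FALSE
    mask[z, , ] <- mk
  }
  prov <- angiogram@provenance
  prov$shadowRejected <- TRUE
  prov$tailFactor <- tailFactor
  prov$compFraction <- compFraction
  prov$replicaCorr <- replicaCorr
  new("Angiogram", mask = mask, geometry = g, provenance = prov)
}

#' Project an angiogram band to a 2D image
#'
#' \code{max_intensity}: the per-column maximum over the band.
#' \code{depth_color}: hue encodes the depth of the brightest voxel in
#' each column (decodable via the stored table to within one voxel pitch),
#' value encodes the maximum itself.
#'
#' @param x an \linkS4class{Angiogram}, \linkS4class{VesselnessVolume},
#'   \linkS4class{Slab} or 3D array
#' @param bandUm depth band c(lo, hi) in um from the volume top; NULL for
#'   the full extent (for a \linkS4class{Slab}, relative to the slab)
#' @param mode "depth_color" or "max_intensity"
#' @param dzUm axial pitch override for bare arrays
#' @return a \linkS4class{DepthProjection}
#' @export
depthProject <- function(x, bandUm = NULL,
                         mode = c("depth_color", "max_intensity"),
                         dzUm = NULL) {
  mode <- match.arg(mode)
  arr <- if (is(x, "Angiogram")) x@mask * 1
         else if (is(x, "VesselnessVolume")) x@scores
         else if (is(x, "Slab")) x@voxels * 1
         else x * 1
  dz <- if (!is.null(dzUm)) dzUm
        else if (is(x, "Angiogram") || is(x, "VesselnessVolume") ||
                 is(x, "Slab")) geometry(x)@dzUm
        else 1.9
  nz <- dim(arr)[1]
  zUm <- (seq_len(nz) - 0.5) * dz
  if (is.null(bandUm)) bandUm <- c(0, nz * dz)
  zi <- which(zUm >= bandUm[1] & zUm <= bandUm[2])
  nxy <- dim(arr)[2:3]
  if (!length(zi)) {
    img <- matrix(0, nxy[1], nxy[2])
    return(new("DepthProjection", image = as.array(img), mode = mode,
               depthRangeUm = as.numeric(bandUm),
               colormapName = "depth_hsv",
               decode = data.frame(hue = numeric(), depth_um = numeric())))
  }
  sub <- arr[zi, , , drop = FALSE]
  dim(sub) <- c(length(zi), prod(nxy))
  mx <- apply(sub, 2, max)
  am <- colArgmax(sub)
  depth <- zUm[zi][am]
  decode <- data.frame(hue = 0.7 * (1 - (zUm[zi] - zUm[zi][1]) /
                                      max(diff(range(zUm[zi])), 1e-9)),
                       depth_um = zUm[zi])
  if (mode == "max_intensity") {
    img <- matrix(mx, nxy[1], nxy[2])
    return(new("DepthProjection", image = as.array(img), mode = mode,
               depthRangeUm = range(zUm[zi]), colormapName = "none",
               decode = decode))
  }
  hue <- decode$hue[am]
  val <- mx / max(mx, 1e-12)
  colr <- grDevices::col2rgb(grDevices::hsv(hue, 1, clampv(val, 0, 1))) / 255
  img <- array(0, dim = c(nxy[1], nxy[2], 3L))
  fg <- mx > 0
  for (ch in 1:3) {
    plane <- numeric(prod(nxy))
    plane[fg] <- colr[ch, fg]
    img[, , ch] <- plane
  }
  new("DepthProjection", image = img, mode = mode,
      depthRangeUm = range(zUm[zi]), colormapName = "depth_hsv",
      decode = decode)
}

#' Decode depths from a depth-coded projection
#'
#' Recovers, from the RGB hues of a \code{depth_color} projection, the
#' encoded depth of each foreground pixel via the projection's decode
#' table.
#'
#' @param projection a \linkS4class{DepthProjection} in depth_color mode
#' @return matrix of depths (um), NA at background pixels
#' @export
decodeProjectionDepth <- function(projection) {
  stopifnot(projection@mode == "depth_color")
  img <- projection@image
  n <- dim(img)[1] * dim(img)[2]
  r <- as.vector(img[, , 1]); gg <- as.vector(img[, , 2])
  b <- as.vector(img[, , 3])
  fg <- (r + gg + b) > 0
  out <- rep(NA_real_, n)
  if (any(fg)) {
    hsv <- grDevices::rgb2hsv(rbind(r[fg], gg[fg], b[fg]), maxColorValue = 1)
    idx <- vapply(hsv[1, ], function(h)
      which.min(abs(projection@decode$hue - h)), integer(1))
    out[fg] <- projection@decode$depth_um[idx]
  }
  matrix(out, dim(img)[1], dim(img)[2])
}
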