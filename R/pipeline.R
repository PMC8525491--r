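# End-to-end analysis: orthographic landmarking of lesion-centered
# B-scans, morphometry, sub-RPE (choroid) void assessment, RPE-rupture
# evidence from segmentation validity, deep-plexus vessel density over
# time, and the final acute-versus-CNV call. Per-volume stages (surface
# segmentation, deep-band angiography, choroid slab) are computed once and
# shared across the lesions of an eye.

#' Landmark the lesion-centered B-scan
#'
#' Picks, within a slow-axis search window around the nominal center, the
#' B-scan maximizing the mid-ONL hyperreflectivity near the lesion's
#' lateral position - the orthographic equivalent of choosing the B-scan
#' through the lesion midpoint.
#'
#' The lesion fill produces a plateau of mid-ONL hyperreflectivity along
#' the slow axis; the midpoint of its half-maximum run is the lesion
#' midpoint (a plain argmax would land anywhere on the plateau).
#'
#' @param volume an \linkS4class{OCTVolume}
#' @param surfaces its \linkS4class{LayerSurfaces}
#' @param centerUm numeric length-2 nominal lesion center (fast, slow), um
#' @param searchRadiusUm slow-axis search half-window (um); wide enough to
#'   include clear retina beyond the lesion
#' @return slow-axis B-scan index
#' @export
findLesionBscan <- function(volume, surfaces, centerUm,
                            searchRadiusUm = 250) {
  g <- volume@geometry
  yIdx <- which(abs((seq_len(g@nSlow) - 0.5) * g@dxUm - centerUm[2]) <=
                  searchRadiusUm)
  if (!length(yIdx)) stop("search window outside the field")
  xIdx <- which(abs((seq_len(g@nFast) - 0.5) * g@dxUm - centerUm[1]) <= 40)
  zUm <- (seq_len(g@nAxial) - 0.5) * g@dzUm
  score <- vapply(yIdx, function(y) {
    rpe <- surfaces@surfaces$RPE[xIdx, y]
    mean(vapply(seq_along(xIdx), function(i) {
      zi <- which(zUm >= rpe[i] - 85 & zUm <= rpe[i] - 55)
      mean(volume@intensities[zi, xIdx[i], y])
    }, numeric(1)))
  }, numeric(1))
  if (length(score) >= 5L)
    score <- as.numeric(stats::runmed(score, 5L, endrule = "median"))
  pk <- which.max(score)
  base <- as.numeric(quantile(score, 0.25))
  lev <- base + 0.5 * (score[pk] - base)
  L <- pk
  while (L > 1L && score[L - 1L] > lev) L <- L - 1L
  R <- pk
  while (R < length(score) && score[R + 1L] > lev) R <- R + 1L
  yIdx[round((L + R) / 2)]
}

# shared per-volume analysis products
analyzeVolumeStage <- function(volume, register = FALSE) {
  if (register) volume <- registerBscans(volume)$volume
  surfaces <- segmentSurfaces(volume)
  vness <- enhanceVessels(volume, surfaces, zRangeUm = c(50, 110))
  ang <- segmentAngiogram(vness)
  ang <- suppressProjectionArtifacts(ang, vness, surfaces)
  dvpSlab <- extractSlab(ang, surfaces, "ILM", offsetUm = 60,
                         thicknessUm = 40)
  chor <- extractSlab(volume, surfaces, "RPE", offsetUm = 8,
                      thicknessUm = 50)
  list(volume = volume, surfaces = surfaces, dvpSlab = dvpSlab,
       chorMap = apply(chor@voxels, c(2, 3), mean))
}

#' Analyze lesions across a longitudinal volume series
#'
#' Runs the full pipeline for one simulated eye: per timepoint, surface
#' segmentation, deep-band vessel enhancement, angiogram segmentation with
#' shadow rejection and deep-plexus slab extraction; then, per lesion,
#' B-scan morphometry, RPE-rupture evidence (fraction of invalid RPE
#' positions in the lesion core), choroid-void evidence (sub-RPE slab
#' intensity in the core versus surround) and deep-plexus vessel density
#' in the lesion footprint. Densities are referenced to the pre-lesion
#' (day 0) volume when present, else to a surround annulus, and fed to
#' \code{\link{detectNonperfusion}}; the per-lesion evidence is classified
#' with \code{\link{classifyLesion}}.
#'
#' @param volumes named list of \linkS4class{OCTVolume}s (or zero-argument
#'   functions returning one, rendered lazily so only one volume is held
#'   in memory at a time), names = days ("0" = pre-lesion baseline)
#' @param centersUm lesion centers: numeric length-2, or an n x 2 matrix
#' @param footprintRadiusUm lateral lesion footprint radius per lesion
#'   (um), recycled
#' @param coreRadiusUm radius of the lesion-core probe disc (um) used for
#'   the rupture and void evidence; about half the laser spot size at the
#'   simulated scale
#' @param dropFraction non-perfusion threshold (fraction of baseline)
#' @param register run B-scan registration before analysis
#' @param heightThresholdUm CNV height criterion (um)
#' @return list with one element per lesion: \code{classification},
#'   \code{evidence}, \code{perfusion}, \code{measurements}
#' @export
analyzeLesionTimecourse <- function(volumes, centersUm, footprintRadiusUm,
                                    coreRadiusUm = 25, dropFraction = 0.5,
                                    register = FALSE,
                                    heightThresholdUm = 200) {
  days <- as.numeric(names(volumes))
  stopifnot(!anyNA(days))
  o <- order(days)
  volumes <- volumes[o]
  days <- days[o]
  if (!is.matrix(centersUm)) centersUm <- matrix(centersUm, ncol = 2)
  nL <- nrow(centersUm)
  footprintRadiusUm <- rep_len(footprintRadiusUm, nL)

  # volume-major: analyze one timepoint at a time so a single volume is
  # resident, then regroup per lesion
  rowsByVol <- lapply(seq_along(volumes), function(k) {
    v <- volumes[[k]]
    if (is.function(v)) v <- v()
    st <- analyzeVolumeStage(v, register = register)
    rm(v)
    g <- st$volume@geometry
    out <- lapply(seq_len(nL), function(i) {
      ctr <- centersUm[i, ]
      fr <- footprintRadiusUm[i]
      coreSel <- roiMatrix(list(cxUm = ctr[1], cyUm = ctr[2],
                                radiusUm = coreRadiusUm),
                           g@nFast, g@nSlow, g@dxUm)
      annSel <- roiMatrix(list(cxUm = ctr[1], cyUm = ctr[2],
                               radiusUm = 1.8 * fr,
                               innerRadiusUm = 1.3 * fr),
                          g@nFast, g@nSlow, g@dxUm)
      yc <- findLesionBscan(st$volume, st$surfaces, ctr)
      meas <- measureLesion(reslice(st$volume, "bscan", yc),
                            st$surfaces, ctr[1], yc)
      dens <- vesselDensity(st$dvpSlab,
                            list(cxUm = ctr[1], cyUm = ctr[2],
                                 radiusUm = fr))
      densAnn <- vesselDensity(st$dvpSlab,
                               list(cxUm = ctr[1], cyUm = ctr[2],
                                    radiusUm = 1.8 * fr,
                                    innerRadiusUm = 1.3 * fr))
      list(day = days[k],
           ruptureFrac = mean(!st$surfaces@validity[coreSel]),
           voidRatio = mean(st$chorMap[coreSel]) /
             mean(st$chorMap[annSel]),
           meas = meas, density = dens, densityAnnulus = densAnn)
    })
    rm(st)
    gc(verbose = FALSE)
    out
  })

  perLesion <- lapply(seq_len(nL), function(i) {
    rows <- lapply(rowsByVol, `[[`, i)
    post <- rows[days > 0]
    baseline <- if (any(days == 0)) rows[[which(days == 0)]]$density
                else stats::median(vapply(post, `[[`, numeric(1),
                                          "densityAnnulus"))
    densDf <- data.frame(day = vapply(post, `[[`, numeric(1), "day"),
                         density = vapply(post, `[[`, numeric(1),
                                          "density"))
    perf <- if (nrow(densDf) >= 2L && baseline > 0)
      detectNonperfusion(densDf, baseline, dropFraction) else NULL
    measDf <- do.call(rbind, lapply(post, function(r)
      cbind(day = r$day, r$meas)))
    evidence <- list(
      rpeRupture = any(vapply(post, `[[`, numeric(1),
                              "ruptureFrac") >= 0.25),
      choroidVoid = any(vapply(post, `[[`, numeric(1),
                               "voidRatio") < 0.5),
      maxHeightUm = max(measDf$height_um),
      dvpNonperfusion = if (is.null(perf))
        any(densDf$density < dropFraction * baseline)
        else nrow(perf@intervals) > 0)
    list(classification = classifyLesion(evidence, heightThresholdUm),
         evidence = evidence, perfusion = perf, measurements = measDf,
         baselineDensity = baseline)
  })
  if (nL == 1L) perLesion[[1]] else perLesion
}
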