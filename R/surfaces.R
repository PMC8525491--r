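# Retinal surface segmentation: per-A-scan gradient/peak extrema followed
# by 2D median smoothing and ordering enforcement. Designed for (and
# validated on) the package's synthetic volumes: the ILM is the first
# strong positive edge, the RPE the deepest bright band, the IS/OS and ELM
# the bright lines above it, and the OPL/ONL boundary the falling edge
# into the dark ONL.

#' Segment retinal layer surfaces
#'
#' @param volume a registered \linkS4class{OCTVolume}
#' @param smoothSigmaVox axial Gaussian smoothing (voxels) before peak
#'   detection
#' @param mapSmooth lateral median-smoothing window for the depth maps
#' @param validityFraction RPE peak brightness (relative to the field
#'   median) below which a position is marked invalid, e.g. inside an RPE
#'   rupture
#' @return a \linkS4class{LayerSurfaces} with ILM, ONLtop, ELM, ISOS and
#'   RPE depth maps (um) and a validity mask
#' @export
segmentSurfaces <- function(volume, smoothSigmaVox = 1.5, mapSmooth = 5L,
                            validityFraction = 0.7) {
  g <- volume@geometry
  nz <- g@nAxial
  ncols <- g@nFast * g@nSlow
  M <- volume@intensities
  dim(M) <- c(nz, ncols)
  if (diff(range(M)) < 1e-9)
    stop("no detectable retina: volume intensity is flat")
  S <- smoothCols(M, gaussKernel1D(smoothSigmaVox))
  rm(M)

  bg <- colMeans(S[1:6, , drop = FALSE])
  pk <- S[cbind(colArgmax(S), seq_len(ncols))]
  thr <- bg + 0.30 * (pk - bg)
  ilmIdx <- firstTrue(sweep(S, 2, thr, ">"))
  bad <- is.na(ilmIdx)
  ilmIdx[bad] <- 1L

  zSeq <- rep(seq_len(nz), times = ncols)
  vox <- function(um) round(um / g@dzUm)
  winArgmax <- function(loIdx, hiIdx) {
    sel <- zSeq >= rep(loIdx, each = nz) & zSeq <= rep(hiIdx, each = nz)
    S2 <- S
    S2[!sel] <- -Inf
    colArgmax(S2)
  }
  # RPE = deepest strong band in the window: take the deepest crossing of
  # a fraction of the window maximum, then the local peak just above it.
  # A plain argmax can lock onto bright lesion material higher up.
  lo <- ilmIdx + vox(120)
  hi <- ilmIdx + vox(205)   # stop above the choroid vessel layer
  sel <- zSeq >= rep(lo, each = nz) & zSeq <= rep(hi, each = nz)
  S2 <- S
  S2[!sel] <- -Inf
  winMax <- S2[cbind(colArgmax(S2), seq_len(ncols))]
  above <- S2 >= rep(0.65 * winMax, each = nz)
  deepest <- nz + 1L - firstTrue(above[rev(seq_len(nz)), , drop = FALSE])
  deepest[is.na(deepest)] <- colArgmax(S2)[is.na(deepest)]
  selPk <- zSeq >= rep(deepest - vox(10), each = nz) &
           zSeq <= rep(deepest, each = nz)
  S3 <- S
  S3[!selPk] <- -Inf
  rpeIdx <- colArgmax(S3)
  rpeVal <- S[cbind(rpeIdx, seq_len(ncols))]
  isosIdx <- winArgmax(rpeIdx - vox(62), rpeIdx - vox(12))
  elmIdx <- winArgmax(isosIdx - vox(26), isosIdx - vox(5))

  # OPL/ONL boundary: strongest falling edge above the dark ONL
  G <- S[2:nz, , drop = FALSE] - S[1:(nz - 1L), , drop = FALSE]
  G2 <- rbind(G, 0)
  sel <- zSeq >= rep(ilmIdx + vox(40), each = nz) &
         zSeq <= rep(elmIdx - vox(25), each = nz)
  G2[!sel] <- Inf
  onlIdx <- colArgmax(-G2)

  toMap <- function(idx) {
    m <- matrix((idx - 0.5) * g@dzUm, g@nFast, g@nSlow)
    medSmoothMap(m, mapSmooth)
  }
  ilm <- toMap(ilmIdx)
  onl <- toMap(onlIdx)
  elm <- toMap(elmIdx)
  isos <- toMap(isosIdx)
  rpe <- toMap(rpeIdx)
  # enforce depth ordering
  onl <- pmax(onl, ilm + g@dzUm)
  elm <- pmax(elm, onl + g@dzUm)
  isos <- pmax(isos, elm + g@dzUm)
  rpe <- pmax(rpe, isos + g@dzUm)

  vmap <- medSmoothMap(matrix(rpeVal, g@nFast, g@nSlow), mapSmooth)
  # a valid RPE is bright and at a plausible depth below the ILM; inside a
  # rupture the detector locks onto shallower lesion material instead
  validity <- vmap > validityFraction * stats::median(vmap) &
    (rpe - ilm) > 165 &
    !matrix(bad, g@nFast, g@nSlow)
  new("LayerSurfaces",
      surfaces = list(ILM = ilm, ONLtop = onl, ELM = elm, ISOS = isos,
                      RPE = rpe),
      validity = validity, geometry = g)
}
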