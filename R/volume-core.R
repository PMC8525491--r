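# Volume-core operations: B-scan motion registration, orthogonal reslicing
# and surface-referenced slab extraction. Registration uses FFT
# cross-correlation of consecutive B-scans over integer shifts, chained
# cumulatively and high-pass detrended with a low-order spline so smooth
# anatomical curvature along the slow axis is preserved.

# integer-shift cross-correlation peak between two images, search +/- maxShift
# returns the (dz, dx) shift of B relative to A (B ~ shift(A, dz, dx))
ccShift <- function(A, B, maxShift = 8L) {
  # removing per-depth means suppresses the laterally uniform layer
  # background so the lateral peak is driven by vessels, surface
  # undulation and the tissue speckle pattern
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  C <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  nr <- nrow(C); nc <- ncol(C)
  sh <- c(seq(0, maxShift), seq(-maxShift, -1))
  idx <- function(s, n) ((s %% n) + n) %% n + 1L
  sub <- C[idx(sh, nr), idx(sh, nc)]
  k <- arrayInd(which.max(sub), dim(sub))
  c(dz = sh[k[1]], dx = sh[k[2]])
}

#' Register B-scans of a volume
#'
#' Estimates per-B-scan rigid (axial, lateral) integer-voxel translations by
#' maximizing cross-correlation of each B-scan with its predecessor, chains
#' the pairwise shifts cumulatively, removes the smooth component with a
#' low-order smoothing spline (preserving anatomical curvature along the
#' slow axis) and shifts each B-scan by the negated high-frequency
#' component. Featureless (constant) B-scans get offset 0 and are flagged.
#'
#' @param volume an \linkS4class{OCTVolume} with at least 2 B-scans
#' @param maxShiftVox integer search range per axis
#' @param detrendWindow smoothness scale of the anatomical trend: the
#'   spline uses about one degree of freedom per this many B-scans
#' @param axialOnly set TRUE to estimate axial motion only
#' @return list: \code{volume} (registered), \code{offsets} (data frame
#'   bscan_index, dz_vox, dx_vox, flagged) where (dz_vox, dx_vox) is the
#'   estimated jitter with sign matching the metadata convention (the
#'   correction applied is its negation)
#' @export
registerBscans <- function(volume, maxShiftVox = 8L, detrendWindow = 64L,
                           axialOnly = FALSE) {
  arr <- volume@intensities
  n <- dim(arr)[3]
  if (n < 2L) stop("registration needs at least 2 B-scans")
  rel <- matrix(0, n, 2L)
  flagged <- logical(n)
  sdv <- apply(arr, 3, stats::sd)
  for (y in 2:n) {
    if (sdv[y] < 1e-12 || sdv[y - 1L] < 1e-12) {
      flagged[y] <- TRUE
      next
    }
    rel[y, ] <- ccShift(arr[, , y - 1L], arr[, , y], maxShiftVox)
  }
  if (axialOnly) rel[, 2L] <- 0
  cum <- apply(rel, 2, cumsum)
  trend <- if (n >= 32L)
    apply(cum, 2, function(v)
      stats::smooth.spline(seq_len(n), v, df = max(4, n / detrendWindow))$y)
    else cum * 0
  est <- round(cum - trend)  # estimated jitter component per B-scan
  out <- arr
  for (y in seq_len(n))
    if (any(est[y, ] != 0))
      out[, , y] <- circShift2D(arr[, , y], -est[y, 1L], -est[y, 2L])
  md <- volume@metadata
  md$estimatedOffsets <- -est  # sign convention of appliedOffsets
  md$registrationFlags <- flagged
  list(volume = new("OCTVolume", intensities = out,
                    geometry = volume@geometry, metadata = md),
       offsets = data.frame(bscan_index = seq_len(n),
                            dz_vox = -est[, 1L], dx_vox = -est[, 2L],
                            flagged = flagged))
}

#' Reslice a volume along an orthogonal plane
#'
#' Exact sub-grid extraction, no interpolation: \code{bscan} returns the
#' axial-by-fast cross-section at slow index \code{index}; \code{cscan}
#' returns the en-face slow-by-fast slice at axial index \code{index};
#' \code{ascan-line} returns the axial-by-slow longitudinal section at fast
#' index \code{index}. Stacking every index of a plane reconstructs the
#' volume bit-exactly.
#'
#' @param volume an \linkS4class{OCTVolume}
#' @param plane "bscan", "cscan" or "ascan-line"
#' @param index slice index (1-based)
#' @return a 2D matrix
#' @export
reslice <- function(volume, plane = c("bscan", "cscan", "ascan-line"),
                    index) {
  plane <- match.arg(plane)
  g <- volume@geometry
  lim <- switch(plane, bscan = g@nSlow, cscan = g@nAxial,
                `ascan-line` = g@nFast)
  if (index < 1L || index > lim)
    stop("index ", index, " out of bounds for plane '", plane, "'")
  switch(plane,
         bscan = volume@intensities[, , index],
         cscan = t(volume@intensities[index, , ]),
         `ascan-line` = volume@intensities[, index, ])
}

#' Extract a surface-referenced slab
#'
#' Flattens the volume to a reference surface (nearest-voxel per-column
#' shifts, no lateral mixing or interpolation) and extracts the depth band
#' starting \code{offsetUm} below the surface with height
#' \code{thicknessUm}; the voxel band height is
#' \code{round(thicknessUm / dzUm)}. Out-of-volume parts of the band are
#' zero-filled and flagged.
#'
#' @param x an \linkS4class{OCTVolume}, \linkS4class{VesselnessVolume},
#'   \linkS4class{Angiogram} or 3D array
#' @param surfaces a \linkS4class{LayerSurfaces} (or the list from
#'   \code{\link{surfacesAt}})
#' @param reference reference surface name (e.g. "ILM", "RPE")
#' @param offsetUm signed start offset from the reference (um)
#' @param thicknessUm band height (um), default 60
#' @return a \linkS4class{Slab}
#' @export
extractSlab <- function(x, surfaces, reference = "ILM", offsetUm = 0,
                        thicknessUm = 60) {
  if (thicknessUm <= 0) stop("thicknessUm must be > 0")
  arr <- if (is(x, "OCTVolume")) x@intensities
         else if (is(x, "VesselnessVolume")) x@scores
         else if (is(x, "Angiogram")) x@mask
         else x
  g <- if (is(x, "OCTVolume") || is(x, "VesselnessVolume") ||
           is(x, "Angiogram")) geometry(x)
       else if (is(surfaces, "LayerSurfaces")) surfaces@geometry
       else if (!is.null(surfaces$geometry)) surfaces$geometry
       else stop("cannot infer geometry for a bare array")
  maps <- if (is(surfaces, "LayerSurfaces")) surfaces@surfaces
          else if (!is.null(surfaces$surfaces)) surfaces$surfaces
          else surfaces
  if (!reference %in% names(maps))
    stop("unknown reference surface '", reference, "'")
  ref <- maps[[reference]]
  if (is(surfaces, "LayerSurfaces") && mean(surfaces@validity) < 0.5)
    stop("reference surface valid over less than half the field")
  nb <- max(1L, round(thicknessUm / g@dzUm))
  nz <- g@nAxial
  ncols <- g@nFast * g@nSlow
  z0 <- round((as.numeric(ref) + offsetUm) / g@dzUm + 0.5)
  zi <- outer(seq_len(nb) - 1L, z0, "+")   # nb x ncols
  clipped <- any(zi < 1L | zi > nz)
  zi <- pmin(pmax(zi, 1L), nz)
  colIdx <- rep(seq_len(ncols), each = nb)
  dim(arr) <- c(nz, ncols)
  vox <- arr[cbind(as.vector(zi), colIdx)]
  if (clipped) {
    bad <- as.vector(outer(seq_len(nb) - 1L, z0, "+"))
    vox[bad < 1L | bad > nz] <- 0
    warning("slab band exceeds volume extent; clipped region zero-filled")
  }
  dim(vox) <- c(nb, g@nFast, g@nSlow)
  new("Slab", referenceSurface = reference, offsetUm = offsetUm,
      thicknessUm = thicknessUm, voxels = vox, geometry = g,
      clipped = clipped)
}
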