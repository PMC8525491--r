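# Lesion morphometry on lesion-centered B-scans. Each width is the lateral
# extent over which a layer-band profile deviates from the smooth surround
# fit by more than a disruption threshold (2x the robust standard deviation
# of the surround residual, with a small absolute floor against degenerate
# surrounds); the height is the maximal vertical extent of the
# hyperreflective disruption between the (possibly dome-displaced) OPL/ONL
# boundary and the RPE.

# disruption width around a center column by half-amplitude crossing: the
# lateral disruption profiles are plateaus with soft edges, so the width at
# half the plateau amplitude recovers the nominal footprint independently
# of the detection threshold. The center must show a clear disruption
# (residual above the threshold) or the width is 0.
crossingWidthUm <- function(res, thr, centerIdx, dxUm, gapPx = 25L) {
  n <- length(res)
  c0 <- centerIdx
  if (res[c0] < thr) {
    # allow a slightly off-center peak, but demand a clear one
    w <- max(1L, c0 - 15L):min(n, c0 + 15L)
    pk <- w[which.max(res[w])]
    if (res[pk] < 2 * thr) return(0)
    c0 <- pk
  }
  # contiguous run around the center, bridging short sub-level stretches
  # (isolated profile dropouts inside a genuine disruption)
  runEnds <- function(lev) {
    scan <- function(dir) {
      i <- c0
      last <- c0
      gap <- 0L
      while (TRUE) {
        j <- i + dir
        if (j < 1L || j > n) break
        if (res[j] > lev) { last <- j; gap <- 0L } else {
          gap <- gap + 1L
          if (gap > gapPx) break
        }
        i <- j
      }
      last
    }
    c(scan(-1L), scan(1L))
  }
  base <- runEnds(0.35 * res[c0])
  amp <- stats::median(res[base[1]:base[2]])
  lev <- 0.5 * amp
  e <- runEnds(lev)
  L <- e[1]; R <- e[2]
  # subpixel interpolation of the two crossings
  left <- if (L > 1L && res[L] > lev)
    L - (res[L] - lev) / max(res[L] - res[L - 1L], 1e-9) else as.numeric(L)
  right <- if (R < n && res[R] > lev)
    R + (res[R] - lev) / max(res[R] - res[R + 1L], 1e-9) else as.numeric(R)
  max(right - left, 0) * dxUm
}

#' Measure the four lesion dimensions on a lesion-centered B-scan
#'
#' Computes, in um: the lateral ONL disruption width (hyperreflectivity of
#' the normally dark mid-ONL band), the lateral RPE disruption width
#' (hyperreflectivity of the band just above the RPE - the lesion's
#' RPE-contact footprint - with contiguous invalid RPE stretches, i.e. a
#' rupture, counting as disrupted), the maximal vertical extent of the
#' disrupted column between the possibly dome-displaced OPL/ONL boundary
#' and the RPE, and the widest ELM-IS/OS protrusion into the ONL (upward
#' displacement of the IS/OS surface). Widths are half-amplitude crossings
#' of the respective residual profiles. The surround (outermost columns of
#' the B-scan) provides the reference level, so the lesion footprint must
#' leave clear retina at both B-scan ends.
#'
#' @param bscan axial-by-fast intensity matrix (from
#'   \code{\link{reslice}})
#' @param surfaces a \linkS4class{LayerSurfaces} of the parent volume
#' @param lesionCenterUm lateral position of the lesion center (um, fast
#'   axis)
#' @param bscanIndex slow-axis index of the B-scan within the parent
#'   volume
#' @param surroundFraction fraction of columns at each B-scan end treated
#'   as surround
#' @return one-row data frame: onl_um, rpe_um, height_um, pr_um, flagged
#'   (TRUE when no disruption was found)
#' @export
measureLesion <- function(bscan, surfaces, lesionCenterUm, bscanIndex,
                          surroundFraction = 0.15) {
  g <- surfaces@geometry
  nx <- g@nFast
  dx <- g@dxUm
  dz <- g@dzUm
  xUm <- (seq_len(nx) - 0.5) * dx
  ci <- which.min(abs(xUm - lesionCenterUm))
  ilm <- surfaces@surfaces$ILM[, bscanIndex]
  onl <- surfaces@surfaces$ONLtop[, bscanIndex]
  isos <- surfaces@surfaces$ISOS[, bscanIndex]
  rpe <- surfaces@surfaces$RPE[, bscanIndex]
  valid <- surfaces@validity[, bscanIndex]

  # only contiguous invalid stretches (a rupture) count as disruption
  # evidence; isolated validity dropouts are detector noise
  invRun <- as.numeric(stats::runmed((!valid) * 1, 7)) > 0.5

  nS <- max(10L, round(surroundFraction * nx))
  sur <- c(seq_len(nS), (nx - nS + 1L):nx)
  surv <- sur[valid[sur]]
  if (length(surv) < 8L) surv <- sur

  # smooth RPE anchor: the RPE is never displaced by a lesion, so a
  # median-smoothed track of the detected RPE (interpolated across invalid
  # stretches such as a rupture) references every band
  rpeTrack <- rpe
  if (any(!valid) && sum(valid) > 8L)
    rpeTrack[!valid] <- stats::approx(xUm[valid], rpe[valid],
                                      xout = xUm[!valid], rule = 2)$y
  k <- min(oddize(31L), oddize(nx - (nx + 1L) %% 2L))
  rpeFit <- as.numeric(stats::runmed(rpeTrack, k, endrule = "median"))
  gapUm <- stats::median(onl[surv] - ilm[surv])

  Bs <- smoothCols(bscan, gaussKernel1D(1.2))
  zUm <- (seq_len(nrow(bscan)) - 0.5) * dz
  bandMean <- function(loUm, hiUm) {
    vapply(seq_len(nx), function(x) {
      zi <- which(zUm >= loUm[x] & zUm <= hiUm[x])
      if (!length(zi)) return(NA_real_)
      mean(Bs[zi, x])
    }, numeric(1))
  }
  smooth5 <- function(v) as.numeric(stats::runmed(v, 7, endrule = "median"))

  robustThr <- function(res, floor) {
    m <- stats::median(res[surv])
    s <- stats::mad(res[surv])
    list(res = res - m, thr = max(2 * s, floor))
  }

  # ONL band: mid-ONL, anchored to the RPE fit
  pOnl <- smooth5(bandMean(rpeFit - 85, rpeFit - 55))
  tOnl <- robustThr(pOnl, 0.10)
  onlUm <- crossingWidthUm(tOnl$res, tOnl$thr, ci, dx)

  # RPE disruption: hyperreflectivity of the normally dark band just above
  # the RPE (the lesion's RPE-contact footprint); invalid positions
  # (rupture) count as maximally disrupted
  pRpe <- smooth5(bandMean(rpeFit - 14, rpeFit - 6))
  tRpe <- robustThr(pRpe, 0.10)
  resRpe <- tRpe$res
  resRpe[invRun] <- pmax(resRpe[invRun], tRpe$thr * 3, 0.5)
  rpeUm <- crossingWidthUm(resRpe, tRpe$thr, ci, dx)

  # photoreceptor protrusion: upward IS/OS displacement vs the RPE anchor
  elev <- smooth5(rpeFit - isos)
  tPr <- robustThr(elev, 6)
  resPr <- tPr$res
  resPr[invRun] <- pmax(resPr[invRun], tPr$thr * 3, 15)
  # depth-based profile: shadow-immune, so no wide gap bridging
  prUm <- crossingWidthUm(resPr, tPr$thr, ci, dx, gapPx = 5L)

  # height: vertical extent of the disrupted column, from the first
  # hyperreflective voxel below the (displaced) OPL/ONL boundary down to
  # the RPE it abuts, maximized over the disrupted region
  heightUm <- 0
  if (onlUm > 0 || rpeUm > 0) {
    darkRef <- stats::median(pOnl[surv])
    thrH <- darkRef + max(3.5 * stats::mad(pOnl[surv]), 0.12)
    half <- max(onlUm, rpeUm, 60) / 2
    cols <- which(abs(xUm - xUm[ci]) <= half * 0.9)
    hcol <- vapply(cols, function(x) {
      zTop <- ilm[x] + gapUm
      zi <- which(zUm > zTop + 2 & zUm <= rpeFit[x] - 2)
      zi <- zi[Bs[zi, x] > thrH]
      if (!length(zi)) return(0)
      # keep only the bright run contiguous (gaps <= 3 voxels) with the
      # deepest voxel: bright slivers from deep-plexus vessels near the
      # search top must not inflate the height
      zi <- rev(zi)
      brk <- which(diff(zi) < -4L)
      if (length(brk)) zi <- zi[seq_len(brk[1])]
      firstB <- min(zUm[zi])
      lastB <- max(zUm[zi])
      if (lastB >= rpeFit[x] - 24) rpeFit[x] - firstB + 2
      else lastB - firstB + 4
    }, numeric(1))
    if (any(hcol > 0)) heightUm <- max(hcol)
  }

  flagged <- onlUm == 0 && rpeUm == 0 && prUm == 0
  if (flagged) heightUm <- 0
  data.frame(onl_um = onlUm, rpe_um = rpeUm, height_um = heightUm,
             pr_um = prUm, flagged = flagged)
}
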