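#' Vessel density within a region of interest
#'
#' Fraction of angiogram-positive voxels inside the ROI's slab columns:
#' positive voxels in roi-by-band over total voxels in roi-by-band.
#'
#' @param slab a \linkS4class{Slab} extracted from an angiogram (binary
#'   voxels), or a 3D array
#' @param roi lateral region: a logical nFast x nSlow matrix, a list
#'   \code{list(cxUm=, cyUm=, radiusUm=)} describing a disc, or NULL for the
#'   whole field
#' @return density in [0, 1]
#' @export
vesselDensity <- function(slab, roi = NULL) {
  vox <- if (is(slab, "Slab")) slab@voxels else slab
  g <- if (is(slab, "Slab")) slab@geometry else NULL
  nFast <- dim(vox)[2]
  nSlow <- dim(vox)[3]
  sel <- roiMatrix(roi, nFast, nSlow, if (is.null(g)) 1 else g@dxUm)
  if (!any(sel)) stop("ROI selects no columns")
  dim(vox) <- c(dim(vox)[1], nFast * nSlow)
  mean(vox[, as.vector(sel)] > 0)
}

roiMatrix <- function(roi, nFast, nSlow, dxUm) {
  if (is.null(roi)) return(matrix(TRUE, nFast, nSlow))
  if (is.matrix(roi)) {
    stopifnot(identical(dim(roi), c(as.integer(nFast), as.integer(nSlow))))
    return(roi)
  }
  x <- (seq_len(nFast) - 0.5) * dxUm
  y <- (seq_len(nSlow) - 0.5) * dxUm
  r2 <- outer((x - roi$cxUm)^2, (y - roi$cyUm)^2, "+")
  if (is.null(roi$innerRadiusUm)) {
    r2 <= roi$radiusUm^2
  } else {
    r2 <= roi$radiusUm^2 & r2 >= roi$innerRadiusUm^2  # annulus
  }
}

#' Detect capillary non-perfusion and reperfusion intervals
#'
#' A timepoint is non-perfused when its vessel density falls below
#' \code{dropFraction} times the baseline density (pre-lesion scan when
#' available, else a surround annulus at the same timepoint). Consecutive
#' non-perfused timepoints merge into intervals; the reperfusion day is the
#' first timepoint at which density recovers after the last interval.
#'
#' @param densities data frame with columns \code{day} and \code{density},
#'   optionally \code{plexus} (multiple plexuses handled independently)
#' @param baseline baseline density; a single value, or a named vector per
#'   plexus
#' @param dropFraction non-perfusion threshold as fraction of baseline
#'   (default 0.5)
#' @return a \linkS4class{PerfusionTimecourse}
#' @examples
#' d <- data.frame(day = c(1, 3, 7, 14, 21),
#'                 density = c(0.04, 0.04, 0.05, 0.18, 0.19))
#' detectNonperfusion(d, baseline = 0.2)
#' @export
detectNonperfusion <- function(densities, baseline, dropFraction = 0.5) {
  stopifnot(is.data.frame(densities),
            all(c("day", "density") %in% names(densities)))
  if (!"plexus" %in% names(densities)) densities$plexus <- "DVP"
  if (is.null(names(baseline)))
    baseline <- setNames(rep(baseline, length(unique(densities$plexus))),
                         unique(densities$plexus))
  if (any(baseline <= 0)) stop("baseline density must be positive")
  densities <- densities[order(densities$plexus, densities$day), ]
  if (length(unique(densities$day)) < 2L)
    stop("at least two timepoints are required")
  out <- lapply(split(densities, densities$plexus), function(d) {
    b <- baseline[[d$plexus[1]]]
    flag <- d$density < dropFraction * b
    d$nonperfused <- flag
    runs <- rle(flag)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    iv <- data.frame(plexus = character(), start_day = numeric(),
                     end_day = numeric())
    rep_day <- NA_real_
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      iv <- rbind(iv, data.frame(plexus = d$plexus[1],
                                 start_day = d$day[starts[k]],
                                 end_day = d$day[ends[k]]))
      rep_day <- if (ends[k] < nrow(d)) d$day[ends[k] + 1L] else NA_real_
    }
    list(densities = d, intervals = iv, reperfusion = rep_day)
  })
  new("PerfusionTimecourse",
      densities = do.call(rbind, c(lapply(out, `[[`, "densities"),
                                   make.row.names = FALSE)),
      baselineDensity = baseline, dropFraction = dropFraction,
      intervals = do.call(rbind, c(lapply(out, `[[`, "intervals"),
                                   make.row.names = FALSE)),
      reperfusionDay = vapply(out, `[[`, numeric(1), "reperfusion"))
}

#' Classify a lesion as acute injury or CNV
#'
#' Pure evidence rule: a lesion is CNV when the RPE is ruptured or the
#' choroid beneath it appears as a void, or when its maximal height reached
#' 200 um or more together with deep-plexus capillary non-perfusion. It is
#' acute when none of the four flags is raised, and indeterminate otherwise
#' (e.g. tall but perfused, with an intact RPE).
#'
#' @param evidence list (or \linkS4class{LesionClassification} evidence)
#'   with logical \code{rpeRupture}, \code{choroidVoid},
#'   \code{dvpNonperfusion} and numeric \code{maxHeightUm}
#' @param heightThresholdUm height criterion for CNV-scale swelling
#'   (default 200)
#' @return a \linkS4class{LesionClassification}
#' @examples
#' classifyLesion(list(rpeRupture = TRUE, choroidVoid = TRUE,
#'                     maxHeightUm = 246, dvpNonperfusion = TRUE))
#' @export
classifyLesion <- function(evidence, heightThresholdUm = 200) {
  need <- c("rpeRupture", "choroidVoid", "maxHeightUm", "dvpNonperfusion")
  miss <- setdiff(need, names(evidence))
  if (length(miss))
    stop("missing evidence fields: ", paste(miss, collapse = ", "))
  if (any(vapply(evidence[need], function(x) length(x) != 1L || is.na(x),
                 logical(1))))
    stop("evidence fields must be scalar and non-missing")
  tall <- evidence$maxHeightUm >= heightThresholdUm
  label <- if (evidence$rpeRupture || evidence$choroidVoid ||
               (tall && evidence$dvpNonperfusion)) "cnv"
           else if (!tall && !evidence$dvpNonperfusion) "acute"
           else "indeterminate"
  new("LesionClassification", label = label, evidence = evidence[need])
}

#' Laser pulse energy
#'
#' Energy delivered by a photocoagulation pulse: power times duration
#' (fluence = intensity x time). Returned at full precision together with
#' the 3-decimal rounding used in dose reporting.
#'
#' @param powerMw laser power in milliwatts (>= 0)
#' @param durationMs pulse duration in milliseconds (>= 0)
#' @return named numeric: \code{joules} (full precision) and
#'   \code{rounded} (3 decimals)
#' @examples
#' pulseEnergy(46, 200)   # 0.0092 J, reported as 0.009
#' @export
pulseEnergy <- function(powerMw, durationMs) {
  if (powerMw < 0 || durationMs < 0)
    stop("power and duration must be non-negative")
  j <- powerMw * 1e-3 * durationMs * 1e-3
  c(joules = j, rounded = round(j, 3))
}
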