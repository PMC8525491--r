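#' Percent-change dynamics of one lesion dimension
#'
#' Normalizes a longitudinal series of lesion measurements to its first
#' (baseline) value M0 and computes the dimensionality-reduced descriptors
#' used for phase detection: percent change P_t = 100 (M_t - M0) / M0,
#' per-interval first differences D1_i = 100 (M_i - M_{i-1}) / M0 (each
#' interval's change as a percent of baseline, the convention that makes
#' lesions of different absolute size comparable), and second differences
#' D2 = diff(D1). Expansion is positive, reduction negative. Steady-state
#' detection per \code{\link{detectSteadyState}} is applied immediately.
#'
#' @param measurements either a numeric vector of measurements (um), or a
#'   data frame holding columns \code{day} and the requested dimension
#'   (e.g. \code{pr_um}) for a single lesion
#' @param dimension measured dimension name (used when \code{measurements}
#'   is a data frame; kept as a label otherwise)
#' @param days timepoints in days (required for the vector form), strictly
#'   increasing, at least two
#' @param significanceThreshold percent-of-baseline threshold for a
#'   significant interval change (default 5)
#' @return a \linkS4class{DynamicsTrace}
#' @examples
#' tab <- lesionDimensionTable("acute")
#' tr <- percentChangeTrace(tab$pr_um, "pr_um", days = tab$day)
#' tr
#' @export
percentChangeTrace <- function(measurements, dimension = "value",
                               days = NULL, significanceThreshold = 5) {
  if (is.data.frame(measurements)) {
    col <- if (dimension %in% names(measurements)) dimension
           else paste0(dimension, "_um")
    if (!col %in% names(measurements))
      stop("dimension '", dimension, "' not found in measurement table")
    o <- order(measurements$day)
    days <- measurements$day[o]
    values <- measurements[[col]][o]
  } else {
    values <- as.numeric(measurements)
    if (is.null(days)) stop("days must be supplied with a measurement vector")
  }
  if (length(days) < 2L) stop("at least two timepoints are required")
  if (is.unsorted(days, strictly = TRUE))
    stop("days must be strictly increasing")
  m0 <- values[1L]
  if (!is.finite(m0) || m0 <= 0)
    stop("baseline measurement must be positive for normalization")
  p <- 100 * (values - m0) / m0
  d1 <- 100 * diff(values) / m0
  d2 <- diff(d1)
  tr <- new("DynamicsTrace", dimension = dimension, days = as.numeric(days),
            values = values, percentChange = p, firstDiff = d1,
            secondDiff = d2, significanceThreshold = significanceThreshold,
            steadyOnset = NA_real_, phaseLabels = phaseLabel(days))
  tr@steadyOnset <- steadyOnsetDay(tr)
  tr
}

phaseLabel <- function(days) {
  ifelse(days <= 3, "early", ifelse(days < 7, "transition", "late"))
}

steadyOnsetDay <- function(trace) {
  d1 <- trace@firstDiff
  thr <- trace@significanceThreshold
  n <- length(trace@days)
  # onset candidates must leave at least two subsequent intervals: a single
  # sub-threshold final interval is not evidence of an asymptote
  for (j in seq_len(max(0L, n - 2L))) {
    if (all(abs(d1[j:(n - 1L)]) <= thr)) return(trace@days[j])
  }
  NA_real_
}

#' Detect steady state and label inflammatory phases
#'
#' A lesion dimension reaches steady state at the earliest timepoint after
#' which every remaining interval change, normalized by the baseline value,
#' stays within the significance threshold (default 5 percent) - the
#' zero-asymptote reading of the second-derivative event model. The onset
#' must be followed by at least two sub-threshold intervals; if no such
#' timepoint exists before the last interval the trace has not converged.
#' Timepoints are additionally labelled by inflammatory phase: early
#' (through day 3), transition (days 3-7) and late (day 7 onward).
#'
#' @param trace a \linkS4class{DynamicsTrace} with at least three timepoints
#' @return list with elements \code{steadyOnset} (day, or NA when the trace
#'   never converges) and \code{phaseLabels}
#' @examples
#' tab <- lesionDimensionTable("acute")
#' detectSteadyState(percentChangeTrace(tab$pr_um, "pr_um", days = tab$day))
#' @export
detectSteadyState <- function(trace) {
  stopifnot(is(trace, "DynamicsTrace"))
  if (length(trace@days) < 3L)
    stop("steady-state detection needs at least three timepoints")
  list(steadyOnset = steadyOnsetDay(trace),
       phaseLabels = setNames(trace@phaseLabels, trace@days))
}

#' Per-condition group statistics and pooled CV
#'
#' Computes, for every (dimension, day) cell of a longitudinal measurement
#' table, the group mean, population standard deviation and coefficient of
#' variation CV = sigma/mu, and pools the condition's consistency into a
#' single number: the unweighted arithmetic mean of all cell CVs. Cells
#' with zero mean have no defined CV; they are excluded and flagged.
#'
#' Two input forms are accepted. A raw per-lesion table (columns
#' \code{lesion_id}, \code{day} and the four *_um dimensions) is summarised
#' from the individual lesions. A summary-form table that already carries
#' *_cv columns alongside the means (such as
#' \code{\link{lesionDimensionTable}}) has its printed CV cells pooled
#' directly.
#'
#' @param table measurement data frame (raw or summary form)
#' @param condition condition label; when the table has a
#'   \code{condition} column it is filtered accordingly
#' @return a \linkS4class{GroupStats}
#' @examples
#' groupStatistics(lesionDimensionTable(), "acute")
#' @export
groupStatistics <- function(table, condition = "all") {
  if ("condition" %in% names(table) && condition != "all")
    table <- table[table$condition == condition, , drop = FALSE]
  if (nrow(table) == 0L) stop("no rows for condition '", condition, "'")
  if (all(cvNames %in% names(table))) {
    cells <- do.call(rbind, lapply(seq_along(dimNames), function(i) {
      data.frame(dimension = dimNames[i], day = table$day,
                 n = NA_integer_, mean = table[[dimNames[i]]],
                 sd = table[[dimNames[i]]] * table[[cvNames[i]]],
                 cv = table[[cvNames[i]]])
    }))
  } else {
    need <- intersect(dimNames, names(table))
    if (length(need) == 0L) stop("no dimension columns found")
    cells <- do.call(rbind, lapply(need, function(d) {
      agg <- do.call(rbind, lapply(split(table[[d]], table$day), function(x) {
        x <- x[is.finite(x)]
        if (length(x) < 2L)
          stop("each (dimension, day) cell needs at least two lesions")
        mu <- mean(x)
        sig <- sqrt(mean((x - mu)^2))  # population denominator
        c(n = length(x), mean = mu, sd = sig)
      }))
      data.frame(dimension = d, day = as.numeric(rownames(agg)),
                 n = as.integer(agg[, "n"]), mean = agg[, "mean"],
                 sd = agg[, "sd"], cv = ifelse(agg[, "mean"] > 0,
                                               agg[, "sd"] / agg[, "mean"],
                                               NA_real_))
    }))
  }
  rownames(cells) <- NULL
  bad <- !is.finite(cells$cv)
  excluded <- cells[bad, , drop = FALSE]
  kept <- cells[!bad, , drop = FALSE]
  if (nrow(excluded))
    warning(nrow(excluded), " cell(s) with zero mean excluded from pooled CV")
  new("GroupStats", cells = kept, pooledCv = mean(kept$cv),
      condition = condition, excluded = excluded)
}
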