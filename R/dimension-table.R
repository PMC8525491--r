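#' Reference lesion-dimension table
#'
#' The packaged table of mean lesion dimensions (um) and their coefficients
#' of variation per condition and timepoint, as measured from
#' lesion-centered B-scans in the laser-injury study this package models:
#' ONL lateral disruption width, RPE lateral disruption width, maximal
#' OPL-RPE height, and ELM-IS/OS protrusion width at days 1, 3, 7, 14 and
#' 21 for the acute-injury and CNV conditions. This table calibrates the
#' synthetic-lesion generator and serves as a summary-form input to
#' \code{\link{groupStatistics}} and the dynamics functions.
#'
#' @param condition optional filter, "acute" or "cnv"
#' @return data frame with columns condition, day, then mean and CV per
#'   dimension (onl, rpe, height, pr)
#' @examples
#' head(lesionDimensionTable("acute"))
#' @export
lesionDimensionTable <- function(condition = NULL) {
  path <- system.file("extdata", "lesion_dimension_means.csv",
                      package = "enfaceOCTA", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(condition)) {
    condition <- match.arg(condition, c("acute", "cnv"))
    tab <- tab[tab$condition == condition, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

dimNames <- c("onl_um", "rpe_um", "height_um", "pr_um")
cvNames <- c("onl_cv", "rpe_cv", "height_cv", "pr_cv")

# condition-level mean dims at arbitrary days (piecewise linear between the
# printed timepoints, flat beyond; times before the first printed day take
# the first printed value - the one-hour convention)
conditionDimsAt <- function(condition, days) {
  tab <- lesionDimensionTable(condition)
  out <- sapply(dimNames, function(d) interpFlat(tab$day, tab[[d]], days))
  matrix(out, nrow = length(days), ncol = 4L,
         dimnames = list(NULL, dimNames))
}

conditionCvAt <- function(condition, days) {
  tab <- lesionDimensionTable(condition)
  out <- sapply(cvNames, function(d) interpFlat(tab$day, tab[[d]], days))
  matrix(out, nrow = length(days), ncol = 4L,
         dimnames = list(NULL, dimNames))
}
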