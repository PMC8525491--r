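# External interchange: multipage TIFF (one page per B-scan, fast axis =
# page width, 16-bit) with a JSON sidecar carrying voxel sizes and
# acquisition metadata; measurement tables as CSV.

#' Write an OCT volume as multipage TIFF + JSON sidecar
#'
#' @param volume an \linkS4class{OCTVolume}
#' @param path output basename; \code{.tif} and \code{.json} are appended
#' @return invisibly, the two file paths
#' @export
writeOCTVolume <- function(volume, path) {
  g <- volume@geometry
  arr <- volume@intensities
  scale <- max(arr, 1e-12)
  pages <- lapply(seq_len(g@nSlow), function(y) arr[, , y] / scale)
  tifPath <- paste0(path, ".tif")
  tiff::writeTIFF(pages, tifPath, bits.per.sample = 16L,
                  compression = "none")
  md <- volume@metadata
  side <- list(dx_um = g@dxUm, dz_um = g@dzUm,
               n_fast = g@nFast, n_slow = g@nSlow, n_axial = g@nAxial,
               timepoint_days = md$timepointDays, seed = md$seed,
               intensity_scale = scale,
               applied_offsets = unname(md$appliedOffsets))
  jsonPath <- paste0(path, ".json")
  jsonlite::write_json(side, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(tifPath, jsonPath))
}

#' Read an OCT volume written by \code{\link{writeOCTVolume}}
#'
#' @param path basename used at write time
#' @return an \linkS4class{OCTVolume}
#' @export
readOCTVolume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  g <- VolumeGeometry(side$n_fast, side$n_slow, side$n_axial,
                      side$dx_um, side$dz_um)
  arr <- array(0, dim = c(g@nAxial, g@nFast, g@nSlow))
  for (y in seq_along(pages)) arr[, , y] <- pages[[y]] * side$intensity_scale
  off <- side$applied_offsets
  if (is.null(off)) off <- matrix(0L, g@nSlow, 2L)
  off <- matrix(as.integer(off), ncol = 2L,
                dimnames = list(NULL, c("axial", "lateral")))
  new("OCTVolume", intensities = arr, geometry = g,
      metadata = list(timepointDays = side$timepoint_days,
                      seed = side$seed, appliedOffsets = off))
}

#' Write / read a lesion measurement table
#'
#' CSV with columns lesion_id, day, onl_um, rpe_um, height_um, pr_um.
#'
#' @param table measurement data frame
#' @param path CSV file path
#' @export
writeMeasurementTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasurementTable
#' @export
readMeasurementTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
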