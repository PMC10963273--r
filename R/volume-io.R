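#' Physical voxel volume in microlitres
#'
#' Converts voxel edge lengths in micrometres to the voxel volume in
#' microlitres (1 ul = 1e9 um^3). At the canonical 25 um isotropic grid one
#' voxel is 1.5625e-5 ul and a 20x20x20-voxel window is 0.125 ul.
#'
#' @param voxelSize Numeric triple of positive edge lengths in micrometres.
#' @return Voxel volume in microlitres.
#' @examples
#' voxelVolumeUl(c(25, 25, 25))            # 1.5625e-05
#' voxelVolumeUl(c(25, 25, 25)) * 20^3     # 0.125
#' @export
voxelVolumeUl <- function(voxelSize) {
  if (length(voxelSize) != 3L || any(!is.finite(voxelSize)) || any(voxelSize <= 0))
    stopDomain("voxelSize must be three positive finite lengths in um")
  prod(voxelSize) / 1e9
}

.unitToUm <- c(um = 1, mm = 1e3, m = 1e6)

#' Read a registered 3D volume from NIfTI or TIFF
#'
#' NIfTI voxel sizes are taken from the header (converted to micrometres
#' from the header's spatial unit); multi-page TIFF carries no z-spacing, so
#' \code{voxelSize} must be supplied. Pages of a TIFF stack map to the third
#' array axis (z), TIFF columns to the first (x) and rows to the second (y).
#' Integer intensities round-trip exactly (TIFF support is 16-bit unsigned,
#' values in [0, 65535]).
#'
#' @param path File path (\code{.nii}, \code{.nii.gz}, \code{.tif}, \code{.tiff}).
#' @param format \code{"auto"} (by extension), \code{"nifti"} or \code{"tiff"}.
#' @param voxelSize Optional explicit voxel edge lengths in micrometres;
#'   overrides any header value. Required for TIFF.
#' @return A \code{\link{Volume3D}}.
#' @export
readVolume <- function(path, format = c("auto", "nifti", "tiff"), voxelSize = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopDomain("cannot read volume: no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "nifti"
  if (format == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stopDomain("unreadable NIfTI file ", path, ": ",
                                                   conditionMessage(e)))
    arr <- as.array(img)
    if (is.null(voxelSize)) {
      unit <- RNifti::pixunits(img)[1]
      scale <- .unitToUm[unit]
      if (is.na(scale)) scale <- 1  # unknown spatial unit: taken as um
      voxelSize <- RNifti::pixdim(img)[1:3] * scale
    }
  } else {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e) stopDomain("unreadable TIFF file ", path, ": ",
                                                     conditionMessage(e)))
    if (is.null(voxelSize))
      stopDomain("TIFF carries no 3D voxel size; supply voxelSize explicitly for ", path)
    # readTIFF returns [row, col] = [y, x]; transpose to [x, y] per page
    arr <- simplify2array(lapply(pages, t))
  }
  attributes(arr) <- list(dim = dim(arr))
  Volume3D(arr, voxelSize = voxelSize)
}

#' Write a volume to NIfTI or TIFF
#'
#' NIfTI stores the voxel size (micrometre units) in the header; TIFF writes
#' one 16-bit page per z-slice and requires non-negative integer intensities
#' up to 65535.
#'
#' @param volume A \code{\link{Volume3D}}.
#' @param path Destination path.
#' @param format \code{"auto"} (by extension), \code{"nifti"} or \code{"tiff"}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path, format = c("auto", "nifti", "tiff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "nifti"
  arr <- gridData(volume)
  if (format == "nifti") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- voxelSize(volume)
    RNifti::pixunits(img) <- c("um", "s")
    RNifti::writeNifti(img, path)
  } else {
    if (any(arr < 0) || any(arr > 65535) || any(arr != round(arr)))
      stopDomain("TIFF output requires integer intensities in [0, 65535]")
    pages <- lapply(seq_len(dim(arr)[3]), function(z) t(arr[, , z]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read or write a label table (two-column TSV: label, name)
#'
#' @param path TSV path.
#' @return \code{readLabelTable}: data.frame with integer \code{label} and
#'   character \code{name}.
#' @export
readLabelTable <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("integer", "character"))
  if (!all(c("label", "name") %in% names(tab)))
    stopDomain("label table must have columns 'label' and 'name': ", path)
  tab
}

#' @param labelTable data.frame with columns \code{label} and \code{name}.
#' @rdname readLabelTable
#' @export
writeLabelTable <- function(labelTable, path) {
  utils::write.table(labelTable[c("label", "name")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
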