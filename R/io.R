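#' Read a 2-D grayscale slice from PNG or NIfTI
#'
#' PNG files are read with the png package, averaged over channels if
#' necessary and rescaled to 0-255. NIfTI volumes (.nii / .nii.gz) are read
#' with RNifti and sliced along the third axis (middle slice by default).
#'
#' @param path Input file.
#' @param slice Slice index for volumes (default: middle slice).
#' @return Numeric matrix on the 0-255 scale.
#' @export
read_image <- function(path, slice = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    a <- as.array(vol)
    if (length(dim(a)) >= 3) {
      if (is.null(slice)) slice <- ceiling(dim(a)[3] / 2)
      a <- a[, , slice]
    }
    return(matrix(as.numeric(a), nrow(a), ncol(a)))
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE],
                                        c(1, 2), mean)
  px * 255
}

#' Write a grayscale image as 8-bit PNG or as NIfTI
#'
#' @param image Numeric matrix.
#' @param path Output file (.png, .nii or .nii.gz).
#' @param peak Intensity mapped to white (default 255).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, peak = 255) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(image), path)
  } else {
    png::writePNG(pmin(pmax(image / peak, 0), 1), path)
  }
  invisible(path)
}

#' Read a label map stored as an 8-bit PNG
#'
#' @param path Input PNG written by [write_labels()].
#' @return Integer label matrix.
#' @export
read_labels <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
}

#' Write a label map as an 8-bit PNG (lossless for labels up to 255)
#'
#' @param labels Integer label matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  png::writePNG(labels / 255, path)
  invisible(path)
}
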