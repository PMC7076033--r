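# Readers and writers for the formats the pipeline consumes: single-channel
# TIFF/PNG intensity images, 16-bit label TIFFs, and track CSVs.

img_ext <- function(path) tolower(tools::file_ext(path))

#' Read a single-channel grayscale image
#'
#' TIFF and PNG are supported; intensities are returned in [0, 1]. A
#' multi-channel file is rejected: the pipeline consumes already-unmixed
#' single-channel crops.
#'
#' @param path image path (.tif/.tiff/.png).
#' @param pixel_size_um physical pixel size attached to the result.
#' @return numeric matrix with attribute \code{pixel_size_um}.
#' @export
read_intensity_image <- function(path, pixel_size_um = 0.32) {
  if (!file.exists(path))
    stop_osteo(sprintf("image file not found: %s", path), "format_error")
  x <- switch(img_ext(path),
              tif = , tiff = tiff::readTIFF(path),
              png = png::readPNG(path),
              stop_osteo(sprintf("unsupported image format: %s", path),
                         "format_error"))
  if (length(dim(x)) == 3) {
    if (dim(x)[3] != 1)
      stop_osteo(sprintf("%s has %d channels; expected a single channel",
                         path, dim(x)[3]), "format_error")
    x <- x[, , 1]
  }
  attr(x, "pixel_size_um") <- pixel_size_um
  x
}

#' Write an intensity image as 16-bit single-channel TIFF
#'
#' @param img numeric matrix in [0, 1].
#' @param path output path.
#' @export
write_intensity_image <- function(img, path) {
  stopifnot(is.matrix(img))
  tiff::writeTIFF(pmin(pmax(unclass(img), 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read an integer label mask
#'
#' TIFF files are read with raw sample values (\code{as.is}); PNG values
#' are rescaled from [0, 1] assuming 16-bit depth.
#'
#' @param path mask path (.tif/.tiff/.png).
#' @return integer matrix of labels (0 = background).
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path))
    stop_osteo(sprintf("mask file not found: %s", path), "format_error")
  x <- switch(img_ext(path),
              tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
              png = round(png::readPNG(path) * 65535),
              stop_osteo(sprintf("unsupported mask format: %s", path),
                         "format_error"))
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x)), nrow(x), ncol(x))
}

#' Write an integer label mask as 16-bit TIFF
#'
#' @param mask integer matrix, labels in 0..65535.
#' @param path output path.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0) || any(mask > 65535))
    stop_osteo("labels must lie in 0..65535 for 16-bit TIFF",
               "validation_error")
  tiff::writeTIFF(unclass(mask) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read cell tracks from CSV
#'
#' @param path CSV with header \code{track_id,time_min,x_um,y_um}.
#' @return data.frame with those columns.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path))
    stop_osteo(sprintf("track file not found: %s", path), "format_error")
  x <- utils::read.csv(path)
  req <- c("track_id", "time_min", "x_um", "y_um")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop_osteo(sprintf("%s is missing track columns: %s", path,
                       paste(miss, collapse = ", ")), "format_error")
  x[req]
}

#' Write cell tracks to CSV
#'
#' @param tracks data.frame with columns track_id, time_min, x_um, y_um.
#' @param path output path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, fileEncoding = "UTF-8")
}
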