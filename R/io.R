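#' Write an image field as a multi-page TIFF
#'
#' One page per channel, in DAPI, actin, tubulin order.
#' @param field An `image_field`.
#' @param path Output .tif path.
#' @export
write_field_tiff <- function(field, path) {
  arr <- array(c(field$dapi, field$actin, field$tubulin),
               dim = c(dim(field$dapi), 3))
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF field
#' @param path Input .tif path (pages in DAPI, actin, tubulin order).
#' @param pixel_size Micrometres per pixel.
#' @param donor_id,field_index Metadata.
#' @return An `image_field`.
#' @export
read_field_tiff <- function(path, pixel_size = 1, donor_id = NA_character_,
                            field_index = 1L) {
  arr <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  structure(list(dapi = arr[, , 1],
                 actin = if (dim(arr)[3] >= 2) arr[, , 2] else arr[, , 1],
                 tubulin = if (dim(arr)[3] >= 3) arr[, , 3] else arr[, , 1],
                 pixel_size = pixel_size, donor_id = donor_id,
                 field_index = as.integer(field_index)),
            class = "image_field")
}

#' Write an integer label map as 16-bit TIFF
#' @param labels Integer label map (ids < 65536).
#' @param path Output .tif path.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  EBImage::writeImage(EBImage::Image(labels / 65535), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label TIFF back to an integer label map
#' @param path Input .tif path.
#' @return Integer matrix.
#' @export
read_label_tiff <- function(path) {
  arr <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  matrix(as.integer(round(arr * 65535)), nrow(arr), ncol(arr))
}
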