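# Reading and writing slides, masks and probability maps. Images are held
# in memory as numeric arrays h x w x 3 on the 0..255 scale; masks as
# integer matrices with labels 0..4.

#' Write a slide image to PNG or TIFF
#'
#' @param image Numeric array `h x w x 3`, values 0..255.
#' @param path Output path; the extension selects the format.
#' @export
write_slide_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3)
  x <- clip01(image / 255)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF images")
    tiff::writeTIFF(x, path)
  } else {
    png::writePNG(x, path)
  }
  invisible(path)
}

#' Read a slide image from PNG or TIFF
#'
#' @param path Image path.
#' @return Numeric array `h x w x 3`, values 0..255.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF images")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' Write a label mask as grayscale PNG (pixel value = label)
#'
#' @param mask Integer matrix with labels 0..4 (0 background, 1 NED tissue,
#'   2 LGD, 3 HGD, 4 IIN).
#' @param path Output PNG path.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0 & mask <= 255))
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#'
#' @param path PNG path.
#' @return Integer matrix of labels.
#' @export
read_label_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Write a probability map as a 16-bit-precision PNG
#'
#' Values are quantized to `round(p * 65535)` and stored across the two
#' channels of a gray+alpha PNG (high byte, low byte), so reading back loses
#' at most 1/131070 per pixel.
#'
#' @param map Numeric matrix with values in `[0, 1]`.
#' @param path Output PNG path.
#' @export
write_probability_map <- function(map, path) {
  stopifnot_prob(map, "map")
  q <- round(map * 65535)
  hi <- q %/% 256; lo <- q %% 256
  png::writePNG(array(c(hi, lo) / 255, dim = c(dim(map), 2)), path)
  invisible(path)
}

#' Read a probability map PNG written by [write_probability_map()]
#' @param path PNG path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_probability_map <- function(path) {
  x <- png::readPNG(path)
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 2)
  (round(x[, , 1] * 255) * 256 + round(x[, , 2] * 255)) / 65535
}

#' Read a dataset manifest CSV
#'
#' @param path CSV with columns `slide_id`, `image_path`, `mask_path`,
#'   `center`, `label` (as written by [generate_dataset()]).
#' @return A `data.frame`.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "image_path", "center", "label")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest is missing columns: ",
                         paste(miss, collapse = ", "))
  m
}
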