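# Image file I/O. PNG via the png package; TIFF via the tiff package when
# installed. Images are held as integer matrices of 8-bit levels.

#' Read an 8-bit grayscale image
#'
#' Color inputs are converted to luminance (0.299 R + 0.587 G + 0.114 B)
#' with a warning; an alpha channel is dropped.
#'
#' @param path PNG or TIFF file path.
#' @return Integer matrix with levels 0-255.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("png")) {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is required to read TIFF files")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc >= 3) {
      warning("color image converted to grayscale by luminance")
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  m <- floor(arr * 255 + 0.5)
  storage.mode(m) <- "integer"
  m
}

#' Write a gray image or mask as PNG
#'
#' @param image Integer matrix with levels in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
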