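#' Read and write core images and exclusion masks
#'
#' Cores are 8-bit RGB PNG (or TIFF when the tiff package is installed);
#' exclusion masks are single-channel PNG with 0 = keep, 255 = exclude.
#'
#' @param path File path; format chosen by extension (`.png` or
#'   `.tif`/`.tiff`).
#' @param img RGB array `height x width x 3` in `[0, 1]`.
#' @return `read_core_image()` returns the RGB array; writers return the path
#'   invisibly.
#' @name core_image_io
NULL

#' @rdname core_image_io
#' @export
write_core_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("The tiff package is required for TIFF output.",
            class = "mosaicquant_format_error")
    }
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}

#' @rdname core_image_io
#' @export
read_core_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("The tiff package is required for TIFF input.",
            class = "mosaicquant_format_error")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    abort("Expected an RGB image.", class = "mosaicquant_format_error")
  }
  img
}

#' @rdname core_image_io
#' @param mask Logical matrix (`TRUE` = exclude).
#' @export
write_exclusion_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname core_image_io
#' @export
read_exclusion_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}
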