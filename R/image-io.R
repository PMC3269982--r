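#' Grayscale image helpers
#'
#' Images are plain numeric matrices with intensities in \[0, 255\], row 1 at
#' the top edge and column 1 at the left edge (the usual raster layout).
#' `as_gray_image()` validates a matrix, `read_gray_image()` loads an 8-bit
#' single-channel PNG or TIFF, and `write_gray_image()` writes one.
#'
#' Multi-channel input is rejected with an explicit error rather than being
#' silently flattened: a panoramic radiograph scan should be grayscale, and a
#' colour file reaching this pipeline usually signals an export mistake.
#'
#' @param x A numeric matrix.
#' @param path File path; format chosen by extension (`.png`, `.tif`, `.tiff`).
#' @param image A grayscale image matrix.
#' @return A numeric matrix of intensities in \[0, 255\].
#' @examples
#' img <- as_gray_image(matrix(0:255, 16, 16))
#' f <- tempfile(fileext = ".png")
#' write_gray_image(img, f)
#' all.equal(read_gray_image(f), img)
#' @name gray_image
NULL

#' @rdname gray_image
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("a grayscale image must be a numeric matrix")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort("a grayscale image must have at least one row and one column")
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    abort("image intensities must be finite and within [0, 255]")
  }
  storage.mode(x) <- "double"
  x
}

#' @rdname gray_image
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image file not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format '.", ext, "' (expected PNG or TIFF)"))
  )
  if (length(dim(raw)) == 3L) {
    abort(paste0(
      "multi-channel image (", dim(raw)[3], " channels) rejected: ",
      "the pipeline requires 8-bit grayscale input"
    ))
  }
  as_gray_image(round(raw * 255))
}

#' @rdname gray_image
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  scaled <- image / 255
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
    abort(paste0("unsupported image format '.", ext, "'"))
  )
  invisible(path)
}

#' Rectangular region-of-interest box
#'
#' Describes one of the two manually placed cortical boxes (right and left
#' side of the mandible, below the mental foramen). Coordinates are 1-based
#' and inclusive at the start; `height`/`width` are extents in pixels. The
#' conventional box is 300 x 300 px on a 300 dpi scan.
#'
#' @param top_row,left_col 1-based offsets of the top-left corner.
#' @param height,width Box extents in pixels.
#' @param side `"right"` or `"left"`.
#' @return A list of class `mcw_roi_box`.
#' @examples
#' roi_box(101, 51, side = "right")
#' @export
roi_box <- function(top_row, left_col, height = 300L, width = 300L,
                    side = c("right", "left")) {
  side <- arg_match(side)
  for (v in list(top_row, left_col, height, width)) {
    if (length(v) != 1L || !is.numeric(v) || v != round(v)) {
      abort("roi_box coordinates and extents must be single whole numbers")
    }
  }
  if (top_row < 1L || left_col < 1L) abort("roi_box offsets must be >= 1")
  if (height < 1L || width < 1L) abort("roi_box extents must be positive")
  structure(
    list(
      top_row = as.integer(top_row), left_col = as.integer(left_col),
      height = as.integer(height), width = as.integer(width), side = side
    ),
    class = "mcw_roi_box"
  )
}

#' Crop a region of interest out of a radiograph
#'
#' Copies exactly `box$height` x `box$width` pixels starting at the box's
#' top-left corner. A box that extends past any image edge is an error naming
#' the offending edge, so misconfigured coordinates fail loudly instead of
#' shifting the measurement region.
#'
#' @param image A grayscale image matrix.
#' @param box An [roi_box()].
#' @return The cropped grayscale image.
#' @examples
#' img <- as_gray_image(matrix(runif(400 * 500, 0, 255), 400, 500))
#' dim(crop_roi(img, roi_box(50, 100, 300, 300)))
#' @export
crop_roi <- function(image, box) {
  image <- as_gray_image(image)
  if (!inherits(box, "mcw_roi_box")) abort("`box` must be created by roi_box()")
  bottom <- box$top_row + box$height - 1L
  right <- box$left_col + box$width - 1L
  if (box$top_row < 1L) abort("roi box exceeds the top edge of the image")
  if (box$left_col < 1L) abort("roi box exceeds the left edge of the image")
  if (bottom > nrow(image)) {
    abort(paste0(
      "roi box exceeds the bottom edge of the image (needs row ", bottom,
      ", image has ", nrow(image), ")"
    ))
  }
  if (right > ncol(image)) {
    abort(paste0(
      "roi box exceeds the right edge of the image (needs column ", right,
      ", image has ", ncol(image), ")"
    ))
  }
  image[box$top_row:bottom, box$left_col:right, drop = FALSE]
}
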