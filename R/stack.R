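#' Slice stacks
#'
#' A `slice_stack` is the unit every pipeline stage operates on: an ordered
#' sequence of same-shaped 2-D grayscale images with spacing metadata.  After
#' windowing, pixel values live on the 8-bit `[0, 255]` scale.
#'
#' @param images list of numeric matrices, all the same shape.
#' @param slice_indices 1-based positions of the slices in the original
#'   series; strictly increasing.  Defaults to `seq_along(images)`.
#' @param pixel_spacing in-plane (row, col) spacing in mm.
#' @param slice_thickness slice thickness in mm.
#' @return an object of class `slice_stack`.
#' @examples
#' s <- slice_stack(list(matrix(0, 8, 8), matrix(1, 8, 8)))
#' length(s)
#' @export
slice_stack <- function(images, slice_indices = seq_along(images),
                        pixel_spacing = c(1, 1), slice_thickness = 1) {
  stopifnot(is.list(images), length(images) >= 1L,
            all(vapply(images, is.matrix, logical(1))))
  shp <- dim(images[[1L]])
  if (!all(vapply(images, function(x) identical(dim(x), shp), logical(1))))
    stop("all slices must share one shape", call. = FALSE)
  slice_indices <- as.integer(slice_indices)
  if (length(slice_indices) != length(images) ||
      any(diff(slice_indices) <= 0L))
    stop("slice_indices must be strictly increasing, one per image",
         call. = FALSE)
  structure(
    list(images = images, slice_indices = slice_indices,
         pixel_spacing = as.numeric(pixel_spacing),
         slice_thickness = as.numeric(slice_thickness)),
    class = "slice_stack")
}

#' @export
length.slice_stack <- function(x) length(x$images)

#' @export
print.slice_stack <- function(x, ...) {
  shp <- dim(x$images[[1L]])
  cat(sprintf(
    "<slice_stack> %d slices of %d x %d px, spacing %.3g x %.3g mm, thickness %.3g mm\n",
    length(x$images), shp[1L], shp[2L],
    x$pixel_spacing[1L], x$pixel_spacing[2L], x$slice_thickness))
  invisible(x)
}

#' @export
`[.slice_stack` <- function(x, i) {
  slice_stack(x$images[i], x$slice_indices[i],
              x$pixel_spacing, x$slice_thickness)
}

#' Read a stack from a directory of PNGs or a multi-page TIFF
#'
#' PNG directories are read in lexicographic filename order.  Values are
#' rescaled from the readers' `[0, 1]` convention back to `[0, 255]`
#' (or `[0, 65535]` for 16-bit input when `bits = 16`).
#'
#' @param path a directory containing `.png` files, or a `.tif`/`.tiff` file.
#' @param bits bit depth the pixel values should be rescaled to (8 or 16).
#' @inheritParams slice_stack
#' @return a [slice_stack].
#' @export
read_stack <- function(path, bits = 8, pixel_spacing = c(1, 1),
                       slice_thickness = 1) {
  scale <- if (bits == 16) 65535 else 255
  to_gray <- function(a) {
    if (length(dim(a)) == 3L) a <- a[, , 1L]  # drop colour channels
    round(a * scale)
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no .png files in ", path, call. = FALSE)
    imgs <- lapply(files, function(f) to_gray(png::readPNG(f)))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    imgs <- lapply(pages, to_gray)
  } else stop("expected a PNG directory or a TIFF file", call. = FALSE)
  slice_stack(imgs, pixel_spacing = pixel_spacing,
              slice_thickness = slice_thickness)
}

#' Write a stack as PNGs or a multi-page TIFF
#'
#' @param stack a [slice_stack] (8-bit values).
#' @param path output directory (PNG mode) or `.tif`/`.tiff` filename.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  norm <- lapply(stack$images, function(m) pmin(pmax(m / 255, 0), 1))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(norm))
      png::writePNG(norm[[i]],
                    file.path(path, sprintf("slice_%04d.png",
                                            stack$slice_indices[i])))
  }
  invisible(path)
}
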