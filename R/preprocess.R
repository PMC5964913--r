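#' CT window transform to 8-bit
#'
#' Linear window of calibrated CT intensities (Hounsfield units when the
#' DICOM rescale slope/intercept has been applied): values at or below
#' `level - width/2` map to 0, values at or above `level + width/2` map to
#' 255, and the interval in between maps linearly, rounded half-up.  The
#' bone window used throughout is width 600, level 900.
#'
#' @param raw numeric matrix of calibrated intensities.
#' @param width window width (> 0), same units as `raw`.
#' @param level window level, same units as `raw`.
#' @return integer matrix with values in `[0, 255]`.
#' @examples
#' window_transform(matrix(c(600, 900, 1200), 1), width = 600, level = 900)
#' @export
window_transform <- function(raw, width = 600, level = 900) {
  stopifnot(is.matrix(raw), all(is.finite(raw)))
  if (width <= 0) stop("window width must be positive", call. = FALSE)
  lo <- level - width / 2
  hi <- level + width / 2
  f <- (raw - lo) * 255 / width
  f <- floor(f + 0.5)            # round half-up
  f[raw <= lo] <- 0
  f[raw >= hi] <- 255
  matrix(as.integer(f), nrow(raw), ncol(raw))
}

#' Largest-component body mask
#'
#' Binarizes a windowed slice (any non-zero pixel is foreground), applies a
#' 3x3 morphological closing then opening to detach thin artifacts (cables),
#' and keeps only the largest 8-connected component -- in a pelvic CT slice
#' that component is the patient's body, so the table and other off-body
#' structure drop out.
#'
#' @param gray 8-bit matrix (windowed slice).
#' @return logical matrix, `TRUE` on the body.
#' @export
body_mask <- function(gray) {
  stopifnot(is.matrix(gray))
  bin <- gray != 0
  if (!any(bin)) stop("cannot build a body mask from an all-zero image",
                      call. = FALSE)
  bin <- .binary_open3(.binary_close3(bin))
  if (!any(bin)) stop("no foreground left after morphological cleaning",
                      call. = FALSE)
  lab <- label_components(bin, 8L)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Mask a slice
#'
#' Pixel-wise product with a binary mask: off-mask pixels become exactly 0.
#'
#' @param gray numeric/integer matrix.
#' @param mask logical or 0/1 matrix of the same shape.
#' @return matrix of the same mode as `gray`.
#' @export
apply_mask <- function(gray, mask) {
  .check_same_shape(gray, mask)
  out <- gray * .as_binary(mask)
  if (is.integer(gray)) out <- matrix(as.integer(out), nrow(gray), ncol(gray))
  out
}

#' Crop a stack to the union bounding box of its masks
#'
#' One box is computed across the whole sequence (padded by `margin` pixels,
#' clamped to the frame) so that all slices keep an identical shape -- the
#' inter-slice difference and similarity measures require it.
#'
#' @param stack a [slice_stack].
#' @param masks list of binary masks, one per slice.
#' @param margin padding around the union box, in pixels.
#' @return the cropped [slice_stack]; the box is attached as attribute
#'   `crop_box` (`c(r1, r2, c1, c2)`).
#' @seealso [crop_to_box()] to apply the same box to other images.
#' @export
crop_stack <- function(stack, masks, margin = 2L) {
  stopifnot(inherits(stack, "slice_stack"), length(masks) == length(stack))
  any_mask <- Reduce(`|`, lapply(masks, .as_binary))
  if (!any(any_mask)) stop("all masks are empty; nothing to crop to",
                           call. = FALSE)
  rr <- range(which(rowSums(any_mask) > 0))
  cc <- range(which(colSums(any_mask) > 0))
  box <- c(max(1L, rr[1L] - margin), min(nrow(any_mask), rr[2L] + margin),
           max(1L, cc[1L] - margin), min(ncol(any_mask), cc[2L] + margin))
  out <- slice_stack(lapply(stack$images, crop_to_box, box = box),
                     stack$slice_indices, stack$pixel_spacing,
                     stack$slice_thickness)
  attr(out, "crop_box") <- as.integer(box)
  out
}

#' Apply a crop box to a single image
#'
#' @param img matrix.
#' @param box `c(r1, r2, c1, c2)` as produced by [crop_stack()].
#' @return the cropped matrix.
#' @export
crop_to_box <- function(img, box) {
  img[box[1L]:box[2L], box[3L]:box[4L], drop = FALSE]
}

#' Pre-process a raw CT stack into the pipeline's input stack
#'
#' Runs the full pre-processing chain: optional windowing to 8-bit, a
#' per-slice body mask, masking (which zeroes the table and other
#' artifacts), and a sequence-global crop.
#'
#' @param stack a [slice_stack] of raw (calibrated) or already 8-bit slices.
#' @param window `c(width, level)` to window with, or `NULL` if the stack is
#'   already 8-bit.
#' @param margin crop margin in pixels.
#' @return list with `stack` (the cropped, masked 8-bit [slice_stack]),
#'   `masks` (cropped body masks) and `crop_box`.
#' @export
preprocess_stack <- function(stack, window = c(600, 900), margin = 2L) {
  stopifnot(inherits(stack, "slice_stack"))
  imgs <- stack$images
  if (!is.null(window))
    imgs <- lapply(imgs, window_transform, width = window[1L],
                   level = window[2L])
  masks <- lapply(imgs, body_mask)
  imgs <- Map(apply_mask, imgs, masks)
  masked <- slice_stack(imgs, stack$slice_indices, stack$pixel_spacing,
                        stack$slice_thickness)
  cropped <- crop_stack(masked, masks, margin = margin)
  box <- attr(cropped, "crop_box")
  list(stack = cropped,
       masks = lapply(masks, crop_to_box, box = box),
       crop_box = box)
}
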