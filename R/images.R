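# Internal raster helpers shared across modules.

# Shifted copy of `img` where out[r, c] = img[r + dr, c + dc], zero-filled
# outside the frame.
.shift0 <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- img
  p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
}

# Shifted copy with replicate (nearest-edge) padding.
.shift_rep <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  k <- max(abs(dr), abs(dc), 1L)
  p <- img[c(rep(1L, k), 1:nr, rep(nr, k)), c(rep(1L, k), 1:nc, rep(nc, k))]
  p[((k + 1L):(nr + k)) + dr, ((k + 1L):(nc + k)) + dc]
}

# The eight neighbour fields of every pixel under the p9 p2 p3 / p8 p1 p4 /
# p7 p6 p5 layout (p2 = north, p4 = east, rows grow downward), zero padding.
.neighbour_fields <- function(img) {
  list(
    p2 = .shift0(img, -1L,  0L), p3 = .shift0(img, -1L,  1L),
    p4 = .shift0(img,  0L,  1L), p5 = .shift0(img,  1L,  1L),
    p6 = .shift0(img,  1L,  0L), p7 = .shift0(img,  1L, -1L),
    p8 = .shift0(img,  0L, -1L), p9 = .shift0(img, -1L, -1L)
  )
}

.binary_dilate3 <- function(mask) {
  acc <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc | .shift0(mask, dr, dc)
  }
  acc
}

.binary_erode3 <- function(mask) {
  # outside the frame counts as background, so erosion shrinks at borders
  acc <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc & .shift0(mask, dr, dc)
  }
  acc
}

.binary_close3 <- function(mask) .binary_erode3(.binary_dilate3(mask))
.binary_open3 <- function(mask) .binary_dilate3(.binary_erode3(mask))

#' Label connected components of a binary image
#'
#' Components are labelled `1..K` in column-major order of each component's
#' first-encountered pixel, which makes labelling deterministic.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  .label_components_cpp(matrix(as.logical(mask), nrow(mask), ncol(mask)),
                        as.integer(connectivity))
}

.as_binary <- function(mask) {
  stopifnot(is.matrix(mask))
  matrix(as.logical(mask), nrow(mask), ncol(mask))
}

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions", call. = FALSE)
}
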