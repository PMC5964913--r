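# Two-subiteration thinning.  Neighbour layout (rows grow downward):
#   p9 p2 p3
#   p8 p1 p4
#   p7 p6 p5
# i.e. p2 = north, p4 = east, p6 = south, p8 = west.

#' Count 0-to-1 transitions around a pixel
#'
#' Number of 0 -> 1 steps in the circular neighbour sequence
#' p2, p3, ..., p9, p2.
#'
#' @param nbhd 3x3 binary matrix; the centre is the pixel itself.
#' @return integer in `[0, 4]`.
#' @export
pixel_transitions <- function(nbhd) {
  p <- .nbhd_vector(nbhd)
  seqv <- c(p, p[1L])
  sum(seqv[-length(seqv)] == 0L & seqv[-1L] == 1L)
}

# 3x3 matrix -> c(p2, p3, p4, p5, p6, p7, p8, p9)
.nbhd_vector <- function(nbhd) {
  stopifnot(is.matrix(nbhd), identical(dim(nbhd), c(3L, 3L)))
  m <- (nbhd != 0) * 1L
  c(m[1L, 2L], m[1L, 3L], m[2L, 3L], m[3L, 3L],
    m[3L, 2L], m[3L, 1L], m[2L, 1L], m[1L, 1L])
}

#' Deletability of a foreground pixel in one thinning subiteration
#'
#' A foreground pixel is deletable when it has 2--6 foreground neighbours,
#' exactly one 0 -> 1 transition around it (so deletion cannot split the
#' region), and it lies on the east/south/northwest border (subiteration 1:
#' `p2 p4 p6 = 0` and `p4 p6 p8 = 0`) or the north/west/southeast border
#' (subiteration 2: `p2 p4 p8 = 0` and `p2 p6 p8 = 0`).
#'
#' @param nbhd 3x3 binary matrix with a foreground centre.
#' @param subiteration 1 or 2.
#' @return `TRUE` if the centre pixel may be deleted.
#' @export
pixel_deletable <- function(nbhd, subiteration = 1L) {
  stopifnot(subiteration %in% c(1L, 2L))
  if (nbhd[2L, 2L] == 0) stop("centre pixel is background", call. = FALSE)
  p <- .nbhd_vector(nbhd)
  n <- sum(p)
  if (n < 2L || n > 6L) return(FALSE)
  if (pixel_transitions(nbhd) != 1L) return(FALSE)
  p2 <- p[1L]; p4 <- p[3L]; p6 <- p[5L]; p8 <- p[7L]
  if (subiteration == 1L) p2 * p4 * p6 == 0L && p4 * p6 * p8 == 0L
  else                    p2 * p4 * p8 == 0L && p2 * p6 * p8 == 0L
}

# vectorized deletable map over a whole binary image (implicit zero padding)
.deletable_map <- function(img, subiteration) {
  nb <- .neighbour_fields(img)
  n <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
  ring <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
  s <- 0
  for (i in 1:8) s <- s + (ring[[i]] == 0) * (ring[[i + 1L]] == 1)
  base <- img == 1 & n >= 2 & n <= 6 & s == 1
  if (subiteration == 1L)
    base & (nb$p2 * nb$p4 * nb$p6 == 0) & (nb$p4 * nb$p6 * nb$p8 == 0)
  else
    base & (nb$p2 * nb$p4 * nb$p8 == 0) & (nb$p2 * nb$p6 * nb$p8 == 0)
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Repeats the two subiterations -- collect all deletable boundary pixels,
#' delete them simultaneously, then the same with the second border
#' condition -- until a full cycle deletes nothing.  Pixels outside the
#' frame count as background.  Note the classical quirk: an isolated 2x2
#' block is wholly deleted in one subiteration; [skeleton_markers()] guards
#' against the resulting empty skeleton.
#'
#' @param mask binary matrix.
#' @return integer 0/1 matrix: the skeleton, a subset of the input
#'   foreground and a fixed point of further thinning.
#' @examples
#' m <- matrix(0L, 7, 7); m[3:5, 2:6] <- 1L
#' thin_mask(m)
#' @export
thin_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  img <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    d1 <- .deletable_map(img, 1L)
    img[d1] <- 0L
    d2 <- .deletable_map(img, 2L)
    img[d2] <- 0L
    if (!any(d1) && !any(d2)) break
  }
  img
}
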