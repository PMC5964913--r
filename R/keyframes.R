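# Key-frame extraction: pixel-difference candidates over wavelet-masked
# "interesting images", then mutual-information and normalized-correlation
# filtering down to the target set.

#' Gaussian smoothing
#'
#' Separable Gaussian filter with the kernel truncated at `truncate * sigma`
#' and replicate padding at the borders.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels (> 0).
#' @param truncate kernel radius in units of sigma.
#' @return numeric matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma = 1, truncate = 4) {
  stopifnot(is.matrix(img), sigma > 0)
  radius <- max(1L, ceiling(truncate * sigma))
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  out <- matrix(0, nrow(img), ncol(img))
  for (d in seq_along(k)) out <- out + k[d] * .shift_rep(img, d - radius - 1L, 0L)
  res <- matrix(0, nrow(img), ncol(img))
  for (d in seq_along(k)) res <- res + k[d] * .shift_rep(out, 0L, d - radius - 1L)
  res
}

#' Wavelet approximation reconstruction
#'
#' Haar analysis with all detail bands zeroed and reconstruction from the
#' approximation band alone; at each level this replaces every 2x2 block by
#' its mean.  Odd-sized images are replicate-padded to even size and the
#' result is cropped back.
#'
#' @param img numeric matrix.
#' @param level decomposition depth (>= 1).
#' @param wavelet wavelet family; only `"haar"` is implemented.
#' @return numeric matrix of the same shape.
#' @export
wavelet_approx <- function(img, level = 1L, wavelet = "haar") {
  stopifnot(is.matrix(img), level >= 1L)
  if (!identical(wavelet, "haar"))
    stop("only the 'haar' wavelet is implemented", call. = FALSE)
  one <- function(x) {
    nr <- nrow(x); nc <- ncol(x)
    if (nr %% 2L) x <- x[c(seq_len(nr), nr), , drop = FALSE]
    if (nc %% 2L) x <- x[, c(seq_len(nc), nc), drop = FALSE]
    a <- (x[c(TRUE, FALSE), c(TRUE, FALSE), drop = FALSE] +
          x[c(FALSE, TRUE), c(TRUE, FALSE), drop = FALSE] +
          x[c(TRUE, FALSE), c(FALSE, TRUE), drop = FALSE] +
          x[c(FALSE, TRUE), c(FALSE, TRUE), drop = FALSE]) / 4
    up <- a[rep(seq_len(nrow(a)), each = 2L), rep(seq_len(ncol(a)), each = 2L),
            drop = FALSE]
    up[seq_len(nr), seq_len(nc), drop = FALSE]
  }
  for (l in seq_len(level)) img <- one(img)
  img
}

#' Build the "interesting image" of a slice
#'
#' Gaussian-smooths the slice, reconstructs it from the wavelet
#' approximation band, thresholds the reconstruction at the mean of its
#' non-zero pixels (the ROI threshold), and returns the smoothed slice
#' masked to the strictly-above-threshold region.  The result isolates the
#' approximate bone region so that inter-slice differences respond to bone
#' topology rather than soft tissue or noise.
#'
#' @param slice 8-bit matrix (a pre-processed slice).
#' @param sigma Gaussian sigma in pixels.
#' @param wavelet wavelet family (only `"haar"`).
#' @param level wavelet decomposition depth.
#' @return numeric matrix; attribute `roi_threshold` carries the threshold.
#' @export
interesting_image <- function(slice, sigma = 1, wavelet = "haar", level = 1L) {
  stopifnot(is.matrix(slice))
  smoothed <- gaussian_blur(slice, sigma = sigma)
  recon <- wavelet_approx(smoothed, level = level, wavelet = wavelet)
  nz <- recon != 0
  if (!any(nz)) stop("all-zero slice: ROI threshold is undefined", call. = FALSE)
  t1 <- sum(recon) / sum(nz)     # mean over the non-zero area
  out <- smoothed * (recon > t1) # strict inequality: ties fall outside
  attr(out, "roi_threshold") <- t1
  out
}

#' Summed absolute pixel difference between two images
#'
#' The scalar dissimilarity used for candidate selection: the sum over all
#' pixels of the absolute difference.  Larger values mean lower similarity.
#'
#' @param a,b same-shaped numeric matrices.
#' @return a non-negative scalar.
#' @export
pixel_diff <- function(a, b) {
  .check_same_shape(a, b)
  sum(abs(b - a))
}

#' Candidate key frames from the adjacent-difference series
#'
#' Computes `Dif[i] = pixel_diff(y[i], y[i+1])` over the interesting images,
#' sets the threshold at `0.7 * mean(Dif)` (deliberately below the mean so
#' key frames are not missed), and adds slice `i + 1` to the candidate set
#' whenever `Dif[i]` strictly exceeds it.  Slice 1 is always a candidate:
#' the earliest slices need a key frame to match against.
#'
#' @param interesting list of same-shaped matrices (interesting images in
#'   spatial order).
#' @return list with `dif` (length `L - 1`), `T2`, and `candidate`
#'   (strictly increasing slice indices, starting at 1).
#' @export
candidate_set <- function(interesting) {
  L <- length(interesting)
  if (L < 2L) stop("need at least 2 slices to form a difference series",
                   call. = FALSE)
  dif <- vapply(seq_len(L - 1L), function(i)
    pixel_diff(interesting[[i]], interesting[[i + 1L]]), numeric(1))
  t2 <- 0.7 * mean(dif)
  cand <- sort(unique(c(1L, which(dif > t2) + 1L)))
  list(dif = dif, T2 = t2, candidate = as.integer(cand))
}

#' Mutual information of two 8-bit images (bits)
#'
#' Histogram estimate on the 256 x 256 joint gray-level grid; base-2
#' logarithm, `0 log 0` terms dropped.  High MI means similar gray
#' structure.
#'
#' @param a,b same-shaped matrices with values in `[0, 255]`.
#' @return a non-negative scalar, in bits.
#' @export
mutual_information <- function(a, b) {
  .check_same_shape(a, b)
  stopifnot(length(a) >= 1L)
  ai <- pmin(pmax(as.integer(round(a)), 0L), 255L)
  bi <- pmin(pmax(as.integer(round(b)), 0L), 255L)
  joint <- tabulate(ai * 256L + bi + 1L, nbins = 65536L)
  n <- length(ai)
  p <- joint[joint > 0L] / n
  pa <- tabulate(ai + 1L, nbins = 256L) / n
  pb <- tabulate(bi + 1L, nbins = 256L) / n
  idx <- which(joint > 0L) - 1L
  sum(p * log2(p / (pa[idx %/% 256L + 1L] * pb[idx %% 256L + 1L])))
}

#' Normalized correlation coefficient of two images
#'
#' Pearson correlation of the pixel values; 1 for identical (up to affine
#' gain) images, -1 for inverted ones.
#'
#' @param a,b same-shaped numeric matrices, both non-constant.
#' @return a scalar in `[-1, 1]`.
#' @export
ncc <- function(a, b) {
  .check_same_shape(a, b)
  if (stats::var(as.numeric(a)) == 0 || stats::var(as.numeric(b)) == 0)
    stop("normalized correlation is undefined for a constant image",
         call. = FALSE)
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Filter candidates down to the target key-frame set
#'
#' Two single-sweep stages over adjacent *candidate* pairs, computed on the
#' pre-processed slices (not the interesting images).  Stage 1: mutual
#' information between each adjacent candidate pair; the threshold is the
#' mean of those values and the later frame of a pair survives iff its MI is
#' at or below it (dissimilar pairs mark a topology change).  Stage 2: the
#' same rule on the normalized correlation coefficient over the surviving
#' (intermediate) set, removing redundant frames.  Slice 1 is retained
#' throughout.  Thresholds are fixed from the initial pass of each stage.
#'
#' @param stack a [slice_stack] of pre-processed slices.
#' @param candidates strictly increasing candidate slice positions
#'   (1-based within the stack).
#' @return an object of class `keyframe_sets`: candidate / intermediate /
#'   target index vectors, the thresholds `T2` (if known), `T3`, `T4`, and
#'   the MI / NCC series.
#' @export
select_target <- function(stack, candidates) {
  stopifnot(inherits(stack, "slice_stack"), length(candidates) >= 1L)
  candidates <- as.integer(candidates)
  imgs <- stack$images
  res <- list(candidate = candidates, T3 = NA_real_, T4 = NA_real_,
              mi = numeric(0), ncc = numeric(0))
  if (length(candidates) < 2L) {
    res$intermediate <- candidates
    res$target <- candidates
    class(res) <- "keyframe_sets"
    return(res)
  }
  mi <- vapply(seq_len(length(candidates) - 1L), function(i)
    mutual_information(imgs[[candidates[i]]], imgs[[candidates[i + 1L]]]),
    numeric(1))
  t3 <- mean(mi)
  inter <- sort(unique(c(candidates[1L], candidates[which(mi <= t3) + 1L])))
  res$mi <- mi; res$T3 <- t3; res$intermediate <- inter
  if (length(inter) < 2L) {
    res$target <- inter
    class(res) <- "keyframe_sets"
    return(res)
  }
  rr <- vapply(seq_len(length(inter) - 1L), function(j)
    ncc(imgs[[inter[j]]], imgs[[inter[j + 1L]]]), numeric(1))
  t4 <- mean(rr)
  res$ncc <- rr; res$T4 <- t4
  res$target <- sort(unique(c(inter[1L], inter[which(rr <= t4) + 1L])))
  class(res) <- "keyframe_sets"
  res
}

#' Extract key frames from a pre-processed stack
#'
#' Runs the whole two-stage procedure: interesting images, the
#' pixel-difference candidate set, then MI and NCC filtering to the target
#' set.
#'
#' @inheritParams interesting_image
#' @param stack a [slice_stack] of pre-processed 8-bit slices (length >= 2).
#' @return a `keyframe_sets` object (see [select_target()]) with the
#'   difference series and `T2` attached.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_slices = 12, seed = 3,
#'   topology_schedule = list(c(1, 3), c(7, 4))))
#' kf <- extract_keyframes(ph$stack)
#' kf$target
#' @export
extract_keyframes <- function(stack, sigma = 1, wavelet = "haar", level = 1L) {
  stopifnot(inherits(stack, "slice_stack"))
  ii <- lapply(stack$images, interesting_image, sigma = sigma,
               wavelet = wavelet, level = level)
  cs <- candidate_set(ii)
  kf <- select_target(stack, cs$candidate)
  kf$dif <- cs$dif
  kf$T2 <- cs$T2
  kf
}

#' @export
print.keyframe_sets <- function(x, ...) {
  cat(sprintf("<keyframe_sets> %d candidate -> %d intermediate -> %d target\n",
              length(x$candidate), length(x$intermediate), length(x$target)))
  cat("  target:", paste(x$target, collapse = ", "), "\n")
  if (!is.null(x$T2)) cat(sprintf("  T2 = %.4g", x$T2))
  cat(sprintf("  T3 = %.4g  T4 = %.4g\n", x$T3, x$T4))
  invisible(x)
}

#' Write key-frame sets to JSON (indices and thresholds) and CSV (series)
#'
#' @param kf a `keyframe_sets` object.
#' @param json_path output JSON path.
#' @param csv_path optional CSV path for the Dif series.
#' @return `json_path`, invisibly.
#' @export
write_keyframes <- function(kf, json_path, csv_path = NULL) {
  stopifnot(inherits(kf, "keyframe_sets"))
  jsonlite::write_json(
    list(candidate = kf$candidate, intermediate = kf$intermediate,
         target = kf$target, T2 = kf$T2, T3 = kf$T3, T4 = kf$T4),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(csv_path) && !is.null(kf$dif)) {
    utils::write.csv(data.frame(pair = seq_along(kf$dif), dif = kf$dif),
                     csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
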