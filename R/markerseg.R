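# Marker-controlled watershed of a single slice: Sobel gradient, skeleton
# markers from a reference foreground mask, minima imposition, flooding.

#' Sobel gradient of a slice
#'
#' Convolves with the 3x3 Sobel templates under the p9 p2 p3 / p8 p1 p4 /
#' p7 p6 p5 neighbour layout: `Gx = p9 + 2 p2 + p3 - (p7 + 2 p6 + p5)`
#' (row above minus row below) and `Gy = p9 + 2 p8 + p7 - (p3 + 2 p4 + p5)`
#' (column left minus column right), with replicate padding at the borders.
#'
#' @param gray numeric matrix, at least 3x3.
#' @return an object of class `gradient_image`: list of `gx`, `gy`, and
#'   `magnitude` (their pixel-wise L2 norm).
#' @export
sobel_gradient <- function(gray) {
  stopifnot(is.matrix(gray))
  if (nrow(gray) < 3L || ncol(gray) < 3L)
    stop("image must be at least 3x3", call. = FALSE)
  g <- gray * 1.0
  p2 <- .shift_rep(g, -1L,  0L); p3 <- .shift_rep(g, -1L,  1L)
  p4 <- .shift_rep(g,  0L,  1L); p5 <- .shift_rep(g,  1L,  1L)
  p6 <- .shift_rep(g,  1L,  0L); p7 <- .shift_rep(g,  1L, -1L)
  p8 <- .shift_rep(g,  0L, -1L); p9 <- .shift_rep(g, -1L, -1L)
  gx <- p9 + 2 * p2 + p3 - (p7 + 2 * p6 + p5)
  gy <- p9 + 2 * p8 + p7 - (p3 + 2 * p4 + p5)
  structure(list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2)),
            class = "gradient_image")
}

#' @export
print.gradient_image <- function(x, ...) {
  cat(sprintf("<gradient_image> %d x %d, |grad| in [%.3g, %.3g]\n",
              nrow(x$magnitude), ncol(x$magnitude),
              min(x$magnitude), max(x$magnitude)))
  invisible(x)
}

.new_marker_image <- function(labels, background_label) {
  structure(labels, class = "marker_image",
            background_label = as.integer(background_label))
}

#' Skeleton markers from a reference foreground mask
#'
#' Thins the foreground mask and its complement to one-pixel skeletons.
#' Each 8-connected component of the foreground skeleton becomes one marker
#' label (`1..K`); the whole background skeleton gets the single label
#' `K + 1`.  A foreground component whose skeleton vanished entirely (the
#' isolated-2x2 thinning quirk) is re-seeded with a single pixel at its
#' centroid (snapped to the nearest component pixel).
#'
#' @param foreground_mask binary matrix, neither empty nor full-frame.
#' @return an object of class `marker_image`: an integer label matrix with
#'   attribute `background_label = K + 1`.
#' @export
skeleton_markers <- function(foreground_mask) {
  fg <- .as_binary(foreground_mask)
  if (!any(fg)) stop("foreground mask is empty", call. = FALSE)
  if (all(fg)) stop("foreground mask covers the whole frame", call. = FALSE)
  skel_fg <- thin_mask(fg) == 1L
  comps <- label_components(fg, 8L)
  for (lab in seq_len(max(comps))) {
    inside <- comps == lab
    if (!any(skel_fg & inside)) {
      idx <- which(inside, arr.ind = TRUE)
      cen <- colMeans(idx)
      d2 <- (idx[, 1L] - cen[1L])^2 + (idx[, 2L] - cen[2L])^2
      pick <- idx[which.min(d2), , drop = FALSE]
      skel_fg[pick] <- TRUE
    }
  }
  labels <- label_components(skel_fg, 8L)
  k <- max(labels)
  skel_bg <- thin_mask(!fg) == 1L
  if (any(skel_bg & skel_fg))
    skel_bg <- skel_bg & !skel_fg  # cannot happen for disjoint sets; guard
  labels[skel_bg] <- k + 1L
  .new_marker_image(labels, k + 1L)
}

#' @export
print.marker_image <- function(x, ...) {
  bg <- attr(x, "background_label")
  cat(sprintf("<marker_image> %d foreground label(s) + background label %d, %d marker px\n",
              bg - 1L, bg, sum(x > 0L)))
  invisible(x)
}

#' Impose markers as the only regional minima of a surface
#'
#' Marker pixels are forced strictly below the surface's global minimum and
#' every other regional minimum is removed by morphological reconstruction
#' by erosion (8-connected) of `min(surface + 1, marker surface)` from the
#' marker surface.  The uniform +1 offset only separates non-marker values
#' from the marker plateau; it does not reorder the surface, so watershed
#' flooding is unaffected.
#'
#' @param grad a `gradient_image` or a plain numeric matrix (the surface).
#' @param markers a `marker_image` (or any matrix with positive labels on
#'   marker pixels) of the same shape.
#' @return numeric matrix whose regional minima are exactly the marker
#'   components.
#' @export
impose_minima <- function(grad, markers) {
  surface <- if (inherits(grad, "gradient_image")) grad$magnitude else grad
  stopifnot(is.matrix(surface))
  .check_same_shape(surface, markers)
  mk <- markers > 0L
  if (!any(mk)) stop("no marker pixels", call. = FALSE)
  lo <- min(surface) - 1
  hi <- max(surface) + 2
  marker_surface <- matrix(hi, nrow(surface), ncol(surface))
  marker_surface[mk] <- lo
  mask <- pmin(surface + 1, marker_surface)
  .reconstruct_erode_cpp(marker_surface, mask)
}

#' Marker-controlled watershed transform
#'
#' Priority-floods the surface from the marker components in increasing
#' surface order (8-connected), popping FIFO among equal priorities with
#' the queue seeded in column-major scan order.  When a pixel is reached by
#' claims from more than one label, the unique *foreground* claimant wins
#' (so on the two-pixel-wide gradient band of a discrete step edge the
#' watershed line falls on the background side instead of eroding thin bone
#' rims); a pixel contested by two different foreground labels becomes a
#' ridge pixel (label 0), which does not propagate.  Marker pixels keep
#' their labels.  Regions carrying foreground labels (`1..K`) form the bone
#' mask, and a clockwise 8-connected contour is traced around each of them
#' starting at its topmost-then-leftmost boundary pixel.
#'
#' @param surface numeric matrix, normally the minima-imposed gradient
#'   magnitude from [impose_minima()].
#' @param markers a `marker_image` with at least 2 labels.
#' @return an object of class `segmentation_result`: `labels` (ridge = 0),
#'   `bone_mask`, and `contours` (one coordinate matrix per foreground
#'   label).
#' @export
watershed_transform <- function(surface, markers) {
  stopifnot(is.matrix(surface))
  .check_same_shape(surface, markers)
  labs <- unique(as.integer(markers[markers > 0L]))
  if (length(labs) < 2L) stop("need at least 2 marker labels", call. = FALSE)
  bg <- attr(markers, "background_label")
  if (is.null(bg)) bg <- max(labs)
  lab <- .watershed_flood_cpp(surface,
                              matrix(as.integer(markers), nrow(markers),
                                     ncol(markers)), as.integer(bg))
  fg_labels <- setdiff(sort(labs), bg)
  bone <- matrix(lab %in% fg_labels, nrow(lab), ncol(lab))
  contours <- lapply(fg_labels, function(l) trace_contours(lab == l))
  names(contours) <- as.character(fg_labels)
  structure(list(labels = lab, bone_mask = bone, contours = contours,
                 background_label = as.integer(bg)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d x %d, %d bone region(s), %d bone px, %d ridge px\n",
              nrow(x$labels), ncol(x$labels), length(x$contours),
              sum(x$bone_mask), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
plot.segmentation_result <- function(x, ...) {
  graphics::image(t(x$labels[nrow(x$labels):1, ]), axes = FALSE,
                  col = grDevices::hcl.colors(max(x$labels) + 1L, "viridis"),
                  main = "watershed labels", ...)
  invisible(x)
}

#' Trace the boundary contours of a binary region
#'
#' Moore-neighbour tracing: for each 8-connected component, the contour is
#' the ordered list of boundary pixel centres, clockwise (in image
#' coordinates, rows growing downward), starting at the
#' topmost-then-leftmost pixel.  Multi-component masks yield the
#' concatenation of the per-component contours.
#'
#' @param mask binary matrix.
#' @return a numeric matrix with columns `row`, `col` (0 rows if the mask
#'   is empty).
#' @export
trace_contours <- function(mask) {
  m <- .as_binary(mask)
  comps <- label_components(m, 8L)
  out <- lapply(seq_len(max(comps)), function(l) .trace_one(comps == l))
  if (length(out) == 0L)
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  do.call(rbind, out)
}

# clockwise Moore neighbourhood, starting north: N NE E SE S SW W NW
.MOORE <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                 ncol = 2L, byrow = TRUE)

.trace_one <- function(comp) {
  idx <- which(comp, arr.ind = TRUE)
  start <- idx[order(idx[, 1L], idx[, 2L])[1L], ]  # topmost, then leftmost
  if (nrow(idx) == 1L)
    return(matrix(as.numeric(start), 1L, 2L,
                  dimnames = list(NULL, c("row", "col"))))
  inside <- function(r, c) r >= 1L && r <= nrow(comp) && c >= 1L &&
    c <= ncol(comp) && comp[r, c]
  # entered the start heading east; the backtrack direction is west (index 7)
  path <- list()
  cur <- start
  dir <- 7L  # Moore index of the neighbour we came from (west of start)
  first_move <- NULL
  repeat {
    path[[length(path) + 1L]] <- cur
    # scan clockwise starting just after the backtrack direction
    found <- FALSE
    for (s in 1:8) {
      d <- (dir + s - 1L) %% 8L + 1L
      r <- cur[1L] + .MOORE[d, 1L]; c <- cur[2L] + .MOORE[d, 2L]
      if (inside(r, c)) {
        if (is.null(first_move)) first_move <- d
        else if (all(cur == start) && d == first_move) {
          found <- FALSE
          break  # re-entered the start the same way: contour closed
        }
        cur <- c(r, c)
        dir <- (d + 3L) %% 8L + 1L  # came from the opposite direction
        found <- TRUE
        break
      }
    }
    if (!found) break
    if (all(cur == start)) {
      # will terminate on the next pass when the first move repeats
      if (length(path) > 4L * sum(comp)) break  # safety net
    }
    if (length(path) > 8L * sum(comp)) break    # safety net
  }
  coords <- do.call(rbind, path)
  # drop a duplicated closing start pixel, keep interior revisits (spurs)
  if (nrow(coords) > 1L && all(coords[nrow(coords), ] == coords[1L, ]))
    coords <- coords[-nrow(coords), , drop = FALSE]
  colnames(coords) <- c("row", "col")
  coords * 1.0
}

#' Edit a marker image
#'
#' Applies removals then additions, and relabels so the `marker_image`
#' invariants hold again: foreground labels are the 8-connected components
#' of the edited foreground marker set, numbered `1..K` in scan order, and
#' the background skeleton keeps the single label `K + 1`.  This is the
#' programmatic counterpart of an expert adding or removing marker points
#' on a key frame.
#'
#' @param markers a `marker_image`.
#' @param add matrix/data.frame with columns `row`, `col`, `label`
#'   (an existing foreground label, the background label, or a new label);
#'   `NULL` for none.
#' @param remove matrix/data.frame with columns `row`, `col`; `NULL` for
#'   none.  Removing a non-marker pixel is an error.
#' @return the edited, relabelled `marker_image`.
#' @export
edit_markers <- function(markers, add = NULL, remove = NULL) {
  stopifnot(inherits(markers, "marker_image"))
  lab <- matrix(as.integer(markers), nrow(markers), ncol(markers))
  bg <- attr(markers, "background_label")
  if (!is.null(remove)) {
    remove <- as.matrix(remove)
    for (i in seq_len(nrow(remove))) {
      r <- remove[i, 1L]; c <- remove[i, 2L]
      if (lab[r, c] == 0L)
        stop(sprintf("no marker at (%d, %d) to remove", r, c), call. = FALSE)
      lab[r, c] <- 0L
    }
  }
  if (!is.null(add)) {
    add <- as.matrix(add)
    for (i in seq_len(nrow(add))) {
      r <- add[i, 1L]; c <- add[i, 2L]; l <- add[i, 3L]
      if (lab[r, c] != 0L && lab[r, c] != l)
        stop(sprintf("pixel (%d, %d) already carries label %d", r, c,
                     lab[r, c]), call. = FALSE)
      lab[r, c] <- l
    }
  }
  fg <- lab > 0L & lab != bg
  if (!any(fg)) stop("edits removed every foreground marker", call. = FALSE)
  relab <- label_components(fg, 8L)
  k <- max(relab)
  relab[lab == bg] <- k + 1L
  .new_marker_image(relab, k + 1L)
}
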