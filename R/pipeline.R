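# Orchestration: preprocess -> key frames -> (expert masks on key frames)
# -> propagate segmentation to every slice via NCC key-frame matching.

#' Automatic initial bone mask for a key frame
#'
#' Thresholds the slice at the mean of its non-zero pixels (the same ROI
#' rule the interesting image uses), keeping the bright bone region.  It
#' seeds the interactive marking loop; experts then edit the derived
#' markers.
#'
#' @param slice 8-bit matrix.
#' @return logical matrix.
#' @export
init_keyframe_mask <- function(slice) {
  stopifnot(is.matrix(slice))
  nz <- slice != 0
  if (!any(nz)) stop("all-zero slice", call. = FALSE)
  t1 <- sum(slice) / sum(nz)
  slice > t1
}

#' Segment one key frame from a bone mask, with optional marker edits
#'
#' Derives skeleton markers from the mask, applies the expert's point edits,
#' imposes the markers on the slice's Sobel gradient magnitude and floods.
#' The returned bone mask is therefore gradient-aligned rather than the raw
#' input mask.
#'
#' @param slice 8-bit matrix.
#' @param mask binary bone mask for this slice (e.g. [init_keyframe_mask()]
#'   output or an expert's mask).
#' @param add,remove marker point edits, see [edit_markers()].
#' @return a `segmentation_result`.
#' @export
segment_keyframe <- function(slice, mask, add = NULL, remove = NULL) {
  markers <- skeleton_markers(mask)
  if (!is.null(add) || !is.null(remove))
    markers <- edit_markers(markers, add = add, remove = remove)
  surface <- impose_minima(sobel_gradient(slice), markers)
  watershed_transform(surface, markers)
}

#' Match a slice to its key frame
#'
#' Returns the key frame whose pre-processed image has maximal normalized
#' correlation with the slice, searching the whole target set.  Ties are
#' broken by the smallest absolute slice-index distance, then by the
#' smaller index.  Key frames whose NCC is undefined (constant image pair)
#' are skipped; it is an error if none remains.
#'
#' @param slice_index position of the slice within `stack`.
#' @param stack a [slice_stack].
#' @param keyframe_indices positions of the key frames within `stack`.
#' @return the matched key-frame index.
#' @export
match_keyframe <- function(slice_index, stack, keyframe_indices) {
  stopifnot(inherits(stack, "slice_stack"), length(keyframe_indices) >= 1L)
  slice <- stack$images[[slice_index]]
  r <- vapply(keyframe_indices, function(k) {
    tryCatch(ncc(slice, stack$images[[k]]), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(r)))
    stop("normalized correlation undefined against every key frame",
         call. = FALSE)
  best <- which(r == max(r, na.rm = TRUE))
  if (length(best) > 1L) {
    d <- abs(keyframe_indices[best] - slice_index)
    best <- best[d == min(d)]
    best <- best[which.min(keyframe_indices[best])]
  }
  as.integer(keyframe_indices[best[1L]])
}

#' Segment every slice of a stack from key-frame bone masks
#'
#' For each slice: match the key frame by maximal NCC, thin the matched
#' frame's bone mask (foreground) and its complement (background) into
#' skeleton markers, impose them on the slice's Sobel gradient magnitude,
#' and flood.  Key-frame slices are themselves re-segmented through the
#' watershed so their contours are gradient-aligned too.
#'
#' @param stack a [slice_stack] of pre-processed slices.
#' @param keyframe_masks named list of binary bone masks; names are the
#'   key-frame positions within `stack` (e.g. `"1"`, `"14"`).
#' @return an object of class `ct_segmentation`: per-slice
#'   `segmentation_result`s, the matched key frame of every slice, and the
#'   per-slice bone masks.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_slices = 6, seed = 2,
#'   topology_schedule = list(c(1, 3))))
#' seg <- segment_sequence(ph$stack, stats::setNames(ph$truth_masks[1], "1"))
#' summary(seg)
#' @export
segment_sequence <- function(stack, keyframe_masks) {
  stopifnot(inherits(stack, "slice_stack"))
  if (length(keyframe_masks) == 0L)
    stop("no key-frame masks supplied", call. = FALSE)
  kf_idx <- as.integer(names(keyframe_masks))
  if (any(is.na(kf_idx)))
    stop("keyframe_masks must be named by slice position", call. = FALSE)
  markers_by_kf <- lapply(keyframe_masks, skeleton_markers)
  matched <- integer(length(stack))
  results <- vector("list", length(stack))
  for (s in seq_len(length(stack))) {
    k <- if (s %in% kf_idx) s else match_keyframe(s, stack, kf_idx)
    matched[s] <- k
    markers <- markers_by_kf[[which(kf_idx == k)]]
    surface <- impose_minima(sobel_gradient(stack$images[[s]]), markers)
    results[[s]] <- watershed_transform(surface, markers)
  }
  structure(
    list(results = results, matched_keyframe = matched,
         keyframe_indices = kf_idx,
         bone_masks = lapply(results, `[[`, "bone_mask")),
    class = "ct_segmentation")
}

#' Run the whole pipeline on a pre-processed stack
#'
#' Extracts the target key-frame set, obtains a bone mask for every key
#' frame (supplied expert masks, or the automatic threshold mask refined
#' through the key-frame watershed), and propagates the segmentation to all
#' slices.
#'
#' @param stack a [slice_stack] of pre-processed 8-bit slices.
#' @param expert_masks optional named list of binary masks overriding the
#'   automatic key-frame marking; names are slice positions.
#' @param edits optional named list of per-key-frame marker edits, each a
#'   list with elements `add` / `remove` (see [edit_markers()]).
#' @param sigma,level interesting-image parameters, see
#'   [extract_keyframes()].
#' @return a `ct_segmentation` (see [segment_sequence()]) with the
#'   `keyframe_sets` attached as `$keyframes`.
#' @export
segment_ct <- function(stack, expert_masks = NULL, edits = NULL,
                       sigma = 1, level = 1L) {
  kf <- extract_keyframes(stack, sigma = sigma, level = level)
  masks <- list()
  for (k in kf$target) {
    key <- as.character(k)
    if (!is.null(expert_masks) && key %in% names(expert_masks)) {
      masks[[key]] <- .as_binary(expert_masks[[key]])
    } else {
      ed <- if (!is.null(edits)) edits[[key]] else NULL
      seg <- segment_keyframe(stack$images[[k]],
                              init_keyframe_mask(stack$images[[k]]),
                              add = ed$add, remove = ed$remove)
      masks[[key]] <- seg$bone_mask
    }
  }
  out <- segment_sequence(stack, masks)
  out$keyframes <- kf
  out
}

#' @export
print.ct_segmentation <- function(x, ...) {
  cat(sprintf("<ct_segmentation> %d slices, %d key frame(s) at {%s}\n",
              length(x$results), length(x$keyframe_indices),
              paste(x$keyframe_indices, collapse = ",")))
  invisible(x)
}

#' @export
summary.ct_segmentation <- function(object, ...) {
  px <- vapply(object$bone_masks, sum, numeric(1))
  cat(sprintf("ct_segmentation of %d slices\n", length(object$results)))
  cat(sprintf("  key frames: %s\n",
              paste(object$keyframe_indices, collapse = ", ")))
  cat(sprintf("  bone pixels per slice: min %d, median %g, max %d\n",
              min(px), stats::median(px), max(px)))
  invisible(object)
}

#' @export
plot.ct_segmentation <- function(x, slice = 1L, ...) {
  plot(x$results[[slice]], ...)
  invisible(x)
}
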