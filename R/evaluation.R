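# Segmentation accuracy: overlap against the expert/truth area, directed
# mean contour deviation, and the accurate / fair / unacceptable classes.

#' Overlapping area of a predicted mask against the truth
#'
#' `O = |pred intersect truth| / |truth| x 100`, i.e. the fraction of the
#' expert (ground-truth) area the prediction recovers, as a percentage.
#'
#' @param pred_mask,truth_mask same-shaped binary matrices; the truth mask
#'   must be non-empty.
#' @return a percentage (can exceed 0--100 only in the degenerate sense of
#'   never being negative; a perfect prediction gives 100).
#' @export
overlap_area <- function(pred_mask, truth_mask) {
  .check_same_shape(pred_mask, truth_mask)
  p <- .as_binary(pred_mask); t <- .as_binary(truth_mask)
  if (!any(t)) stop("truth mask is empty", call. = FALSE)
  100 * sum(p & t) / sum(t)
}

#' Directed mean deviation distance between two contours
#'
#' For each of the `K` points of the predicted contour, the Euclidean
#' distance to the nearest point of the reference contour; the mean of
#' those `K` distances, in pixels.  Directed (prediction to reference), not
#' symmetrized.
#'
#' @param pred_contour,truth_contour non-empty numeric matrices with
#'   columns `row`, `col`.
#' @return mean deviation in pixels.
#' @export
mean_deviation <- function(pred_contour, truth_contour) {
  p <- as.matrix(pred_contour); t <- as.matrix(truth_contour)
  if (nrow(p) == 0L || nrow(t) == 0L)
    stop("contours must be non-empty", call. = FALSE)
  d2 <- outer(p[, 1L], t[, 1L], `-`)^2 + outer(p[, 2L], t[, 2L], `-`)^2
  mean(sqrt(apply(d2, 1L, min)))
}

#' Classify an overlap percentage
#'
#' `accurate` above 90, `fair` in the inclusive 80--90 band, `unacceptable`
#' below 80.
#'
#' @param O overlap percentage(s).
#' @return character vector of classes.
#' @export
classify_overlap <- function(O) {
  stopifnot(all(O >= 0))
  ifelse(O > 90, "accurate", ifelse(O >= 80, "fair", "unacceptable"))
}

#' Evaluate a segmentation against ground truth
#'
#' Per-slice overlap `O`, directed mean contour deviation `Mad` (contours
#' traced as 8-connected boundary pixel centres), and class.
#'
#' @param pred_masks list of predicted binary masks (or a
#'   `ct_segmentation`, whose `bone_masks` are used).
#' @param truth_masks list of ground-truth binary masks, same length.
#' @return an object of classes `eval_report` and `data.frame` with columns
#'   `slice`, `O`, `Mad`, `klass`.  Slices with an empty truth mask get
#'   `NA` metrics.
#' @export
evaluate_segmentation <- function(pred_masks, truth_masks) {
  if (inherits(pred_masks, "ct_segmentation"))
    pred_masks <- pred_masks$bone_masks
  stopifnot(length(pred_masks) == length(truth_masks))
  n <- length(pred_masks)
  O <- Mad <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    t <- .as_binary(truth_masks[[i]])
    if (!any(t)) next
    p <- .as_binary(pred_masks[[i]])
    O[i] <- overlap_area(p, t)
    if (any(p)) {
      Mad[i] <- mean_deviation(trace_contours(p), trace_contours(t))
    }
  }
  out <- data.frame(slice = seq_len(n), O = O, Mad = Mad,
                    klass = ifelse(is.na(O), NA_character_,
                                   classify_overlap(pmax(O, 0))))
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
summary.eval_report <- function(object, ...) {
  ok <- !is.na(object$O)
  res <- list(
    n = sum(ok),
    mean_O = mean(object$O[ok]),
    mean_Mad = mean(object$Mad[ok], na.rm = TRUE),
    pct_accurate = 100 * mean(object$klass[ok] == "accurate"),
    pct_fair = 100 * mean(object$klass[ok] == "fair"),
    pct_unacceptable = 100 * mean(object$klass[ok] == "unacceptable"))
  cat(sprintf(
    "eval_report over %d slice(s): mean O %.2f%%, mean Mad %.3f px\n",
    res$n, res$mean_O, res$mean_Mad))
  cat(sprintf("  accurate %.1f%%  fair %.1f%%  unacceptable %.1f%%\n",
              res$pct_accurate, res$pct_fair, res$pct_unacceptable))
  invisible(res)
}

#' Write an evaluation report as CSV
#'
#' Per-slice rows plus a trailing summary row (average O, class
#' percentages).
#'
#' @param report an `eval_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
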