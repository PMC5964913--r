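#' Specify a synthetic CT-like phantom sequence
#'
#' The phantom emulates the structure the segmentation pipeline relies on: a
#' bright elliptical "body" on a dark background, 1--6 bright convex "bone"
#' ellipses inside it whose count changes only at known slice indices (the
#' topology schedule) and whose centres drift slowly in between, an optional
#' off-body "table" strip, and additive Gaussian noise.  Every slice carries a
#' ground-truth bone mask, so all downstream stages are testable without
#' patient data.
#'
#' @param n_slices number of slices.
#' @param image_shape `(rows, cols)` of every slice.
#' @param topology_schedule list of `c(start_slice, n_bones)` pairs; the
#'   starts must be strictly increasing and the first must be slice 1;
#'   bone counts are 1--6.
#' @param bone_intensity,body_intensity,background_intensity 8-bit gray
#'   values; must satisfy bone > body > background.
#' @param noise_sigma standard deviation of the i.i.d. Gaussian noise added
#'   last (gray levels); 0 disables noise.
#' @param include_table_artifact add a bright strip disjoint from the body,
#'   standing in for the CT table.
#' @param emit_raw also emit a 16-bit-style "raw" stack obtained by the
#'   inverse of the bone window (`raw_window` width/level), so that the
#'   windowing stage can be exercised end to end.
#' @param raw_window `c(width, level)` of the linear map used for `emit_raw`.
#' @param seed integer; the same seed and spec give bit-identical output.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(n_slices = 30L,
                         image_shape = c(64L, 64L),
                         topology_schedule = list(c(1L, 3L), c(11L, 4L), c(21L, 3L)),
                         bone_intensity = 220,
                         body_intensity = 80,
                         background_intensity = 0,
                         noise_sigma = 0,
                         include_table_artifact = TRUE,
                         emit_raw = FALSE,
                         raw_window = c(600, 900),
                         seed = 1L) {
  n_slices <- as.integer(n_slices)
  image_shape <- as.integer(image_shape)
  stopifnot(n_slices >= 1L, length(image_shape) == 2L, all(image_shape >= 32L),
            noise_sigma >= 0,
            bone_intensity > body_intensity,
            body_intensity > background_intensity)
  starts <- vapply(topology_schedule, function(e) as.integer(e[1L]), integer(1))
  counts <- vapply(topology_schedule, function(e) as.integer(e[2L]), integer(1))
  if (starts[1L] != 1L) stop("topology_schedule must start at slice 1", call. = FALSE)
  if (any(diff(starts) <= 0L))
    stop("topology_schedule slice indices must be strictly increasing", call. = FALSE)
  if (any(starts > n_slices))
    stop("topology_schedule index beyond n_slices", call. = FALSE)
  if (any(counts < 1L | counts > 6L))
    stop("bone counts must be between 1 and 6", call. = FALSE)
  structure(
    list(n_slices = n_slices, image_shape = image_shape,
         schedule_starts = starts, schedule_counts = counts,
         bone_intensity = bone_intensity, body_intensity = body_intensity,
         background_intensity = background_intensity,
         noise_sigma = noise_sigma,
         include_table_artifact = isTRUE(include_table_artifact),
         emit_raw = isTRUE(emit_raw), raw_window = as.numeric(raw_window),
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d slices %dx%d, changes at {%s}, counts {%s}, noise sd %.3g, seed %d\n",
    x$n_slices, x$image_shape[1L], x$image_shape[2L],
    paste(x$schedule_starts, collapse = ","),
    paste(x$schedule_counts, collapse = ","), x$noise_sigma, x$seed))
  invisible(x)
}

# evaluate an RNG-consuming expression under the spec seed without touching
# the caller's RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# rasterize a rotated ellipse: pixel centres (r, c) inside
.ellipse_mask <- function(shape, center, semi_axes, theta) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  dr <- r - center[1L]; dc <- c - center[2L]
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  (u / semi_axes[1L])^2 + (v / semi_axes[2L])^2 <= 1
}

#' Generate a phantom CT sequence with ground truth
#'
#' Bones are placed on a ring inside the body ellipse, far enough apart that
#' they stay disjoint under the bounded per-slice drift; a topology change
#' re-draws the ring phase and bone shapes.  Noise is added last and the
#' result is clipped to `[0, 255]` and rounded to integers.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`: list with `stack` (a
#'   [slice_stack]), `truth_masks` (list of logical matrices),
#'   `truth_keyslices` (slice indices where the topology changes), `spec`,
#'   and, when `spec$emit_raw`, `raw_stack`.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_slices = 5, seed = 7,
#'   topology_schedule = list(c(1, 2), c(4, 3))))
#' ph$truth_keyslices
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
    center <- c(nr / 2, nc / 2)
    body_ax <- c(0.42 * nc, 0.38 * nr)          # (col, row) semi-axes
    ring_r <- 0.25 * min(nr, nc)
    body <- .ellipse_mask(spec$image_shape, center, body_ax, 0)

    table_mask <- matrix(FALSE, nr, nc)
    if (spec$include_table_artifact) {
      rows <- (nr - 3L):(nr - 2L)
      cols <- max(1L, round(0.1 * nc)):min(nc, round(0.9 * nc))
      table_mask[rows, cols] <- TRUE
      table_mask <- table_mask & !body
    }

    n_epochs <- length(spec$schedule_starts)
    epoch_of <- findInterval(seq_len(spec$n_slices), spec$schedule_starts)

    # per-epoch bone geometry: evenly spaced ring angles with random phase,
    # random semi-axes in [4, 5.5] x [4, 5] and random orientation
    epochs <- lapply(seq_len(n_epochs), function(e) {
      k <- spec$schedule_counts[e]
      phase <- stats::runif(1, 0, 2 * pi)
      ang <- phase + 2 * pi * (seq_len(k) - 1L) / k
      list(
        centers = cbind(center[1L] + ring_r * sin(ang),   # rows
                        center[2L] + ring_r * cos(ang)),  # cols
        axes = cbind(stats::runif(k, 4, 5.5), stats::runif(k, 4, 5)),
        theta = stats::runif(k, 0, pi))
    })

    images <- vector("list", spec$n_slices)
    masks <- vector("list", spec$n_slices)
    offsets <- NULL
    prev_epoch <- 0L
    for (s in seq_len(spec$n_slices)) {
      e <- epoch_of[s]
      ep <- epochs[[e]]
      k <- nrow(ep$centers)
      if (e != prev_epoch) {
        offsets <- matrix(0, k, 2L)  # drift resets at each topology change
        prev_epoch <- e
      } else {
        step <- matrix(stats::runif(2L * k, -0.8, 0.8), k, 2L)
        offsets <- pmin(pmax(offsets + step, -2), 2)  # |drift| <= 2 px overall
      }
      bone <- matrix(FALSE, nr, nc)
      for (b in seq_len(k)) {
        bone <- bone | .ellipse_mask(
          spec$image_shape, ep$centers[b, ] + offsets[b, ],
          ep$axes[b, ], ep$theta[b])
      }
      img <- matrix(spec$background_intensity, nr, nc)
      img[body] <- spec$body_intensity
      img[bone] <- spec$bone_intensity
      img[table_mask] <- 200
      if (spec$noise_sigma > 0)
        img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
      images[[s]] <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), nr, nc)
      masks[[s]] <- bone
    }

    out <- list(
      stack = slice_stack(images),
      truth_masks = masks,
      truth_keyslices = spec$schedule_starts,
      spec = spec)
    if (spec$emit_raw) {
      w <- spec$raw_window[1L]; cl <- spec$raw_window[2L]
      out$raw_stack <- slice_stack(lapply(images, function(m)
        m / 255 * w + (cl - w / 2)))
    }
    class(out) <- "phantom"
    out
  })
}

#' Draw a random topology schedule
#'
#' Produces a valid `topology_schedule` for [phantom_spec()]: `n_changes`
#' change slices at least `min_gap` slices apart (and from slice 1), each
#' with a bone count different from the epoch before it, so every scheduled
#' change is a real topology change.
#'
#' @param n_slices sequence length.
#' @param n_changes number of topology changes after slice 1.
#' @param min_gap minimal epoch length in slices.
#' @param seed integer seed; the draw is deterministic and leaves the
#'   caller's RNG untouched.
#' @return a list of `c(start_slice, n_bones)` pairs.
#' @export
phantom_schedule <- function(n_slices, n_changes, min_gap = 6L, seed = 1L) {
  stopifnot(n_changes >= 1L, n_slices > (n_changes + 1L) * min_gap)
  .with_seed(seed, {
    repeat {
      starts <- sort(sample(seq(1L + min_gap, n_slices - 2L), n_changes))
      if (all(diff(c(1L, starts)) >= min_gap)) break
    }
    counts <- integer(n_changes + 1L)
    counts[1L] <- sample(2:5, 1L)
    for (i in seq_len(n_changes))
      counts[i + 1L] <- sample(setdiff(1:6, counts[i]), 1L)
    mapply(function(s, k) c(s, k), c(1L, starts), counts, SIMPLIFY = FALSE)
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d slices, topology changes at {%s}\n",
              length(x$stack), paste(x$truth_keyslices, collapse = ",")))
  invisible(x)
}

#' Write a phantom to disk
#'
#' The stack and the truth masks are written as PNG directories (or
#' multi-page TIFFs when paths end in `.tif`), and the schedule plus spec as
#' a JSON sidecar.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(phantom$stack, file.path(dir, "stack"))
  write_stack(slice_stack(lapply(phantom$truth_masks, function(m) m * 255L)),
              file.path(dir, "truth"))
  side <- unclass(phantom$spec)
  side$truth_keyslices <- phantom$truth_keyslices
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
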