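test_that("Sobel gradient matches hand convolution and the brute-force oracle", {
  expect_error(sobel_gradient(matrix(1, 2, 2)), "3x3")
  # constant image -> zero field
  g0 <- sobel_gradient(matrix(9, 6, 6))
  expect_true(all(g0$magnitude == 0))
  # vertical step of height h: |Gy| = 4h on the two columns flanking the edge
  h <- 50
  img <- cbind(matrix(0, 6, 3), matrix(h, 6, 3))
  g <- sobel_gradient(img)
  expect_true(all(abs(g$gy[, 3]) == 4 * h))
  expect_true(all(abs(g$gy[, 4]) == 4 * h))
  expect_true(all(g$gy[, c(1, 2, 5, 6)] == 0))
  expect_true(all(g$gx == 0))
  # random image vs double-loop oracle
  set.seed(5)
  x <- matrix(runif(64, 0, 255), 8, 8)
  o <- oracle_sobel(x)
  got <- sobel_gradient(x)
  expect_equal(got$gx, o$gx)
  expect_equal(got$gy, o$gy)
  expect_equal(got$magnitude, o$magnitude)
})

test_that("skeleton markers label foreground components and one background label", {
  m <- matrix(FALSE, 24, 24)
  m[blob_mask(24, 24, c(6, 6), 3)] <- TRUE
  m[blob_mask(24, 24, c(6, 18), 3)] <- TRUE
  m[blob_mask(24, 24, c(18, 12), 3)] <- TRUE
  mk <- skeleton_markers(m)
  expect_identical(attr(mk, "background_label"), 4L)   # K = 3 blobs
  expect_setequal(unique(as.integer(mk[mk > 0])), 1:4)
  expect_true(all(mk[m] %in% c(0L, 1L, 2L, 3L)))       # fg skeleton inside fg
  expect_true(all(mk[!m] %in% c(0L, 4L)))              # bg skeleton outside

  single <- matrix(FALSE, 12, 12); single[4:8, 4:8] <- TRUE
  mk1 <- skeleton_markers(single)
  expect_identical(attr(mk1, "background_label"), 2L)

  # 2x2 blob thins to nothing; the guard re-seeds its centroid
  quirk <- matrix(FALSE, 10, 10); quirk[5:6, 5:6] <- TRUE
  mkq <- skeleton_markers(quirk)
  fgpix <- which(mkq == 1L)
  expect_identical(length(fgpix), 1L)
  expect_true(quirk[fgpix])

  expect_error(skeleton_markers(matrix(FALSE, 5, 5)), "empty")
  expect_error(skeleton_markers(matrix(TRUE, 5, 5)), "whole frame")
})

test_that("minima imposition makes the markers the only regional minima", {
  set.seed(11)
  for (i in 1:25) {
    surf <- matrix(sample(0:9, 64, TRUE) + runif(64) * 0.01, 8, 8)
    mk <- matrix(0L, 8, 8)
    for (l in 1:sample(2:4, 1)) mk[sample(64, 1)] <- l
    # ensure at least 2 distinct labelled pixels
    if (sum(mk > 0) < 2) mk[1, 1] <- 1L
    imp <- impose_minima(surf, mk)
    expect_identical(oracle_regional_minima(imp), mk > 0L)
  }
  # constant surface + one marker: only that pixel is a minimum
  mk1 <- matrix(0L, 6, 6); mk1[3, 3] <- 1L
  imp1 <- impose_minima(matrix(4, 6, 6), mk1)
  expect_identical(oracle_regional_minima(imp1), mk1 > 0L)
  # markers everywhere: constant output on markers
  mkall <- matrix(1L, 4, 4)
  expect_equal(length(unique(as.numeric(impose_minima(matrix(2, 4, 4), mkall)))), 1L)
  expect_error(impose_minima(matrix(1, 4, 4), matrix(0L, 4, 4)), "no marker")
})

test_that("imposition does not reorder the surface away from markers", {
  set.seed(12)
  surf <- matrix(runif(100, 0, 10), 10, 10)
  mk <- matrix(0L, 10, 10); mk[2, 2] <- 1L; mk[9, 9] <- 2L
  imp <- impose_minima(surf, mk)
  expect_true(all(imp[mk > 0] < min(surf)))
  expect_true(all(imp[mk == 0] >= surf[mk == 0]))  # reconstruction raises, never lowers
})

test_that("watershed on a ridge surface assigns basins and keeps marker labels", {
  # two basins separated by a high column; the foreground claimant takes the
  # contested column under the documented tie rule
  surf <- matrix(rep(c(0, 0, 9, 0, 0), each = 3), 3, 5)
  mk <- matrix(0L, 3, 5); mk[2, 1] <- 1L; mk[2, 5] <- 2L
  ws <- watershed_transform(surf, mk)
  expect_true(all(ws$labels[, 1:2] == 1L))
  expect_true(all(ws$labels[, 4:5] == 2L))
  expect_true(all(ws$labels[, 3] == 1L))  # unique fg claimant (2 = background)
  expect_identical(ws$labels[2, 1], 1L)   # marker fidelity
  expect_identical(ws$labels[2, 5], 2L)

  # markers already partitioning the image reproduce themselves
  mkfull <- matrix(rep(c(1L, 1L, 2L, 2L), each = 4), 4, 4)
  wsf <- watershed_transform(matrix(0, 4, 4),
                             structure(mkfull, background_label = 2L))
  expect_identical(wsf$labels, mkfull)

  expect_error(watershed_transform(surf, matrix(1L, 3, 5)), "at least 2")
})

test_that("watershed equals the brute-force flood oracle on random surfaces", {
  set.seed(99)
  for (i in 1:30) {
    nr <- sample(6:16, 1); nc <- sample(6:16, 1)
    surf <- matrix(sample(0:6, nr * nc, TRUE) * 1.0, nr, nc)
    k <- sample(2:4, 1)
    mk <- matrix(0L, nr, nc)
    seeds <- sample(nr * nc, k)
    mk[seeds] <- seq_len(k)
    ws <- watershed_transform(surf, structure(mk, background_label = k))
    expect_identical(ws$labels, oracle_watershed(surf, mk, k))
    # conservation: labels partition the image (ridge = 0 allowed)
    expect_true(all(ws$labels %in% 0:k))
    # marker fidelity
    expect_identical(ws$labels[seeds], seq_len(k))
  }
})

test_that("segmenting a noiseless phantom slice from its own truth mask is near-exact", {
  ph <- generate_phantom(phantom_spec(
    n_slices = 2L, topology_schedule = list(c(1, 3)), noise_sigma = 0, seed = 17L))
  truth <- ph$truth_masks[[1L]]
  seg <- segment_keyframe(ph$stack$images[[1L]], truth)
  expect_gte(overlap_area(seg$bone_mask, truth), 95)
  # bone mask contains an erosion of the truth (rim may move by a pixel)
  inner <- truth
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(FALSE, nrow(truth), ncol(truth))
    src_r <- seq_len(nrow(truth)) + dr; src_c <- seq_len(ncol(truth)) + dc
    ok_r <- src_r >= 1 & src_r <= nrow(truth)
    ok_c <- src_c >= 1 & src_c <= ncol(truth)
    shifted[ok_r, ok_c] <- truth[src_r[ok_r], src_c[ok_c]]
    inner <- inner & shifted
  }
  expect_true(all(seg$bone_mask[inner]))
})

test_that("marker edits relabel consistently", {
  m <- matrix(FALSE, 16, 16)
  m[blob_mask(16, 16, c(5, 5), 2.5)] <- TRUE
  m[blob_mask(16, 16, c(11, 11), 2.5)] <- TRUE
  mk <- skeleton_markers(m)
  expect_identical(attr(mk, "background_label"), 3L)

  # identity edit
  expect_identical(unclass(edit_markers(mk)), unclass(mk))

  # adding an isolated point with a new label increases K by 1
  mk2 <- edit_markers(mk, add = cbind(2, 14, 99))
  expect_identical(attr(mk2, "background_label"), 4L)
  expect_identical(sum(mk2 > 0L & mk2 != 4L),
                   sum(mk > 0L & mk != 3L) + 1L)

  # removing every pixel of one label renumbers the rest contiguously
  pix <- which(mk == 2L, arr.ind = TRUE)
  mk3 <- edit_markers(mk, remove = pix)
  expect_identical(attr(mk3, "background_label"), 2L)
  expect_setequal(unique(as.integer(mk3[mk3 > 0L])), 1:2)

  expect_error(edit_markers(mk, remove = cbind(1, 1)), "no marker")
})

test_that("contour tracing is clockwise from the topmost-leftmost pixel", {
  m <- matrix(FALSE, 6, 6); m[2:4, 2:4] <- TRUE
  ct <- trace_contours(m)
  expect_identical(nrow(ct), 8L)                     # 3x3 block boundary
  expect_equal(ct[1, ], c(row = 2, col = 2))         # topmost-then-leftmost
  expect_equal(ct[2, ], c(row = 2, col = 3))         # clockwise: east first
  expect_false(any(ct[, 1] == 3 & ct[, 2] == 3))     # interior excluded
  # single pixel
  p <- matrix(FALSE, 3, 3); p[2, 2] <- TRUE
  expect_equal(nrow(trace_contours(p)), 1L)
  # empty mask
  expect_identical(nrow(trace_contours(matrix(FALSE, 3, 3))), 0L)
})
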