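# Independent reference implementations, deliberately written pixel-by-pixel
# (plain double loops, no shared code with the package internals) so they can
# serve as oracles for the vectorized / compiled paths.

# --- two-subiteration thinning, one pixel at a time ------------------------

.o_nbhd <- function(img, r, c) {
  # 3x3 neighbourhood with zero padding
  out <- matrix(0L, 3L, 3L)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nrow(img) && cc >= 1 && cc <= ncol(img))
      out[dr + 2L, dc + 2L] <- img[rr, cc]
  }
  out
}

.o_deletable <- function(nb, pass) {
  p2 <- nb[1, 2]; p3 <- nb[1, 3]; p4 <- nb[2, 3]; p5 <- nb[3, 3]
  p6 <- nb[3, 2]; p7 <- nb[3, 1]; p8 <- nb[2, 1]; p9 <- nb[1, 1]
  ring <- c(p2, p3, p4, p5, p6, p7, p8, p9)
  n <- sum(ring)
  if (n < 2 || n > 6) return(FALSE)
  s <- 0L
  cyc <- c(ring, ring[1])
  for (i in 1:8) if (cyc[i] == 0 && cyc[i + 1] == 1) s <- s + 1L
  if (s != 1L) return(FALSE)
  if (pass == 1L) (p2 * p4 * p6 == 0) && (p4 * p6 * p8 == 0)
  else            (p2 * p4 * p8 == 0) && (p2 * p6 * p8 == 0)
}

oracle_thin <- function(mask) {
  img <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    any_del <- FALSE
    for (pass in 1:2) {
      del <- matrix(FALSE, nrow(img), ncol(img))
      for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
        if (img[r, c] == 1L && .o_deletable(.o_nbhd(img, r, c), pass))
          del[r, c] <- TRUE
      }
      if (any(del)) { img[del] <- 0L; any_del <- TRUE }
    }
    if (!any_del) break
  }
  img
}

# --- watershed flood, naive queue-as-vectors -------------------------------
# Same documented rules as the package: pops in (value, insertion) order;
# queue seeded from marker pixels in column-major order with neighbours
# enumerated column-major; the unique foreground claimant wins a contested
# pixel; two different foreground claimants make it a ridge (0).

oracle_watershed <- function(surface, markers, background_label) {
  nr <- nrow(surface); nc <- ncol(surface)
  offs <- cbind(dr = c(-1, 0, 1, -1, 1, -1, 0, 1),
                dc = c(-1, -1, -1, 0, 0, 1, 1, 1))
  lab <- matrix(0L, nr, nc)
  done <- matrix(FALSE, nr, nc)
  claims <- vector("list", nr * nc)
  qv <- numeric(0); qs <- integer(0); qr <- integer(0); qc <- integer(0)
  ql <- integer(0); qa <- logical(0)
  nseq <- 0L
  push <- function(r, c, l) {
    nseq <<- nseq + 1L
    qv <<- c(qv, surface[r, c]); qs <<- c(qs, nseq)
    qr <<- c(qr, r); qc <<- c(qc, c); ql <<- c(ql, l); qa <<- c(qa, TRUE)
    j <- (c - 1L) * nr + r
    claims[[j]] <<- unique(c(claims[[j]], l))
  }
  for (c in seq_len(nc)) for (r in seq_len(nr))
    if (markers[r, c] > 0L) { lab[r, c] <- markers[r, c]; done[r, c] <- TRUE }
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (!done[r, c]) next
    for (k in 1:8) {
      rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || done[rr, cc]) next
      push(rr, cc, lab[r, c])
    }
  }
  while (any(qa)) {
    act <- which(qa)
    act <- act[qv[act] == min(qv[act])]
    i <- act[which.min(qs[act])]
    qa[i] <- FALSE
    r <- qr[i]; c <- qc[i]
    if (done[r, c]) next
    done[r, c] <- TRUE
    cl <- claims[[(c - 1L) * nr + r]]
    fg <- setdiff(cl, background_label)
    if (length(fg) >= 2L) { lab[r, c] <- 0L; next }
    assign <- if (length(fg) == 1L) fg else background_label
    lab[r, c] <- assign
    for (k in 1:8) {
      rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || done[rr, cc]) next
      push(rr, cc, assign)
    }
  }
  lab
}

# --- regional minima by plateau inspection ---------------------------------
# A regional minimum is an 8-connected constant plateau with no strictly
# lower 8-neighbour.

oracle_regional_minima <- function(surface) {
  nr <- nrow(surface); nc <- ncol(surface)
  visited <- matrix(FALSE, nr, nc)
  minima <- matrix(FALSE, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (visited[r0, c0]) next
    v <- surface[r0, c0]
    plateau <- matrix(FALSE, nr, nc)
    queue <- list(c(r0, c0)); plateau[r0, c0] <- TRUE
    is_min <- TRUE
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (surface[rr, cc] < v) is_min <- FALSE
        else if (surface[rr, cc] == v && !plateau[rr, cc]) {
          plateau[rr, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
    visited[plateau] <- TRUE
    if (is_min) minima[plateau] <- TRUE
  }
  minima
}

# --- Sobel by explicit convolution -----------------------------------------

oracle_sobel <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  at <- function(r, c) img[min(max(r, 1L), nr), min(max(c, 1L), nc)]
  gx <- gy <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    p2 <- at(r - 1, c); p3 <- at(r - 1, c + 1); p4 <- at(r, c + 1)
    p5 <- at(r + 1, c + 1); p6 <- at(r + 1, c); p7 <- at(r + 1, c - 1)
    p8 <- at(r, c - 1); p9 <- at(r - 1, c - 1)
    gx[r, c] <- p9 + 2 * p2 + p3 - (p7 + 2 * p6 + p5)
    gy[r, c] <- p9 + 2 * p8 + p7 - (p3 + 2 * p4 + p5)
  }
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

# --- directed mean contour deviation by double loop ------------------------

oracle_mad <- function(L1, L2) {
  tot <- 0
  for (i in seq_len(nrow(L1))) {
    best <- Inf
    for (j in seq_len(nrow(L2))) {
      d <- sqrt((L1[i, 1] - L2[j, 1])^2 + (L1[i, 2] - L2[j, 2])^2)
      if (d < best) best <- d
    }
    tot <- tot + best
  }
  as.numeric(tot / nrow(L1))
}

# --- misc fixtures ----------------------------------------------------------

random_mask <- function(nr = 16L, nc = 16L, p = 0.5) {
  matrix(stats::rbinom(nr * nc, 1L, p), nr, nc)
}

blob_mask <- function(nr, nc, centre, radius) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (r - centre[1L])^2 + (c - centre[2L])^2 <= radius^2
}
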