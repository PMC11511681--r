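# Dense optical flow by polynomial expansion (Farneback-style).
#
# Each frame neighbourhood is approximated by a quadratic polynomial
# f(x) ~ x'Ax + b'x + c fitted under Gaussian applicability weights; the
# displacement field is estimated from the expansion coefficients of
# consecutive frames, averaged over a Gaussian integration window, with
# iterative warping and a coarse-to-fine pyramid.

# Quadratic polynomial expansion of one frame.
# Returns per-pixel fields b1, b2 (linear terms, x = columns, y = rows)
# and a11, a12, a22 (quadratic terms).
poly_expansion <- function(img, n = 2, sigma = 1.2) {
  off <- seq(-n, n)
  a <- exp(-off^2 / (2 * sigma^2))
  # basis over the window: 1, x, y, x^2, y^2, xy  (x = col, y = row)
  X <- outer(rep(1, length(off)), off)   # column offsets
  Y <- outer(off, rep(1, length(off)))   # row offsets
  Wt <- outer(a, a)
  basis <- list(one = X * 0 + 1, x = X, y = Y, x2 = X^2, y2 = Y^2, xy = X * Y)
  G <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    G[i, j] <- sum(Wt * basis[[i]] * basis[[j]])
  Ginv <- solve(G)
  v <- lapply(basis, function(bk)
    EBImage::filter2(img, Wt * bk, boundary = "replicate"))
  # r = Ginv %*% v, per pixel. filter2 convolves (kernel flipped in both
  # axes), which negates the odd (linear) basis projections; the quadratic
  # terms are parity-even and unaffected.
  r <- lapply(1:6, function(i)
    Reduce(`+`, Map(function(vk, g) vk * g, v, Ginv[i, ])))
  list(b1 = -r[[2]], b2 = -r[[3]],
       a11 = r[[4]], a12 = r[[6]] / 2, a22 = r[[5]])
}

# One Farneback displacement update at a single scale.
# e1, e2: poly expansions; vx, vy: prior flow (col/row displacement).
flow_update <- function(e1, e2, vx, vy, win_sigma) {
  nr <- nrow(e1$b1); nc <- ncol(e1$b1)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  wr <- rows + vy; wc <- cols + vx
  b1w <- bilinear_sample(e2$b1, wr, wc); dim(b1w) <- c(nr, nc)
  b2w <- bilinear_sample(e2$b2, wr, wc); dim(b2w) <- c(nr, nc)
  a11 <- (e1$a11 + matrix(bilinear_sample(e2$a11, wr, wc), nr, nc)) / 2
  a12 <- (e1$a12 + matrix(bilinear_sample(e2$a12, wr, wc), nr, nc)) / 2
  a22 <- (e1$a22 + matrix(bilinear_sample(e2$a22, wr, wc), nr, nc)) / 2
  db1 <- -0.5 * (b1w - e1$b1) + a11 * vx + a12 * vy
  db2 <- -0.5 * (b2w - e1$b2) + a12 * vx + a22 * vy
  g11 <- gauss_smooth(a11^2 + a12^2, win_sigma)
  g12 <- gauss_smooth(a12 * (a11 + a22), win_sigma)
  g22 <- gauss_smooth(a12^2 + a22^2, win_sigma)
  h1 <- gauss_smooth(a11 * db1 + a12 * db2, win_sigma)
  h2 <- gauss_smooth(a12 * db1 + a22 * db2, win_sigma)
  det <- g11 * g22 - g12^2
  det[abs(det) < 1e-12] <- 1e-12
  list(vx = (g22 * h1 - g12 * h2) / det,
       vy = (g11 * h2 - g12 * h1) / det)
}

#' Dense optical flow between two frames
#'
#' Polynomial-expansion dense flow with a coarse-to-fine Gaussian pyramid
#' and iterative warping. Returns the per-pixel displacement taking frame 1
#' onto frame 2, in pixels (`vx` along columns, `vy` along rows).
#'
#' @param f1,f2 numeric matrices (single-channel frames of equal size).
#' @param levels pyramid levels (default 3).
#' @param winsize integration window size in pixels (default 15; the
#'   Gaussian window sigma is `winsize / 4`).
#' @param iterations warping iterations per level (default 3).
#' @param poly_n half-width of the polynomial expansion window (default 2,
#'   i.e. a 5x5 window).
#' @param poly_sigma applicability Gaussian sigma (default 1.2).
#' @return list with matrices `vx` and `vy`.
#' @export
optical_flow <- function(f1, f2, levels = 3, winsize = 15, iterations = 3,
                         poly_n = 2, poly_sigma = 1.2) {
  stopifnot(all(dim(f1) == dim(f2)))
  pyr1 <- list(f1); pyr2 <- list(f2)
  for (l in seq_len(levels - 1)) {
    prev1 <- pyr1[[l]]; prev2 <- pyr2[[l]]
    if (min(dim(prev1)) < 16) break
    k <- gauss_kernel(1)
    pyr1[[l + 1]] <- EBImage::resize(sep_filter(prev1, k),
                                     w = ceiling(nrow(prev1) / 2),
                                     h = ceiling(ncol(prev1) / 2))
    pyr2[[l + 1]] <- EBImage::resize(sep_filter(prev2, k),
                                     w = ceiling(nrow(prev2) / 2),
                                     h = ceiling(ncol(prev2) / 2))
  }
  nl <- length(pyr1)
  vx <- vy <- matrix(0, nrow(pyr1[[nl]]), ncol(pyr1[[nl]]))
  for (l in rev(seq_len(nl))) {
    if (l < nl) { # upscale the flow from the coarser level
      vx <- EBImage::resize(vx, w = nrow(pyr1[[l]]), h = ncol(pyr1[[l]])) * 2
      vy <- EBImage::resize(vy, w = nrow(pyr1[[l]]), h = ncol(pyr1[[l]])) * 2
    }
    e1 <- poly_expansion(pyr1[[l]], poly_n, poly_sigma)
    e2 <- poly_expansion(pyr2[[l]], poly_n, poly_sigma)
    for (it in seq_len(iterations)) {
      upd <- flow_update(e1, e2, vx, vy, winsize / 4)
      vx <- upd$vx; vy <- upd$vy
    }
  }
  list(vx = vx, vy = vy)
}

#' Dense optical flow over a frame sequence
#'
#' Applies [optical_flow()] to each consecutive frame pair.
#'
#' @param frames 3-D array (rows x cols x time) or list of matrices, with at
#'   least 2 frames.
#' @param ... passed to [optical_flow()].
#' @return list of length `n_frames - 1` of `list(vx, vy)` flow fields.
#' @export
dense_flow <- function(frames, ...) {
  fl <- frames_as_list(frames)
  if (length(fl) < 2) stop("need at least 2 frames")
  lapply(seq_len(length(fl) - 1), function(t)
    optical_flow(fl[[t]], fl[[t + 1]], ...))
}

frames_as_list <- function(frames) {
  if (is.list(frames)) return(frames)
  stopifnot(length(dim(frames)) == 3)
  lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
}
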