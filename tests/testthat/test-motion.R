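# Textured test image: scattered Gaussian blobs.
blob_image <- function(h = 64, w = 64, n = 15, sigma = 2.5, seed = 1) {
  set.seed(seed)
  img <- matrix(0, h, w)
  for (i in seq_len(n)) {
    x <- runif(1, 10, w - 10); y <- runif(1, 10, h - 10)
    img <- img + exp(-outer((seq_len(h) - y)^2, (seq_len(w) - x)^2, `+`) /
                       (2 * sigma^2))
  }
  img
}

shift_image <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (r in seq_len(h))
    out[r, ] <- bilinear_sample(img, rep(min(max(r - dy, 1), h), w),
                                pmin(pmax(seq_len(w) - dx, 1), w))
  out
}

test_that("dense flow recovers global translations within a quarter pixel", {
  img <- blob_image()
  for (s in list(c(3, 0), c(0, 2), c(-2, 1))) {
    fl <- optical_flow(img, shift_image(img, s[1], s[2]))
    sel <- img > 0.2
    expect_lt(abs(median(fl$vx[sel]) - s[1]), 0.25)
    expect_lt(abs(median(fl$vy[sel]) - s[2]), 0.25)
  }
})

test_that("flow on identical frames is zero and time reversal negates it", {
  img <- blob_image(seed = 2)
  fl0 <- optical_flow(img, img)
  expect_lt(max(abs(c(fl0$vx, fl0$vy))), 1e-6)
  img2 <- shift_image(img, 2, 1)
  fwd <- optical_flow(img, img2)
  rev_ <- optical_flow(img2, img)
  sel <- img > 0.2
  expect_lt(abs(median(fwd$vx[sel]) + median(rev_$vx[sel])), 0.2)
  expect_lt(abs(median(fwd$vy[sel]) + median(rev_$vy[sel])), 0.2)
})

test_that("superpixel tracks stay put on a static video and follow translation", {
  img <- blob_image(seed = 3)
  static <- list(img, img, img)
  tr <- track_superpixels(static, n_superpixels = 100)
  expect_equal(tr$x[, 3], tr$x[, 1], tolerance = 1e-6)
  expect_equal(tr$y[, 3], tr$y[, 1], tolerance = 1e-6)

  mov <- list(img, shift_image(img, 2, 0), shift_image(img, 4, 0))
  trm <- track_superpixels(mov, n_superpixels = 100, reseed = FALSE,
                           drift_warn_px = Inf)
  on_texture <- bilinear_sample(img, trm$y[, 1], trm$x[, 1]) > 0.2
  steps <- trm$x[on_texture, 2] - trm$x[on_texture, 1]
  expect_lt(max(abs(steps - 2)), 0.5)
})

test_that("initial tracks tile the frame and reseeding fills vacated cells", {
  img <- blob_image(32, 32, n = 6, seed = 4)
  frames <- list(img, shift_image(img, 6, 6), shift_image(img, 12, 12))
  tr <- track_superpixels(frames, n_superpixels = 64, drift_warn_px = Inf)
  expect_equal(tr$n_initial, 64)
  expect_true(all(tr$birth[seq_len(64)] == 1))
  # coverage audit: every grid cell has a track within one superpixel width
  w_sp <- tr$w_sp
  nf <- ncol(tr$x)
  alive <- !is.na(tr$x[, nf])
  cells_r <- ceiling((tr$y[alive, nf] - 0.5) / w_sp)
  cells_c <- ceiling((tr$x[alive, nf] - 0.5) / w_sp)
  n_cells <- ceiling(32 / w_sp)
  covered <- unique(paste(pmin(cells_r, n_cells), pmin(cells_c, n_cells)))
  expect_gte(length(covered), 0.9 * n_cells^2)
})

test_that("mesh connects axial grid neighbours at rest length", {
  # hand-built tracks on a regular grid
  gx <- as.vector(outer(rep(1, 5), seq(4, 20, by = 4)))
  gy <- as.vector(outer(seq(4, 20, by = 4), rep(1, 5)))
  tr <- make_trackset(cbind(gx, gx), cbind(gy, gy), w_sp = 4,
                      frame_shape = c(24, 24))
  mesh <- build_mesh(tr)
  # interior tracks have exactly 4 axial neighbours (sqrt(2) w_sp >= 1.2 w_sp)
  deg <- tabulate(as.vector(mesh$edges), nbins = 25)
  interior <- which(gx > 4 & gx < 20 & gy > 4 & gy < 20)
  expect_true(all(deg[interior] == 4))
  expect_true(all(mesh$rest_length == 4))
  # single track: empty mesh
  tr1 <- make_trackset(matrix(5, 1, 2), matrix(5, 1, 2))
  expect_equal(nrow(build_mesh(tr1)$edges), 0)
  # edge count invariant under track reordering
  ord <- sample(25)
  tro <- make_trackset(cbind(gx, gx)[ord, ], cbind(gy, gy)[ord, ],
                       w_sp = 4, frame_shape = c(24, 24))
  expect_equal(nrow(build_mesh(tro)$edges), nrow(mesh$edges))
})

test_that("mesh strain is zero under rigid motion and |s-1| under scaling", {
  set.seed(5)
  x0 <- runif(30, 10, 50); y0 <- runif(30, 10, 50)
  theta <- 0.3
  xr <- 30 + cos(theta) * (x0 - 30) - sin(theta) * (y0 - 30) + 5
  yr <- 30 + sin(theta) * (x0 - 30) + cos(theta) * (y0 - 30) - 3
  tr <- make_trackset(cbind(x0, x0 + 7, xr), cbind(y0, y0 - 2, yr),
                      w_sp = 8)
  mesh <- build_mesh(tr, threshold_factor = 3)
  sc <- mesh_strain_curve(mesh, tr)
  expect_equal(sc[1], 0)
  expect_lt(sc[2], 1e-9) # translation
  expect_lt(sc[3], 1e-9) # rotation + translation
  # uniform scaling by 1.1 about any centre: strain exactly 0.1
  trs <- make_trackset(cbind(x0, 30 + 1.1 * (x0 - 30)),
                       cbind(y0, 30 + 1.1 * (y0 - 30)), w_sp = 8)
  scs <- mesh_strain_curve(build_mesh(trs, threshold_factor = 3), trs)
  expect_equal(scs[2], 0.1, tolerance = 1e-9)
  # unnormalized variant scales with the rest length instead
  sca <- mesh_strain_curve(build_mesh(trs, threshold_factor = 3), trs,
                           normalized = FALSE)
  expect_gt(sca[2], scs[2])
})

test_that("saliency peaks where tracks converge", {
  # all tracks converge to (40, 20)
  set.seed(6)
  n <- 80
  x <- cbind(runif(n, 5, 60), rep(40, n))
  y <- cbind(runif(n, 5, 60), rep(20, n))
  tr <- make_trackset(x, y, w_sp = 4)
  sal <- motion_saliency(tr, kind = "sink")
  peak <- which(sal$map == 1, arr.ind = TRUE)
  expect_lt(abs(peak[1, "row"] - 20), 4)
  expect_lt(abs(peak[1, "col"] - 40), 4)
  expect_lt(abs(sal$median_coord["x"] - 40), 8)
  expect_lt(abs(sal$median_coord["y"] - 20), 8)
  expect_true(all(sal$map >= 0 & sal$map <= 1))
  # stationary tracks give a flatter map than converging ones
  trs <- make_trackset(cbind(x[, 1], x[, 1]), cbind(y[, 1], y[, 1]),
                       w_sp = 4)
  flat <- motion_saliency(trs, kind = "sink")
  cv <- function(mp) sd(mp) / mean(mp)
  expect_lt(cv(flat$map), cv(sal$map))
})

test_that("motion signatures concatenate truncated strain curves", {
  f <- seq(0, 1, length.out = 100)
  r <- seq(0, 2, length.out = 95)
  sig <- motion_signature(f, r, 90)
  expect_length(sig, 180)
  expect_equal(sig[1:90], f[1:90], ignore_attr = TRUE)
  expect_equal(sig[91:180], r[1:90], ignore_attr = TRUE)
  # identical curves give a signature symmetric about the midpoint
  sg <- motion_signature(f, f, 90)
  expect_equal(sg[1:90], sg[91:180], ignore_attr = TRUE)
  expect_error(motion_signature(f[1:50], r, 90), "shorter")
})

test_that("phenotype PCA reports split loadings and explained variance", {
  set.seed(7)
  sigs <- rbind(matrix(rep(seq(0, 1, length.out = 20), 4), 4, 20,
                       byrow = TRUE),
                matrix(rep(seq(0, 0.4, length.out = 20), 4), 4, 20,
                       byrow = TRUE)) + matrix(rnorm(160, 0, 0.01), 8)
  res <- phenotype_pca(sigs, labels = rep(c("wt", "mut"), each = 4))
  expect_gt(res$explained_variance[1], 0.9)
  # PC1 separates the cohorts
  s1 <- res$scores[1:4, 1]; s2 <- res$scores[5:8, 1]
  expect_true(max(range(s1)) < min(range(s2)) ||
                min(range(s1)) > max(range(s2)))
  # loadings unit norm, split into halves
  l1 <- c(res$loadings[[1]]$forward, res$loadings[[1]]$reverse)
  expect_equal(sum(l1^2), 1, tolerance = 1e-12)
  expect_length(res$loadings[[1]]$forward, 10)
  # identical embryos: no real variance
  same <- matrix(rep(seq_len(20), 5), 5, 20, byrow = TRUE)
  res0 <- phenotype_pca(same)
  expect_lt(res0$explained_variance[1], 1e-6)
  expect_error(phenotype_pca(sigs[1:2, ]), "at least 3")
})

test_that("planted sink is localized and speed orders the strain curves", {
  spec_fast <- video_sim_spec(mean_speed = 1.5, seed = 3)
  sim <- simulate_migration_video(spec_fast)
  tf <- track_superpixels(sim$frames, n_superpixels = 150,
                          direction = "forward")
  sal <- motion_saliency(tf)
  err <- sqrt(sum((sal$median_coord -
                     spec_fast$sink_position)^2))
  expect_lte(err, 2 * tf$w_sp)
  sc_fast <- mesh_strain_curve(build_mesh(tf), tf)
  expect_equal(sc_fast[1], 0)

  spec_slow <- video_sim_spec(mean_speed = 0.6, seed = 3)
  sims <- simulate_migration_video(spec_slow)
  ts <- track_superpixels(sims$frames, n_superpixels = 150,
                          direction = "forward")
  sc_slow <- mesh_strain_curve(build_mesh(ts), ts)
  expect_true(all(sc_fast[6:length(sc_fast)] >= sc_slow[6:length(sc_slow)]))
  # faster speed crosses any strain level earlier
  lev <- 0.05
  expect_lt(min(which(sc_fast > lev)), min(which(sc_slow > lev)))
})
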