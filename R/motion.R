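#' Superpixel tracking by dense optical flow
#'
#' Seeds ~`n_superpixels` track centroids on a regular grid, then advects
#' each track per frame by the mean optical flow within a superpixel-width
#' window centred on it. After each step, grid cells left without any track
#' are reseeded with a new track born there, maintaining near-uniform
#' coverage so cells entering the field of view are tracked too. Positions
#' are clamped at the frame borders. Reverse tracking runs on the reversed
#' frame sequence.
#'
#' @param frames 3-D array (rows x cols x time) or list of matrices.
#' @param n_superpixels target number of initial superpixels (default 1000).
#' @param direction `"forward"` or `"reverse"`.
#' @param flows optional precomputed [dense_flow()] result for the frame
#'   sequence in tracking order.
#' @param reseed reseed vacated grid cells (default TRUE).
#' @param drift_warn_px warn when the median background flow per frame
#'   exceeds this (residual registration drift); default 0.5.
#' @param ... passed to [dense_flow()].
#' @return list of class `TrackSet`: `x`, `y` (tracks x frames positions, NA
#'   before a track's birth), `birth` (frame of first appearance), `w_sp`
#'   (superpixel width), `direction`, `frame_shape`, `n_initial`.
#' @export
track_superpixels <- function(frames, n_superpixels = 1000,
                              direction = c("forward", "reverse"),
                              flows = NULL, reseed = TRUE,
                              drift_warn_px = 0.5, ...) {
  direction <- match.arg(direction)
  fl <- frames_as_list(frames)
  if (direction == "reverse") fl <- rev(fl)
  nf <- length(fl)
  h <- nrow(fl[[1]]); w <- ncol(fl[[1]])
  w_sp <- max(2L, round(sqrt(h * w / n_superpixels)))
  cy <- seq(w_sp / 2 + 0.5, h, by = w_sp)
  cx <- seq(w_sp / 2 + 0.5, w, by = w_sp)
  grid <- expand.grid(y = cy, x = cx)
  n0 <- nrow(grid)

  if (is.null(flows)) flows <- dense_flow(fl, ...)
  stopifnot(length(flows) == nf - 1)

  x <- matrix(NA_real_, n0, nf); y <- matrix(NA_real_, n0, nf)
  x[, 1] <- grid$x; y[, 1] <- grid$y
  birth <- rep(1L, n0)
  box_len <- w_sp + (w_sp %% 2 == 0) # filter kernels must have odd size
  box <- rep(1, box_len) / box_len
  med_drift <- numeric(nf - 1)
  for (t in seq_len(nf - 1)) {
    vx <- sep_filter(flows[[t]]$vx, box)
    vy <- sep_filter(flows[[t]]$vy, box)
    med_drift[t] <- median(sqrt(flows[[t]]$vx^2 + flows[[t]]$vy^2))
    alive <- which(birth <= t)
    px <- x[alive, t]; py <- y[alive, t]
    dx <- bilinear_sample(vx, py, px)
    dy <- bilinear_sample(vy, py, px)
    x[alive, t + 1] <- pmin(pmax(px + dx, 1), w)
    y[alive, t + 1] <- pmin(pmax(py + dy, 1), h)
    if (reseed) {
      occ_r <- pmin(pmax(ceiling((y[alive, t + 1] - 0.5) / w_sp), 1),
                    length(cy))
      occ_c <- pmin(pmax(ceiling((x[alive, t + 1] - 0.5) / w_sp), 1),
                    length(cx))
      occupied <- unique(paste(occ_r, occ_c))
      all_cells <- expand.grid(r = seq_along(cy), c = seq_along(cx))
      vac <- all_cells[!(paste(all_cells$r, all_cells$c) %in% occupied), ,
                       drop = FALSE]
      if (nrow(vac)) {
        nx <- matrix(NA_real_, nrow(vac), nf)
        ny <- matrix(NA_real_, nrow(vac), nf)
        nx[, t + 1] <- cx[vac$c]; ny[, t + 1] <- cy[vac$r]
        x <- rbind(x, nx); y <- rbind(y, ny)
        birth <- c(birth, rep(t + 1L, nrow(vac)))
      }
    }
  }
  if (median(med_drift) > drift_warn_px)
    warning(sprintf(
      "median global flow %.2f px/frame exceeds %.2f: residual drift?",
      median(med_drift), drift_warn_px))
  structure(list(x = x, y = y, birth = birth, w_sp = w_sp,
                 direction = direction, frame_shape = c(h, w),
                 n_initial = n0),
            class = "TrackSet")
}

#' Motion mesh over a track set
#'
#' Connects pairs of tracks alive at the tracking start frame whose
#' start-frame distance is below 1.2 times the mean superpixel width; edge
#' rest lengths are frozen at the start frame.
#'
#' @param tracks a [track_superpixels()] result.
#' @param threshold_factor neighbour distance threshold as a multiple of the
#'   superpixel width (default 1.2).
#' @return list of class `MotionMesh`: `edges` (2-column matrix of track
#'   indices), `rest_length`, `w_sp`.
#' @export
build_mesh <- function(tracks, threshold_factor = 1.2) {
  stopifnot(inherits(tracks, "TrackSet"))
  init <- which(tracks$birth == 1L)
  p0 <- cbind(tracks$x[init, 1], tracks$y[init, 1])
  thr <- threshold_factor * tracks$w_sp
  dd <- as.matrix(dist(p0))
  sel <- which(dd < thr & upper.tri(dd), arr.ind = TRUE)
  edges <- cbind(init[sel[, 1]], init[sel[, 2]])
  rl <- dd[sel]
  keep <- rl > 0
  if (any(!keep)) message("excluded ", sum(!keep), " zero-length edge(s)")
  structure(list(edges = edges[keep, , drop = FALSE],
                 rest_length = rl[keep], w_sp = tracks$w_sp),
            class = "MotionMesh")
}

#' Mesh strain curve
#'
#' Per frame, the mean absolute difference of the mesh edge lengths from
#' their rest (start-frame) lengths, by default relative to the rest
#' lengths. Zero under any rigid motion; equal to `|s - 1|` under uniform
#' scaling by `s`.
#'
#' @param mesh a [build_mesh()] result.
#' @param tracks the [track_superpixels()] result the mesh was built on.
#' @param normalized divide by the rest length (default TRUE); FALSE gives
#'   the absolute variant.
#' @return numeric vector of length n_frames (class `StrainCurve`);
#'   strain\[1\] is 0.
#' @export
mesh_strain_curve <- function(mesh, tracks, normalized = TRUE) {
  stopifnot(inherits(mesh, "MotionMesh"), inherits(tracks, "TrackSet"))
  nf <- ncol(tracks$x)
  i <- mesh$edges[, 1]; j <- mesh$edges[, 2]
  out <- vapply(seq_len(nf), function(t) {
    L <- sqrt((tracks$x[i, t] - tracks$x[j, t])^2 +
                (tracks$y[i, t] - tracks$y[j, t])^2)
    dev <- abs(L - mesh$rest_length)
    if (normalized) dev <- dev / mesh$rest_length
    mean(dev)
  }, numeric(1))
  attr(out, "direction") <- tracks$direction
  class(out) <- "StrainCurve"
  out
}

#' Motion saliency map (sources / sinks)
#'
#' Density of terminal track positions — forward tracking localises motion
#' sinks (where motion converges), reverse tracking motion sources —
#' smoothed with a Gaussian of sigma one superpixel width and normalised to
#' max 1. The median source/sink is the coordinate-wise median of the
#' pixels above the 95th percentile of the map.
#'
#' @param tracks a [track_superpixels()] result.
#' @param kind `"sink"` (forward tracks) or `"source"` (reverse tracks);
#'   defaults to the value implied by the track direction.
#' @return list of class `SaliencyMap`: `map` (rows x cols, values in
#'   \[0,1\]), `kind`, `median_coord` (x, y).
#' @export
motion_saliency <- function(tracks, kind = NULL) {
  stopifnot(inherits(tracks, "TrackSet"))
  if (nrow(tracks$x) == 0) stop("empty track set")
  if (is.null(kind))
    kind <- if (tracks$direction == "forward") "sink" else "source"
  kind <- match.arg(kind, c("sink", "source"))
  nf <- ncol(tracks$x)
  h <- tracks$frame_shape[1]; w <- tracks$frame_shape[2]
  fx <- tracks$x[, nf]; fy <- tracks$y[, nf]
  r <- pmin(pmax(round(fy), 1), h)
  c_ <- pmin(pmax(round(fx), 1), w)
  mp <- matrix(0, h, w)
  for (t in seq_along(r)) mp[r[t], c_[t]] <- mp[r[t], c_[t]] + 1
  mp <- pmax(gauss_smooth(mp, tracks$w_sp), 0) # clip FFT ringing
  mp <- mp / max(mp)
  thr <- quantile(mp, 0.95, names = FALSE)
  top <- which(mp > thr, arr.ind = TRUE)
  med <- c(x = median(top[, 2]), y = median(top[, 1]))
  structure(list(map = mp, kind = kind, median_coord = med),
            class = "SaliencyMap")
}

#' Motion signature from forward and reverse strain curves
#'
#' Truncates both curves to the cohort's common frame count (dropping only
#' trailing frames) and concatenates forward then reverse, giving a vector
#' of length `2 * common_frames`.
#'
#' @param forward,reverse strain curves ([mesh_strain_curve()]).
#' @param common_frames common frame count across the cohort.
#' @return numeric vector of length `2 * common_frames` (class
#'   `MotionSignature`).
#' @export
motion_signature <- function(forward, reverse, common_frames) {
  if (length(forward) < common_frames || length(reverse) < common_frames)
    stop("curve shorter than common_frames")
  out <- c(unclass(forward)[seq_len(common_frames)],
           unclass(reverse)[seq_len(common_frames)])
  class(out) <- "MotionSignature"
  out
}

#' PCA motion phenotyping over a cohort of signatures
#'
#' Column-centered PCA over embryos x signature dimensions. Loadings are
#' reported split into their forward and reverse halves for temporal
#' interpretation.
#'
#' @param signatures matrix (embryos x dimensions) or list of equal-length
#'   [motion_signature()] vectors.
#' @param labels optional cohort labels per embryo.
#' @param n_comps components to report (capped at embryos - 1).
#' @return list of class `MotionPCA`: `scores`, `explained_variance`,
#'   `loadings` (list per component with `forward` and `reverse` halves),
#'   `labels`.
#' @export
phenotype_pca <- function(signatures, labels = NULL, n_comps = 2) {
  if (is.list(signatures)) signatures <- do.call(rbind, signatures)
  n <- nrow(signatures)
  if (n < 3) stop("need at least 3 embryos")
  n_comps <- min(n_comps, n - 1, ncol(signatures))
  pc <- prcomp(signatures, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  ev <- if (tot > 1e-300) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  half <- ncol(signatures) / 2
  loadings <- lapply(seq_len(n_comps), function(j)
    list(forward = pc$rotation[seq_len(half), j],
         reverse = pc$rotation[half + seq_len(half), j]))
  structure(list(scores = pc$x[, seq_len(n_comps), drop = FALSE],
                 explained_variance = ev[seq_len(n_comps)],
                 loadings = loadings, labels = labels),
            class = "MotionPCA")
}
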