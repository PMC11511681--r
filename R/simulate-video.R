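#' Specification for a synthetic migration video
#'
#' Describes a 2-D time-lapse of Gaussian-blob cells advecting from a motion
#' source towards a sink at a given mean speed, with optional logistic
#' slow-down after a deceleration onset, positional noise and intensity
#' noise. Defaults emulate a registered confocal time-lapse of GFP-labelled
#' migrating cells at desk scale.
#'
#' @param frame_shape (height, width) in pixels.
#' @param n_frames number of frames.
#' @param frame_interval minutes between frames (metadata; default 6).
#' @param n_cells number of cells.
#' @param blob_sigma Gaussian blob sigma in pixels.
#' @param source_position,sink_position (x, y) pixel coordinates; equal
#'   positions give a stationary control.
#' @param mean_speed pixels per frame (>= 0).
#' @param deceleration_onset frame index after which speed decays
#'   logistically (Inf = no deceleration).
#' @param deceleration_tau logistic decay time constant in frames.
#' @param positional_noise_sigma per-frame positional jitter (pixels).
#' @param intensity_noise_sigma additive intensity noise (a.u.).
#' @param cell_spread sigma of the initial cell scatter around the source.
#' @param seed integer seed; fixes the output bit-for-bit.
#' @return A `VideoSimSpec` list.
#' @export
video_sim_spec <- function(frame_shape = c(96, 96), n_frames = 40,
                           frame_interval = 6, n_cells = 40,
                           blob_sigma = 2.5,
                           source_position = c(30, 70),
                           sink_position = c(70, 30),
                           mean_speed = 1.5,
                           deceleration_onset = Inf,
                           deceleration_tau = 3,
                           positional_noise_sigma = 0,
                           intensity_noise_sigma = 0,
                           cell_spread = 12,
                           seed = 1) {
  stopifnot(length(frame_shape) == 2, all(frame_shape > 0), n_frames >= 1,
            n_cells >= 1, mean_speed >= 0, blob_sigma > 0)
  inside <- function(p) all(p >= 1) && p[1] <= frame_shape[2] &&
    p[2] <= frame_shape[1]
  if (!inside(source_position) || !inside(sink_position))
    stop("source and sink positions must lie inside the frame")
  out <- as.list(environment())
  out$inside <- NULL
  class(out) <- "VideoSimSpec"
  out
}

#' Simulate a migration time-lapse video
#'
#' Cells start scattered around the source and advect towards the sink at
#' `mean_speed` pixels/frame (arriving cells stop at the sink), with a
#' logistic speed decay after `deceleration_onset`. Frames render each cell
#' as an isotropic Gaussian blob on a black background — enough texture for
#' dense optical flow.
#'
#' @param spec a [video_sim_spec()].
#' @return list with `frames` (rows x cols x n_frames array, non-negative
#'   floats) and `truth` (exact per-cell trajectories `x`, `y` as cells x
#'   frames matrices, plus the per-frame commanded speed).
#' @export
simulate_migration_video <- function(spec) {
  stopifnot(inherits(spec, "VideoSimSpec"))
  with_seed(spec$seed, simulate_video_impl(spec))
}

simulate_video_impl <- function(spec) {
  h <- spec$frame_shape[1]; w <- spec$frame_shape[2]
  nf <- spec$n_frames; nc <- spec$n_cells
  src <- spec$source_position; snk <- spec$sink_position
  px <- pmin(pmax(src[1] + rnorm(nc, 0, spec$cell_spread), 2), w - 1)
  py <- pmin(pmax(src[2] + rnorm(nc, 0, spec$cell_spread), 2), h - 1)
  X <- matrix(NA_real_, nc, nf); Y <- matrix(NA_real_, nc, nf)
  X[, 1] <- px; Y[, 1] <- py
  speed_t <- numeric(max(nf - 1, 0))
  for (t in seq_len(nf - 1)) {
    s <- if (is.finite(spec$deceleration_onset))
      spec$mean_speed * plogis((spec$deceleration_onset - t) /
                                 spec$deceleration_tau)
    else spec$mean_speed
    speed_t[t] <- s
    dx <- snk[1] - X[, t]; dy <- snk[2] - Y[, t]
    dd <- sqrt(dx^2 + dy^2)
    step <- pmin(s, dd)
    ux <- ifelse(dd > 0, dx / dd, 0); uy <- ifelse(dd > 0, dy / dd, 0)
    nx <- X[, t] + step * ux
    ny <- Y[, t] + step * uy
    if (spec$positional_noise_sigma > 0) {
      nx <- nx + rnorm(nc, 0, spec$positional_noise_sigma)
      ny <- ny + rnorm(nc, 0, spec$positional_noise_sigma)
    }
    X[, t + 1] <- pmin(pmax(nx, 1), w)
    Y[, t + 1] <- pmin(pmax(ny, 1), h)
  }
  frames <- array(0, dim = c(h, w, nf))
  rad <- ceiling(4 * spec$blob_sigma)
  for (t in seq_len(nf)) {
    fr <- matrix(0, h, w)
    for (i in seq_len(nc)) {
      r0 <- max(1, floor(Y[i, t] - rad)); r1 <- min(h, ceiling(Y[i, t] + rad))
      c0 <- max(1, floor(X[i, t] - rad)); c1 <- min(w, ceiling(X[i, t] + rad))
      rr <- r0:r1; cc <- c0:c1
      fr[rr, cc] <- fr[rr, cc] +
        exp(-outer((rr - Y[i, t])^2, (cc - X[i, t])^2, `+`) /
              (2 * spec$blob_sigma^2))
    }
    if (spec$intensity_noise_sigma > 0)
      fr <- fr + matrix(rnorm(h * w, 0, spec$intensity_noise_sigma), h, w)
    frames[, , t] <- pmax(fr, 0)
  }
  list(frames = frames,
       truth = list(x = X, y = Y, speed = speed_t,
                    source = src, sink = snk, seed = spec$seed))
}

#' Write a frame stack as a multi-page TIFF
#'
#' Frames are rescaled to \[0, 1\] jointly (preserving relative intensity)
#' before writing as 16-bit pages.
#'
#' @param frames rows x cols x time array or list of matrices.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_video_tiff <- function(frames, path) {
  fl <- frames_as_list(frames)
  mx <- max(vapply(fl, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(fl, function(f) f / mx), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF file path (single-channel pages).
#' @return rows x cols x time array.
#' @export
read_video_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
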