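# Contrast-frame rendering: turns 3D bubble events into the 2D acquisition
# stream the localization chain consumes, with slab gating, an isotropic
# Gaussian in-plane point-spread function, tissue-motion displacement and
# additive Gaussian noise.

new_frame_stack <- function(frames, grid, frame_rate, ground_truth = NULL) {
  structure(list(frames = frames, grid = grid, pixel_size = grid$pixel_size,
                 frame_rate = frame_rate, ground_truth = ground_truth),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d px (%.3f mm), %g Hz\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_rate))
  invisible(x)
}

# world -> slab coordinates for a slab placed by `placement`
# (slab-to-world similarity transform)
events_to_slab <- function(events, placement) {
  p <- apply_transform(invert_transform(placement),
                       cbind(events$x_mm, events$y_mm, events$z_mm))
  data.frame(frame = events$frame, axial = p[, 1], lateral = p[, 2],
             elev = p[, 3], bubble_id = events$bubble_id,
             segment_id = events$segment_id, amplitude = events$amplitude)
}

#' Render contrast frames from bubble events
#'
#' Each event inside the slab (elevation within `[-thickness/2,
#' thickness/2)`) contributes an isotropic Gaussian blob of width
#' `psf_sigma` at its in-plane position, displaced by the tissue-motion
#' field; additive Gaussian noise of standard deviation `noise_level` is
#' added per pixel. The returned ground truth lists the motion-free
#' in-plane positions of the rendered (in-slab) events.
#'
#' @param events events from [sample_bubble_events()] (world mm).
#' @param slab a [slab_geometry()].
#' @param placement slab-to-world `similarity_transform` positioning the
#'   slab in the phantom.
#' @param pixel_size acquisition pixel size, mm.
#' @param psf_sigma Gaussian point-spread width, mm.
#' @param noise_level additive Gaussian noise s.d. (a.u.).
#' @param motion optional `motion_field` on the acquisition grid.
#' @param n_frames number of frames (default from the events attribute).
#' @param frame_rate Hz (default from the events attribute, else 54).
#' @param seed integer seed for the noise stream.
#' @return a `frame_stack`; `$ground_truth` holds the motion-free in-plane
#'   positions (`frame`, `axial`, `lateral`, `bubble_id`, `segment_id`,
#'   `amplitude`).
#' @export
render_contrast_frames <- function(events, slab, placement =
                                     similarity_transform(),
                                   pixel_size = 0.1, psf_sigma = 0.15,
                                   noise_level = 0, motion = NULL,
                                   n_frames = attr(events, "n_frames"),
                                   frame_rate = attr(events, "frame_rate"),
                                   seed = 1) {
  if (psf_sigma <= 0) stop("`psf_sigma` must be > 0", call. = FALSE)
  if (is.null(n_frames)) n_frames <- max(events$frame, 1L)
  if (is.null(frame_rate)) frame_rate <- 54
  grid <- grid_for_slab(slab, pixel_size)
  ev <- events_to_slab(events, placement)
  inslab <- ev$elev >= -slab$thickness / 2 & ev$elev < slab$thickness / 2
  ev <- ev[inslab, , drop = FALSE]
  frames <- array(0, c(grid$nrow, grid$ncol, n_frames))
  win <- ceiling(4 * psf_sigma / pixel_size)
  for (fr in seq_len(n_frames)) {
    sub <- ev[ev$frame == fr, , drop = FALSE]
    if (nrow(sub) == 0) next
    pos <- cbind(sub$axial, sub$lateral)
    if (!is.null(motion)) pos <- pos + motion_at(motion, fr, pos)
    for (b in seq_len(nrow(sub))) {
      ij <- grid_index(grid, pos[b, , drop = FALSE])
      ilo <- max(1L, ij[1] - win); ihi <- min(grid$nrow, ij[1] + win)
      jlo <- max(1L, ij[2] - win); jhi <- min(grid$ncol, ij[2] + win)
      if (ilo > ihi || jlo > jhi) next   # blob entirely off-grid
      ii <- ilo:ihi; jj <- jlo:jhi
      cx <- grid$origin[1] + (ii - 0.5) * pixel_size
      cy <- grid$origin[2] + (jj - 0.5) * pixel_size
      blob <- sub$amplitude[b] *
        exp(-outer((cx - pos[b, 1])^2, (cy - pos[b, 2])^2, "+") /
              (2 * psf_sigma^2))
      frames[ii, jj, fr] <- frames[ii, jj, fr] + blob
    }
  }
  if (noise_level > 0) {
    with_seed(derive_seed(seed, "render-noise"), {
      frames <- frames + array(stats::rnorm(length(frames), 0, noise_level),
                               dim(frames))
    })
  }
  gt <- ev[, c("frame", "axial", "lateral", "bubble_id", "segment_id",
               "amplitude")]
  rownames(gt) <- NULL
  new_frame_stack(frames, grid, frame_rate, ground_truth = gt)
}

#' Render speckle-texture frames for motion estimation
#'
#' B-mode-like frames: a fixed spatially correlated noise texture advected
#' by the motion field, used to exercise the block-matching motion
#' estimator.
#'
#' @param grid acquisition [raster_grid()].
#' @param motion a `motion_field`.
#' @param n_frames number of frames.
#' @param corr_scale texture correlation length, mm.
#' @param seed integer seed.
#' @return a `frame_stack`.
#' @export
render_speckle_frames <- function(grid, motion, n_frames,
                                  corr_scale = 0.4, seed = 1) {
  with_seed(derive_seed(seed, "speckle"), {
    # fine texture: smoothed white noise on a half-pixel-denser grid so the
    # advected lookup stays well-defined under sub-pixel shifts
    pad <- 4L
    big <- raster_grid(grid$nrow + 2 * pad, grid$ncol + 2 * pad,
                       grid$pixel_size,
                       origin = grid$origin - pad * grid$pixel_size)
    tex <- matrix(stats::rnorm(big$nrow * big$ncol), big$nrow, big$ncol)
    k <- max(1L, round(corr_scale / grid$pixel_size))
    if (k > 1) {
      kern <- stats::dnorm(seq(-2, 2, length.out = 2 * k + 1))
      tex <- apply(tex, 2, stats::filter, filter = kern, sides = 2)
      tex <- t(apply(t(tex), 2, stats::filter, filter = kern, sides = 2))
      tex[is.na(tex)] <- 0
    }
    ij <- as.matrix(expand.grid(seq_len(grid$nrow), seq_len(grid$ncol)))
    ctr <- grid_center(grid, ij)
    frames <- array(0, c(grid$nrow, grid$ncol, n_frames))
    for (fr in seq_len(n_frames)) {
      disp <- motion_at(motion, fr, ctr)
      val <- grid_bilinear(tex, big, ctr - disp)
      frames[, , fr][ij] <- val
    }
    new_frame_stack(frames, grid, frame_rate = NA_real_)
  })
}
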