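# Tissue motion fields: synthesis (phantom side) and a shared parametric /
# per-frame representation with bilinear evaluation.
#
# A `motion_field` holds per-frame in-plane displacement rasters (mm) on an
# acquisition grid, either explicitly (`u`, `v` arrays, one slice per frame)
# or as a separable pattern times a periodic temporal weight (the synthetic
# generator). `motion_at()` is the single evaluation entry point.

new_motion_field <- function(grid, n_frames, u = NULL, v = NULL,
                             u_pattern = NULL, v_pattern = NULL,
                             weights = NULL, smoothness_scale = NA_real_) {
  structure(list(grid = grid, n_frames = as.integer(n_frames), u = u, v = v,
                 u_pattern = u_pattern, v_pattern = v_pattern,
                 weights = weights, smoothness_scale = smoothness_scale),
            class = "motion_field")
}

# per-frame displacement matrices (axial = u, lateral = v)
motion_frame <- function(motion, frame) {
  if (!is.null(motion$weights)) {
    w <- motion$weights[(frame - 1L) %% length(motion$weights) + 1L]
    list(u = motion$u_pattern * w, v = motion$v_pattern * w)
  } else {
    k <- min(frame, dim(motion$u)[3])
    list(u = motion$u[, , k], v = motion$v[, , k])
  }
}

#' Evaluate a motion field at image points
#'
#' Bilinear interpolation of the per-frame displacement rasters; points
#' outside the grid use the nearest-edge displacement.
#'
#' @param motion a `motion_field`.
#' @param frame 1-based frame index.
#' @param pts n x 2 matrix of (axial, lateral) mm points.
#' @return n x 2 matrix of (axial, lateral) displacements, mm.
#' @export
motion_at <- function(motion, frame, pts) {
  mf <- motion_frame(motion, frame)
  cbind(grid_bilinear(mf$u, motion$grid, pts),
        grid_bilinear(mf$v, motion$grid, pts))
}

#' Generate a smooth periodic synthetic tissue-motion field
#'
#' A spatially smooth random displacement pattern (bilinear interpolation of
#' coarse Gaussian knots spaced `smoothness_scale` apart) oscillating
#' sinusoidally over `period` frames. The displacement magnitude is bounded
#' by `amplitude` everywhere and the discrete spatial gradient is bounded by
#' `amplitude / smoothness_scale`.
#'
#' @param grid acquisition [raster_grid()].
#' @param amplitude peak displacement magnitude, mm (in vivo renal motion is
#'   an unquantified few tenths of a mm; the pipeline default is 0.3).
#' @param period temporal period in frames.
#' @param smoothness_scale spatial correlation length, mm.
#' @param n_frames number of frames the field will be applied to.
#' @param seed integer seed.
#' @return a `motion_field`.
#' @export
generate_motion_field <- function(grid, amplitude, period = 20,
                                  smoothness_scale = 3, n_frames = period,
                                  seed = 1) {
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (period < 1) stop("`period` must be >= 1", call. = FALSE)
  with_seed(derive_seed(seed, "motion"), {
    make_pattern <- function() {
      nk_r <- max(2, ceiling(grid$nrow * grid$pixel_size /
                               smoothness_scale) + 1)
      nk_c <- max(2, ceiling(grid$ncol * grid$pixel_size /
                               smoothness_scale) + 1)
      knots <- matrix(stats::rnorm(nk_r * nk_c), nk_r, nk_c)
      kg <- raster_grid(nk_r, nk_c, smoothness_scale,
                        origin = c(-smoothness_scale / 2,
                                   -smoothness_scale / 2))
      ctr <- grid_center(grid, as.matrix(expand.grid(seq_len(grid$nrow),
                                                     seq_len(grid$ncol))))
      matrix(grid_bilinear(knots, kg, ctr), grid$nrow, grid$ncol)
    }
    up <- make_pattern(); vp <- make_pattern()
    mag <- sqrt(up^2 + vp^2)
    scale <- if (max(mag) > 0) amplitude / max(mag) else 0
    up <- up * scale; vp <- vp * scale
    # enforce the gradient bound amplitude / smoothness_scale
    gb <- function(m) {
      g <- max(abs(diff(m)) , abs(t(diff(t(m)))), 0) / grid$pixel_size
      g
    }
    gmax <- max(gb(up), gb(vp))
    bound <- amplitude / smoothness_scale
    if (gmax > bound && gmax > 0) {
      f <- bound / gmax
      up <- up * f; vp <- vp * f
    }
    w <- sin(2 * pi * (seq_len(period) - 1) / period)
    new_motion_field(grid, n_frames, u_pattern = up, v_pattern = vp,
                     weights = w, smoothness_scale = smoothness_scale)
  })
}
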