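# Speckle-tracking motion estimation: block-matching normalized
# cross-correlation against a reference frame with parabolic sub-pixel
# peak refinement, invalid-block inpainting and spatial smoothing.

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

# parabolic refinement around an integer peak given scores at -1, 0, +1
parabolic_offset <- function(sm1, s0, sp1) {
  den <- sm1 - 2 * s0 + sp1
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (sm1 - sp1) / den
  max(min(off, 0.5), -0.5)
}

#' Estimate tissue motion by speckle tracking
#'
#' Block-matching NCC of every frame against the reference frame. Each
#' block's best integer shift is refined to sub-pixel precision with a
#' parabolic fit; blocks with flat texture are marked invalid and inpainted
#' from their valid neighbors; the block-center field is smoothed and
#' bilinearly upsampled to the full grid.
#'
#' @param stack a `frame_stack` of speckle (B-mode-like) frames.
#' @param reference_index frame used as the motion reference.
#' @param block_size block edge, pixels.
#' @param search_radius maximum shift searched, pixels.
#' @param smooth smooth the block field with a 3x3 mean filter.
#' @return a `motion_field` with per-frame displacement rasters (mm).
#' @export
estimate_motion <- function(stack, reference_index = 1L, block_size = 16L,
                            search_radius = 4L, smooth = TRUE) {
  frames <- stack$frames
  d <- dim(frames)
  if (reference_index < 1 || reference_index > d[3])
    stop("`reference_index` out of range", call. = FALSE)
  if (block_size >= min(d[1], d[2]))
    stop("`block_size` must be smaller than the frame", call. = FALSE)
  ref <- frames[, , reference_index]
  r <- search_radius
  bi <- seq(1 + r, d[1] - block_size - r + 1, by = block_size)
  bj <- seq(1 + r, d[2] - block_size - r + 1, by = block_size)
  if (!length(bi) || !length(bj))
    stop("frame too small for the requested block/search sizes",
         call. = FALSE)
  nb_r <- length(bi); nb_c <- length(bj)
  ps <- stack$grid$pixel_size
  # block-center grid geometry for upsampling: block (1,1) center sits at
  # origin + (bi[1] - 1 + block_size/2) * ps
  bgrid <- raster_grid(nb_r, nb_c, block_size * ps,
                       origin = stack$grid$origin +
                         c((bi[1] - 1) * ps, (bj[1] - 1) * ps))
  u <- array(0, c(d[1], d[2], d[3]))
  v <- array(0, c(d[1], d[2], d[3]))
  ij_full <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2])))
  ctr_full <- grid_center(stack$grid, ij_full)
  for (fr in seq_len(d[3])) {
    bu <- matrix(NA_real_, nb_r, nb_c)
    bv <- matrix(NA_real_, nb_r, nb_c)
    if (fr != reference_index) {
      cur <- frames[, , fr]
      for (a in seq_len(nb_r)) for (b in seq_len(nb_c)) {
        i0 <- bi[a]; j0 <- bj[b]
        blk <- ref[i0:(i0 + block_size - 1), j0:(j0 + block_size - 1)]
        if (stats::sd(blk) < 1e-12) next   # flat texture: invalid
        scores <- matrix(NA_real_, 2 * r + 1, 2 * r + 1)
        for (di in -r:r) for (dj in -r:r) {
          cand <- cur[(i0 + di):(i0 + di + block_size - 1),
                      (j0 + dj):(j0 + dj + block_size - 1)]
          scores[di + r + 1, dj + r + 1] <- ncc(blk, cand)
        }
        if (all(is.na(scores))) next
        best <- which(scores == max(scores, na.rm = TRUE), arr.ind = TRUE)[1, ]
        sdi <- best[1] - r - 1; sdj <- best[2] - r - 1
        # sub-pixel refinement (skipped at the search border and for
        # perfect integer matches, where the parabola vertex is spurious)
        offi <- offj <- 0
        if (scores[best[1], best[2]] >= 1 - 1e-9) {
          bu[a, b] <- sdi * ps
          bv[a, b] <- sdj * ps
          next
        }
        if (best[1] > 1 && best[1] < 2 * r + 1)
          offi <- parabolic_offset(scores[best[1] - 1, best[2]],
                                   scores[best[1], best[2]],
                                   scores[best[1] + 1, best[2]])
        if (best[2] > 1 && best[2] < 2 * r + 1)
          offj <- parabolic_offset(scores[best[1], best[2] - 1],
                                   scores[best[1], best[2]],
                                   scores[best[1], best[2] + 1])
        bu[a, b] <- (sdi + offi) * ps
        bv[a, b] <- (sdj + offj) * ps
      }
      bu <- inpaint_na(bu); bv <- inpaint_na(bv)
      if (smooth) { bu <- mean_filter3(bu); bv <- mean_filter3(bv) }
    } else {
      bu[] <- 0; bv[] <- 0
    }
    bu[is.na(bu)] <- 0; bv[is.na(bv)] <- 0
    u[, , fr][ij_full] <- grid_bilinear(bu, bgrid, ctr_full)
    v[, , fr][ij_full] <- grid_bilinear(bv, bgrid, ctr_full)
  }
  new_motion_field(stack$grid, d[3], u = u, v = v)
}

# fill NA entries from the mean of valid 8-neighbors, iterating outward
inpaint_na <- function(m) {
  if (!anyNA(m)) return(m)
  if (all(is.na(m))) return(m)
  for (it in 1:(nrow(m) + ncol(m))) {
    nas <- which(is.na(m), arr.ind = TRUE)
    if (nrow(nas) == 0) break
    filled <- FALSE
    for (k in seq_len(nrow(nas))) {
      i <- nas[k, 1]; j <- nas[k, 2]
      ni <- max(1, i - 1):min(nrow(m), i + 1)
      nj <- max(1, j - 1):min(ncol(m), j + 1)
      vals <- m[ni, nj]
      if (any(!is.na(vals))) {
        m[i, j] <- mean(vals, na.rm = TRUE)
        filled <- TRUE
      }
    }
    if (!filled) break
  }
  m
}

mean_filter3 <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ni <- max(1, i - 1):min(nrow(m), i + 1)
    nj <- max(1, j - 1):min(ncol(m), j + 1)
    out[i, j] <- mean(m[ni, nj], na.rm = TRUE)
  }
  out
}
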