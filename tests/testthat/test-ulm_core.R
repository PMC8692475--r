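# ULM processing chain: localization, motion estimation/compensation,
# Kalman-gated linking, track maps, flow separation and statistics.

gauss_frame <- function(grid, centers, sigma = 0.15, amps = 1) {
  cx <- (seq_len(grid$nrow) - 0.5) * grid$pixel_size + grid$origin[1]
  cy <- (seq_len(grid$ncol) - 0.5) * grid$pixel_size + grid$origin[2]
  f <- matrix(0, grid$nrow, grid$ncol)
  centers <- rbind(centers)
  amps <- rep_len(amps, nrow(centers))
  for (k in seq_len(nrow(centers)))
    f <- f + amps[k] * exp(-outer((cx - centers[k, 1])^2,
                                  (cy - centers[k, 2])^2, "+") /
                             (2 * sigma^2))
  f
}

test_that("localization: symmetric blobs, empty frames, two-blob oracle", {
  g <- raster_grid(60, 80, 0.1)
  d <- localize_bubbles(gauss_frame(g, c(2.00, 5.00)), g, 0.5)
  expect_identical(nrow(d), 1L)
  expect_lt(abs(d$axial - 2.00), 0.05 * 0.1)
  expect_lt(abs(d$lateral - 5.00), 0.05 * 0.1)

  expect_identical(nrow(localize_bubbles(matrix(0, 20, 20),
                                         raster_grid(20, 20, 0.1), 0.5)),
                   0L)

  # two blobs 1 mm apart: one detection each, at the component centroids
  ctrs <- rbind(c(2.03, 4.01), c(2.03, 5.01))
  d2 <- localize_bubbles(gauss_frame(g, ctrs, sigma = 0.1), g, 0.5)
  expect_identical(nrow(d2), 2L)
  d2 <- d2[order(d2$lateral), ]
  for (k in 1:2) {
    expect_lt(abs(d2$axial[k] - ctrs[k, 1]), 0.01)
    expect_lt(abs(d2$lateral[k] - ctrs[k, 2]), 0.01)
  }
  expect_warning(localize_bubbles(gauss_frame(g, c(2, 5)), g, 2,
                                  mode = "absolute"), "threshold")
})

test_that("localization precision degrades monotonically with noise", {
  g <- raster_grid(21, 21, 0.1)
  rms_at_noise <- function(noise_sd) {
    set.seed(40)
    errs <- vapply(1:150, function(i) {
      pos <- c(1.05, 1.05) + stats::runif(2, -0.05, 0.05)
      f <- gauss_frame(g, pos) +
        matrix(stats::rnorm(441, 0, noise_sd), 21, 21)
      d <- localize_bubbles(f, g, 0.5)
      d <- d[which.max(d$amplitude), ]
      sqrt(sum((c(d$axial, d$lateral) - pos)^2))
    }, 1)
    sqrt(mean(errs^2))
  }
  r <- vapply(c(0, 0.03, 0.1), rms_at_noise, 1)
  expect_true(all(diff(r) > 0))
})

test_that("motion estimation recovers integer, zero and sub-pixel shifts", {
  g <- raster_grid(80, 80, 0.1)
  still <- generate_motion_field(g, 0, n_frames = 1, seed = 1)
  tex <- render_speckle_frames(g, still, 1, seed = 3)$frames[, , 1]

  # identical frames: zero field
  fr <- array(0, c(80, 80, 2)); fr[, , 1] <- tex; fr[, , 2] <- tex
  m0 <- estimate_motion(srusct:::new_frame_stack(fr, g, 54), 1,
                        block_size = 16, search_radius = 4)
  expect_identical(max(abs(m0$u)), 0)

  # integer (3, -2) pixel shift recovered exactly at interior blocks
  sh <- matrix(0, 80, 80)
  sh[4:80, 1:78] <- tex[1:77, 3:80]
  fr[, , 2] <- sh
  m1 <- estimate_motion(srusct:::new_frame_stack(fr, g, 54), 1,
                        block_size = 16, search_radius = 4, smooth = FALSE)
  got <- motion_at(m1, 2, cbind(c(3, 4, 5), c(3, 4, 5)))
  expect_equal(got, cbind(rep(0.3, 3), rep(-0.2, 3)), tolerance = 1e-9)

  # 0.4-pixel sub-pixel shift within 0.1 pixel; oracle = dense NCC of the
  # bilinearly shifted texture evaluated on a 10x upsampled shift lattice
  big <- raster_grid(96, 96, 0.1, origin = c(-0.8, -0.8))
  btex <- render_speckle_frames(big, generate_motion_field(
    big, 0, n_frames = 1, seed = 1), 1, seed = 5)$frames[, , 1]
  ij <- as.matrix(expand.grid(seq_len(80), seq_len(80)))
  ctr <- srusct:::grid_center(g, ij)
  sample_shifted <- function(dx_px, dy_px) {
    v <- srusct:::grid_bilinear(btex, big,
                                cbind(ctr[, 1] - dx_px * 0.1,
                                      ctr[, 2] - dy_px * 0.1))
    matrix(v, 80, 80)
  }
  ref <- sample_shifted(0, 0)
  shifted <- sample_shifted(0.4, 0)
  # oracle estimate of the global shift
  cand <- seq(-1, 1, by = 0.1)
  scores <- vapply(cand, function(dx)
    stats::cor(as.vector(sample_shifted(dx, 0)), as.vector(shifted)), 1)
  expect_equal(cand[which.max(scores)], 0.4, tolerance = 1e-9)
  fr2 <- array(0, c(80, 80, 2)); fr2[, , 1] <- ref; fr2[, , 2] <- shifted
  m2 <- estimate_motion(srusct:::new_frame_stack(fr2, g, 54), 1,
                        block_size = 16, search_radius = 4, smooth = FALSE)
  got2 <- motion_at(m2, 2, cbind(4, 4))
  expect_lt(abs(got2[1] - 0.04), 0.1 * 0.1)
  expect_lt(abs(got2[2] - 0), 0.1 * 0.1)
})

test_that("flat-texture blocks are inpainted from neighbors", {
  g <- raster_grid(80, 80, 0.1)
  still <- generate_motion_field(g, 0, n_frames = 1, seed = 1)
  tex <- render_speckle_frames(g, still, 1, seed = 7)$frames[, , 1]
  tex[30:50, 30:50] <- 0.5   # flat patch spanning a block
  sh <- matrix(0, 80, 80); sh[2:80, ] <- tex[1:79, ]
  fr <- array(0, c(80, 80, 2)); fr[, , 1] <- tex; fr[, , 2] <- sh
  m <- estimate_motion(srusct:::new_frame_stack(fr, g, 54), 1,
                       block_size = 16, search_radius = 4)
  got <- motion_at(m, 2, cbind(4, 4))
  expect_lt(abs(got[1] - 0.1), 0.05)
  expect_true(all(is.finite(m$u)))
})

test_that("compensation applies the negative interpolated displacement", {
  det <- det_df(c(1, 1, 2), c(1.0, 2.0, 1.5), c(1.0, 2.0, 2.5))
  g <- raster_grid(40, 40, 0.1)
  zero <- generate_motion_field(g, 0, n_frames = 2, seed = 1)
  out <- compensate_detections(det, zero)
  expect_equal(out$axial, det$axial)
  expect_true(all(out$compensated))

  # uniform +0.2 mm axial displacement: positions shift back by -0.2
  u <- array(0.2, c(40, 40, 2)); v <- array(0, c(40, 40, 2))
  uni <- srusct:::new_motion_field(g, 2, u = u, v = v)
  out2 <- compensate_detections(det, uni)
  expect_equal(out2$axial, det$axial - 0.2, tolerance = 1e-12)
  expect_equal(out2$lateral, det$lateral, tolerance = 1e-12)
})

test_that("linking gates and minimum length follow the tracking contract", {
  p <- tracking_params()
  expect_identical(p$max_link_distance, 278)
  expect_identical(p$min_track_frames, 3L)

  # three detections 100 um apart in consecutive frames: one track
  tr <- link_tracks(det_df(1:3, c(0, 0, 0), c(0, 0.1, 0.2)), p, 54)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$path_length_um, 200, tolerance = 1e-9)
  expect_identical(tr[[1]]$n_links, 2L)

  # only two consecutive frames: no track
  expect_length(link_tracks(det_df(1:2, c(0, 0), c(0, 0.1)), p, 54), 0)

  # 300 um exceeds the 278 um gate
  expect_length(link_tracks(det_df(1:2, c(0, 0), c(0, 0.3)), p, 54), 0)

  # a frame gap breaks a track (consecutive frames required)
  tr_gap <- link_tracks(det_df(c(1, 2, 4, 5, 6), rep(0, 5),
                               c(0, 0.1, 0.2, 0.3, 0.4)), p, 54)
  expect_length(tr_gap, 1)
  expect_identical(tr_gap[[1]]$detections$frame, c(4L, 5L, 6L))

  expect_error(tracking_params(max_link_distance = 0), "max_link_distance")
  expect_error(tracking_params(min_track_frames = 1), "min_track_frames")
})

test_that("gate invariants hold on every tracking run", {
  set.seed(11)
  for (rep in 1:5) {
    det <- det_df(sample(1:30, 120, replace = TRUE),
                  stats::runif(120, 0, 5), stats::runif(120, 0, 5))
    det <- det[order(det$frame), ]
    tr <- link_tracks(det, tracking_params(), 54)
    for (t_ in tr) {
      r <- t_$detections
      expect_gte(nrow(r), 3)
      expect_true(all(diff(r$frame) == 1L))
      links <- sqrt(diff(r$axial)^2 + diff(r$lateral)^2) * 1000
      expect_true(all(links <= 278 + 1e-9))
    }
  }
})

test_that("tracker matches the exhaustive-assignment oracle", {
  # sparse scene: <= 4 bubbles/frame in lanes spaced far beyond the gate
  gate <- tracking_params()
  for (sd in 1:6) {
    set.seed(sd)
    rows <- list()
    for (lane in 1:4) {
      t0 <- sample(1:10, 1)
      life <- sample(5:25, 1)
      pos <- c(stats::runif(1, 1, 4), lane * 3)
      for (fr in t0:(t0 + life)) {
        pos <- pos + c(stats::runif(1, -0.05, 0.05),
                       stats::runif(1, 0.05, 0.15))
        rows[[length(rows) + 1]] <- det_df(fr, pos[1], pos[2])
      }
    }
    det <- do.call(rbind, rows)
    det <- det[order(det$frame), ]
    got <- links_key(track_rows(link_tracks(det, gate, 54)))
    want <- links_key(oracle_tracker(det, 0.278, 3))
    expect_identical(got, want)
  }
})

test_that("track maps count traversals with direction and speed", {
  g <- raster_grid(20, 20, 0.1)
  # horizontal track crossing 10 pixels left to right: direction 0 degrees
  mk_track <- function(lat0, lat1, axial, frames = 3) {
    det_df(seq_len(frames), rep(axial, frames),
           seq(lat0, lat1, length.out = frames))
  }
  tr <- link_tracks(rbind(mk_track(0.25, 0.45, 0.55),
                          mk_track(1.05, 0.85, 0.75)),
                    tracking_params(), 54)
  expect_length(tr, 2)
  map <- render_track_maps(tr, g)
  nz <- which(map$intensity > 0, arr.ind = TRUE)
  # track 1 occupies row 6 (axial 0.55), direction 0
  r6 <- nz[nz[, 1] == 6, , drop = FALSE]
  expect_true(nrow(r6) >= 2)
  expect_true(all(abs(map$direction[r6]) < 1e-9))
  # track 2 runs the opposite way in row 8: direction 180
  r8 <- nz[nz[, 1] == 8, , drop = FALSE]
  expect_true(all(abs(abs(map$direction[r8]) - 180) < 1e-9))
  # additivity: duplicating a track doubles its pixels' counts
  tr2 <- c(tr, tr[1])
  class(tr2) <- "track_set"
  map2 <- render_track_maps(tr2, g)
  expect_identical(map2$intensity[r6], 2L * map$intensity[r6])
  # conservation: total intensity equals the sum of per-track pixel counts
  per_track <- vapply(tr, function(t_) {
    pts <- NULL
    r <- t_$detections
    for (k in seq_len(nrow(r) - 1))
      pts <- rbind(pts, srusct:::resample_polyline(
        rbind(c(r$axial[k], r$lateral[k]),
              c(r$axial[k + 1], r$lateral[k + 1])), 0.05))
    nrow(unique(srusct:::grid_index(g, pts)))
  }, 1L)
  expect_identical(sum(map$intensity), sum(per_track))
  # speed raster defined only where intensity > 0
  expect_true(all(is.na(map$speed[map$intensity == 0])))
})

test_that("flow separation classifies by angle to the reference", {
  g <- raster_grid(20, 20, 0.1)
  regions <- structure(list(
    labels = matrix("cortex", 20, 20),
    subregions = list(list(mask = matrix(TRUE, 20, 20),
                           reference_direction = 0, label = "cortex")),
    grid = g), class = "region_label_map")
  fwd <- link_tracks(det_df(1:3, rep(1, 3), c(0.2, 0.4, 0.6)),
                     tracking_params(), 54)
  bwd <- link_tracks(det_df(1:3, rep(1.5, 3), c(0.6, 0.4, 0.2)),
                     tracking_params(), 54)
  both <- c(fwd, bwd); class(both) <- "track_set"
  sep <- separate_by_flow(both, regions)
  expect_length(sep$artery, 1)
  expect_length(sep$vein, 1)
  expect_equal(sep$artery[[1]]$mean_direction, 0)
  expect_equal(abs(sep$vein[[1]]$mean_direction), 180)
})

test_that("separation accuracy on a well-separated phantom exceeds 0.95", {
  cfg <- phantom_config(n_cortical_per_arcuate = 0, n_vasa_bundles = 0,
                        vein_offset_factor = 3)
  ph <- generate_kidney_phantom(cfg, seed = 7)
  ev <- sample_bubble_events(ph, 0.1, 5, 54, seed = 7)
  slab <- slab_geometry()
  pl <- srusct:::default_placement(ph, slab)
  st <- render_contrast_frames(ev, slab, pl, pixel_size = 0.1,
                               psf_sigma = 0.12, noise_level = 0.01,
                               seed = 7)
  det <- localize_stack(st, 0.5, min_amplitude = 0.1)
  tr <- link_tracks(det, tracking_params(), 54)
  reg <- region_label_map(ph, slab, pl, grid_for_slab(slab, 0.05))
  sep <- separate_by_flow(tr, reg)
  gt <- st$ground_truth
  side_of <- vapply(ph$segments, function(s) s$side, "")
  truth <- vapply(tr, function(t_) {
    r <- t_$detections
    sides <- character(0)
    for (k in seq_len(nrow(r))) {
      sub <- gt[gt$frame == r$frame[k], ]
      if (nrow(sub) == 0) next
      d <- sqrt((sub$axial - r$axial[k])^2 + (sub$lateral - r$lateral[k])^2)
      if (min(d) < 0.1)
        sides <- c(sides, side_of[sub$segment_id[which.min(d)]])
    }
    if (!length(sides)) NA_character_
    else names(sort(table(sides), decreasing = TRUE))[1]
  }, "")
  ok <- !is.na(truth)
  expect_gt(sum(ok), 20)
  expect_gte(mean(sep$assignments$side[ok] == truth[ok]), 0.95)
})

test_that("track statistics match a direct recomputation", {
  tr <- link_tracks(det_df(1:3, c(0, 0, 0), c(0, 0.1, 0.2)),
                    tracking_params(), 54)
  st <- track_statistics(tr)
  expect_identical(st$n_tracks, 1L)
  expect_identical(st$n_links, 2L)
  expect_equal(st$median_path_length_um, 200, tolerance = 1e-9)

  empty <- structure(list(), class = "track_set")
  st0 <- track_statistics(empty)
  expect_identical(st0$n_tracks, 0L)
  expect_true(st0$undefined)

  # 100 simulated tracks: medians equal the sort-based oracle
  set.seed(21)
  rows <- list()
  fr0 <- 1
  for (k in 1:100) {
    n <- sample(3:8, 1)
    ax <- cumsum(c(stats::runif(1, 0, 5), stats::runif(n - 1, -0.05, 0.05)))
    lat <- cumsum(c(stats::runif(1, 0, 5), stats::runif(n - 1, 0.02, 0.1)))
    rows[[k]] <- det_df(fr0:(fr0 + n - 1), ax, lat)
    fr0 <- fr0 + n + 2
  }
  tr100 <- link_tracks(do.call(rbind, rows), tracking_params(), 54)
  expect_length(tr100, 100)
  st100 <- track_statistics(tr100)
  lens <- sort(vapply(tr100, function(t_) t_$path_length_um, 1))
  n <- length(lens)
  med_oracle <- if (n %% 2 == 1) lens[(n + 1) / 2]
                else mean(lens[n / 2 + 0:1])
  expect_equal(st100$median_path_length_um, med_oracle, tolerance = 1e-12)
  expect_identical(st100$n_links,
                   sum(vapply(tr100, function(t_)
                     nrow(t_$detections) - 1L, 1L)))
})
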