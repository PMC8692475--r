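# Overlap metrics: ROI dilation, recoveries, mirrored control, skeletons,
# diameters, line profiles and superposition counting.

test_that("ROI dilation sweeps a disk along the centerline", {
  g <- raster_grid(40, 60, 0.1)
  cl <- list(list(points = cbind(2.05, seq(0.55, 5.55, 0.1)),
                  vessel_class = "arcuate", side = "vein"))
  roi <- dilate_to_roi(cl, list(`arcuate/vein` = 3 * 0.1), g, "vein")
  # straight line, radius 3 px: perpendicular width 2r + 1 = 7 px
  expect_identical(sum(roi$mask[, 30]), 7L)
  expect_identical(roi$side, "vein")
  expect_identical(roi$provenance, "original")

  expect_identical(sum(dilate_to_roi(list(), list(a = 1), g)$mask), 0L)
  expect_error(dilate_to_roi(cl, list(`segmental/vein` = 0.1), g),
               "arcuate/vein")
})

test_that("dilation equals the brute-force distance oracle for crossing lines", {
  g <- raster_grid(30, 30, 0.1)
  cls <- list(
    list(points = rbind(c(0.55, 0.55), c(2.55, 2.55)),
         vessel_class = "a", side = "artery"),
    list(points = rbind(c(2.35, 0.75), c(0.35, 2.75)),
         vessel_class = "b", side = "artery"))
  r <- 0.25
  roi <- dilate_to_roi(cls, list(a = r, b = r), g)
  ij <- as.matrix(expand.grid(seq_len(30), seq_len(30)))
  ctr <- srusct:::grid_center(g, ij)
  want <- pmin(srusct:::dist_to_polyline(ctr, cls[[1]]$points),
               srusct:::dist_to_polyline(ctr, cls[[2]]$points)) <= r + 1e-9
  got <- roi$mask[ij]
  # the swept-disk rasterization may differ from the exact distance oracle
  # only on boundary pixels whose center sits within half a resampling
  # step of the radius
  d <- pmin(srusct:::dist_to_polyline(ctr, cls[[1]]$points),
            srusct:::dist_to_polyline(ctr, cls[[2]]$points))
  boundary <- abs(d - r) <= g$pixel_size / 2
  expect_true(all(got[!boundary] == want[!boundary]))
  expect_gt(mean(got == want), 0.98)
})

test_that("centerline recovery measures arc-length fractions", {
  g <- raster_grid(20, 40, 0.1)
  full <- matrix(TRUE, 20, 40)
  roi <- structure(list(mask = full, grid = g, side = "vein",
                        provenance = "original"), class = "roi_mask")
  cl <- list(list(points = rbind(c(1, 0.5), c(1, 3.5))))
  expect_equal(centerline_recovery(cl, roi), 100)

  half <- full; half[, 21:40] <- FALSE   # right half (lateral >= 2) empty
  roi$mask <- half
  cl2 <- list(list(points = rbind(c(1, 0.0), c(1, 4.0))))
  expect_equal(centerline_recovery(cl2, roi), 50, tolerance = 1)

  roi$mask[] <- FALSE
  expect_equal(centerline_recovery(cl, roi), 0)

  und <- centerline_recovery(list(), roi)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("trackmap recovery equals the per-pixel counting oracle", {
  g <- raster_grid(25, 25, 0.1)
  set.seed(15)
  intensity <- matrix(rpois(625, 0.3), 25, 25)
  map <- structure(list(intensity = intensity, grid = g,
                        pixel_size = 0.1), class = "track_map")
  mask <- matrix(stats::runif(625) < 0.4, 25, 25)
  roi <- structure(list(mask = mask, grid = g, side = "artery",
                        provenance = "original"), class = "roi_mask")
  got <- trackmap_recovery(map, roi)
  want <- 100 * sum(intensity > 0 & mask) / sum(intensity > 0)
  expect_equal(got, want, tolerance = 1e-12)

  roi_all <- roi; roi_all$mask[] <- TRUE
  expect_equal(trackmap_recovery(map, roi_all), 100)
  roi_none <- roi; roi_none$mask <- !(intensity > 0)
  expect_equal(trackmap_recovery(map, roi_none), 0)

  map0 <- map; map0$intensity[] <- 0L
  und <- trackmap_recovery(map0, roi)
  expect_true(is.na(und) && attr(und, "undefined"))

  g2 <- raster_grid(10, 10, 0.1)
  roi_bad <- structure(list(mask = matrix(TRUE, 10, 10), grid = g2),
                       class = "roi_mask")
  expect_error(trackmap_recovery(map, roi_bad), "grids")
})

test_that("mirroring is an involution about the requested axis", {
  g <- raster_grid(8, 12, 0.1)
  m <- matrix(FALSE, 8, 12); m[3, 4] <- TRUE
  roi <- structure(list(mask = m, grid = g, side = "vein",
                        provenance = "original"), class = "roi_mask")
  mir <- mirror_roi(roi, "axial_center")
  expect_true(mir$mask[3, 12 - 4 + 1])
  expect_identical(sum(mir$mask), 1L)
  expect_identical(mir$provenance, "mirrored")
  expect_identical(mirror_roi(mir, "axial_center")$mask, roi$mask)

  mir2 <- mirror_roi(roi, "lateral_center")
  expect_true(mir2$mask[8 - 3 + 1, 4])

  sym <- roi; sym$mask[] <- FALSE; sym$mask[, 6:7] <- TRUE
  expect_identical(mirror_roi(sym, "axial_center")$mask, sym$mask)
})

test_that("skeletons find bar midlines and Y-junction topology", {
  g <- raster_grid(60, 60, 0.05)
  bar <- matrix(0L, 60, 60); bar[26:35, 6:54] <- 1L
  map <- structure(list(intensity = bar, grid = g, pixel_size = 0.05),
                   class = "track_map")
  sk <- skeleton_centerlines(map, min_branch_length = 0.5)
  expect_length(sk, 1)
  # midline of rows 26..35 is 30.5 -> axial (30.5 - 0.5) * 0.05 = 1.5
  expect_lt(max(abs(sk[[1]]$points[, 1] - 1.5)), 0.05 + 1e-9)

  empty <- structure(list(intensity = matrix(0L, 10, 10),
                          grid = raster_grid(10, 10, 0.05),
                          pixel_size = 0.05), class = "track_map")
  expect_warning(sk0 <- skeleton_centerlines(empty), "empty")
  expect_length(sk0, 0)

  # Y-shape: three branches meeting at one junction
  y <- matrix(0L, 60, 60)
  y[30:31, 5:30] <- 1L           # stem
  for (k in 0:22) { y[30 - k, 30 + k + 0:1] <- 1L }  # upper arm
  for (k in 0:22) { y[31 + k, 30 + k + 0:1] <- 1L }  # lower arm
  mapy <- structure(list(intensity = y, grid = g, pixel_size = 0.05),
                    class = "track_map")
  sky <- skeleton_centerlines(mapy, min_branch_length = 0.3)
  expect_identical(length(sky), 3L)
})

test_that("4-s.d. diameter matches its definition and analytic laws", {
  cline <- cbind(seq(0, 10, 0.5), 0)
  # exact: positions at perpendicular offsets with sample s.d. 0.1
  off <- c(-0.1, 0.1)
  pos <- cbind(rep(seq(0.5, 9.5, 0.5), each = 2), off)
  sd_hat <- stats::sd(rep(off, length.out = nrow(pos)))
  expect_equal(diameter_4sd(pos, cline), 4 * sd_hat, tolerance = 1e-9)

  on_line <- cbind(seq(0.5, 9.5, length.out = 20), 0)
  expect_equal(diameter_4sd(on_line, cline), 0)

  und <- diameter_4sd(cbind(1:5, 0), cline)
  expect_true(is.na(und) && attr(und, "undefined"))

  # Gaussian offsets sigma = 0.1, n = 1000: 0.400 within 5%
  set.seed(16)
  posg <- cbind(stats::runif(1000, 0, 10), stats::rnorm(1000, 0, 0.1))
  expect_equal(diameter_4sd(posg, cline), 0.4, tolerance = 0.05)

  # uniform offsets on [-R, R]: 4R/sqrt(3) within 2%
  posu <- cbind(stats::runif(1e5, 0, 10), stats::runif(1e5, -0.3, 0.3))
  expect_equal(diameter_4sd(posu, cline), 4 * 0.3 / sqrt(3),
               tolerance = 0.02)
})

test_that("4-s.d. diameter is invariant under rigid motions", {
  set.seed(17)
  cline <- cbind(seq(0, 5, 0.25), 0.3 * sin(seq(0, 5, 0.25)))
  pos <- cbind(stats::runif(200, 0.5, 4.5), stats::rnorm(200, 0, 0.08))
  d0 <- diameter_4sd(pos, cline)
  th <- 0.77; rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  shift <- c(2, -1)
  pos2 <- sweep(pos %*% t(rot), 2, -shift)
  cl2 <- sweep(cline %*% t(rot), 2, -shift)
  expect_equal(diameter_4sd(pos2, cl2), d0, tolerance = 1e-9)
})

test_that("line profiles are exact bilinear samples", {
  g <- raster_grid(10, 10, 0.1)
  img <- matrix(0.42, 10, 10)
  pr <- line_profile(img, g, c(0.5, 0.1), c(0.5, 0.9), 50)
  expect_true(all(abs(pr$value - 0.42) < 1e-12))

  img2 <- matrix(rep(1:10, each = 10) * 1.0, 10, 10, byrow = TRUE)
  img2 <- t(img2)   # value = column index
  pr2 <- line_profile(img2, g, c(0.45, 0.05), c(0.45, 0.95), 10)
  expect_equal(pr2$value[1], 1, tolerance = 1e-9)
  expect_equal(pr2$value[10], 10, tolerance = 1e-9)

  # bilinear form on a separable gradient image: f(x, y) = x * y in mm
  ij <- as.matrix(expand.grid(1:10, 1:10))
  ctr <- srusct:::grid_center(g, ij)
  img3 <- matrix(0, 10, 10); img3[ij] <- ctr[, 1] * ctr[, 2]
  pr3 <- line_profile(img3, g, c(0.15, 0.25), c(0.85, 0.75), 25)
  t_ <- seq(0, 1, length.out = 25)
  px <- 0.15 + t_ * 0.7; py <- 0.25 + t_ * 0.5
  expect_equal(pr3$value, px * py, tolerance = 1e-9)

  expect_error(line_profile(img, g, c(1, 1), c(1, 1), 10), "coincide")
})

test_that("superposition counting matches the brute-force oracle", {
  slab <- slab_geometry(c(10, 10), 1.8)
  idt <- similarity_transform()
  # nine bundles stacked purely in elevation over one in-plane point
  bundles <- lapply(1:9, function(k)
    list(points = rbind(c(5, 2, -0.8 + (k - 1) * 0.2),
                        c(5, 8, -0.8 + (k - 1) * 0.2)),
         label = sprintf("vr%02d", k)))
  expect_identical(
    count_superposed_bundles(bundles, idt, slab, c(5, 5), 0.05), 9L)
  # a single vessel through the pixel
  expect_identical(
    count_superposed_bundles(bundles[1], idt, slab, c(5, 5), 0.05), 1L)
  # the tenth bundle outside the slab does not count
  b10 <- c(bundles, list(list(points = rbind(c(5, 2, 1.5), c(5, 8, 1.5)),
                              label = "vr10")))
  expect_identical(
    count_superposed_bundles(b10, idt, slab, c(5, 5), 0.05), 9L)

  # random phantom vs exhaustive point-to-segment oracle
  ph <- generate_kidney_phantom(phantom_config(), seed = 18)
  slab2 <- slab_geometry()
  pl <- srusct:::default_placement(ph, slab2)
  cls <- phantom_centerlines(ph)
  inv <- invert_transform(pl)
  for (pix in list(c(5, 9), c(7.5, 11), c(4, 14))) {
    got <- count_superposed_bundles(cls, pl, slab2, pix, 0.1)
    oracle <- 0L
    for (cl in cls) {
      p <- apply_transform(inv, cl$points)
      sp <- srusct:::resample_polyline(p, 0.01)
      hit <- sp[, 3] >= -0.9 & sp[, 3] < 0.9 &
        sqrt((sp[, 1] - pix[1])^2 + (sp[, 2] - pix[2])^2) <= 0.1
      if (any(hit)) oracle <- oracle + 1L
    }
    expect_identical(got, oracle)
  }
})

test_that("recoveries grow monotonically with the dilation radius", {
  set.seed(19)
  g <- raster_grid(60, 60, 0.05)
  cl <- list(list(points = cbind(seq(0.3, 2.7, 0.1),
                                 1.5 + 0.4 * sin(seq(0.3, 2.7, 0.1))),
                  vessel_class = "arcuate", side = "vein"))
  query <- list(list(points = cbind(seq(0.3, 2.7, 0.1),
                                    1.55 + 0.4 * sin(seq(0.3, 2.7, 0.1)))))
  intensity <- matrix(0L, 60, 60)
  ij <- srusct:::grid_index(g, query[[1]]$points)
  intensity[ij[srusct:::grid_inside(g, ij), , drop = FALSE]] <- 1L
  map <- structure(list(intensity = intensity, grid = g,
                        pixel_size = 0.05), class = "track_map")
  prev_cl <- -1; prev_tm <- -1
  for (r in c(0.05, 0.1, 0.2, 0.4)) {
    roi <- dilate_to_roi(cl, list(`arcuate/vein` = r), g)
    cur_cl <- centerline_recovery(query, roi)
    cur_tm <- trackmap_recovery(map, roi)
    expect_gte(cur_cl, prev_cl)
    expect_gte(cur_tm, prev_tm)
    prev_cl <- cur_cl; prev_tm <- cur_tm
  }
  expect_equal(prev_cl, 100)
})

test_that("projected parallel vessels merge: skeleton count never exceeds truth", {
  # two parallel vessels separated only in elevation rasterize onto the
  # same in-plane pixels: the skeleton sees at most one vessel
  g <- raster_grid(40, 40, 0.05)
  intensity <- matrix(0L, 40, 40)
  intensity[19:22, 5:35] <- 1L   # both vessels fall on the same band
  map <- structure(list(intensity = intensity, grid = g,
                        pixel_size = 0.05), class = "track_map")
  sk <- skeleton_centerlines(map, min_branch_length = 0.3)
  expect_lte(length(sk), 2)
})
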