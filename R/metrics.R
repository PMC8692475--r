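# Quantitative comparison of track maps against projected CT centerlines:
# ROI dilation, overlap percentages with a mirrored null control, skeleton
# centerlines, 4-s.d. diameters, line profiles with -3 dB widths and
# superposed-bundle counting.

#' Dilate projected centerlines into a vessel ROI mask
#'
#' The mask is the union of disks swept along each centerline, one disk
#' radius per `(vessel_class, side)` taken from the dilation table (the
#' "approximate expected vessel diameter" step; radii are explicit
#' configuration here). Centerline parts outside the grid are clipped with
#' a warning.
#'
#' @param centerlines list of 2D labeled polylines (`points` n x 2 mm,
#'   `vessel_class`, `side`), e.g. from [project_centerlines_to_plane()].
#' @param dilation_table named radii (mm): either one number per
#'   `vessel_class` name, or flat with names `class/side`.
#' @param grid target [raster_grid()].
#' @param side_label label stored on the mask (`"artery"`, `"vein"`, ...).
#' @return an `roi_mask`: logical matrix + grid + side + provenance.
#' @export
dilate_to_roi <- function(centerlines, dilation_table, grid,
                          side_label = NA_character_) {
  mask <- matrix(FALSE, grid$nrow, grid$ncol)
  clipped <- FALSE
  for (cl in centerlines) {
    key2 <- paste(cl$vessel_class, cl$side, sep = "/")
    r <- if (!is.null(dilation_table[[key2]])) dilation_table[[key2]]
         else dilation_table[[cl$vessel_class]]
    if (is.null(r))
      stop(sprintf("no dilation radius for `%s`", key2), call. = FALSE)
    if (r <= 0) stop("dilation radii must be > 0", call. = FALSE)
    rp <- ceiling(r / grid$pixel_size)
    off <- as.matrix(expand.grid(-rp:rp, -rp:rp))
    off <- off[sqrt(off[, 1]^2 + off[, 2]^2) * grid$pixel_size <= r + 1e-12,
               , drop = FALSE]
    sp <- resample_polyline(cl$points, grid$pixel_size / 2)
    ij <- unique(grid_index(grid, sp))
    if (any(!grid_inside(grid, ij))) clipped <- TRUE
    for (k in seq_len(nrow(ij))) {
      pix <- cbind(ij[k, 1] + off[, 1], ij[k, 2] + off[, 2])
      pix <- pix[grid_inside(grid, pix), , drop = FALSE]
      mask[pix] <- TRUE
    }
  }
  if (clipped) warning("centerline extends outside the grid; clipped")
  structure(list(mask = mask, grid = grid, side = side_label,
                 provenance = "original"), class = "roi_mask")
}

#' Mirror an ROI mask about a central image axis
#'
#' The null-control construction: reflecting the CT vessel ROIs about the
#' image's central axial axis (left-right flip) estimates the overlap
#' expected by chance in a densely vascularized organ.
#'
#' @param roi an `roi_mask`.
#' @param axis `"axial_center"` reflects across the central axial line
#'   (reverses the lateral/column order); `"lateral_center"` reverses rows.
#' @return the mirrored `roi_mask` (provenance `"mirrored"`).
#' @export
mirror_roi <- function(roi, axis = c("axial_center", "lateral_center")) {
  axis <- match.arg(axis)
  m <- roi$mask
  m <- if (axis == "axial_center") m[, ncol(m):1, drop = FALSE]
       else m[nrow(m):1, , drop = FALSE]
  roi$mask <- m
  roi$provenance <- "mirrored"
  roi
}

#' Fraction of centerline arc length recovered inside an ROI
#'
#' Each query centerline is resampled at a fixed step (half the ROI pixel
#' by default) and the percentage of samples landing on TRUE ROI pixels is
#' returned — an arc-length based recovery percentage, independent of the
#' vertex density of the input polylines.
#'
#' @param centerlines list of 2D polylines (`points` n x 2 mm).
#' @param roi an `roi_mask`.
#' @param step resampling step, mm.
#' @return percentage in `[0, 100]`; `NA` with attribute
#'   `undefined = TRUE` when the query has zero total length.
#' @export
centerline_recovery <- function(centerlines, roi,
                                step = roi$grid$pixel_size / 2) {
  n_in <- 0L; n_tot <- 0L
  for (cl in centerlines) {
    sp <- resample_polyline(cl$points, step)
    if (nrow(sp) < 2) next
    ij <- grid_index(roi$grid, sp)
    ok <- grid_inside(roi$grid, ij)
    n_tot <- n_tot + nrow(sp)
    if (any(ok)) n_in <- n_in + sum(roi$mask[ij[ok, , drop = FALSE]])
  }
  if (n_tot == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * n_in / n_tot
}

#' Fraction of track-map area covered by an ROI
#'
#' The percentage of nonzero track-map pixels (optionally restricted to a
#' set of region labels) that fall inside the ROI.
#'
#' @param map a `track_map`.
#' @param roi an `roi_mask` on the same grid.
#' @param regions optional [region_label_map()] for filtering.
#' @param region_filter labels to keep when `regions` is given.
#' @return percentage in `[0, 100]`; `NA` (attribute `undefined`) when no
#'   nonzero pixels remain after filtering.
#' @export
trackmap_recovery <- function(map, roi, regions = NULL,
                              region_filter = NULL) {
  if (!identical(dim(map$intensity), dim(roi$mask)))
    stop("track map and ROI are on different grids", call. = FALSE)
  nz <- map$intensity > 0
  if (!is.null(regions) && !is.null(region_filter))
    nz <- nz & matrix(regions$labels %in% region_filter,
                      nrow(nz), ncol(nz))
  n_tot <- sum(nz)
  if (n_tot == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * sum(nz & roi$mask) / n_tot
}

# --- skeletonization ------------------------------------------------------

# Guo-Hall thinning (1989, two-subiteration form) of a logical matrix,
# vectorized per subiteration. Chosen over Zhang-Suen because the latter
# deletes 2x2 blocks wholesale and retracts 2-pixel-wide diagonals, both
# of which vessel rasters are full of.
thin_guo_hall <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      idx <- which(m, arr.ind = TRUE)
      idx <- idx[idx[, 1] > 1 & idx[, 1] < nrow(m) &
                 idx[, 2] > 1 & idx[, 2] < ncol(m), , drop = FALSE]
      if (nrow(idx) == 0) break
      p <- function(di, dj) m[cbind(idx[, 1] + di, idx[, 2] + dj)]
      p2 <- p(-1, 0); p3 <- p(-1, 1); p4 <- p(0, 1); p5 <- p(1, 1)
      p6 <- p(1, 0); p7 <- p(1, -1); p8 <- p(0, -1); p9 <- p(-1, -1)
      cc <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
            (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      nmin <- pmin(n1, n2)
      o <- if (phase == 1) (p2 | p3 | !p5) & p4 else (p6 | p7 | !p9) & p8
      cond <- cc == 1 & nmin >= 2 & nmin <= 3 & !o
      if (any(cond)) {
        m[idx[cond, , drop = FALSE]] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
}

# neighbors of a skeleton pixel (8-connectivity)
skel_neighbors <- function(mask, i, j) {
  out <- NULL
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ii <- i + di; jj <- j + dj
    if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
        mask[ii, jj]) out <- rbind(out, c(ii, jj))
  }
  out
}

#' Extract skeleton centerlines from a track map
#'
#' Binarizes the map (intensity > 0), thins it to a one-pixel skeleton
#' (Guo-Hall), traces the skeleton into branch polylines between
#' endpoints/junctions and prunes branches shorter than
#' `min_branch_length`.
#'
#' @param map a `track_map`.
#' @param regions optional [region_label_map()]; with `region_filter`,
#'   restricts the binarized mask to those labels.
#' @param region_filter labels to keep.
#' @param min_branch_length prune branches shorter than this, mm.
#' @param side label recorded on the output centerlines.
#' @return list of `centerline_2d` (points n x 2 mm,
#'   `source = "skeleton"`); empty with a warning if nothing survives.
#' @export
skeleton_centerlines <- function(map, regions = NULL, region_filter = NULL,
                                 min_branch_length = 0.2,
                                 side = NA_character_) {
  mask <- map$intensity > 0
  if (!is.null(regions) && !is.null(region_filter))
    mask <- mask & matrix(regions$labels %in% region_filter,
                          nrow(mask), ncol(mask))
  if (!any(mask)) {
    warning("empty track map in the requested region")
    return(list())
  }
  sk <- thin_guo_hall(mask)
  grid <- map$grid
  deg <- matrix(0L, nrow(sk), ncol(sk))
  idx <- which(sk, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    nb <- skel_neighbors(sk, idx[k, 1], idx[k, 2])
    deg[idx[k, 1], idx[k, 2]] <- if (is.null(nb)) 0L else nrow(nb)
  }
  visited <- matrix(FALSE, nrow(sk), ncol(sk))
  paths <- list()
  # walk from every endpoint or junction along unvisited skeleton pixels
  starts <- which(sk & (deg != 2), arr.ind = TRUE)
  trace_from <- function(i, j) {
    nb <- skel_neighbors(sk, i, j)
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      ii <- nb[k, 1]; jj <- nb[k, 2]
      if (visited[ii, jj] && deg[ii, jj] == 2) next
      path <- rbind(c(i, j))
      ci <- ii; cj <- jj; pi <- i; pj <- j
      while (TRUE) {
        path <- rbind(path, c(ci, cj))
        if (deg[ci, cj] != 2) break
        if (visited[ci, cj]) break
        visited[ci, cj] <<- TRUE
        nb2 <- skel_neighbors(sk, ci, cj)
        nxt <- nb2[!(nb2[, 1] == pi & nb2[, 2] == pj), , drop = FALSE]
        if (nrow(nxt) == 0) break
        pi <- ci; pj <- cj
        ci <- nxt[1, 1]; cj <- nxt[1, 2]
      }
      if (nrow(path) >= 2) paths[[length(paths) + 1]] <<- path
    }
  }
  if (nrow(starts) > 0) {
    for (k in seq_len(nrow(starts))) trace_from(starts[k, 1], starts[k, 2])
  } else if (nrow(idx) > 0) {
    trace_from(idx[1, 1], idx[1, 2])   # pure cycle
  }
  # dedupe reversed duplicates of the same branch
  keys <- character(0)
  out <- list()
  for (p in paths) {
    lin <- (p[, 2] - 1) * nrow(sk) + p[, 1]
    key <- paste(sort(c(lin[1], lin[length(lin)])), collapse = "-")
    key <- paste(key, length(lin))
    if (key %in% keys) next
    keys <- c(keys, key)
    pts <- grid_center(grid, p)
    len <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2)))
    if (len < min_branch_length) next
    out[[length(out) + 1]] <- list(points = pts, source = "skeleton",
                                   side = side, length_mm = len)
  }
  if (!length(out)) warning("no skeleton branches survive pruning")
  out
}

# --- diameters and profiles ----------------------------------------------

#' 4-s.d. vessel diameter from bubble positions around a centerline
#'
#' Computes each position's signed perpendicular distance to its nearest
#' centerline segment and returns four times the sample standard deviation
#' of those distances — the simple diameter proxy for tubular vessels with
#' a Gaussian cross-profile.
#'
#' @param positions n x 2 matrix of bubble positions (mm) assigned to one
#'   vessel.
#' @param centerline a 2D centerline (`points` n x 2) or bare matrix.
#' @param min_positions minimum sample size (default 10); below it the
#'   estimate is `NA` with attribute `undefined`.
#' @return diameter, mm.
#' @export
diameter_4sd <- function(positions, centerline, min_positions = 10) {
  pts <- if (is.list(centerline)) centerline$points else centerline
  positions <- rbind(positions)
  if (nrow(positions) < min_positions) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  d <- signed_perp_distance(positions, pts)
  4 * stats::sd(d)
}

# signed perpendicular distance of 2D points to their nearest segment of a
# polyline (sign = side of the segment direction)
signed_perp_distance <- function(positions, poly) {
  best <- rep(Inf, nrow(positions))
  sgn <- rep(0, nrow(positions))
  for (k in seq_len(nrow(poly) - 1)) {
    a <- poly[k, ]; b <- poly[k + 1, ]
    ab <- b - a; ab2 <- sum(ab^2)
    if (ab2 == 0) next
    rel <- sweep(positions, 2, a)
    t_ <- pmin(pmax(rel %*% ab / ab2, 0), 1)
    proj <- matrix(a, nrow(positions), 2, byrow = TRUE) + t_ %*% rbind(ab)
    d <- sqrt(rowSums((positions - proj)^2))
    cr <- rel[, 1] * ab[2] - rel[, 2] * ab[1]
    upd <- d < best
    best[upd] <- d[upd]
    sgn[upd] <- sign(cr[upd])
  }
  sgn[sgn == 0] <- 1
  best * sgn
}

#' Sample an intensity profile along a line
#'
#' Bilinear samples at `n_samples` equispaced points from `p0` to `p1`.
#'
#' @param image 2D raster.
#' @param grid the image's [raster_grid()].
#' @param p0,p1 endpoints, mm (must differ).
#' @param n_samples number of samples.
#' @return an `intensity_profile`: `position` (mm along the line),
#'   `value`, endpoints and step.
#' @export
line_profile <- function(image, grid, p0, p1, n_samples = 200) {
  if (all(p0 == p1)) stop("profile endpoints coincide", call. = FALSE)
  t_ <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0[1] + t_ * (p1[1] - p0[1]), p0[2] + t_ * (p1[2] - p0[2]))
  len <- sqrt(sum((p1 - p0)^2))
  structure(list(position = t_ * len,
                 value = grid_bilinear(image, grid, pts),
                 p0 = p0, p1 = p1, step = len / (n_samples - 1)),
            class = "intensity_profile")
}

#' -3 dB widths of the peaks of an intensity profile
#'
#' For each local maximum above the prominence threshold, the width between
#' the two crossings of `peak * 10^(-3/10)` (half power on the linear
#' intensity scale), linearly interpolated between samples. Peaks whose
#' level never crosses before the profile boundary get a one-sided width
#' flagged in `$one_sided`.
#'
#' @param profile an `intensity_profile` (linear intensity; de-compress
#'   log-display images first).
#' @param prominence minimum peak height as a fraction of the profile
#'   maximum.
#' @return data.frame `peak_position`, `peak_value`, `width_mm`,
#'   `one_sided`, ordered by position.
#' @export
width_minus_3db <- function(profile, prominence = 0.1) {
  v <- profile$value; x <- profile$position
  n <- length(v)
  thr <- prominence * max(v)
  # plateau-tolerant local maxima: compress equal-value runs, find runs
  # higher than both neighbors, report each run's midpoint sample
  r <- rle(v)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  peaks <- integer(0)
  for (k in seq_len(nr)) {
    left_ok <- k == 1 || r$values[k] > r$values[k - 1]
    right_ok <- k == nr || r$values[k] > r$values[k + 1]
    interior <- k > 1 && k < nr
    if (left_ok && right_ok && (interior || nr == 1 ||
                                (k == 1 && right_ok && nr > 1 &&
                                 r$values[k] > r$values[k + 1]) ||
                                (k == nr && left_ok && nr > 1 &&
                                 r$values[k] > r$values[k - 1])))
      peaks <- c(peaks, (starts[k] + ends[k]) %/% 2L)
  }
  peaks <- peaks[v[peaks] >= thr]
  if (!length(peaks))
    return(data.frame(peak_position = numeric(0), peak_value = numeric(0),
                      width_mm = numeric(0), one_sided = logical(0)))
  out <- lapply(peaks, function(p) {
    level <- v[p] * 10^(-3 / 10)
    # walk left
    li <- p
    while (li > 1 && v[li] > level) li <- li - 1
    left <- if (v[li] > level) NA_real_ else {
      x[li] + (x[li + 1] - x[li]) * (level - v[li]) / (v[li + 1] - v[li])
    }
    ri <- p
    while (ri < n && v[ri] > level) ri <- ri + 1
    right <- if (v[ri] > level) NA_real_ else {
      x[ri - 1] + (x[ri] - x[ri - 1]) * (v[ri - 1] - level) /
        (v[ri - 1] - v[ri])
    }
    one_sided <- is.na(left) || is.na(right)
    w <- if (!one_sided) right - left
         else if (!is.na(left)) 2 * (x[p] - left)
         else if (!is.na(right)) 2 * (right - x[p])
         else NA_real_
    data.frame(peak_position = x[p], peak_value = v[p], width_mm = w,
               one_sided = one_sided)
  })
  res <- do.call(rbind, out)
  res[order(res$peak_position), , drop = FALSE]
}

#' Count superposed vessels above one image pixel
#'
#' The number of distinct labeled 3D polylines whose slab-frame course
#' passes within `pixel_radius` of the pixel's in-plane location at any
#' elevation inside the slab — the elevational superposition count that
#' explains several vasa recta bundles summing into a single track-map
#' pixel.
#'
#' @param centerlines3d list of labeled 3D polylines in volume coordinates.
#' @param transform slab-to-volume `similarity_transform` (inverted
#'   internally).
#' @param slab a [slab_geometry()].
#' @param pixel in-plane location (axial, lateral), mm.
#' @param pixel_radius capture radius, mm.
#' @return integer count.
#' @export
count_superposed_bundles <- function(centerlines3d, transform, slab, pixel,
                                     pixel_radius) {
  inv <- invert_transform(transform)
  n <- 0L
  for (cl in centerlines3d) {
    p <- apply_transform(inv, cl$points)
    sp <- resample_polyline(p, pixel_radius / 4)
    hit <- sp[, 3] >= -slab$thickness / 2 & sp[, 3] < slab$thickness / 2 &
      sqrt((sp[, 1] - pixel[1])^2 + (sp[, 2] - pixel[2])^2) <= pixel_radius
    if (any(hit)) n <- n + 1L
  }
  n
}
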