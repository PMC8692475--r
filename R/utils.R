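#' @keywords internal
"_PACKAGE"

# Shared geometry, raster and RNG plumbing used by every module.
# Conventions (fixed package-wide):
#  - physical coordinates are right-handed, in mm;
#  - 2D image points are (axial, lateral); rasters are matrices with
#    row = axial (depth), col = lateral;
#  - pixel/voxel centers sit at origin + (index - 0.5) * spacing (1-based
#    indices); membership in cells/slabs uses half-open intervals [lo, hi).

#' Define a 2D raster grid
#'
#' @param nrow,ncol raster dimensions (rows = axial, cols = lateral).
#' @param pixel_size pixel edge length, mm.
#' @param origin mm coordinate (axial, lateral) of the outer corner of
#'   pixel `[1, 1]`.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(nrow, ncol, pixel_size, origin = c(0, 0)) {
  stopifnot(nrow >= 1, ncol >= 1, pixel_size > 0, length(origin) == 2)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 pixel_size = pixel_size, origin = as.numeric(origin)),
            class = "raster_grid")
}

#' Build the raster grid covering a slab's in-plane extent
#' @param slab a [slab_geometry()].
#' @param pixel_size pixel edge length, mm.
#' @export
grid_for_slab <- function(slab, pixel_size) {
  raster_grid(ceiling(slab$extent[1] / pixel_size - 1e-9),
              ceiling(slab$extent[2] / pixel_size - 1e-9),
              pixel_size)
}

# mm -> 1-based integer indices (half-open cells); points exactly on the
# upper boundary fall outside.
grid_index <- function(grid, pts) {
  pts <- rbind(pts)
  i <- floor((pts[, 1] - grid$origin[1]) / grid$pixel_size) + 1L
  j <- floor((pts[, 2] - grid$origin[2]) / grid$pixel_size) + 1L
  cbind(i, j)
}

grid_inside <- function(grid, ij) {
  ij[, 1] >= 1L & ij[, 1] <= grid$nrow & ij[, 2] >= 1L & ij[, 2] <= grid$ncol
}

# pixel centers in mm for index matrix ij
grid_center <- function(grid, ij) {
  ij <- rbind(ij)
  cbind(grid$origin[1] + (ij[, 1] - 0.5) * grid$pixel_size,
        grid$origin[2] + (ij[, 2] - 0.5) * grid$pixel_size)
}

# Bilinear interpolation of matrix `m` (grid geometry `grid`) at mm points.
# Out-of-grid points are clamped to the border (documented nearest-edge rule).
grid_bilinear <- function(m, grid, pts) {
  pts <- rbind(pts)
  fx <- (pts[, 1] - grid$origin[1]) / grid$pixel_size - 0.5
  fy <- (pts[, 2] - grid$origin[2]) / grid$pixel_size - 0.5
  fx <- pmin(pmax(fx, 0), grid$nrow - 1)
  fy <- pmin(pmax(fy, 0), grid$ncol - 1)
  i0 <- pmin(floor(fx), grid$nrow - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), grid$ncol - 2); j0 <- pmax(j0, 0)
  if (grid$nrow == 1) i0 <- rep(0, length(fx))
  if (grid$ncol == 1) j0 <- rep(0, length(fy))
  wx <- fx - i0; wy <- fy - j0
  i1 <- pmin(i0 + 1, grid$nrow - 1); j1 <- pmin(j0 + 1, grid$ncol - 1)
  idx <- function(i, j) m[cbind(i + 1L, j + 1L)]
  (1 - wx) * (1 - wy) * idx(i0, j0) + (1 - wx) * wy * idx(i0, j1) +
    wx * (1 - wy) * idx(i1, j0) + wx * wy * idx(i1, j1)
}

# --- angles ---------------------------------------------------------------
# 0 deg = +lateral, 90 deg = +axial, range (-180, 180].
angle_deg <- function(d_axial, d_lateral) {
  a <- atan2(d_axial, d_lateral) * 180 / pi
  a[a <= -180] <- a[a <= -180] + 360
  a
}

# circular mean of angles in degrees (vector averaging)
circ_mean_deg <- function(deg, w = NULL) {
  r <- deg * pi / 180
  if (is.null(w)) w <- rep(1, length(r))
  angle_deg(sum(w * sin(r)), sum(w * cos(r)))
}

# absolute angular difference in [0, 180]
ang_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# --- RNG ------------------------------------------------------------------
# FNV-1a over a string, folded below 2^31 (R integers are 32-bit).
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

# Derive a per-operation stream seed from a master seed and a tag, keeping
# every stream a pure function of (master, tag).
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + fnv1a(tag)) %% .Machine$integer.max)
}

# Evaluate expr under a local RNG state (restores the caller's stream).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- misc -----------------------------------------------------------------

# resample a polyline (n x d matrix) at fixed arc-length step; always keeps
# both endpoints
resample_polyline <- function(pts, step) {
  pts <- rbind(pts)
  if (nrow(pts) < 2) return(pts)
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  if (total == 0) return(pts[1, , drop = FALSE])
  s <- unique(c(seq(0, total, by = step), total))
  interp_polyline(pts, cum, s)
}

# interpolate positions at arc lengths s along polyline with cumulative
# lengths cum (duplicate vertices collapse to one support point)
interp_polyline <- function(pts, cum, s) {
  keep <- c(TRUE, diff(cum) > 0)
  cum <- cum[keep]; pts <- pts[keep, , drop = FALSE]
  out <- matrix(NA_real_, length(s), ncol(pts))
  if (length(cum) == 1) {
    out[] <- rep(pts[1, ], each = length(s))
    return(out)
  }
  for (d in seq_len(ncol(pts)))
    out[, d] <- stats::approx(cum, pts[, d], xout = s, rule = 2)$y
  out
}

# minimum distance from points (n x d) to a polyline (m x d)
dist_to_polyline <- function(pts, poly) {
  pts <- rbind(pts); poly <- rbind(poly)
  if (nrow(poly) == 1)
    return(sqrt(rowSums(sweep(pts, 2, poly[1, ])^2)))
  dmin <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(poly) - 1)) {
    a <- poly[k, ]; b <- poly[k + 1, ]
    ab <- b - a
    ab2 <- sum(ab^2)
    if (ab2 == 0) {
      d <- sqrt(rowSums(sweep(pts, 2, a)^2))
    } else {
      t <- pmin(pmax(sweep(pts, 2, a) %*% ab / ab2, 0), 1)
      proj <- matrix(a, nrow(pts), length(a), byrow = TRUE) + t %*% rbind(ab)
      d <- sqrt(rowSums((pts - proj)^2))
    }
    dmin <- pmin(dmin, d)
  }
  dmin
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a content hash of an R object (manifest checksums)
object_checksum <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  # fold in 8k-byte strides to keep it cheap on large arrays
  idx <- unique(c(seq(1, length(raw), by = max(1L, length(raw) %/% 8192L)),
                  length(raw)))
  for (b in as.integer(raw[idx])) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("fnv1a:%08x:%d", as.integer(h %% 2^31), length(raw))
}
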