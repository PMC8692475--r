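# Co-registration between the 2D ultrasound slab and the 3D CT volume.
#
# The geometric contract: slab-frame coordinates are (axial, lateral,
# elevation) with axial in [0, extent_1), lateral in [0, extent_2) and
# elevation in [-thickness/2, thickness/2); a similarity transform
# x' = scale * R * x + t maps slab coordinates into volume coordinates.

#' Slab geometry of a 2D ultrasound acquisition
#'
#' @param extent in-plane extent (axial depth, lateral width), mm.
#'   Default 15.3 x 21.5 mm.
#' @param thickness elevational slab thickness, mm (default 1.8).
#' @export
slab_geometry <- function(extent = c(15.3, 21.5), thickness = 1.8) {
  stopifnot(length(extent) == 2, all(extent > 0), thickness > 0)
  structure(list(extent = as.numeric(extent), thickness = thickness),
            class = "slab_geometry")
}

#' Construct a 3D similarity transform
#'
#' Maps points as `x' = scale * R %*% x + translation`.
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param scale positive scalar.
#' @param translation length-3 vector, mm.
#' @export
similarity_transform <- function(rotation = diag(3), scale = 1,
                                 translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("`rotation` is not orthonormal", call. = FALSE)
  if (det(rotation) < 0)
    stop("`rotation` must be proper (det = +1)", call. = FALSE)
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  structure(list(rotation = rotation, scale = scale,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#' @param transform a `similarity_transform`.
#' @param pts n x 3 matrix, mm.
#' @export
apply_transform <- function(transform, pts) {
  pts <- rbind(pts)
  sweep(transform$scale * pts %*% t(transform$rotation), 2,
        -transform$translation)
}

#' Invert a similarity transform
#' @param transform a `similarity_transform`.
#' @export
invert_transform <- function(transform) {
  rinv <- t(transform$rotation)
  similarity_transform(rotation = rinv, scale = 1 / transform$scale,
                       translation = -drop(rinv %*% transform$translation) /
                         transform$scale)
}

#' Compose transforms (`a` applied after `b`)
#' @param a,b `similarity_transform`s.
#' @export
compose_transform <- function(a, b) {
  similarity_transform(rotation = a$rotation %*% b$rotation,
                       scale = a$scale * b$scale,
                       translation = a$scale *
                         drop(a$rotation %*% b$translation) + a$translation)
}

#' Least-squares similarity transform from landmark pairs
#'
#' Closed-form fit (cross-covariance SVD with the proper-rotation sign
#' constraint) of `x' = s R x + t` minimizing the sum of squared residuals
#' over the pairs; the registration surrogate for a manual alignment.
#'
#' @param source n x 3 matrix of slab-frame landmarks, mm (n >= 3,
#'   non-collinear).
#' @param target n x 3 matrix of the same landmarks in volume coordinates.
#' @return a `similarity_transform`; RMS residual in attribute `"rms"`.
#' @export
fit_similarity <- function(source, target) {
  source <- rbind(source); target <- rbind(target)
  if (nrow(source) < 3)
    stop("need >= 3 landmark pairs", call. = FALSE)
  if (nrow(source) != nrow(target))
    stop("landmark sets differ in size", call. = FALSE)
  mx <- colMeans(source); my <- colMeans(target)
  xc <- sweep(source, 2, mx); yc <- sweep(target, 2, my)
  sv <- svd(xc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate landmark configuration: points are collinear",
         call. = FALSE)
  cc <- crossprod(yc, xc) / nrow(source)   # cross-covariance
  dec <- svd(cc)
  s3 <- diag(c(1, 1, sign(det(dec$u) * det(dec$v))))
  rot <- dec$u %*% s3 %*% t(dec$v)
  var_x <- sum(xc^2) / nrow(source)
  scale <- sum(diag(diag(dec$d) %*% s3)) / var_x
  tr <- my - scale * drop(rot %*% mx)
  out <- similarity_transform(rotation = rot, scale = scale,
                              translation = tr)
  res <- apply_transform(out, source) - target
  attr(out, "rms") <- sqrt(mean(rowSums(res^2)))
  out
}

# --- sampling -------------------------------------------------------------

# Trilinear sampling of a synthetic_ct at mm points; samples outside the
# volume return -Inf (they never win a maximum projection).
ct_sample <- function(ct, pts) {
  pts <- rbind(pts)
  dims <- dim(ct$voxels)
  f <- sweep(pts, 2, ct$origin) / ct$spacing - 0.5
  out <- rep(-Inf, nrow(pts))
  ok <- f[, 1] >= 0 & f[, 1] <= dims[1] - 1 &
        f[, 2] >= 0 & f[, 2] <= dims[2] - 1 &
        f[, 3] >= 0 & f[, 3] <= dims[3] - 1
  if (!any(ok)) return(out)
  f <- f[ok, , drop = FALSE]
  i0 <- pmin(pmax(floor(f[, 1]), 0), max(dims[1] - 2, 0))
  j0 <- pmin(pmax(floor(f[, 2]), 0), max(dims[2] - 2, 0))
  k0 <- pmin(pmax(floor(f[, 3]), 0), max(dims[3] - 2, 0))
  wx <- f[, 1] - i0; wy <- f[, 2] - j0; wz <- f[, 3] - k0
  g <- function(di, dj, dk)
    ct$voxels[cbind(i0 + di + 1L, j0 + dj + 1L, k0 + dk + 1L)]
  val <- (1 - wx) * (1 - wy) * (1 - wz) * g(0, 0, 0) +
    (1 - wx) * (1 - wy) * wz * g(0, 0, 1) +
    (1 - wx) * wy * (1 - wz) * g(0, 1, 0) +
    (1 - wx) * wy * wz * g(0, 1, 1) +
    wx * (1 - wy) * (1 - wz) * g(1, 0, 0) +
    wx * (1 - wy) * wz * g(1, 0, 1) +
    wx * wy * (1 - wz) * g(1, 1, 0) +
    wx * wy * wz * g(1, 1, 1)
  out[ok] <- val
  out
}

#' Slab maximum intensity projection of a CT volume
#'
#' For each in-plane pixel of the slab the maximum of trilinear volume
#' samples along the elevational segment of length `thickness`, mapped
#' through the co-registration transform. Pixels whose samples all fall
#' outside the volume are `NA` (invalid).
#'
#' @param ct a `synthetic_ct` (or imported volume with the same fields).
#' @param transform slab-to-volume `similarity_transform`.
#' @param slab a [slab_geometry()].
#' @param pixel_size in-plane MIP pixel size, mm.
#' @param step elevational sampling step, mm (default half the voxel
#'   spacing; must not exceed the voxel spacing).
#' @return matrix (rows = axial, cols = lateral); grid in attribute
#'   `"grid"`.
#' @export
slab_mip <- function(ct, transform, slab, pixel_size,
                     step = ct$spacing / 2) {
  if (step > ct$spacing + 1e-12)
    stop("`step` must be <= voxel spacing", call. = FALSE)
  grid <- grid_for_slab(slab, pixel_size)
  ij <- as.matrix(expand.grid(seq_len(grid$nrow), seq_len(grid$ncol)))
  ctr <- grid_center(grid, ij)
  zs <- seq(-slab$thickness / 2, slab$thickness / 2, by = step)
  best <- rep(-Inf, nrow(ctr))
  for (z in zs) {
    p <- apply_transform(transform, cbind(ctr, z))
    best <- pmax(best, ct_sample(ct, p))
  }
  if (all(!is.finite(best)))
    stop("slab lies entirely outside the volume", call. = FALSE)
  best[!is.finite(best)] <- NA_real_
  m <- matrix(NA_real_, grid$nrow, grid$ncol)
  m[ij] <- best
  attr(m, "grid") <- grid
  m
}

#' Project labeled 3D centerlines into the slab plane
#'
#' Vertices are mapped to the slab frame with the inverse co-registration
#' transform; runs of consecutive in-slab vertices (elevation in
#' `[-thickness/2, thickness/2)`) become 2D polylines, split where the
#' vessel exits the slab. Labels are preserved.
#'
#' @param centerlines list of labeled polylines (`points` n x 3 mm in volume
#'   coordinates plus label fields), e.g. from [phantom_centerlines()].
#' @param transform volume-to-slab `similarity_transform` (the inverse of
#'   the slab-to-volume co-registration).
#' @param slab a [slab_geometry()].
#' @return list of 2D labeled polylines (`points` n x 2 (axial, lateral),
#'   label fields copied, `source = "projected_ct"`).
#' @export
project_centerlines_to_plane <- function(centerlines, transform, slab) {
  out <- list()
  for (cl in centerlines) {
    p <- apply_transform(transform, cl$points)
    inside <- p[, 3] >= -slab$thickness / 2 & p[, 3] < slab$thickness / 2
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      if (length(idx) < 2) next
      piece <- cl
      piece$points <- p[idx, 1:2, drop = FALSE]
      piece$source <- "projected_ct"
      out[[length(out) + 1]] <- piece
    }
  }
  out
}
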