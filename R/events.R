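# Microbubble event simulation on a kidney phantom.
#
# Bubbles arrive as a Poisson process per frame at the roots of the arterial
# and venous trees and advect along root-to-leaf paths. Arterial speed is
# modulated by a single cardiac sinusoid, venous flow is steady; vein paths
# are traversed leaf-to-root so venous flow opposes the paired artery. Each
# bubble keeps a fixed lateral offset inside the tube for its lifetime.

# children adjacency + attachment arc positions for one side's tree
tree_index <- function(phantom, side) {
  segs <- phantom$segments
  keep <- vapply(segs, function(s) s$side == side, TRUE)
  ids <- vapply(segs[keep], function(s) s$id, 1L)
  children <- lapply(ids, function(id) {
    kids <- Filter(function(s) !is.na(s$parent_id) && s$parent_id == id &&
                     s$side == side, segs)
    vapply(kids, function(s) s$id, 1L)
  })
  names(children) <- as.character(ids)
  roots <- ids[vapply(segs[keep], function(s) is.na(s$parent_id), TRUE)]
  list(ids = ids, children = children, roots = roots)
}

polyline_cumlen <- function(pts) {
  c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))))
}

# arc position on parent polyline nearest to a point
nearest_arc <- function(pts, p) {
  cum <- polyline_cumlen(pts)
  samp <- seq(0, cum[length(cum)], length.out = 200)
  sp <- interp_polyline(pts, cum, samp)
  samp[which.min(rowSums(sweep(sp, 2, p)^2))]
}

# assemble a random root-to-leaf path: concatenated points with per-point
# segment id, speed, pulsatility and radius
random_path <- function(phantom, tree, root_id) {
  segs <- phantom$segments
  pts <- NULL; seg_id <- integer(0); spd <- numeric(0)
  pul <- numeric(0); rad <- numeric(0)
  cur <- root_id; entry <- 0
  repeat {
    s <- segs[[cur]]
    cum <- polyline_cumlen(s$polyline)
    kids <- tree$children[[as.character(cur)]]
    nxt <- NA_integer_; exit_arc <- cum[length(cum)]
    if (length(kids) > 0) {
      # pick a child attached downstream of the entry point, if any
      arcs <- vapply(kids, function(k)
        nearest_arc(s$polyline, segs[[k]]$polyline[1, ]), 1)
      ok <- which(arcs >= entry - 1e-9)
      if (length(ok) > 0) {
        pick <- ok[sample.int(length(ok), 1)]
        nxt <- kids[pick]; exit_arc <- arcs[pick]
      }
    }
    samp <- seq(entry, max(exit_arc, entry + 1e-6), length.out =
                  max(2, ceiling((exit_arc - entry) / 0.05)))
    pp <- interp_polyline(s$polyline, cum, samp)
    pts <- rbind(pts, pp)
    seg_id <- c(seg_id, rep(s$id, nrow(pp)))
    spd <- c(spd, rep(s$mean_speed, nrow(pp)))
    pul <- c(pul, rep(s$pulsatility, nrow(pp)))
    rad <- c(rad, rep(s$radius, nrow(pp)))
    if (is.na(nxt)) break
    cur <- nxt; entry <- 0
  }
  list(points = pts, segment_id = seg_id, speed = spd, pulsatility = pul,
       radius = rad)
}

reverse_path <- function(path) {
  n <- nrow(path$points)
  list(points = path$points[n:1, , drop = FALSE],
       segment_id = rev(path$segment_id), speed = rev(path$speed),
       pulsatility = rev(path$pulsatility), radius = rev(path$radius))
}

# local orthonormal frame (N1, N2) perpendicular to the tangent at each
# sampled point of a polyline
path_normals <- function(pts) {
  n <- nrow(pts)
  d <- rbind(pts[2, ] - pts[1, ],
             (pts[pmin(3:(n + 1), n), , drop = FALSE] -
              pts[pmax(1:(n - 1), 1), , drop = FALSE])[seq_len(n - 1), ,
                                                       drop = FALSE])
  tl <- sqrt(rowSums(d^2)); tl[tl == 0] <- 1
  t_ <- d / tl
  ez <- c(0, 0, 1)
  n1 <- cbind(t_[, 2] * ez[3] - t_[, 3] * ez[2],
              t_[, 3] * ez[1] - t_[, 1] * ez[3],
              t_[, 1] * ez[2] - t_[, 2] * ez[1])
  l1 <- sqrt(rowSums(n1^2))
  deg <- l1 < 1e-6
  if (any(deg)) n1[deg, ] <- matrix(c(0, 1, 0), sum(deg), 3, byrow = TRUE)
  l1[deg] <- 1
  n1 <- n1 / l1
  n2 <- cbind(t_[, 2] * n1[, 3] - t_[, 3] * n1[, 2],
              t_[, 3] * n1[, 1] - t_[, 1] * n1[, 3],
              t_[, 1] * n1[, 2] - t_[, 2] * n1[, 1])
  list(n1 = n1, n2 = n2)
}

#' Simulate microbubble events on a phantom
#'
#' @param phantom a `kidney_phantom`.
#' @param concentration expected bubble arrivals per frame (Poisson).
#' @param duration acquisition duration, s.
#' @param frame_rate frames per second (54 Hz by default).
#' @param seed integer seed.
#' @param p_artery fraction of bubbles seeded in the arterial tree (the
#'   rest flow leaf-to-root through the venous tree).
#' @return data.frame with columns `frame` (1-based), `x_mm` (axial),
#'   `y_mm` (lateral), `z_mm` (elevational), `bubble_id`, `segment_id`,
#'   `amplitude`; frame count and rate in attributes.
#' @export
sample_bubble_events <- function(phantom, concentration, duration,
                                 frame_rate = 54, seed = 1,
                                 p_artery = 0.5) {
  if (frame_rate <= 0) stop("`frame_rate` must be > 0", call. = FALSE)
  if (concentration < 0) stop("`concentration` must be >= 0", call. = FALSE)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  n_frames <- max(1L, as.integer(round(duration * frame_rate)))
  empty <- data.frame(frame = integer(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      bubble_id = integer(0), segment_id = integer(0),
                      amplitude = numeric(0))
  attr(empty, "n_frames") <- n_frames
  attr(empty, "frame_rate") <- frame_rate
  if (concentration == 0) return(empty)

  with_seed(derive_seed(seed, "events"), {
    atree <- tree_index(phantom, "artery")
    vtree <- tree_index(phantom, "vein")
    f_c <- phantom$config$cardiac_rate
    arrivals <- stats::rpois(n_frames, concentration)
    out <- vector("list", sum(arrivals))
    bid <- 0L
    for (fr in seq_len(n_frames)) {
      for (a in seq_len(arrivals[fr])) {
        bid <- bid + 1L
        use_art <- stats::runif(1) < p_artery && length(atree$roots) > 0
        if (!use_art && length(vtree$roots) == 0) use_art <- TRUE
        if (use_art) {
          root <- atree$roots[sample.int(length(atree$roots), 1)]
          path <- random_path(phantom, atree, root)
        } else {
          root <- vtree$roots[sample.int(length(vtree$roots), 1)]
          path <- reverse_path(random_path(phantom, vtree, root))
        }
        cum <- polyline_cumlen(path$points)
        total <- cum[length(cum)]
        # fixed in-tube offset (uniform in the 0.8 r safety disk)
        rmin <- 0.8 * min(path$radius)
        repeat {
          ab <- stats::runif(2, -1, 1)
          if (sum(ab^2) <= 1) break
        }
        ab <- ab * rmin
        amp <- stats::rlnorm(1, 0, 0.2)
        # advect: step arc length once per frame at the local speed
        s <- 0; k <- fr
        ss <- numeric(0); fs <- integer(0)
        while (s <= total && k <= n_frames) {
          ss <- c(ss, s); fs <- c(fs, k)
          i <- findInterval(s, cum, all.inside = TRUE)
          v <- path$speed[i] *
            (1 + path$pulsatility[i] * sin(2 * pi * f_c * (k / frame_rate)))
          s <- s + v / frame_rate
          k <- k + 1L
        }
        if (length(ss) == 0) next
        pos <- interp_polyline(path$points, cum, ss)
        nf <- path_normals(path$points)
        i <- findInterval(ss, cum, all.inside = TRUE)
        pos <- pos + ab[1] * nf$n1[i, , drop = FALSE] +
          ab[2] * nf$n2[i, , drop = FALSE]
        out[[bid]] <- data.frame(frame = fs, x_mm = pos[, 1],
                                 y_mm = pos[, 2], z_mm = pos[, 3],
                                 bubble_id = bid,
                                 segment_id = path$segment_id[i],
                                 amplitude = amp)
      }
    }
    out <- out[!vapply(out, is.null, TRUE)]
    ev <- if (length(out)) do.call(rbind, out) else empty
    ev <- ev[order(ev$frame, ev$bubble_id), ]
    rownames(ev) <- NULL
    attr(ev, "n_frames") <- n_frames
    attr(ev, "frame_rate") <- frame_rate
    ev
  })
}
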