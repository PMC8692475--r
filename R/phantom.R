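# Synthetic kidney-like vascular phantom.
#
# The phantom is the stated world for the whole pipeline: a branching
# arterial tree (renal branch -> segmental -> arcuate -> cortical radial)
# with a paired venous tree laid as a parallel offset copy at larger radius
# (emulating veins wrapping their paired artery), plus straight vasa recta
# bundles spanning the medulla, stacked mainly in the elevational direction.
# All coordinates are mm, axes (axial, lateral, elevational); the cortex
# sits at low axial values and the hilum at high axial values.

#' Phantom configuration
#'
#' Defaults describe a rat-kidney-like scene sized to a 15.3 x 21.5 mm
#' imaging plane with a few mm of elevational depth. Radii follow the
#' ~100-1300 um vessel diameter range, with veins substantially wider than
#' their paired arteries; mean speeds are kept at or below the trackable
#' limit of gate/frame interval (0.278 mm * 54 Hz = 15 mm/s), with arterial
#' pulsatility pushing systolic peaks above it.
#'
#' @param extent axis-aligned bounding box (axial, lateral, elevational), mm.
#' @param n_renal_branches,n_segmental,n_arcuate_per_segmental,
#'   n_cortical_per_arcuate branching counts of the arterial tree (the vein
#'   tree mirrors it).
#' @param n_vasa_bundles number of vasa recta bundles; `bundle_size` vessels
#'   per bundle (alternating descending/ascending), `bundle_spacing` mm
#'   between them (stacked in elevation).
#' @param radius named list per vessel class: `c(artery, vein)` radii in mm.
#' @param mean_speed named list per vessel class: `c(artery, vein)` mm/s.
#' @param pulsatility fraction in `[0, 1)` for arteries (veins are steady).
#' @param cardiac_rate heart rate used for arterial speed modulation, Hz.
#' @param vein_offset_factor vein centerline offset from its paired artery,
#'   as a multiple of the artery radius (1.5-3 emulates wrapping).
#' @param vein_offset_dir unit 3-vector of the offset direction.
#' @param seed_jitter polyline bending jitter (radians per step).
#' @param hilum_frac position of the hilum as fractions of the axial and
#'   lateral extent; moving it off-center (e.g. `c(0.92, 0.25)`) yields a
#'   laterally asymmetric phantom for mirrored-control experiments.
#' @export
phantom_config <- function(extent = c(15.3, 21.5, 6),
                           n_renal_branches = 2,
                           n_segmental = 4,
                           n_arcuate_per_segmental = 2,
                           n_cortical_per_arcuate = 2,
                           n_vasa_bundles = 2,
                           bundle_size = 4,
                           bundle_spacing = 0.08,
                           radius = list(
                             renal_branch    = c(artery = 0.50, vein = 0.65),
                             segmental       = c(artery = 0.25, vein = 0.45),
                             arcuate         = c(artery = 0.10, vein = 0.20),
                             cortical_radial = c(artery = 0.035, vein = 0.06),
                             vasa_recta      = c(artery = 0.012, vein = 0.015)),
                           mean_speed = list(
                             renal_branch    = c(artery = 12, vein = 6),
                             segmental       = c(artery = 10, vein = 5),
                             arcuate         = c(artery = 7,  vein = 3.5),
                             cortical_radial = c(artery = 4,  vein = 2),
                             vasa_recta      = c(artery = 1.5, vein = 1)),
                           pulsatility = 0.4,
                           cardiac_rate = 5,
                           vein_offset_factor = 2,
                           vein_offset_dir = c(0, 0.6, 0.8),
                           seed_jitter = 0.12,
                           hilum_frac = c(0.92, 0.5)) {
  cfg <- list(extent = extent, n_renal_branches = n_renal_branches,
              n_segmental = n_segmental,
              n_arcuate_per_segmental = n_arcuate_per_segmental,
              n_cortical_per_arcuate = n_cortical_per_arcuate,
              n_vasa_bundles = n_vasa_bundles, bundle_size = bundle_size,
              bundle_spacing = bundle_spacing, radius = radius,
              mean_speed = mean_speed, pulsatility = pulsatility,
              cardiac_rate = cardiac_rate,
              vein_offset_factor = vein_offset_factor,
              vein_offset_dir = vein_offset_dir / sqrt(sum(vein_offset_dir^2)),
              seed_jitter = seed_jitter, hilum_frac = hilum_frac)
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (any(cfg$extent <= 0))
    stop("phantom config: `extent` must be positive", call. = FALSE)
  for (cls in names(cfg$radius)) {
    r <- cfg$radius[[cls]]
    if (any(r <= 0))
      stop(sprintf("phantom config: `radius$%s` must be > 0", cls),
           call. = FALSE)
    if (r[["artery"]] >= r[["vein"]])
      stop(sprintf(
        "phantom config: `radius$%s` requires artery < vein", cls),
        call. = FALSE)
    if (2 * max(r) >= min(cfg$extent))
      stop(sprintf("phantom config: `radius$%s` exceeds `extent`", cls),
           call. = FALSE)
  }
  counts <- c("n_renal_branches", "n_segmental", "n_arcuate_per_segmental",
              "n_cortical_per_arcuate", "n_vasa_bundles", "bundle_size")
  for (nm in counts)
    if (cfg[[nm]] < 0)
      stop(sprintf("phantom config: `%s` must be >= 0", nm), call. = FALSE)
  invisible(cfg)
}

new_vessel_segment <- function(id, parent_id, polyline, radius, vessel_class,
                               side, mean_speed, pulsatility, flow_sense,
                               paired_id = NA_integer_) {
  structure(list(id = as.integer(id),
                 parent_id = if (is.na(parent_id)) NA_integer_
                             else as.integer(parent_id),
                 polyline = polyline, radius = radius,
                 vessel_class = vessel_class, side = side,
                 mean_speed = mean_speed, pulsatility = pulsatility,
                 flow_sense = flow_sense,
                 paired_id = as.integer(paired_id)),
            class = "vessel_segment")
}

# grow a gently bending polyline from `start` along `dir`, clamped inside
# the extent with a margin
grow_polyline <- function(start, dir, length_mm, n_pts, jitter, extent,
                          margin) {
  dir <- dir / sqrt(sum(dir^2))
  step <- length_mm / (n_pts - 1)
  pts <- matrix(NA_real_, n_pts, 3)
  pts[1, ] <- start
  for (k in 2:n_pts) {
    # small smooth random rotation of the direction in the ax/lat plane
    th <- stats::rnorm(1, 0, jitter)
    c2 <- cos(th); s2 <- sin(th)
    dir <- c(c2 * dir[1] - s2 * dir[2], s2 * dir[1] + c2 * dir[2], dir[3])
    dir <- dir / sqrt(sum(dir^2))
    pts[k, ] <- pts[k - 1, ] + step * dir
  }
  pts[, 1] <- pmin(pmax(pts[, 1], margin), extent[1] - margin)
  pts[, 2] <- pmin(pmax(pts[, 2], margin), extent[2] - margin)
  pts[, 3] <- pmin(pmax(pts[, 3], margin), extent[3] - margin)
  pts
}

# point on polyline at arc fraction f in [0, 1]
polyline_point_at <- function(pts, f) {
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  drop(interp_polyline(pts, cum, f * cum[length(cum)]))
}

#' Generate a kidney-like vascular phantom
#'
#' Builds the paired artery/vein trees plus vasa recta bundles described in
#' [phantom_config()], deterministically from `(config, seed)`.
#'
#' @param config a [phantom_config()].
#' @param seed integer master seed.
#' @return a `kidney_phantom`: list of `vessel_segment`s, extent, region
#'   band boundaries, config and seed.
#' @export
generate_kidney_phantom <- function(config = phantom_config(), seed = 1) {
  validate_phantom_config(config)
  with_seed(derive_seed(seed, "phantom"), {
    ext <- config$extent
    margin <- 0.3
    hilum <- c(config$hilum_frac[1] * ext[1],
               config$hilum_frac[2] * ext[2], 0.5 * ext[3])
    segs <- list()
    nid <- 0L
    add <- function(...) {
      nid <<- nid + 1L
      s <- new_vessel_segment(id = nid, ...)
      segs[[nid]] <<- s
      nid
    }
    spd <- function(cls, side) config$mean_speed[[cls]][[side]]
    rad <- function(cls, side) config$radius[[cls]][[side]]
    puls <- function(side) if (side == "artery") config$pulsatility else 0

    # --- arterial tree ---
    renal_ids <- integer(0)
    for (b in seq_len(config$n_renal_branches)) {
      ang <- (b - 0.5) / max(config$n_renal_branches, 1) * pi / 2 - pi / 4
      dir <- c(-cos(ang) * 0.5, sin(ang), 0)
      pl <- grow_polyline(hilum, dir, 0.22 * ext[2], 5, config$seed_jitter,
                          ext, margin)
      renal_ids <- c(renal_ids,
                     add(parent_id = NA, polyline = pl,
                         radius = rad("renal_branch", "artery"),
                         vessel_class = "renal_branch", side = "artery",
                         mean_speed = spd("renal_branch", "artery"),
                         pulsatility = puls("artery"),
                         flow_sense = "antegrade"))
    }
    seg_ids <- integer(0)
    for (si in seq_len(config$n_segmental)) {
      parent <- renal_ids[(si - 1) %% length(renal_ids) + 1]
      pstart <- polyline_point_at(segs[[parent]]$polyline,
                                  stats::runif(1, 0.6, 1))
      ang <- (si - 0.5) / config$n_segmental * pi * 0.8 - pi * 0.4
      dir <- c(-cos(ang * 0.5), sin(ang), stats::runif(1, -0.1, 0.1))
      pl <- grow_polyline(pstart, dir, 0.25 * ext[1], 6, config$seed_jitter,
                          ext, margin)
      seg_ids <- c(seg_ids,
                   add(parent_id = parent, polyline = pl,
                       radius = rad("segmental", "artery"),
                       vessel_class = "segmental", side = "artery",
                       mean_speed = spd("segmental", "artery"),
                       pulsatility = puls("artery"),
                       flow_sense = "antegrade"))
    }
    arc_ids <- integer(0)
    for (pid in seg_ids) {
      for (ai in seq_len(config$n_arcuate_per_segmental)) {
        pstart <- polyline_point_at(segs[[pid]]$polyline,
                                    stats::runif(1, 0.7, 1))
        lat_sign <- if (ai %% 2 == 0) 1 else -1
        dir <- c(-0.4, lat_sign * 1, stats::runif(1, -0.15, 0.15))
        pl <- grow_polyline(pstart, dir, 0.18 * ext[2], 6,
                            config$seed_jitter, ext, margin)
        arc_ids <- c(arc_ids,
                     add(parent_id = pid, polyline = pl,
                         radius = rad("arcuate", "artery"),
                         vessel_class = "arcuate", side = "artery",
                         mean_speed = spd("arcuate", "artery"),
                         pulsatility = puls("artery"),
                         flow_sense = "antegrade"))
      }
    }
    for (pid in arc_ids) {
      for (ci in seq_len(config$n_cortical_per_arcuate)) {
        pstart <- polyline_point_at(segs[[pid]]$polyline,
                                    stats::runif(1, 0.4, 0.95))
        dir <- c(-1, stats::runif(1, -0.3, 0.3), stats::runif(1, -0.1, 0.1))
        pl <- grow_polyline(pstart, dir, 0.2 * ext[1], 5,
                            config$seed_jitter, ext, margin)
        add(parent_id = pid, polyline = pl,
            radius = rad("cortical_radial", "artery"),
            vessel_class = "cortical_radial", side = "artery",
            mean_speed = spd("cortical_radial", "artery"),
            pulsatility = puls("artery"), flow_sense = "antegrade")
      }
    }
    n_art <- nid

    # --- venous tree: parallel offset copy of the arterial tree ---
    # offset scales with the artery radius (wrapping veins run 1.5-3 radii
    # from their artery); each child vein is re-anchored on its parent vein
    # so the venous tree stays geometrically connected.
    art_to_vein <- integer(n_art)
    for (k in seq_len(n_art)) {
      a <- segs[[k]]
      off <- config$vein_offset_dir * config$vein_offset_factor * a$radius
      pl <- sweep(a$polyline, 2, -off)
      pl[, 1] <- pmin(pmax(pl[, 1], margin), ext[1] - margin)
      pl[, 2] <- pmin(pmax(pl[, 2], margin), ext[2] - margin)
      pl[, 3] <- pmin(pmax(pl[, 3], margin), ext[3] - margin)
      vparent <- if (is.na(a$parent_id)) NA else art_to_vein[a$parent_id]
      if (!is.na(vparent)) {
        # re-anchor: prepend the nearest point on the parent vein polyline
        pp <- segs[[vparent]]$polyline
        ppts <- resample_polyline(pp, 0.05)
        dd <- sqrt(rowSums(sweep(ppts, 2, pl[1, ])^2))
        pl <- rbind(ppts[which.min(dd), ], pl)
      }
      vid <- add(parent_id = vparent, polyline = pl,
                 radius = config$radius[[a$vessel_class]][["vein"]],
                 vessel_class = a$vessel_class, side = "vein",
                 mean_speed = config$mean_speed[[a$vessel_class]][["vein"]],
                 pulsatility = 0, flow_sense = "antegrade")
      art_to_vein[k] <- vid
      segs[[k]]$paired_id <- vid
      segs[[vid]]$paired_id <- k
    }

    # --- vasa recta bundles: straight parallel vessels in the medulla,
    # stacked in elevation; descending (artery, antegrade) and ascending
    # (vein, retrograde) alternate within a bundle ---
    if (config$n_vasa_bundles > 0 && length(arc_ids) > 0) {
      med_top <- 0.25 * ext[1]
      med_bot <- 0.62 * ext[1]
      for (b in seq_len(config$n_vasa_bundles)) {
        pa <- arc_ids[(b - 1) %% length(arc_ids) + 1]
        anchor <- polyline_point_at(segs[[pa]]$polyline, 0.5)
        for (v in seq_len(config$bundle_size)) {
          side <- if (v %% 2 == 1) "artery" else "vein"
          parent <- if (side == "artery") pa else art_to_vein[pa]
          z <- anchor[3] + (v - (config$bundle_size + 1) / 2) *
            config$bundle_spacing
          z <- min(max(z, margin), ext[3] - margin)
          lat <- anchor[2] + stats::runif(1, -0.05, 0.05)
          top <- c(med_top, lat, z)
          bot <- c(min(med_bot, anchor[1]), lat, z)
          pl <- rbind(anchor, bot, top)   # anchored on the arcuate parent
          add(parent_id = parent, polyline = pl,
              radius = rad("vasa_recta", side),
              vessel_class = "vasa_recta", side = side,
              mean_speed = spd("vasa_recta", side),
              pulsatility = puls(side),
              flow_sense = if (side == "artery") "antegrade" else "retrograde")
        }
      }
    }

    # region partition: contiguous axial bands covering the full extent
    bands <- c(0, 0.25, 0.43, 0.62, 0.84, 1) * ext[1]
    names(bands) <- c("", "cortex", "outer_medulla", "inner_medulla",
                      "segmental_or_larger_arcuate", "hilum")
    structure(list(segments = segs, extent = ext,
                   region_bands = bands, seed = seed, config = config),
              class = "kidney_phantom")
  })
}

#' @export
print.kidney_phantom <- function(x, ...) {
  cls <- vapply(x$segments, function(s) s$vessel_class, "")
  side <- vapply(x$segments, function(s) s$side, "")
  cat("kidney_phantom:", length(x$segments), "segments, extent",
      paste(round(x$extent, 1), collapse = " x "), "mm\n")
  print(table(cls, side))
  invisible(x)
}

#' Region label for 3D points
#'
#' Labels points of the phantom extent with the axial-band region partition
#' (`hilum`, `segmental_or_larger_arcuate`, `inner_medulla`, `outer_medulla`,
#' `cortex`); every point of the extent gets exactly one label.
#'
#' @param phantom a `kidney_phantom`.
#' @param pts n x 3 matrix of mm points.
#' @return character vector of labels.
#' @export
region_label_points <- function(phantom, pts) {
  pts <- rbind(pts)
  b <- phantom$region_bands
  lab <- names(b)[-1]
  idx <- findInterval(pts[, 1], b, rightmost.closed = TRUE,
                      all.inside = TRUE)
  lab[idx]
}

# --- helpers used across modules and tests -------------------------------

phantom_segments_df <- function(phantom) {
  do.call(rbind, lapply(phantom$segments, function(s)
    data.frame(id = s$id, parent_id = s$parent_id,
               vessel_class = s$vessel_class, side = s$side,
               radius = s$radius, mean_speed = s$mean_speed,
               pulsatility = s$pulsatility, flow_sense = s$flow_sense,
               paired_id = s$paired_id, n_points = nrow(s$polyline))))
}

#' Ground-truth 3D centerlines of a phantom
#'
#' @param phantom a `kidney_phantom`.
#' @param classes optional subset of vessel classes.
#' @param sides optional subset of `c("artery", "vein")`.
#' @return list of labeled polylines (`points` n x 3 mm, `label`, `id`).
#' @export
phantom_centerlines <- function(phantom, classes = NULL, sides = NULL) {
  keep <- vapply(phantom$segments, function(s) {
    (is.null(classes) || s$vessel_class %in% classes) &&
      (is.null(sides) || s$side %in% sides)
  }, TRUE)
  lapply(phantom$segments[keep], function(s)
    list(points = s$polyline, id = s$id,
         label = paste(s$vessel_class, s$side, sep = "/"),
         vessel_class = s$vessel_class, side = s$side, radius = s$radius))
}
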