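# Fixtures built in code: hand-made phantoms with known geometry, plus
# small independent oracles used across the suite.

make_segment <- function(id, polyline, radius = 0.2,
                         vessel_class = "segmental", side = "artery",
                         mean_speed = 5, pulsatility = 0, parent_id = NA,
                         flow_sense = "antegrade", paired_id = NA) {
  srusct:::new_vessel_segment(id, parent_id, polyline, radius,
                              vessel_class, side, mean_speed, pulsatility,
                              flow_sense, paired_id)
}

make_phantom <- function(segments, extent = c(10, 10, 4)) {
  bands <- c(0, 0.25, 0.43, 0.62, 0.84, 1) * extent[1]
  names(bands) <- c("", "cortex", "outer_medulla", "inner_medulla",
                    "segmental_or_larger_arcuate", "hilum")
  structure(list(segments = segments, extent = extent,
                 region_bands = bands, seed = 0,
                 config = list(cardiac_rate = 5)),
            class = "kidney_phantom")
}

# a single straight tube along the lateral axis at given axial/elev level
straight_phantom <- function(axial = 5, elev = 2, radius = 0.2,
                             mean_speed = 5, side = "artery",
                             extent = c(10, 10, 4), pulsatility = 0) {
  seg <- make_segment(1, rbind(c(axial, 0.5, elev),
                               c(axial, extent[2] - 0.5, elev)),
                      radius = radius, side = side,
                      mean_speed = mean_speed, pulsatility = pulsatility)
  make_phantom(list(seg), extent)
}

# graph-traversal oracle: is the side's tree connected via parent links,
# with every child's first point geometrically on/near its parent?
tree_connected_oracle <- function(phantom, side) {
  segs <- Filter(function(s) s$side == side, phantom$segments)
  ids <- vapply(segs, function(s) s$id, 1L)
  roots <- ids[vapply(segs, function(s) is.na(s$parent_id), TRUE)]
  if (length(roots) == 0) return(FALSE)
  parent_of <- stats::setNames(
    vapply(segs, function(s) ifelse(is.na(s$parent_id), 0L, s$parent_id),
           1L), as.character(ids))
  reach <- as.character(roots)
  repeat {
    add <- names(parent_of)[as.character(parent_of) %in% reach &
                              !(names(parent_of) %in% reach)]
    if (!length(add)) break
    reach <- c(reach, add)
  }
  if (length(reach) != length(ids)) return(FALSE)
  by_id <- stats::setNames(phantom$segments,
                           vapply(phantom$segments,
                                  function(s) as.character(s$id), ""))
  for (s in segs) {
    if (is.na(s$parent_id)) next
    p <- by_id[[as.character(s$parent_id)]]
    d <- srusct:::dist_to_polyline(s$polyline[1, , drop = FALSE],
                                   p$polyline)
    if (d > p$radius + 1e-6) return(FALSE)
  }
  TRUE
}

# detections data.frame helper
det_df <- function(frame, axial, lateral, amplitude = 1) {
  data.frame(frame = as.integer(frame), axial = axial, lateral = lateral,
             amplitude = amplitude, compensated = FALSE)
}

# Exhaustive-assignment tracking oracle: per frame, enumerate all feasible
# injective matchings between active tracks (gated by the distance from
# each track's last detection) and detections; pick the matching with the
# most links, breaking ties by total distance. Independent of the Kalman
# path: predictions are not used.
oracle_tracker <- function(detections, gate_mm, min_frames) {
  frames <- sort(unique(detections$frame))
  if (!length(frames)) return(list())
  active <- list(); done <- list()
  for (fr in seq(min(frames), max(frames))) {
    dets <- detections[detections$frame == fr, , drop = FALSE]
    na <- length(active); nd <- nrow(dets)
    best <- NULL
    if (na > 0 && nd > 0) {
      dmat <- matrix(Inf, na, nd)
      for (a in seq_len(na)) {
        last <- active[[a]][nrow(active[[a]]), ]
        dmat[a, ] <- sqrt((dets$axial - last$axial)^2 +
                            (dets$lateral - last$lateral)^2)
      }
      feas <- dmat <= gate_mm
      # enumerate assignments of tracks to detections (or none)
      best_links <- -1; best_cost <- Inf
      assign_rec <- function(a, used, links, cost, cur) {
        if (a > na) {
          if (links > best_links ||
              (links == best_links && cost < best_cost - 1e-12)) {
            best_links <<- links; best_cost <<- cost; best <<- cur
          }
          return()
        }
        assign_rec(a + 1, used, links, cost, c(cur, NA))
        for (j in seq_len(nd)) {
          if (!used[j] && feas[a, j]) {
            used[j] <- TRUE
            assign_rec(a + 1, used, links + 1, cost + dmat[a, j],
                       c(cur, j))
            used[j] <- FALSE
          }
        }
      }
      assign_rec(1, rep(FALSE, nd), 0, 0, integer(0))
    }
    keep <- rep(FALSE, na); taken <- rep(FALSE, nd)
    if (!is.null(best)) {
      for (a in seq_len(na)) {
        j <- best[a]
        if (!is.na(j)) {
          active[[a]] <- rbind(active[[a]], dets[j, ])
          keep[a] <- TRUE; taken[j] <- TRUE
        }
      }
    }
    if (na > 0) {
      done <- c(done, active[!keep])
      active <- active[keep]
    }
    if (nd > 0)
      for (j in which(!taken))
        active[[length(active) + 1]] <- dets[j, , drop = FALSE]
  }
  done <- c(done, active)
  Filter(function(r) nrow(r) >= min_frames, done)
}

# canonical representation of a set of links for comparing trackers
links_key <- function(track_rows_list) {
  out <- character(0)
  for (r in track_rows_list) {
    if (nrow(r) < 2) next
    for (k in seq_len(nrow(r) - 1))
      out <- c(out, sprintf("%d:%.6f,%.6f->%.6f,%.6f", r$frame[k],
                            r$axial[k], r$lateral[k], r$axial[k + 1],
                            r$lateral[k + 1]))
  }
  sort(out)
}

track_rows <- function(tracks) lapply(tracks, function(t_) t_$detections)
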