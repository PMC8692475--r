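# Kalman-gated microbubble track linking.
#
# Per active track a constant-velocity Kalman filter predicts the next
# position; frame-to-frame correspondence is the optimal bipartite
# assignment between predictions and detections (Hungarian algorithm on
# Euclidean distance), with a hard distance gate applied between the new
# detection and the track's last detection so that no emitted link can
# exceed the gate. Tracks require strictly consecutive frames (no
# coasting); unassigned detections seed new candidates; candidates shorter
# than the minimum frame count are discarded.

#' Tracking parameters
#'
#' @param max_link_distance hard gate on the distance between linked
#'   detections, micrometers (default 278).
#' @param min_track_frames minimum consecutive frames for a track
#'   (default 3).
#' @param process_noise constant-velocity model acceleration noise
#'   (mm/s^2 s.d.); kept small so the gate, not the covariance, dominates.
#' @param measurement_noise localization noise s.d., mm.
#' @export
tracking_params <- function(max_link_distance = 278, min_track_frames = 3,
                            process_noise = 20, measurement_noise = 0.02) {
  if (max_link_distance <= 0)
    stop("`max_link_distance` must be > 0", call. = FALSE)
  if (min_track_frames < 2)
    stop("`min_track_frames` must be >= 2", call. = FALSE)
  structure(list(max_link_distance = max_link_distance,
                 min_track_frames = as.integer(min_track_frames),
                 process_noise = process_noise,
                 measurement_noise = measurement_noise),
            class = "tracking_params")
}

# Hungarian algorithm (shortest augmenting path with potentials) for a
# rectangular cost matrix; returns for each row the assigned column (NA if
# unassigned). Requires nrow <= ncol internally; transposes otherwise.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) { cost <- t(cost); transposed <- TRUE; tmp <- n; n <- m; m <- tmp }
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)   # p[j]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign_row[p[j + 1]] <- j
  if (transposed) {
    out <- rep(NA_integer_, ncol(cost))
    for (r in seq_len(n)) if (!is.na(assign_row[r])) out[assign_row[r]] <- r
    out
  } else {
    assign_row
  }
}

# --- Kalman filter (constant velocity, 2D) --------------------------------

kf_init <- function(pos, params, dt) {
  r2 <- params$measurement_noise^2
  list(x = c(pos, 0, 0),
       P = diag(c(r2, r2, (params$max_link_distance / 1000 / dt)^2,
                  (params$max_link_distance / 1000 / dt)^2)),
       dt = dt)
}

kf_predict <- function(kf, params) {
  dt <- kf$dt
  f_ <- diag(4); f_[1, 3] <- dt; f_[2, 4] <- dt
  q <- params$process_noise^2
  g <- c(dt^2 / 2, dt^2 / 2, dt, dt)
  qm <- q * outer(g, g) * diag(c(1, 1, 1, 1))
  kf$x <- drop(f_ %*% kf$x)
  kf$P <- f_ %*% kf$P %*% t(f_) + qm
  kf
}

kf_update <- function(kf, pos, params) {
  h <- matrix(0, 2, 4); h[1, 1] <- 1; h[2, 2] <- 1
  r <- diag(2) * params$measurement_noise^2
  s <- h %*% kf$P %*% t(h) + r
  k <- kf$P %*% t(h) %*% solve(s)
  kf$x <- drop(kf$x + k %*% (pos - drop(h %*% kf$x)))
  kf$P <- (diag(4) - k %*% h) %*% kf$P
  kf
}

#' Link detections into microbubble tracks
#'
#' @param detections data.frame with `frame`, `axial`, `lateral` (mm).
#' @param params a [tracking_params()].
#' @param frame_rate Hz, used for velocities and the Kalman time step.
#' @return list of tracks; each track is a list with `detections`
#'   (data.frame ordered by frame, strictly consecutive), `velocities`
#'   (per-link, mm/s), `mean_direction` (degrees), `path_length_um`,
#'   `n_links`. Class `track_set`.
#' @export
link_tracks <- function(detections, params = tracking_params(),
                        frame_rate = 54) {
  gate_mm <- params$max_link_distance / 1000
  dt <- 1 / frame_rate
  active <- list()    # each: list(rows = df, kf = kf state)
  done <- list()
  frames_present <- sort(unique(detections$frame))
  all_frames <- if (length(frames_present))
    seq(min(frames_present), max(frames_present)) else integer(0)
  for (fr in all_frames) {
    dets <- detections[detections$frame == fr, , drop = FALSE]
    nd <- nrow(dets); na <- length(active)
    assigned_det <- rep(FALSE, nd)
    keep <- rep(FALSE, na)
    if (na > 0) {
      # predict
      for (t_ in seq_len(na))
        active[[t_]]$kf <- kf_predict(active[[t_]]$kf, params)
      if (nd > 0) {
        pred <- t(vapply(active, function(a) a$kf$x[1:2], numeric(2)))
        last <- t(vapply(active, function(a) {
          r <- a$rows; c(r$axial[nrow(r)], r$lateral[nrow(r)])
        }, numeric(2)))
        dp <- cbind(dets$axial, dets$lateral)
        cost <- matrix(0, na, nd)
        feas <- matrix(FALSE, na, nd)
        for (t_ in seq_len(na)) {
          dpred <- sqrt((dp[, 1] - pred[t_, 1])^2 +
                          (dp[, 2] - pred[t_, 2])^2)
          dlast <- sqrt((dp[, 1] - last[t_, 1])^2 +
                          (dp[, 2] - last[t_, 2])^2)
          feas[t_, ] <- dlast <= gate_mm
          cost[t_, ] <- dpred
        }
        BIG <- 1e6
        cost[!feas] <- BIG
        sol <- solve_assignment(cost)
        for (t_ in seq_len(na)) {
          j <- sol[t_]
          if (!is.na(j) && feas[t_, j]) {
            active[[t_]]$rows <- rbind(active[[t_]]$rows, dets[j, ])
            active[[t_]]$kf <- kf_update(active[[t_]]$kf,
                                         c(dets$axial[j], dets$lateral[j]),
                                         params)
            assigned_det[j] <- TRUE
            keep[t_] <- TRUE
          }
        }
      }
    }
    # terminate unextended tracks (consecutive frames required)
    if (na > 0) {
      done <- c(done, lapply(active[!keep], function(a) a$rows))
      active <- active[keep]
    }
    # new candidates from unassigned detections
    if (nd > 0) {
      for (j in which(!assigned_det)) {
        active[[length(active) + 1]] <- list(
          rows = dets[j, , drop = FALSE],
          kf = kf_init(c(dets$axial[j], dets$lateral[j]), params, dt))
      }
    }
  }
  done <- c(done, lapply(active, function(a) a$rows))
  done <- Filter(function(r) nrow(r) >= params$min_track_frames, done)
  tracks <- lapply(seq_along(done), function(k) {
    r <- done[[k]]
    rownames(r) <- NULL
    d <- cbind(diff(r$axial), diff(r$lateral))
    linklen <- sqrt(rowSums(d^2))
    list(id = k, detections = r,
         velocities = linklen * frame_rate,
         link_angles = angle_deg(d[, 1], d[, 2]),
         mean_direction = angle_deg(sum(d[, 1]), sum(d[, 2])),
         path_length_um = sum(linklen) * 1000,
         n_links = nrow(r) - 1L)
  })
  structure(tracks, class = "track_set",
            params = params, frame_rate = frame_rate)
}

#' Track summary statistics
#'
#' @param tracks a `track_set`.
#' @param speed_probs quantile probabilities for link speeds.
#' @return list: `n_tracks`, `n_links`, `median_path_length_um`,
#'   `speed_quantiles_mm_s`; medians are `NA` (flagged `undefined`) for
#'   empty input.
#' @export
track_statistics <- function(tracks, speed_probs = c(0.25, 0.5, 0.75)) {
  if (length(tracks) == 0)
    return(list(n_tracks = 0L, n_links = 0L,
                median_path_length_um = NA_real_,
                speed_quantiles_mm_s = stats::setNames(rep(NA_real_,
                                                    length(speed_probs)),
                                                paste0(speed_probs * 100, "%")),
                undefined = TRUE))
  lens <- vapply(tracks, function(t_) t_$path_length_um, 1)
  speeds <- unlist(lapply(tracks, function(t_) t_$velocities))
  list(n_tracks = length(tracks),
       n_links = sum(vapply(tracks, function(t_) t_$n_links, 1L)),
       median_path_length_um = stats::median(lens),
       speed_quantiles_mm_s = stats::quantile(speeds, speed_probs),
       undefined = FALSE)
}
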