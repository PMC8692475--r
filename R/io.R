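# Plain-text external interfaces. Rasters and volumes travel as CSV
# matrices (one file per frame/slice) with a JSON sidecar carrying the
# physical metadata (pixel size, frame rate, origin, spacing); metadata is
# mandatory on import and never guessed. Phantoms, centerlines and
# transforms are schema-versioned JSON; events and tracks are CSV.

SCHEMA_VERSION <- "1.0"

write_matrix_csv <- function(m, path) {
  # %.17g keeps doubles round-trip exact
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                         collapse = ","))
  writeLines(lines, path)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write a frame stack to a directory (CSV frames + JSON sidecar)
#' @param stack a `frame_stack`.
#' @param dir output directory (created).
#' @export
write_frame_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$frames)
  for (k in seq_len(d[3]))
    write_matrix_csv(stack$frames[, , k],
                     file.path(dir, sprintf("frame_%04d.csv", k)))
  sidecar <- list(schema_version = SCHEMA_VERSION, kind = "frame_stack",
                  nrow = d[1], ncol = d[2], n_frames = d[3],
                  pixel_size_mm = stack$pixel_size,
                  frame_rate_hz = stack$frame_rate,
                  origin_mm = stack$grid$origin)
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame stack written by [write_frame_stack()]
#' @param dir directory containing `frame_*.csv` and `sidecar.json`.
#' @export
read_frame_stack <- function(dir) {
  sc_path <- file.path(dir, "sidecar.json")
  if (!file.exists(sc_path))
    stop("missing sidecar.json: frame metadata is mandatory", call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(sc$pixel_size_mm))
    stop("sidecar lacks `pixel_size_mm`; refusing to guess", call. = FALSE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame files found", call. = FALSE)
  frames <- array(0, c(sc$nrow, sc$ncol, length(files)))
  for (k in seq_along(files)) {
    m <- read_matrix_csv(files[k])
    if (nrow(m) != sc$nrow || ncol(m) != sc$ncol)
      stop(sprintf("frame %d is %d x %d but sidecar declares %d x %d",
                   k, nrow(m), ncol(m), sc$nrow, sc$ncol), call. = FALSE)
    frames[, , k] <- m
  }
  grid <- raster_grid(sc$nrow, sc$ncol, sc$pixel_size_mm,
                      origin = as.numeric(sc$origin_mm))
  new_frame_stack(frames, grid, sc$frame_rate_hz)
}

#' Write a CT volume (CSV slices + JSON sidecar)
#' @param ct a `synthetic_ct`.
#' @param dir output directory.
#' @export
write_volume <- function(ct, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ct$voxels)
  for (k in seq_len(d[3]))
    write_matrix_csv(ct$voxels[, , k],
                     file.path(dir, sprintf("slice_%04d.csv", k)))
  sidecar <- list(schema_version = SCHEMA_VERSION, kind = "volume",
                  dims = d, spacing_mm = ct$spacing, origin_mm = ct$origin)
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a CT volume written by [write_volume()]
#' @param dir directory with `slice_*.csv` and `sidecar.json`.
#' @export
read_volume <- function(dir) {
  sc_path <- file.path(dir, "sidecar.json")
  if (!file.exists(sc_path))
    stop("missing sidecar.json: volume metadata is mandatory",
         call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(sc$spacing_mm))
    stop("sidecar lacks `spacing_mm`; refusing to guess", call. = FALSE)
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.csv$",
                           full.names = TRUE))
  dims <- as.integer(sc$dims)
  vox <- array(0, dims)
  for (k in seq_along(files)) {
    m <- read_matrix_csv(files[k])
    if (nrow(m) != dims[1] || ncol(m) != dims[2])
      stop(sprintf("slice %d is %d x %d but sidecar declares %d x %d",
                   k, nrow(m), ncol(m), dims[1], dims[2]), call. = FALSE)
    vox[, , k] <- m
  }
  new_synthetic_ct(vox, sc$spacing_mm, as.numeric(sc$origin_mm))
}

#' Write a phantom to schema-versioned JSON
#' @param phantom a `kidney_phantom`.
#' @param path output file.
#' @export
write_phantom_json <- function(phantom, path) {
  segs <- lapply(phantom$segments, function(s)
    list(id = s$id, parent_id = s$parent_id,
         polyline = unname(apply(s$polyline, 1, as.numeric,
                                 simplify = FALSE)),
         radius = s$radius, vessel_class = s$vessel_class, side = s$side,
         mean_speed = s$mean_speed, pulsatility = s$pulsatility,
         flow_sense = s$flow_sense, paired_id = s$paired_id))
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION, kind = "kidney_phantom",
         extent_mm = phantom$extent, region_bands_mm = phantom$region_bands,
         seed = phantom$seed, segments = segs),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a phantom from JSON
#' @param path file written by [write_phantom_json()].
#' @export
read_phantom_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- lapply(j$segments, function(s)
    new_vessel_segment(id = s$id,
                       parent_id = if (is.null(s$parent_id)) NA
                                   else s$parent_id,
                       polyline = do.call(rbind,
                                          lapply(s$polyline, unlist)),
                       radius = s$radius, vessel_class = s$vessel_class,
                       side = s$side, mean_speed = s$mean_speed,
                       pulsatility = s$pulsatility,
                       flow_sense = s$flow_sense,
                       paired_id = if (is.null(s$paired_id)) NA
                                   else s$paired_id))
  structure(list(segments = segs, extent = unlist(j$extent_mm),
                 region_bands = stats::setNames(
                   unlist(j$region_bands_mm),
                   names(j$region_bands_mm)),
                 seed = j$seed, config = NULL),
            class = "kidney_phantom")
}

#' Write events or ground truth to CSV
#' @param events events data.frame.
#' @param path output file.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read events CSV
#' @param path file written by [write_events_csv()].
#' @export
read_events_csv <- function(path) utils::read.csv(path)

#' Write tracks to CSV (`frame, x_mm, y_mm, amplitude, track_id`)
#' @param tracks a `track_set`.
#' @param path output file.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- lapply(tracks, function(t_) {
    r <- t_$detections
    data.frame(frame = r$frame, x_mm = r$axial, y_mm = r$lateral,
               amplitude = r$amplitude, track_id = t_$id)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a similarity transform to JSON (rotation row-major)
#' @param transform a `similarity_transform`.
#' @param path output file.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION, kind = "similarity_transform",
         rotation_row_major = as.numeric(t(transform$rotation)),
         scale = transform$scale,
         translation_mm = transform$translation),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a similarity transform from JSON
#' @param path file written by [write_transform_json()].
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(
    rotation = matrix(j$rotation_row_major, 3, 3, byrow = TRUE),
    scale = j$scale, translation = j$translation_mm)
}

#' Write labeled centerlines to JSON
#' @param centerlines list of polylines (`points` plus label fields).
#' @param path output file.
#' @export
write_centerlines_json <- function(centerlines, path) {
  out <- lapply(centerlines, function(cl) {
    cl$points <- unname(apply(rbind(cl$points), 1, as.numeric,
                              simplify = FALSE))
    cl
  })
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION,
                            kind = "centerlines", centerlines = out),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read labeled centerlines from JSON
#' @param path file written by [write_centerlines_json()].
#' @export
read_centerlines_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j$centerlines, function(cl) {
    cl$points <- do.call(rbind, lapply(cl$points, unlist))
    cl
  })
}

#' Import externally produced pipeline inputs
#'
#' Validates and normalizes real (or previously exported) data: a contrast
#' frame stack, a CT volume, labeled 3D centerlines and a co-registration
#' transform. Missing metadata (pixel size, spacing) is a hard error.
#'
#' @param frames_dir frame-stack directory ([read_frame_stack()] format).
#' @param volume_dir volume directory ([read_volume()] format); optional.
#' @param centerlines_path centerlines JSON; optional.
#' @param transform_path transform JSON; optional.
#' @return list with `frames`, `volume`, `centerlines`, `transform`.
#' @export
import_real_data <- function(frames_dir, volume_dir = NULL,
                             centerlines_path = NULL,
                             transform_path = NULL) {
  out <- list(frames = read_frame_stack(frames_dir))
  out$volume <- if (!is.null(volume_dir)) read_volume(volume_dir)
  out$centerlines <- if (!is.null(centerlines_path))
    read_centerlines_json(centerlines_path)
  out$transform <- if (!is.null(transform_path))
    read_transform_json(transform_path)
  out
}
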