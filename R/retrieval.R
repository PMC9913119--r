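#' Stage calibration for image-to-stage coordinate conversion
#'
#' Describes how pixel coordinates of each acquired tile map onto absolute
#' stage positions: the stage position (µm) of every tile's pixel (0,0)
#' corner, the pixel pitch, per-axis sign flips, and an optional axis swap
#' (applied last) for stages whose x/y are transposed with respect to the
#' camera. All stage math is in µm (stage native), pixel sizes in nm.
#'
#' @param pixel_size_nm pixel pitch of the acquisition objective.
#' @param tile_offsets_um data.frame with `tile_index`, `x_um`, `y_um` (the
#'   stage position of each tile's pixel-origin corner).
#' @param sx,sy axis sign flags, +1 or -1.
#' @param swap_axes swap stage x/y after scaling and sign.
#' @return object of class `stage_calibration`.
#' @export
stage_calibration <- function(pixel_size_nm, tile_offsets_um,
                              sx = 1L, sy = 1L, swap_axes = FALSE) {
  if (pixel_size_nm <= 0) .stop2("calibration_error", "pixel_size_nm must be > 0")
  if (!all(c("tile_index", "x_um", "y_um") %in% names(tile_offsets_um)))
    .stop2("calibration_error", "tile_offsets_um needs tile_index, x_um, y_um")
  if (!all(abs(c(sx, sy)) == 1))
    .stop2("calibration_error", "axis signs must be +1 or -1")
  structure(list(pixel_size_nm = pixel_size_nm,
                 tile_offsets_um = tile_offsets_um,
                 sx = sx, sy = sy, swap_axes = swap_axes),
            class = "stage_calibration")
}

#' Read / write a stage calibration as YAML
#' @param path YAML file.
#' @param calib a [stage_calibration()].
#' @return the calibration (read) or `path` invisibly (write).
#' @export
read_stage_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  off <- do.call(rbind, lapply(y$tiles, function(t)
    data.frame(tile_index = t$tile_index, x_um = t$x_um, y_um = t$y_um)))
  stage_calibration(y$pixel_size_nm, off, sx = y$sx %||% 1L, sy = y$sy %||% 1L,
                    swap_axes = isTRUE(y$swap_axes))
}

#' @rdname read_stage_calibration
#' @export
write_stage_calibration <- function(calib, path) {
  yaml::write_yaml(list(
    pixel_size_nm = calib$pixel_size_nm, sx = calib$sx, sy = calib$sy,
    swap_axes = calib$swap_axes,
    tiles = lapply(seq_len(nrow(calib$tile_offsets_um)), function(i)
      as.list(calib$tile_offsets_um[i, ]))), path)
  invisible(path)
}

.tile_offset <- function(calib, tile_index) {
  i <- match(tile_index, calib$tile_offsets_um$tile_index)
  if (anyNA(i))
    .stop2("calibration_error", "unknown tile index: %s",
           paste(unique(tile_index[is.na(i)]), collapse = ", "))
  cbind(calib$tile_offsets_um$x_um[i], calib$tile_offsets_um$y_um[i])
}

#' Convert image centroids to absolute stage positions
#'
#' `stage = tile_offset + sign * (centroid_px + 0.5) * pixel_size` (µm,
#' pixel-centre convention), with the axis swap applied last.
#'
#' @param centroid_px n x 2 matrix (or length-2 vector) of 0-based pixel
#'   centroids, columns x and y.
#' @param tile_index tile index per event (recycled).
#' @param calibration a [stage_calibration()].
#' @return n x 2 matrix of stage positions, µm.
#' @export
image_to_stage <- function(centroid_px, tile_index, calibration) {
  p <- if (is.null(dim(centroid_px))) matrix(centroid_px, ncol = 2) else as.matrix(centroid_px)
  off <- .tile_offset(calibration, rep_len(tile_index, nrow(p)))
  um_per_px <- calibration$pixel_size_nm / 1000
  x <- off[, 1] + calibration$sx * (p[, 1] + 0.5) * um_per_px
  y <- off[, 2] + calibration$sy * (p[, 2] + 0.5) * um_per_px
  if (calibration$swap_axes) cbind(stage_x_um = y, stage_y_um = x)
  else cbind(stage_x_um = x, stage_y_um = y)
}

#' Convert stage positions back to in-tile pixel centroids
#'
#' Exact inverse of [image_to_stage()].
#'
#' @param stage_um n x 2 matrix (or length-2 vector) of stage positions, µm.
#' @param tile_index tile index per event (recycled).
#' @param calibration a [stage_calibration()].
#' @return n x 2 matrix of 0-based pixel centroids, columns x and y.
#' @export
stage_to_image <- function(stage_um, tile_index, calibration) {
  s <- if (is.null(dim(stage_um))) matrix(stage_um, ncol = 2) else as.matrix(stage_um)
  if (calibration$swap_axes) s <- s[, 2:1, drop = FALSE]
  off <- .tile_offset(calibration, rep_len(tile_index, nrow(s)))
  um_per_px <- calibration$pixel_size_nm / 1000
  cbind(x_px = (s[, 1] - off[, 1]) / (calibration$sx * um_per_px) - 0.5,
        y_px = (s[, 2] - off[, 2]) / (calibration$sy * um_per_px) - 0.5)
}

#' Build a position list for selected events
#'
#' One stage position per selected event (labels = cell ids), computed with
#' [image_to_stage()]; events whose tile is missing from the calibration
#' are skipped with a warning and counted in attribute `n_skipped`.
#'
#' @param event_ids selected `cell_id`s (e.g. from [select_events()]).
#' @param cell_table cell table with `cell_id`, `centroid_x_px`,
#'   `centroid_y_px`, `tile_index`.
#' @param calibration a [stage_calibration()].
#' @return a [position_list()], deterministic order (by id as given).
#' @export
build_position_list <- function(event_ids, cell_table, calibration) {
  rows <- match(event_ids, cell_table$cell_id)
  if (anyNA(rows))
    .stop2("validation_error", "event id(s) not in cell table: %s",
           paste(head(event_ids[is.na(rows)], 10), collapse = ", "))
  sub <- cell_table[rows, , drop = FALSE]
  known <- sub$tile_index %in% calibration$tile_offsets_um$tile_index
  n_skip <- sum(!known)
  if (n_skip > 0)
    warning(sprintf("%d event(s) skipped: tile metadata missing", n_skip))
  sub <- sub[known, , drop = FALSE]
  if (!nrow(sub)) {
    pl <- position_list()
  } else {
    st <- image_to_stage(cbind(sub$centroid_x_px, sub$centroid_y_px),
                         sub$tile_index, calibration)
    pl <- position_list(label = as.character(sub$cell_id),
                        stage_x_um = st[, 1], stage_y_um = st[, 2])
  }
  attr(pl, "n_skipped") <- n_skip
  pl
}
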