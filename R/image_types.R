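#' Calibrated image plane
#'
#' A single 2D intensity image plus its physical calibration: the unit all
#' imaging stages exchange. Pixel values are non-negative finite photon-scale
#' intensities; `pixel_size_nm` is the physical pitch; `origin_stage_um`,
#' when set, is the stage position of the (0,0) pixel corner.
#'
#' @param pixels numeric matrix, rows = y, columns = x, non-negative finite.
#' @param pixel_size_nm positive pixel pitch in nanometres.
#' @param channel channel name.
#' @param origin_stage_um optional numeric length-2 stage position (µm) of
#'   the pixel (0,0) corner.
#' @return an object of class `image_plane`.
#' @examples
#' p <- image_plane(matrix(0, 8, 8), pixel_size_nm = 65)
#' dim(p$pixels)
#' @export
image_plane <- function(pixels, pixel_size_nm, channel = "ch1",
                        origin_stage_um = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    .stop2("calibration_error", "pixel_size_nm must be a single positive number")
  if (any(!is.finite(pixels)))
    .stop2("validation_error", "image contains non-finite intensities")
  if (any(pixels < 0))
    .stop2("validation_error", "image contains negative intensities")
  if (!is.null(origin_stage_um)) {
    origin_stage_um <- as.numeric(origin_stage_um)
    stopifnot(length(origin_stage_um) == 2L, all(is.finite(origin_stage_um)))
  }
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 channel = as.character(channel),
                 origin_stage_um = origin_stage_um),
            class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, %.3g nm/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$channel))
  invisible(x)
}

#' Multi-channel, multi-plane image stack
#'
#' An ordered collection of [image_plane()] objects sharing dimensions and
#' pixel size. Planes are stored z-major, channel-minor: plane index
#' `(z - 1) * n_channels + c` holds channel `c` of slice `z`.
#'
#' @param planes list of `image_plane` objects.
#' @param channel_names character vector of channel names (cycle fastest).
#' @param z_step_nm positive z spacing in nm (use 1 for single-slice data).
#' @return an object of class `image_stack` with fields `planes`,
#'   `channel_names`, `n_z`, `z_step_nm`, `pixel_size_nm`.
#' @seealso [get_plane()]
#' @export
image_stack <- function(planes, channel_names = NULL, z_step_nm = 1) {
  if (!length(planes)) .stop2("validation_error", "stack needs >= 1 plane")
  stopifnot(all(vapply(planes, inherits, TRUE, "image_plane")))
  if (is.null(channel_names))
    channel_names <- unique(vapply(planes, `[[`, "", "channel"))
  nc <- length(channel_names)
  if (length(planes) %% nc != 0L)
    .stop2("validation_error", "plane count %d not a multiple of channel count %d",
           length(planes), nc)
  d0 <- dim(planes[[1]]$pixels); p0 <- planes[[1]]$pixel_size_nm
  for (p in planes)
    if (!identical(dim(p$pixels), d0) || p$pixel_size_nm != p0)
      .stop2("validation_error", "all planes must share dimensions and pixel size")
  if (!is.finite(z_step_nm) || z_step_nm <= 0)
    .stop2("calibration_error", "z_step_nm must be positive")
  structure(list(planes = planes, channel_names = channel_names,
                 n_z = length(planes) %/% nc, z_step_nm = z_step_nm,
                 pixel_size_nm = p0),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d x %d px, %d channel(s) [%s], %d z-slice(s), %.3g nm/px\n",
              nrow(x$planes[[1]]$pixels), ncol(x$planes[[1]]$pixels),
              length(x$channel_names), paste(x$channel_names, collapse = ", "),
              x$n_z, x$pixel_size_nm))
  invisible(x)
}

#' Extract one plane from a stack
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @param z 1-based z index.
#' @return the requested [image_plane()].
#' @export
get_plane <- function(stack, channel = 1L, z = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    ci <- match(channel, stack$channel_names)
    if (is.na(ci)) .stop2("validation_error", "unknown channel '%s'", channel)
  } else ci <- as.integer(channel)
  if (z < 1L || z > stack$n_z) .stop2("validation_error", "z index out of range")
  stack$planes[[(z - 1L) * length(stack$channel_names) + ci]]
}

# physical x/y (nm) of pixel centres of a plane, 0-based pixel convention
.pixel_centers_nm <- function(plane) {
  d <- dim(plane$pixels)
  list(x = (seq_len(d[2]) - 0.5) * plane$pixel_size_nm,
       y = (seq_len(d[1]) - 0.5) * plane$pixel_size_nm)
}
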