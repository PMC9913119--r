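# ---- grayscale morphology with a disc structuring element ------------------
# column shift with +Inf padding: out[, j] = m[, j + d]
.shift_cols <- function(m, d) {
  n <- ncol(m)
  if (d == 0) return(m)
  out <- matrix(Inf, nrow(m), n)
  if (d > 0 && d < n) out[, seq_len(n - d)] <- m[, (d + 1):n]
  if (d < 0 && -d < n) out[, (1 - d):n] <- m[, seq_len(n + d)]
  out
}

.shift_rows <- function(m, d) t(.shift_cols(t(m), d))

# running minimum over a centred window of half-width w along columns,
# via log-doubling (van Herk style)
.runmin_cols <- function(m, w) {
  if (w == 0) return(m)
  n <- ncol(m)
  W <- 2 * w + 1
  # pad so border windows are correct partial minima
  P <- cbind(matrix(Inf, nrow(m), w), m, matrix(Inf, nrow(m), w))
  len <- 1
  while (len * 2 <= W) { P <- pmin(P, .shift_cols(P, len)); len <- len * 2 }
  res <- pmin(P, .shift_cols(P, W - len))
  res[, seq_len(n), drop = FALSE]
}

# grayscale erosion with a disc of the given radius: the disc is decomposed
# into rows of half-width floor(sqrt(r^2 - dy^2)); each row is a separable
# horizontal running min, combined over vertical offsets
.erode_disc <- function(m, radius) {
  r <- as.integer(radius)
  dys <- -r:r
  widths <- floor(sqrt(pmax(r^2 - dys^2, 0)))
  uw <- sort(unique(widths))
  rows <- lapply(uw, function(w) .runmin_cols(m, w))
  names(rows) <- as.character(uw)
  out <- matrix(Inf, nrow(m), ncol(m))
  for (k in seq_along(dys))
    out <- pmin(out, .shift_rows(rows[[as.character(widths[k])]], dys[k]))
  out
}

.dilate_disc <- function(m, radius) -.erode_disc(-m, radius)

.opening_disc <- function(m, radius) .dilate_disc(.erode_disc(m, radius), radius)

# block-minimum shrink by integer factor k (pads the partial border block)
.block_min <- function(m, k) {
  d <- dim(m)
  nr <- ceiling(d[1] / k); nc <- ceiling(d[2] / k)
  pad <- matrix(Inf, nr * k, nc * k)
  pad[seq_len(d[1]), seq_len(d[2])] <- m
  out <- matrix(Inf, nr, nc)
  for (i in seq_len(k)) for (j in seq_len(k))
    out <- pmin(out, pad[seq(i, nr * k, by = k), seq(j, nc * k, by = k)])
  out
}

#' Rolling-ball style background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the plane with a disc structuring element of the given radius (the
#' envelope a ball of that radius can reach from below) and subtracts it.
#' As in classic rolling-ball implementations the estimate is computed on a
#' lightly smoothed copy (otherwise the erosion tracks the lower noise
#' envelope instead of the background level), for large radii on a
#' block-shrunk copy, and then subtracted from the original at full
#' resolution. Output is clamped at 0.
#'
#' @param plane an [image_plane()] (a bare matrix is accepted).
#' @param radius_px ball radius in pixels (>= 1).
#' @param presmooth_sigma_px Gaussian sigma of the pre-smoothing used for
#'   the background estimate only (0 disables).
#' @param shrink integer shrink factor for the background estimate
#'   (`"auto"`: `radius_px / 8`, at least 1).
#' @return background-subtracted [image_plane()].
#' @export
subtract_background <- function(plane, radius_px,
                                presmooth_sigma_px = max(2, radius_px / 8),
                                shrink = "auto") {
  m <- if (inherits(plane, "image_plane")) plane$pixels else as.matrix(plane)
  if (radius_px < 1) .stop2("parameter_error", "radius_px must be >= 1")
  if (2 * radius_px + 1 > min(dim(m)))
    .stop2("parameter_error", "rolling-ball radius %d exceeds the image", radius_px)
  if (identical(shrink, "auto")) shrink <- max(1L, as.integer(radius_px / 8))
  sm <- if (presmooth_sigma_px > 0) EBImage::gblur(m, presmooth_sigma_px) else m
  if (shrink > 1) {
    small <- .block_min(sm, shrink)
    bg_small <- .opening_disc(small, max(1L, as.integer(round(radius_px / shrink))))
    d <- dim(m)
    # sample the shrunk background at full-resolution pixel centres
    xs <- ((seq_len(d[2]) - 0.5) / shrink) - 0.5
    ys <- ((seq_len(d[1]) - 0.5) / shrink) - 0.5
    X <- matrix(xs, d[1], d[2], byrow = TRUE); Y <- matrix(ys, d[1], d[2])
    Xc <- pmin(pmax(X, 0), ncol(bg_small) - 1)
    Yc <- pmin(pmax(Y, 0), nrow(bg_small) - 1)
    bg <- matrix(.bilinear_sample(bg_small, Xc, Yc), d[1], d[2])
  } else {
    bg <- .opening_disc(sm, as.integer(radius_px))
  }
  out <- pmax(m - bg, 0)
  if (inherits(plane, "image_plane"))
    image_plane(out, plane$pixel_size_nm, plane$channel, plane$origin_stage_um)
  else out
}

#' Flat-field illumination correction
#'
#' Divides the plane by the flat-field normalised to unit mean, so a plane
#' equal to the flat-field becomes constant at its own mean and a constant
#' flat-field is the identity.
#'
#' @param plane an [image_plane()] or matrix.
#' @param flatfield reference illumination image (same shape, > 0).
#' @return corrected image of the same class as `plane`.
#' @export
flatfield_correct <- function(plane, flatfield) {
  m <- if (inherits(plane, "image_plane")) plane$pixels else as.matrix(plane)
  ff <- if (inherits(flatfield, "image_plane")) flatfield$pixels else as.matrix(flatfield)
  if (!identical(dim(m), dim(ff)))
    .stop2("validation_error", "flat-field shape does not match the plane")
  if (any(ff <= 0))
    .stop2("validation_error", "flat-field contains non-positive pixels")
  out <- m / (ff / mean(ff))
  if (inherits(plane, "image_plane"))
    image_plane(out, plane$pixel_size_nm, plane$channel, plane$origin_stage_um)
  else out
}

#' Segmentation parameters
#'
#' @param method `"otsu"` (global Otsu threshold) or `"manual"`.
#' @param threshold manual threshold (required for `method = "manual"`).
#' @param log_transform compute the Otsu threshold on `log10(1 + I)`;
#'   fluorescence nuclei span a wide intensity range and linear-space Otsu
#'   tends to land above the dimmest nuclei.
#' @param presmooth_sigma_px Gaussian smoothing applied before thresholding
#'   (0 disables); reduces boundary raggedness from shot noise.
#' @param fill_holes fill enclosed holes in objects.
#' @param watershed split touching objects on distance-transform maxima.
#' @param min_area_px,max_area_px size filter in pixels.
#' @param clear_border drop objects touching the image border (their area
#'   and intensity are biased).
#' @return parameter list.
#' @export
segmentation_params <- function(method = c("otsu", "manual"), threshold = NULL,
                                log_transform = TRUE, presmooth_sigma_px = 1,
                                fill_holes = TRUE, watershed = FALSE,
                                min_area_px = 50, max_area_px = Inf,
                                clear_border = TRUE) {
  list(method = match.arg(method), threshold = threshold,
       log_transform = log_transform, presmooth_sigma_px = presmooth_sigma_px,
       fill_holes = fill_holes, watershed = watershed,
       min_area_px = min_area_px, max_area_px = max_area_px,
       clear_border = clear_border)
}

#' Segment nuclei from a DNA-stain plane
#'
#' Global threshold (Otsu by default), optional hole filling, optional
#' watershed splitting on the distance transform, size filtering, and
#' removal of border-touching objects. Labels are returned contiguous
#' 1..N; an empty result (0 labels) is valid, not an error.
#'
#' @param dna_plane preprocessed [image_plane()] (or matrix) of the nuclear
#'   stain.
#' @param params see [segmentation_params()].
#' @return integer label matrix (0 = background) of class `label_map` with
#'   attribute `pixel_size_nm`.
#' @export
segment_nuclei <- function(dna_plane, params = segmentation_params()) {
  m <- if (inherits(dna_plane, "image_plane")) dna_plane$pixels else as.matrix(dna_plane)
  px <- if (inherits(dna_plane, "image_plane")) dna_plane$pixel_size_nm else NA_real_
  thr <- if (params$method == "manual") {
    if (is.null(params$threshold))
      .stop2("parameter_error", "manual method needs a threshold")
    params$threshold
  } else NULL
  ms <- if (params$method == "otsu" && params$presmooth_sigma_px > 0)
    EBImage::gblur(m, params$presmooth_sigma_px) else m
  if (is.null(thr)) {
    v <- if (params$log_transform) log10(1 + ms) else ms
    mx <- max(v)
    thr <- if (mx <= 0) Inf
    else EBImage::otsu(EBImage::Image(v / mx), range = c(0, 1)) * mx
    if (params$log_transform && is.finite(thr)) thr <- 10^thr - 1
    # noise floor: with very sparse foreground Otsu has no bimodality to
    # work with and can land inside the background noise
    if (is.finite(thr))
      thr <- max(thr, stats::median(ms) + 5 * stats::mad(ms))
  }
  mask <- ms > thr
  if (!any(mask)) {
    out <- matrix(0L, nrow(m), ncol(m))
    class(out) <- c("label_map", class(out))
    attr(out, "pixel_size_nm") <- px
    return(out)
  }
  if (params$fill_holes) mask <- EBImage::fillHull(mask) > 0
  if (params$watershed) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    lab <- as.matrix(EBImage::imageData(lab))
  } else {
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(mask)))
  }
  storage.mode(lab) <- "integer"
  if (params$clear_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    lab[lab %in% border[border > 0]] <- 0L
  }
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(sizes < params$min_area_px | sizes > params$max_area_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  keep <- sort(unique(lab[lab > 0]))
  remap <- integer(max(lab, 1L)); remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  class(lab) <- c("label_map", class(lab))
  attr(lab, "pixel_size_nm") <- px
  lab
}

# contour-based perimeter with Kulpa step weights (straight 0.948,
# diagonal 1.340): anti-aliasing-aware enough that a digitised disc stays
# within a few percent of pi * d
.perimeters <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(numeric(0))
  oc <- EBImage::ocontour(lab)
  vapply(seq_len(n), function(k) {
    pts <- oc[[k]]
    if (is.null(pts) || nrow(pts) < 2) return(4 * 0.948)
    dd <- abs(pts[c(2:nrow(pts), 1), , drop = FALSE] - pts)
    dd <- pmin(dd, 1)  # guard against contour jumps
    diag_ <- dd[, 1] > 0 & dd[, 2] > 0
    straight <- xor(dd[, 1] > 0, dd[, 2] > 0)
    0.948 * sum(straight) + 1.340 * sum(diag_)
  }, 0)
}

# core measurement shared by cells and spots
.measure_labels <- function(lab, planes, pixel_size_nm) {
  n <- max(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  rows0 <- (idx - 1) %% nrow(lab)        # 0-based y
  cols0 <- (idx - 1) %/% nrow(lab)       # 0-based x
  area <- tabulate(l, nbins = n)
  cx <- as.vector(rowsum(cols0, l)) / area
  cy <- as.vector(rowsum(rows0, l)) / area
  per <- .perimeters(lab)
  circ <- pmin(4 * pi * area / per^2, 1)
  area_um2 <- area * (pixel_size_nm / 1000)^2
  out <- data.frame(centroid_x_px = cx, centroid_y_px = cy,
                    area_px = area, area_um2 = area_um2,
                    circularity = circ)
  for (ch in names(planes)) {
    tot <- as.vector(rowsum(planes[[ch]][idx], l))
    out[[paste0(ch, "_integrated")]] <- tot
    out[[paste0(ch, "_mean")]] <- tot / area
  }
  out
}

#' Measure every segmented cell across all channels
#'
#' One record per label: geometry (area in µm², circularity `4*pi*A/P^2`
#' with a contour-corrected perimeter, clamped at 1, centroid in 0-based
#' pixels) and, per channel, the mean intensity per pixel and the
#' integrated intensity.
#'
#' @param labelmap a `label_map` from [segment_nuclei()].
#' @param stack the [image_stack()] the labels were derived from (all
#'   channels are measured); a single [image_plane()] is accepted.
#' @param source_file,tile_index provenance columns stored per record.
#' @param z 1-based z slice measured (default 1).
#' @return data.frame (cell table): `cell_id`, `source_file`, `tile_index`,
#'   geometry, and `<channel>_mean` / `<channel>_integrated` per channel.
#' @export
measure_cells <- function(labelmap, stack, source_file = NA_character_,
                          tile_index = 1L, z = 1L) {
  if (inherits(stack, "image_plane"))
    stack <- image_stack(list(stack))
  d <- dim(stack$planes[[1]]$pixels)
  if (!identical(dim(unclass(labelmap))[1:2], d))
    .stop2("alignment_error", "label map and stack dimensions differ")
  planes <- lapply(stack$channel_names, function(ch) get_plane(stack, ch, z)$pixels)
  names(planes) <- stack$channel_names
  lab <- unclass(labelmap); storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n == 0L) {
    base <- .measure_labels(matrix(0L, 2, 2), planes[0], stack$pixel_size_nm)
    return(cbind(data.frame(cell_id = integer(0), source_file = character(0),
                            tile_index = integer(0)), base[0, , drop = FALSE]))
  }
  meas <- .measure_labels(lab, planes, stack$pixel_size_nm)
  cbind(data.frame(cell_id = seq_len(n), source_file = source_file,
                   tile_index = tile_index), meas)
}

#' Spot detection parameters
#'
#' @param sigma_small,sigma_large band-pass (difference-of-Gaussians)
#'   scales in pixels.
#' @param k_mad detection threshold: `k_mad` robust sigmas (MAD) above the
#'   median of the band-passed image.
#' @param split_touching split touching spots by watershed on the
#'   band-passed intensity (seeded at its local maxima).
#' @param split_tolerance minimum peak-to-saddle height for a split
#'   (`NULL`: half the detection threshold above background, so noise
#'   ripples inside one spot do not shatter it).
#' @param min_area_px,max_area_px size filter.
#' @return parameter list.
#' @export
spot_params <- function(sigma_small = 1, sigma_large = 4, k_mad = 6,
                        split_touching = TRUE, split_tolerance = NULL,
                        min_area_px = 2, max_area_px = 2000) {
  list(sigma_small = sigma_small, sigma_large = sigma_large, k_mad = k_mad,
       split_touching = split_touching, split_tolerance = split_tolerance,
       min_area_px = min_area_px, max_area_px = max_area_px)
}

#' Detect and measure intracellular spots
#'
#' Band-pass filters the plane (difference of Gaussians), thresholds at
#' `k_mad` MADs above the median, labels the result, size-filters, and
#' measures each spot like a cell on the original plane. Each spot is
#' assigned to the parent cell whose label contains its centroid
#' (`parent_cell_id = 0` outside every cell).
#'
#' @param plane [image_plane()] of the spot channel.
#' @param parent_labels `label_map` of the cells (may be `NULL`).
#' @param params see [spot_params()].
#' @param source_file,tile_index provenance columns.
#' @return data.frame (spot table): `spot_id`, `parent_cell_id`, `channel`,
#'   geometry and intensity columns as in [measure_cells()].
#' @export
detect_spots <- function(plane, parent_labels = NULL, params = spot_params(),
                         source_file = NA_character_, tile_index = 1L) {
  m <- if (inherits(plane, "image_plane")) plane$pixels else as.matrix(plane)
  px <- if (inherits(plane, "image_plane")) plane$pixel_size_nm else NA_real_
  chn <- if (inherits(plane, "image_plane")) plane$channel else "ch1"
  bp <- EBImage::gblur(m, sigma = params$sigma_small) -
    EBImage::gblur(m, sigma = params$sigma_large)
  rsig <- params$k_mad * stats::mad(bp)
  thr <- stats::median(bp) + rsig
  mask <- bp > thr
  if (params$split_touching && any(mask)) {
    tol <- params$split_tolerance %||% (rsig / 2)
    lab <- EBImage::watershed((bp - thr) * mask, tolerance = tol, ext = 1)
    lab <- as.matrix(EBImage::imageData(lab))
  } else {
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(mask)))
  }
  storage.mode(lab) <- "integer"
  sizes <- tabulate(lab[lab > 0], nbins = max(lab, 1L))
  drop <- which(sizes < params$min_area_px | sizes > params$max_area_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  keep <- sort(unique(lab[lab > 0]))
  if (!length(keep)) {
    out <- data.frame(spot_id = integer(0), parent_cell_id = integer(0),
                      channel = character(0))
    return(out)
  }
  remap <- integer(max(lab)); remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  meas <- .measure_labels(lab, setNames(list(m), chn), px)
  pid <- rep(0L, nrow(meas))
  if (!is.null(parent_labels)) {
    pl <- unclass(parent_labels)
    ri <- pmin(pmax(floor(meas$centroid_y_px) + 1L, 1L), nrow(pl))
    ci <- pmin(pmax(floor(meas$centroid_x_px) + 1L, 1L), ncol(pl))
    pid <- pl[cbind(ri, ci)]
  }
  cbind(data.frame(spot_id = seq_len(nrow(meas)), parent_cell_id = pid,
                   channel = chn, source_file = source_file,
                   tile_index = tile_index), meas)
}

#' Run the full cytometry stage over a set of tiles
#'
#' Preprocesses each tile (optional flat-field, rolling-ball background
#' subtraction), segments nuclei on the DNA channel, measures cells on all
#' channels and detects spots on the requested channels; results from all
#' tiles are concatenated with globally unique `cell_id`s.
#'
#' @param tiles list of [image_stack()] (or a `phantom_population`).
#' @param dna_channel channel used for segmentation.
#' @param rolling_ball_radius_px background-subtraction radius (0 disables).
#' @param flatfield optional flat-field matrix applied to every channel.
#' @param seg_params see [segmentation_params()].
#' @param spot_channels channels run through [detect_spots()].
#' @param spot_par see [spot_params()].
#' @return list with `cells` and `spots` data.frames.
#' @export
run_cytometry <- function(tiles, dna_channel = "dna",
                          rolling_ball_radius_px = 25, flatfield = NULL,
                          seg_params = segmentation_params(),
                          spot_channels = character(0),
                          spot_par = spot_params()) {
  if (inherits(tiles, "phantom_population")) tiles <- tiles$tiles
  cells <- list(); spots <- list(); offset <- 0L
  for (t in seq_along(tiles)) {
    st <- tiles[[t]]
    planes <- lapply(st$channel_names, function(ch) {
      p <- get_plane(st, ch)
      if (!is.null(flatfield)) p <- flatfield_correct(p, flatfield)
      if (rolling_ball_radius_px > 0)
        p <- subtract_background(p, rolling_ball_radius_px)
      p
    })
    pre <- image_stack(planes, channel_names = st$channel_names)
    lab <- segment_nuclei(get_plane(pre, dna_channel), seg_params)
    ct <- measure_cells(lab, pre, tile_index = t)
    ct$cell_id <- ct$cell_id + offset
    cells[[t]] <- ct
    for (sc in spot_channels) {
      sp <- detect_spots(get_plane(pre, sc), lab, spot_par, tile_index = t)
      if (nrow(sp)) {
        sp$parent_cell_id <- ifelse(sp$parent_cell_id > 0,
                                    sp$parent_cell_id + offset, 0L)
        spots[[length(spots) + 1L]] <- sp
      }
    }
    offset <- offset + nrow(ct)
  }
  spots <- if (length(spots)) do.call(rbind, spots) else NULL
  if (!is.null(spots)) spots$spot_id <- seq_len(nrow(spots))
  list(cells = do.call(rbind, cells), spots = spots)
}
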