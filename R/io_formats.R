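#' @section File formats:
#' Images travel as TIFF with a JSON side-car (`<path>.meta.json`) carrying
#' the physical calibration (pixel size, z-step, channel order, intensity
#' scale); localizations as ThunderSTORM-style CSV; single-cell tables as
#' tab-delimited text; position lists as CSV.
#' @name io_formats
NULL

# ---- images -----------------------------------------------------------------

#' Write an image stack to TIFF with calibration metadata
#'
#' Pixel data are stored as 16-bit integers when the stack is integral and
#' fits, otherwise as 32-bit samples scaled by the stack maximum; the scale
#' and all physical calibration go to a JSON side-car `<path>.meta.json` so
#' [read_image()] restores the stack losslessly (16-bit) or to ~1e-9
#' relative precision (scaled 32-bit).
#'
#' @param stack an [image_stack()] (an [image_plane()] is promoted).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(stack, path) {
  if (inherits(stack, "image_plane")) stack <- image_stack(list(stack))
  stopifnot(inherits(stack, "image_stack"))
  mats <- lapply(stack$planes, `[[`, "pixels")
  mx <- max(vapply(mats, max, 0), 0)
  integral <- all(vapply(mats, function(m) all(m == round(m)), TRUE))
  if (integral && mx <= 65535) {
    bits <- 16L; scale <- 65535
  } else {
    bits <- 32L; scale <- if (mx > 0) mx else 1
  }
  ok <- tryCatch({
    tiff::writeTIFF(lapply(mats, function(m) m / scale), path,
                    bits.per.sample = bits, compression = "none",
                    reduce = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .stop2("io_error", "cannot write TIFF to '%s'", path)
  org <- stack$planes[[1]]$origin_stage_um
  meta <- list(pixel_size_nm = stack$pixel_size_nm,
               z_step_nm = stack$z_step_nm,
               channel_names = as.list(stack$channel_names),
               n_z = stack$n_z, bits = bits, scale = scale,
               origin_stage_um = if (is.null(org)) NULL else as.list(org))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a TIFF image stack with calibration
#'
#' Calibration comes from the JSON side-car written by [write_image()]; for
#' third-party TIFFs without one, `pixel_size_nm` (and optionally
#' `channel_names`, `z_step_nm`) must be supplied.
#'
#' @param path TIFF path.
#' @param pixel_size_nm calibration override (required without side-car).
#' @param channel_names,z_step_nm optional overrides.
#' @return an [image_stack()].
#' @export
read_image <- function(path, pixel_size_nm = NULL, channel_names = NULL,
                       z_step_nm = NULL) {
  if (!file.exists(path)) .stop2("io_error", "no such file: '%s'", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) NULL)
  if (is.null(pages)) .stop2("format_error", "'%s' is not a readable TIFF", path)
  side <- paste0(path, ".meta.json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  px <- pixel_size_nm %||% meta$pixel_size_nm
  if (is.null(px))
    .stop2("calibration_error",
           "no pixel size: '%s' has no side-car metadata and no override given", path)
  ch <- channel_names %||% unlist(meta$channel_names) %||% "ch1"
  zs <- z_step_nm %||% meta$z_step_nm %||% 1
  scale <- meta$scale %||% 1
  org <- if (!is.null(meta$origin_stage_um)) unlist(meta$origin_stage_um)
  mats <- lapply(pages, function(m) {
    m <- m * scale
    if (identical(meta$bits, 16L) || identical(meta$bits, 16)) m <- round(m)
    m
  })
  nc <- length(ch)
  planes <- lapply(seq_along(mats), function(i)
    image_plane(mats[[i]], px, channel = ch[((i - 1L) %% nc) + 1L],
                origin_stage_um = org))
  image_stack(planes, channel_names = ch, z_step_nm = zs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- localization tables ----------------------------------------------------

#' ThunderSTORM-style localization CSV dialect
#'
#' Maps the fields of a localization table to CSV column headers. The
#' default follows the open ThunderSTORM convention; vendor exports are
#' accommodated by overriding individual column names.
#'
#' @param ... overrides, e.g. `x_nm = "x (nm)"`.
#' @return named list mapping field names to column headers.
#' @export
thunderstorm_dialect <- function(...) {
  d <- list(frame = "frame", x_nm = "x [nm]", y_nm = "y [nm]",
            sigma_nm = "sigma [nm]", photons = "intensity [photon]",
            background = "offset [photon]", precision_nm = "uncertainty [nm]",
            channel = "channel")
  utils::modifyList(d, list(...))
}

.loc_defaults <- c(sigma_nm = 150, photons = 1, background = 0,
                   precision_nm = 10)

#' Build a validated localization table
#'
#' @param x_nm,y_nm coordinates in nm.
#' @param frame 0-based frame indices.
#' @param channel channel name(s).
#' @param sigma_nm fitted PSF sigma, nm.
#' @param photons detected photons (> 0).
#' @param background background level (>= 0).
#' @param precision_nm localization precision, nm.
#' @return `data.frame` of class `localization_table`.
#' @export
localization_table <- function(x_nm, y_nm, frame = 0L, channel = "ch1",
                               sigma_nm = 150, photons = 1, background = 0,
                               precision_nm = 10) {
  n <- length(x_nm)
  df <- data.frame(channel = rep_len(as.character(channel), n),
                   frame = rep_len(as.integer(frame), n),
                   x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                   sigma_nm = rep_len(as.numeric(sigma_nm), n),
                   photons = rep_len(as.numeric(photons), n),
                   background = rep_len(as.numeric(background), n),
                   precision_nm = rep_len(as.numeric(precision_nm), n))
  .validate_locs(df)
  class(df) <- c("localization_table", "data.frame")
  df
}

.validate_locs <- function(df) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      .stop2("validation_error", "%s in rows: %s", what,
             paste(head(i, 20), collapse = ", "))
  }
  bad(!is.finite(df$x_nm) | !is.finite(df$y_nm), "non-finite coordinates")
  bad(df$frame < 0, "negative frame indices")
  bad(!(df$photons > 0), "non-positive photon counts")
  bad(df$background < 0, "negative background")
  bad(!(df$sigma_nm > 0), "non-positive sigma")
  bad(!(df$precision_nm > 0), "non-positive precision")
  invisible(df)
}

#' Read a localization CSV
#'
#' @param path CSV with header.
#' @param dialect column mapping from [thunderstorm_dialect()].
#' @return a [localization_table()]. Rows are fully validated; an invalid
#'   value raises a validation error listing the offending rows (records are
#'   never silently dropped).
#' @export
read_localizations <- function(path, dialect = thunderstorm_dialect()) {
  if (!file.exists(path)) .stop2("io_error", "no such file: '%s'", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("frame", "x_nm", "y_nm")
  for (f in need)
    if (!dialect[[f]] %in% names(raw))
      .stop2("schema_error", "missing mandatory column '%s'", dialect[[f]])
  n <- nrow(raw)
  get <- function(f) {
    col <- dialect[[f]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]]
    else if (f == "channel") rep("ch1", n)
    else rep(.loc_defaults[[f]], n)
  }
  if (n == 0L) return(localization_table(numeric(0), numeric(0)))
  localization_table(x_nm = as.numeric(get("x_nm")),
                     y_nm = as.numeric(get("y_nm")),
                     frame = as.integer(get("frame")),
                     channel = as.character(get("channel")),
                     sigma_nm = as.numeric(get("sigma_nm")),
                     photons = as.numeric(get("photons")),
                     background = as.numeric(get("background")),
                     precision_nm = as.numeric(get("precision_nm")))
}

#' Write a localization table as CSV
#'
#' @param locs a [localization_table()].
#' @param path output path.
#' @param dialect column mapping; see [thunderstorm_dialect()].
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path, dialect = thunderstorm_dialect()) {
  .validate_locs(locs)
  out <- data.frame(locs$channel, locs$frame, locs$x_nm, locs$y_nm,
                    locs$sigma_nm, locs$photons, locs$background,
                    locs$precision_nm, check.names = FALSE)
  names(out) <- unlist(dialect[c("channel", "frame", "x_nm", "y_nm",
                                 "sigma_nm", "photons", "background",
                                 "precision_nm")])
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- cell / spot tables -----------------------------------------------------

#' Write the single-cell (or spot) repository
#'
#' One tab-delimited row per event, one column per measurement; the format
#' every downstream gating and retrieval step consumes.
#'
#' @param table data.frame with a unique `cell_id` (or `spot_id`) column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  idcol <- intersect(c("cell_id", "spot_id"), names(table))[1]
  if (is.na(idcol)) .stop2("validation_error", "table needs a cell_id or spot_id column")
  if (anyDuplicated(table[[idcol]]))
    .stop2("validation_error", "duplicate identifiers in '%s'", idcol)
  chr <- vapply(table, is.character, TRUE) | vapply(table, is.factor, TRUE)
  for (cn in names(table)[chr])
    if (any(grepl("\t", as.character(table[[cn]]))))
      .stop2("validation_error", "field '%s' contains tab characters", cn)
  num <- vapply(table, is.numeric, TRUE)
  out <- table
  out[num] <- lapply(table[num], function(v)
    formatC(v, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-cell repository written by [write_cell_table()]
#'
#' @param path tab-delimited file.
#' @return data.frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) .stop2("io_error", "no such file: '%s'", path)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

# ---- position lists ---------------------------------------------------------

#' Build a stage position list
#'
#' @param label unique entry labels.
#' @param stage_x_um,stage_y_um stage coordinates in µm.
#' @param stage_z_um optional z positions in µm.
#' @return data.frame of class `position_list`.
#' @export
position_list <- function(label = character(0), stage_x_um = numeric(0),
                          stage_y_um = numeric(0), stage_z_um = NULL) {
  if (anyDuplicated(label))
    .stop2("validation_error", "position labels must be unique")
  df <- data.frame(label = as.character(label),
                   stage_x_um = as.numeric(stage_x_um),
                   stage_y_um = as.numeric(stage_y_um))
  if (!is.null(stage_z_um)) df$stage_z_um <- as.numeric(stage_z_um)
  class(df) <- c("position_list", "data.frame")
  df
}

#' Write a position list for the microscope control software
#'
#' The `format` tag is the customization point for stage-software dialects:
#' `"generic"` emits `label,stage_x_um,stage_y_um[,stage_z_um]`;
#' `"xy"` emits bare `x,y` micrometre columns.
#'
#' @param plist a [position_list()].
#' @param path output CSV path.
#' @param format dialect tag.
#' @return `path`, invisibly.
#' @export
write_position_list <- function(plist, path, format = "generic") {
  stopifnot(inherits(plist, "position_list") || is.data.frame(plist))
  if (!format %in% c("generic", "xy"))
    .stop2("configuration_error", "unknown position-list format '%s'", format)
  out <- as.data.frame(plist)
  if (format == "xy") out <- setNames(out[c("stage_x_um", "stage_y_um")], c("x", "y"))
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a position list CSV
#'
#' @param path CSV path.
#' @param format dialect tag used at write time.
#' @return a [position_list()].
#' @export
read_position_list <- function(path, format = "generic") {
  if (!file.exists(path)) .stop2("io_error", "no such file: '%s'", path)
  if (!format %in% c("generic", "xy"))
    .stop2("configuration_error", "unknown position-list format '%s'", format)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "xy")
    return(position_list(label = as.character(seq_len(nrow(raw))),
                         stage_x_um = raw$x, stage_y_um = raw$y))
  position_list(label = as.character(raw$label), stage_x_um = raw$stage_x_um,
                stage_y_um = raw$stage_y_um, stage_z_um = raw$stage_z_um)
}
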