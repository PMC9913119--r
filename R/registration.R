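#' Similarity transform in physical coordinates
#'
#' The registration currency linking modalities with different pixel sizes:
#' a point p (nm) maps to `scale * R(rotation) %*% p + t`. The model
#' hierarchy is translation (rotation = 0, scale = 1) c rigid (scale = 1) c
#' similarity.
#'
#' @param model `"translation"`, `"rigid"` or `"similarity"`.
#' @param tx_nm,ty_nm translation, nm.
#' @param rotation_rad rotation about the origin, radians.
#' @param scale isotropic scale (> 0).
#' @return object of class `transform2d`.
#' @export
transform2d <- function(model = c("translation", "rigid", "similarity"),
                        tx_nm = 0, ty_nm = 0, rotation_rad = 0, scale = 1) {
  model <- match.arg(model)
  if (model == "translation" && (rotation_rad != 0 || scale != 1))
    .stop2("validation_error", "translation model cannot rotate or scale")
  if (model == "rigid" && scale != 1)
    .stop2("validation_error", "rigid model cannot scale")
  if (!is.finite(scale) || scale <= 0)
    .stop2("validation_error", "scale must be positive")
  structure(list(model = model, tx_nm = unname(tx_nm), ty_nm = unname(ty_nm),
                 rotation_rad = unname(rotation_rad), scale = unname(scale)),
            class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d %s> t = (%.4g, %.4g) nm, rot = %.6g rad, scale = %.6g\n",
              x$model, x$tx_nm, x$ty_nm, x$rotation_rad, x$scale))
  invisible(x)
}

#' Apply a transform to an n x 2 matrix of (x, y) nm points
#' @param tf a [transform2d()].
#' @param pts numeric matrix, columns x and y in nm.
#' @return transformed matrix of the same shape.
#' @export
transform_points <- function(tf, pts) {
  pts <- as.matrix(pts)
  cs <- cos(tf$rotation_rad); sn <- sin(tf$rotation_rad)
  cbind(tf$scale * (cs * pts[, 1] - sn * pts[, 2]) + tf$tx_nm,
        tf$scale * (sn * pts[, 1] + cs * pts[, 2]) + tf$ty_nm)
}

#' Invert a transform
#' @param tf a [transform2d()].
#' @return the inverse [transform2d()].
#' @export
invert_transform <- function(tf) {
  cs <- cos(-tf$rotation_rad); sn <- sin(-tf$rotation_rad)
  s <- 1 / tf$scale
  transform2d(tf$model, tx_nm = -s * (cs * tf$tx_nm - sn * tf$ty_nm),
              ty_nm = -s * (sn * tf$tx_nm + cs * tf$ty_nm),
              rotation_rad = -tf$rotation_rad, scale = s)
}

#' Compose transforms (applied left to right)
#'
#' `compose(T1, T2)` is the single transform equivalent to applying `T1`
#' then `T2`; used to chain modality pairs (e.g. confocal -> widefield and
#' relay-widefield -> widefield, so a STORM rendering inherits the
#' relay-widefield alignment).
#'
#' @param ... [transform2d()] objects.
#' @return the composed [transform2d()].
#' @export
compose <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && is.list(ts[[1]]) && !inherits(ts[[1]], "transform2d"))
    ts <- ts[[1]]
  Reduce(function(a, b) {
    # combined: p -> b(a(p))
    t0 <- transform_points(b, matrix(c(a$tx_nm, a$ty_nm), 1))
    model <- c("translation", "rigid", "similarity")[
      max(match(a$model, c("translation", "rigid", "similarity")),
          match(b$model, c("translation", "rigid", "similarity")))]
    transform2d(model, tx_nm = t0[1], ty_nm = t0[2],
                rotation_rad = a$rotation_rad + b$rotation_rad,
                scale = a$scale * b$scale)
  }, ts)
}

# bilinear sample of matrix m at fractional 0-based pixel-centre coords
# (x_px, y_px); NA outside. Vectorised.
.bilinear_sample <- function(m, x_px, y_px) {
  d <- dim(m)
  x <- as.vector(x_px); y <- as.vector(y_px)
  j0 <- floor(x); i0 <- floor(y)
  fx <- x - j0; fy <- y - i0
  out <- rep(NA_real_, length(x))
  ok <- j0 >= 0 & i0 >= 0 & j0 <= d[2] - 1 & i0 <= d[1] - 1
  # clamp the upper neighbour at the border (replicate edge)
  j1 <- pmin(j0 + 1, d[2] - 1); i1 <- pmin(i0 + 1, d[1] - 1)
  idx <- function(i, j) i + 1 + j * d[1]
  w <- which(ok)
  if (length(w)) {
    v00 <- m[idx(i0[w], j0[w])]; v01 <- m[idx(i0[w], j1[w])]
    v10 <- m[idx(i1[w], j0[w])]; v11 <- m[idx(i1[w], j1[w])]
    out[w] <- (1 - fy[w]) * ((1 - fx[w]) * v00 + fx[w] * v01) +
      fy[w] * ((1 - fx[w]) * v10 + fx[w] * v11)
  }
  out
}

#' Resample two planes onto a common grid
#'
#' The coarser plane is resampled (bilinear) to the finer pixel size over
#' the overlapping physical extent, so that modalities sampled at e.g. 65
#' and 160 nm can be compared pixel by pixel. Physical origins
#' (`origin_stage_um`, defaulting to 0) are honoured.
#'
#' @param planeA,planeB [image_plane()]s.
#' @return list with resampled `A` and `B` on the common (finer) grid.
#' @export
resample_to_common_grid <- function(planeA, planeB) {
  stopifnot(inherits(planeA, "image_plane"), inherits(planeB, "image_plane"))
  org <- function(p) if (is.null(p$origin_stage_um)) c(0, 0) else p$origin_stage_um * 1000
  oA <- org(planeA); oB <- org(planeB)
  extent <- function(p, o)
    c(xmin = o[1], xmax = o[1] + ncol(p$pixels) * p$pixel_size_nm,
      ymin = o[2], ymax = o[2] + nrow(p$pixels) * p$pixel_size_nm)
  eA <- extent(planeA, oA); eB <- extent(planeB, oB)
  ov <- c(xmin = max(eA["xmin"], eB["xmin"]), xmax = min(eA["xmax"], eB["xmax"]),
          ymin = max(eA["ymin"], eB["ymin"]), ymax = min(eA["ymax"], eB["ymax"]))
  if (ov["xmax"] <= ov["xmin"] || ov["ymax"] <= ov["ymin"])
    .stop2("geometry_error", "planes have no physical overlap")
  px <- min(planeA$pixel_size_nm, planeB$pixel_size_nm)
  nx <- floor((ov["xmax"] - ov["xmin"]) / px)
  ny <- floor((ov["ymax"] - ov["ymin"]) / px)
  gx <- ov["xmin"] + (seq_len(nx) - 0.5) * px
  gy <- ov["ymin"] + (seq_len(ny) - 0.5) * px
  X <- matrix(gx, ny, nx, byrow = TRUE); Y <- matrix(gy, ny, nx)
  samp <- function(p, o) {
    # clamp to the pixel-centre span: the half-pixel border zone of the
    # coarser plane replicates its edge instead of dropping out
    xq <- pmin(pmax((X - o[1]) / p$pixel_size_nm - 0.5, 0), ncol(p$pixels) - 1)
    yq <- pmin(pmax((Y - o[2]) / p$pixel_size_nm - 0.5, 0), nrow(p$pixels) - 1)
    v <- .bilinear_sample(p$pixels, xq, yq)
    image_plane(matrix(v, ny, nx), px, channel = p$channel,
                origin_stage_um = c(ov[["xmin"]], ov[["ymin"]]) / 1000)
  }
  list(A = samp(planeA, oA), B = samp(planeB, oB))
}

#' Estimate the translation between two planes by phase correlation
#'
#' Returns the physical displacement of `planeB`'s content relative to
#' `planeA` (i.e. B(x) looks like A(x - d)), from the phase-correlation
#' peak with parabolic sub-pixel refinement. Planes with different pixel
#' sizes are first brought onto a common grid, and spatial frequencies
#' beyond the Nyquist limit of the coarser sampling are excluded from the
#' correlation (they carry no signal from the coarser plane, only noise,
#' which phase correlation would otherwise weight equally).
#'
#' @param planeA,planeB [image_plane()]s.
#' @param lowpass_cutoff_nm drop spatial frequencies above `0.5 /
#'   lowpass_cutoff_nm` (`NULL`: automatic — the coarser of the two
#'   original pixel sizes when they differ, no cutoff otherwise).
#' @return a translation [transform2d()] with attributes `confidence`
#'   (peak-to-next ratio) and `low_confidence` flag.
#' @export
estimate_translation <- function(planeA, planeB, lowpass_cutoff_nm = NULL) {
  if (is.null(lowpass_cutoff_nm) &&
      planeA$pixel_size_nm != planeB$pixel_size_nm)
    lowpass_cutoff_nm <- max(planeA$pixel_size_nm, planeB$pixel_size_nm)
  if (planeA$pixel_size_nm != planeB$pixel_size_nm ||
      !identical(dim(planeA$pixels), dim(planeB$pixels))) {
    rs <- resample_to_common_grid(planeA, planeB)
    planeA <- rs$A; planeB <- rs$B
  }
  a <- planeA$pixels; b <- planeB$pixels
  d <- dim(a)
  # Hann window suppresses wrap-around edge ringing
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(d[1]) - 1) / (d[1] - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(d[2]) - 1) / (d[2] - 1))
  W <- wy %o% wx
  Fa <- stats::fft((a - mean(a)) * W); Fb <- stats::fft((b - mean(b)) * W)
  R <- Fa * Conj(Fb)
  R <- R / pmax(Mod(R), .Machine$double.eps)
  if (!is.null(lowpass_cutoff_nm)) {
    px <- planeA$pixel_size_nm
    fy <- c(0:(d[1] %/% 2), -((d[1] - 1) %/% 2):-1) / (d[1] * px)
    fx <- c(0:(d[2] %/% 2), -((d[2] - 1) %/% 2):-1) / (d[2] * px)
    FY <- matrix(fy, d[1], d[2])
    FX <- matrix(fx, d[1], d[2], byrow = TRUE)
    R[sqrt(FX^2 + FY^2) > 0.5 / lowpass_cutoff_nm] <- 0
  }
  cc <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  pk <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  # parabolic refinement along each axis with circular neighbours
  refine <- function(vm1, v0, vp1) {
    den <- vm1 - 2 * v0 + vp1
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (vm1 - vp1) / den
  }
  gi <- function(i, n) ((i - 1) %% n) + 1
  dy0 <- wrap(pk[1], d[1]); dx0 <- wrap(pk[2], d[2])
  ddy <- refine(cc[gi(pk[1] - 1, d[1]), pk[2]], cc[pk[1], pk[2]],
                cc[gi(pk[1] + 1, d[1]), pk[2]])
  ddx <- refine(cc[pk[1], gi(pk[2] - 1, d[2])], cc[pk[1], pk[2]],
                cc[pk[1], gi(pk[2] + 1, d[2])])
  # peak of fft(Fa * Conj(Fb)) at lag l means a(x) ~ b(x - l): content of B
  # displaced by -l relative to A; flip sign to report B relative to A.
  shift_px <- c(x = -(dx0 + ddx), y = -(dy0 + ddy))
  srt <- sort(as.vector(cc), decreasing = TRUE)
  conf <- if (length(srt) > 10) srt[1] / max(mean(abs(srt[-(1:5)])), 1e-12) else Inf
  tf <- transform2d("translation",
                    tx_nm = shift_px["x"] * planeA$pixel_size_nm,
                    ty_nm = shift_px["y"] * planeA$pixel_size_nm)
  attr(tf, "confidence") <- conf
  attr(tf, "low_confidence") <- is.finite(conf) && conf < 5
  tf
}

#' Least-squares landmark transform (closed form)
#'
#' Fits the chosen model to paired landmarks by the closed-form Procrustes
#' solution (SVD for rotation, variance ratio for scale); deterministic, no
#' iterative optimiser.
#'
#' @param pointsA_nm,pointsB_nm n x 2 matrices of corresponding points, nm.
#' @param model `"translation"`, `"rigid"` or `"similarity"`.
#' @return a [transform2d()] mapping A onto B, with attribute
#'   `residual_rms_nm`.
#' @export
estimate_landmark_transform <- function(pointsA_nm, pointsB_nm,
                                        model = c("translation", "rigid",
                                                  "similarity")) {
  model <- match.arg(model)
  A <- as.matrix(pointsA_nm); B <- as.matrix(pointsB_nm)
  stopifnot(ncol(A) == 2, nrow(A) == nrow(B))
  n <- nrow(A)
  if (n < 1 || (model != "translation" && n < 2))
    .stop2("fit_error", "model '%s' needs at least %d point pairs", model,
           if (model == "translation") 1 else 2)
  if (model == "translation") {
    t <- colMeans(B) - colMeans(A)
    tf <- transform2d("translation", t[1], t[2])
  } else {
    mA <- colMeans(A); mB <- colMeans(B)
    Ac <- sweep(A, 2, mA); Bc <- sweep(B, 2, mB)
    va <- sum(Ac^2)
    if (va < .Machine$double.eps)
      .stop2("fit_error", "degenerate landmark configuration (coincident points)")
    H <- t(Ac) %*% Bc
    sv <- svd(H)
    S <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% S %*% t(sv$u)
    rot <- atan2(R[2, 1], R[1, 1])
    s <- if (model == "similarity") sum(diag(S) * sv$d) / va else 1
    t <- mB - s * as.vector(R %*% mA)
    tf <- transform2d(model, t[1], t[2], rotation_rad = rot, scale = s)
  }
  res <- transform_points(tf, A) - B
  attr(tf, "residual_rms_nm") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Apply a transform to an image plane or a localization table
#'
#' Localization coordinates are mapped exactly (no interpolation); image
#' planes are resampled by inverse-mapping bilinear interpolation with
#' out-of-frame pixels set to 0.
#'
#' @param target an [image_plane()] or [localization_table()].
#' @param transform a [transform2d()].
#' @return the transformed target of the same class.
#' @export
apply_transform <- function(target, transform) {
  stopifnot(inherits(transform, "transform2d"))
  if (inherits(target, "localization_table")) {
    p <- transform_points(transform, cbind(target$x_nm, target$y_nm))
    target$x_nm <- p[, 1]; target$y_nm <- p[, 2]
    return(target)
  }
  stopifnot(inherits(target, "image_plane"))
  d <- dim(target$pixels)
  px <- target$pixel_size_nm
  gx <- (seq_len(d[2]) - 0.5) * px; gy <- (seq_len(d[1]) - 0.5) * px
  X <- matrix(gx, d[1], d[2], byrow = TRUE); Y <- matrix(gy, d[1], d[2])
  inv <- invert_transform(transform)
  src <- transform_points(inv, cbind(as.vector(X), as.vector(Y)))
  v <- .bilinear_sample(target$pixels, src[, 1] / px - 0.5, src[, 2] / px - 0.5)
  v[!is.finite(v)] <- 0
  image_plane(matrix(v, d[1], d[2]), px, channel = target$channel,
              origin_stage_um = target$origin_stage_um)
}

#' Serialize / deserialize a transform as JSON
#' @param tf a [transform2d()].
#' @param path JSON path.
#' @return `path` (write) or the [transform2d()] (read).
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(list(model = tf$model, tx_nm = tf$tx_nm,
                            ty_nm = tf$ty_nm, rotation_rad = tf$rotation_rad,
                            scale = tf$scale,
                            residual_rms_nm = attr(tf, "residual_rms_nm")),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path)
  transform2d(j$model, j$tx_nm, j$ty_nm, j$rotation_rad %||% 0, j$scale %||% 1)
}
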