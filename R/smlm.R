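#' Localization fitting parameters
#'
#' @param k detection threshold in robust sigmas (MAD) above the frame
#'   background.
#' @param window fit window side in pixels (odd).
#' @param sigma_bounds_nm admissible fitted PSF sigma range.
#' @param sigma_init_nm initial PSF sigma.
#' @param min_photons fits below this photon count are discarded (rejects
#'   noise maxima that survive the detection threshold).
#' @return parameter list.
#' @export
fit_params <- function(k = 6, window = 7, sigma_bounds_nm = c(50, 400),
                       sigma_init_nm = 150, min_photons = 100) {
  list(k = k, window = window, sigma_bounds_nm = sigma_bounds_nm,
       sigma_init_nm = sigma_init_nm, min_photons = min_photons)
}

# Pixel-integrated 2D Gaussian + offset least-squares fit on a small
# window (the model integrates the PSF over each pixel, so large camera
# pixels do not bias the centre estimate).
# Returns NULL when the fit fails to converge or leaves the window/bounds.
.fit_gaussian_window <- function(win, x0, y0, sigma0) {
  d <- dim(win)
  xs <- rep(seq_len(d[2]) - 0.5, each = d[1])
  ys <- rep(seq_len(d[1]) - 0.5, d[2])
  z <- as.vector(win)
  b0 <- min(z)
  a0 <- max(sum(z) - b0 * length(z), max(z) - b0)
  df <- data.frame(z = z, xs = xs, ys = ys)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A *
        (pnorm(xs + 0.5, mx, s) - pnorm(xs - 0.5, mx, s)) *
        (pnorm(ys + 0.5, my, s) - pnorm(ys - 0.5, my, s)),
      data = df,
      start = list(b = b0, A = a0, mx = x0, my = y0, s = sigma0),
      lower = c(b = -Inf, A = 0, mx = 0, my = 0, s = 1e-3),
      upper = c(b = Inf, A = Inf, mx = d[2], my = d[1], s = d[2]),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  stats::coef(fit)
}

#' Fit single-molecule localizations in a frame stack
#'
#' Candidate detection (local maxima above background + `k` robust sigmas)
#' followed by least-squares 2D Gaussian fits (x, y, sigma, amplitude,
#' offset) in a `window` x `window` region. Photons are the fitted Gaussian
#' integral; the localization precision follows the Thompson-style formula
#' `sigma_loc^2 = s^2/N + a^2/(12 N) + 8 pi s^4 b^2 / (a^2 N^2)` with `s`
#' the fitted PSF sigma, `N` the photons, `a` the pixel size and `b` the
#' background noise per pixel. Fits that fail to converge or violate the
#' sigma bounds are discarded; their count is in attribute `n_discarded`.
#'
#' @param frames an [image_stack()] of camera frames (one channel), or a
#'   single [image_plane()].
#' @param params see [fit_params()].
#' @param channel channel name for the output table.
#' @return a [localization_table()] (frames are 0-based).
#' @export
fit_localizations <- function(frames, params = fit_params(), channel = "smlm") {
  if (inherits(frames, "image_plane")) frames <- image_stack(list(frames))
  if (!inherits(frames, "image_stack") || !length(frames$planes))
    .stop2("input_error", "empty frame stack")
  px <- frames$pixel_size_nm
  w <- params$window; hw <- w %/% 2
  res <- list(); discarded <- 0L
  for (f in seq_along(frames$planes)) {
    m <- frames$planes[[f]]$pixels
    bg <- stats::median(m); rs <- stats::mad(m)
    thr <- bg + params$k * max(rs, 1e-9)
    d <- dim(m)
    cand <- which(m > thr)
    if (!length(cand)) next
    ri <- (cand - 1) %% d[1] + 1; ci <- (cand - 1) %/% d[1] + 1
    keep <- ri > hw & ri <= d[1] - hw & ci > hw & ci <= d[2] - hw
    ri <- ri[keep]; ci <- ci[keep]
    if (!length(ri)) next
    # strict local maxima over the 3x3 neighbourhood
    ismax <- vapply(seq_along(ri), function(q) {
      nb <- m[(ri[q] - 1):(ri[q] + 1), (ci[q] - 1):(ci[q] + 1)]
      m[ri[q], ci[q]] >= max(nb)
    }, TRUE)
    ri <- ri[ismax]; ci <- ci[ismax]
    # suppress candidates closer than the window size (keep the brighter)
    if (length(ri) > 1) {
      o <- order(m[cbind(ri, ci)], decreasing = TRUE)
      ri <- ri[o]; ci <- ci[o]
      sel <- rep(TRUE, length(ri))
      for (q in seq_along(ri)[-1]) {
        prev <- which(sel[seq_len(q - 1)])
        if (any(abs(ri[prev] - ri[q]) <= hw & abs(ci[prev] - ci[q]) <= hw))
          sel[q] <- FALSE
      }
      ri <- ri[sel]; ci <- ci[sel]
    }
    for (q in seq_along(ri)) {
      win <- m[(ri[q] - hw):(ri[q] + hw), (ci[q] - hw):(ci[q] + hw)]
      co <- .fit_gaussian_window(win, x0 = hw + 0.5, y0 = hw + 0.5,
                                 sigma0 = params$sigma_init_nm / px)
      if (is.null(co)) { discarded <- discarded + 1L; next }
      s_nm <- co["s"] * px
      if (s_nm < params$sigma_bounds_nm[1] || s_nm > params$sigma_bounds_nm[2] ||
          co["A"] <= 0) { discarded <- discarded + 1L; next }
      N <- co["A"]
      if (N < params$min_photons) { discarded <- discarded + 1L; next }
      bnoise <- max(sqrt(max(bg, 0)), rs)
      prec2 <- s_nm^2 / N + px^2 / (12 * N) +
        8 * pi * s_nm^4 * bnoise^2 / (px^2 * N^2)
      # window origin: pixel (ri-hw-1, ci-hw-1) 0-based; fitted centre is in
      # window pixel units with pixel-centre at half-integers
      x_nm <- (ci[q] - hw - 1 + co["mx"]) * px
      y_nm <- (ri[q] - hw - 1 + co["my"]) * px
      res[[length(res) + 1L]] <- c(f - 1, x_nm, y_nm, s_nm, N, bg, sqrt(prec2))
    }
  }
  if (!length(res)) {
    out <- localization_table(numeric(0), numeric(0), channel = channel)
  } else {
    mres <- do.call(rbind, res)
    out <- localization_table(mres[, 2], mres[, 3], frame = mres[, 1],
                              channel = channel, sigma_nm = mres[, 4],
                              photons = mres[, 5], background = mres[, 6],
                              precision_nm = mres[, 7])
  }
  attr(out, "n_discarded") <- discarded
  out
}

#' Track fiducial markers into a drift trajectory
#'
#' Fiducial localizations (one table, several markers per anchor frame) are
#' linked across anchors by nearest neighbour within `search_radius_nm` of
#' their drift-predicted positions; the drift at each anchor is the mean
#' displacement of the linked markers relative to the first anchor, so
#' independent placement noise averages out across markers.
#'
#' @param fiducial_locs [localization_table()] of fiducial localizations.
#' @param search_radius_nm linking radius.
#' @return data.frame of class `drift_trajectory` (`frame`, `dx_nm`,
#'   `dy_nm`; zero at the first anchor) with attribute
#'   `interpolation = "linear"`.
#' @export
track_fiducials <- function(fiducial_locs, search_radius_nm = 500) {
  anchors <- sort(unique(fiducial_locs$frame))
  if (length(anchors) < 2)
    .stop2("drift_error", "fiducials visible in fewer than 2 anchor frames")
  ref <- fiducial_locs[fiducial_locs$frame == anchors[1], ]
  nref <- nrow(ref)
  pos <- cbind(ref$x_nm, ref$y_nm)      # current predicted positions
  start <- pos
  drift <- matrix(0, length(anchors), 2)
  for (i in seq_along(anchors)[-1]) {
    cur <- fiducial_locs[fiducial_locs$frame == anchors[i], ]
    dx <- c(); dy <- c(); linked <- FALSE
    newpos <- pos
    for (k in seq_len(nref)) {
      dd <- (cur$x_nm - pos[k, 1])^2 + (cur$y_nm - pos[k, 2])^2
      if (!length(dd)) next
      j <- which.min(dd)
      if (dd[j] <= search_radius_nm^2) {
        dx <- c(dx, cur$x_nm[j] - start[k, 1])
        dy <- c(dy, cur$y_nm[j] - start[k, 2])
        newpos[k, ] <- c(cur$x_nm[j], cur$y_nm[j])
        linked <- TRUE
      }
    }
    if (!linked)
      .stop2("drift_error", "no linkable fiducial at anchor frame %d", anchors[i])
    drift[i, ] <- c(mean(dx), mean(dy))
    pos <- newpos
  }
  out <- data.frame(frame = anchors, dx_nm = drift[, 1], dy_nm = drift[, 2])
  class(out) <- c("drift_trajectory", "data.frame")
  attr(out, "interpolation") <- "linear"
  out
}

#' Subtract an interpolated drift trajectory from localizations
#'
#' Drift at each record's frame is interpolated piecewise-linearly between
#' anchors (clamped extrapolation outside the anchor range) and subtracted
#' from the coordinates.
#'
#' @param locs a [localization_table()].
#' @param trajectory a `drift_trajectory` from [track_fiducials()].
#' @return drift-corrected [localization_table()].
#' @export
correct_drift <- function(locs, trajectory) {
  if (!nrow(locs)) return(locs)
  dx <- stats::approx(trajectory$frame, trajectory$dx_nm, xout = locs$frame,
                      rule = 2)$y
  dy <- stats::approx(trajectory$frame, trajectory$dy_nm, xout = locs$frame,
                      rule = 2)$y
  locs$x_nm <- locs$x_nm - dx
  locs$y_nm <- locs$y_nm - dy
  locs
}

#' Estimate the translation between two channels from mutual fiducials
#'
#' Fiducials are paired by mutual nearest neighbour within
#' `search_radius_nm`; the returned translation is the mean displacement of
#' channel 2 relative to channel 1 (apply its inverse to channel-2 data to
#' align it onto channel 1).
#'
#' @param fiducials_ch1,fiducials_ch2 [localization_table()]s.
#' @param search_radius_nm pairing radius.
#' @return a translation [transform2d()] with attribute `n_pairs`.
#' @export
estimate_channel_shift <- function(fiducials_ch1, fiducials_ch2,
                                   search_radius_nm = 500) {
  n1 <- nrow(fiducials_ch1); n2 <- nrow(fiducials_ch2)
  if (!n1 || !n2) .stop2("alignment_error", "no fiducial pairs within radius")
  dx <- dy <- numeric(0)
  for (k in seq_len(n1)) {
    dd <- (fiducials_ch2$x_nm - fiducials_ch1$x_nm[k])^2 +
      (fiducials_ch2$y_nm - fiducials_ch1$y_nm[k])^2
    j <- which.min(dd)
    if (dd[j] > search_radius_nm^2) next
    back <- (fiducials_ch1$x_nm - fiducials_ch2$x_nm[j])^2 +
      (fiducials_ch1$y_nm - fiducials_ch2$y_nm[j])^2
    if (which.min(back) != k) next
    dx <- c(dx, fiducials_ch2$x_nm[j] - fiducials_ch1$x_nm[k])
    dy <- c(dy, fiducials_ch2$y_nm[j] - fiducials_ch1$y_nm[k])
  }
  if (!length(dx)) .stop2("alignment_error", "no fiducial pairs within radius")
  tf <- transform2d("translation", mean(dx), mean(dy))
  attr(tf, "n_pairs") <- length(dx)
  tf
}

#' Render localizations into a super-resolution image
#'
#' Each molecule adds a unit-integral 2D Gaussian (pixel-integrated) at its
#' position, with sigma equal to its localization precision
#' (`sigma_mode = "precision"`) or a fixed value (default 10 nm), scaled by
#' its photon count (`weight = "photons"`) or by 1 (`weight = "unit"`; the
#' mode of choice before correlation analysis, which photon weighting would
#' bias towards bright molecules). Molecules outside the field of view are
#' skipped and counted in attribute `n_skipped`.
#'
#' @param locs a [localization_table()].
#' @param fov_um field of view, length-2 (width, height) in µm (scalar =
#'   square).
#' @param pixel_size_nm rendering pixel size (default 10).
#' @param sigma_mode `"fixed"` or `"precision"`.
#' @param sigma_nm fixed rendering sigma.
#' @param weight `"photons"` or `"unit"`.
#' @return an [image_plane()] of class `rendered_image` with attributes
#'   `sigma_mode`, `n_skipped`.
#' @export
render <- function(locs, fov_um, pixel_size_nm = 10,
                   sigma_mode = c("fixed", "precision"), sigma_nm = 10,
                   weight = c("photons", "unit")) {
  sigma_mode <- match.arg(sigma_mode); weight <- match.arg(weight)
  if (pixel_size_nm <= 0) .stop2("parameter_error", "pixel_size_nm must be > 0")
  fov_nm <- rep_len(fov_um, 2) * 1000
  nx <- ceiling(fov_nm[1] / pixel_size_nm); ny <- ceiling(fov_nm[2] / pixel_size_nm)
  img <- matrix(0, ny, nx)
  inb <- locs$x_nm >= 0 & locs$x_nm <= fov_nm[1] &
    locs$y_nm >= 0 & locs$y_nm <= fov_nm[2]
  n_skipped <- sum(!inb)
  sub <- locs[inb, , drop = FALSE]
  if (nrow(sub)) {
    sg <- if (sigma_mode == "precision") sub$precision_nm
    else rep(sigma_nm, nrow(sub))
    wt <- if (weight == "photons") sub$photons else rep(1, nrow(sub))
    for (q in seq_len(nrow(sub)))
      img <- .paint_gaussian(img, sub$x_nm[q] / pixel_size_nm - 0.5,
                             sub$y_nm[q] / pixel_size_nm - 0.5,
                             sg[q] / pixel_size_nm, wt[q])
  }
  out <- image_plane(img, pixel_size_nm,
                     channel = if (nrow(locs)) locs$channel[1] else "render")
  class(out) <- c("rendered_image", class(out))
  attr(out, "sigma_mode") <- sigma_mode
  attr(out, "n_skipped") <- n_skipped
  out
}
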