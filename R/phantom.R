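#' Phantom generator configuration
#'
#' Returns the default configuration for the synthetic phantom generator and
#' lets callers override any entry (nested lists are merged). The defaults
#' describe a well-separated adherent cell population imaged at cytometry
#' resolution plus a blinking-emitter SMLM acquisition:
#'
#' * `population`: 500 cells in (G1, S, G2M) fractions (0.60, 0.25, 0.15),
#'   20% of G2M mitotic; G1 DNA integral Normal(20000, CV 0.07) photons, G2/M
#'   at twice that, S in a mid-band of 1.30-1.60 G1 equivalents; nuclei are
#'   rough ellipses of ~4.2 µm radius placed without contact on 512 px tiles
#'   at 325 nm/px, 50 cells per tile; mitotic nuclei shrink to 55% area
#'   (condensation doubles their mean DNA intensity) and become circular;
#'   EdU channel bright only in S, a mitosis marker channel bright only in
#'   M; a foci channel carries Poisson(5) diffraction-sized spots per
#'   nucleus and a 10% G1 subpopulation one large bright focus; a sparse
#'   PLA-like spot channel completes the stack.
#' * `camera`: Poisson photon noise plus Gaussian read noise (sd 2), uniform
#'   background 10 photons/px, gain 1 photon/ADU.
#' * `smlm`: 40 emitters blinking as a two-state Markov chain (on->off 0.5,
#'   off->on 0.002 per frame) over 2000 frames in a 10 µm field at 160
#'   nm/px, PSF sigma 150 nm, ~3000 photons per on-frame; 3 always-on
#'   fiducials sampled 1 every `cadence_K = 1000` frames with 2 nm centroid
#'   jitter; stage drift linear (100, 100) nm over the movie by default;
#'   emulated localization precision 10 nm.
#'
#' @param ... overrides merged into the defaults, e.g.
#'   `population = list(n_cells = 2000)`.
#' @return nested configuration list of class `phantom_config`.
#' @export
phantom_config <- function(...) {
  cfg <- list(
    population = list(
      n_cells = 500,
      phase_fractions = c(G1 = 0.60, S = 0.25, G2M = 0.15),
      mitotic_fraction = 0.20,
      dna_g1_mean = 20000,
      dna_cv = 0.07,
      s_band = c(1.30, 1.60),
      nucleus_radius_um = 4.2,
      radius_cv = 0.08,
      ellipticity_max = 1.25,
      boundary_roughness = 0.04,
      mitotic_area_factor = 0.55,
      edu_s_mean = 60, edu_bg_mean = 2,
      marker_m_mean = 80, marker_bg_mean = 3,
      foci_rate = 5, foci_sigma_px = 1.6, foci_photons = 4000,
      large_focus_fraction = 0.10,
      large_focus_sigma_px = 3.2, large_focus_photons = 40000,
      pla_rate = 2, pla_sigma_px = 1.3, pla_photons = 2500,
      foci_min_sep_px = 6,
      tile_px = 512, pixel_size_nm = 325, cells_per_tile = 50
    ),
    camera = list(background = 10, read_noise_sd = 2),
    smlm = list(
      n_emitters = 40, frames = 2000, fov_um = 10, pixel_size_nm = 160,
      psf_sigma_nm = 150, photons_mean = 3000, photons_cv = 0.2,
      k_on = 0.002, k_off = 0.5,
      n_fiducials = 3, cadence_K = 1000, fiducial_jitter_nm = 2,
      fiducial_photons = 20000,
      drift = list(model = "linear", total_nm = c(100, 100), step_sd_nm = 1),
      loc_precision_nm = 10,
      background = 5
    )
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = c("phantom_config", "list"))
}

.phantom_channels <- c("dna", "edu", "marker", "foci", "pla")

# paint an additive 2D Gaussian (pixel-integrated) onto a tile, in place
.paint_gaussian <- function(tile, cx, cy, sigma_px, integral) {
  d <- dim(tile); r <- ceiling(5 * sigma_px)
  i0 <- max(1L, floor(cy + 1 - r)); i1 <- min(d[1], ceiling(cy + 1 + r))
  j0 <- max(1L, floor(cx + 1 - r)); j1 <- min(d[2], ceiling(cx + 1 + r))
  if (i0 > i1 || j0 > j1) return(tile)
  ii <- i0:i1; jj <- j0:j1
  gy <- diff(pnorm(c(ii - 1, i1), mean = cy + 0.5, sd = sigma_px))
  gx <- diff(pnorm(c(jj - 1, j1), mean = cx + 0.5, sd = sigma_px))
  tile[ii, jj] <- tile[ii, jj] + integral * (gy %o% gx)
  tile
}

# rough-ellipse nucleus mask on a local patch; returns list(rows, cols) of
# 1-based tile indices and the patch mask
.nucleus_mask <- function(cx, cy, a, b, theta, rough, phase0, tile_px) {
  r <- ceiling(max(a, b) * (1 + rough) + 2)
  i0 <- max(1L, floor(cy + 1 - r)); i1 <- min(tile_px, ceiling(cy + 1 + r))
  j0 <- max(1L, floor(cx + 1 - r)); j1 <- min(tile_px, ceiling(cx + 1 + r))
  ii <- i0:i1; jj <- j0:j1
  # pixel centres, 0-based convention
  Y <- matrix(ii - 0.5, length(ii), length(jj)) - (cy + 0.5)
  X <- matrix(jj - 0.5, length(ii), length(jj), byrow = TRUE) - (cx + 0.5)
  u <- (cos(theta) * X + sin(theta) * Y) / a
  v <- (-sin(theta) * X + cos(theta) * Y) / b
  rho <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  lim <- 1 + rough * sin(3 * phi + phase0) + 0.5 * rough * sin(5 * phi - phase0)
  list(rows = ii, cols = jj, mask = rho <= lim)
}

#' Generate a synthetic cell population with ground truth
#'
#' Renders a multi-channel, multi-tile image set emulating a DNA-stained
#' population with cell-cycle structure (see [phantom_config()] for the
#' generative model) and returns it together with per-cell truth labels.
#' Channels per tile: `dna`, `edu`, `marker`, `foci`, `pla`.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list of class `phantom_population` with elements `tiles` (list of
#'   [image_stack()]), `truth` (data.frame: `cell_id`, `tile_index`, `phase`,
#'   `centroid_x_px`, `centroid_y_px`, `dna_integral`, `area_px`,
#'   `focus_count`, `large_focus`) and `config`.
#' @export
generate_population <- function(config = phantom_config(), seed = 1) {
  p <- config$population; cam <- config$camera
  n <- p$n_cells
  if (n < 1) .stop2("generation_error", "n_cells must be >= 1")
  fr <- p$phase_fractions / sum(p$phase_fractions)

  set.seed(.substream(seed, "population-geometry"))
  grp <- sample(names(fr), n, replace = TRUE, prob = fr)
  phase <- grp
  m <- grp == "G2M"
  phase[m] <- ifelse(runif(sum(m)) < p$mitotic_fraction, "M", "G2")

  mu <- p$dna_g1_mean
  dna <- numeric(n)
  dna[phase == "G1"] <- rnorm(sum(phase == "G1"), mu, p$dna_cv * mu)
  dna[phase == "S"] <- mu * runif(sum(phase == "S"), p$s_band[1], p$s_band[2])
  g2m <- phase %in% c("G2", "M")
  dna[g2m] <- rnorm(sum(g2m), 2 * mu, p$dna_cv * 2 * mu)
  dna <- pmax(dna, 0.1 * mu)

  r0 <- p$nucleus_radius_um * 1000 / p$pixel_size_nm
  radius <- r0 * pmax(rnorm(n, 1, p$radius_cv), 0.6)
  ell <- runif(n, 1, p$ellipticity_max)
  a <- radius * sqrt(ell); b <- radius / sqrt(ell)
  theta <- runif(n, 0, pi)
  rough <- rep(p$boundary_roughness, n)
  mit <- phase == "M"
  a[mit] <- radius[mit] * sqrt(p$mitotic_area_factor)
  b[mit] <- a[mit]; rough[mit] <- 0
  rphase <- runif(n, 0, 2 * pi)

  large <- phase == "G1" & runif(n) < p$large_focus_fraction
  nfoci <- rpois(n, p$foci_rate)

  n_tiles <- ceiling(n / p$cells_per_tile)
  tile_of <- rep(seq_len(n_tiles), each = p$cells_per_tile)[seq_len(n)]
  tp <- p$tile_px
  cx <- cy <- numeric(n)
  for (t in seq_len(n_tiles)) {
    idx <- which(tile_of == t)
    margin <- max(a[idx], b[idx]) * 1.1 + 3
    minsep <- 2 * max(a[idx], b[idx]) * 1.05 + 4
    px <- py <- numeric(0)
    for (k in idx) {
      placed <- FALSE
      for (try in seq_len(400)) {
        x <- runif(1, margin, tp - margin); y <- runif(1, margin, tp - margin)
        if (!length(px) || min((px - x)^2 + (py - y)^2) >= minsep^2) {
          px <- c(px, x); py <- c(py, y); placed <- TRUE; break
        }
      }
      if (!placed)
        .stop2("generation_error",
               "cannot place %d non-touching cells on a %d px tile", length(idx), tp)
    }
    cx[idx] <- px; cy[idx] <- py
  }

  set.seed(.substream(seed, "population-intensity"))
  edu_cell <- ifelse(phase == "S", p$edu_s_mean, p$edu_bg_mean) *
    pmax(rnorm(n, 1, 0.12), 0.5)
  mark_cell <- ifelse(phase == "M", p$marker_m_mean, p$marker_bg_mean) *
    pmax(rnorm(n, 1, 0.12), 0.5)

  tiles <- vector("list", n_tiles)
  truth_cx <- truth_cy <- truth_area <- numeric(n)
  for (t in seq_len(n_tiles)) {
    ch <- lapply(.phantom_channels, function(z) matrix(0, tp, tp))
    names(ch) <- .phantom_channels
    for (k in which(tile_of == t)) {
      nm <- .nucleus_mask(cx[k], cy[k], a[k], b[k], theta[k], rough[k],
                          rphase[k], tp)
      area <- sum(nm$mask)
      truth_area[k] <- area
      idxm <- which(nm$mask, arr.ind = TRUE)
      truth_cy[k] <- mean(nm$rows[idxm[, 1]] - 1)  # 0-based centroid
      truth_cx[k] <- mean(nm$cols[idxm[, 2]] - 1)
      add <- function(chan, per_px) {
        sub <- ch[[chan]][nm$rows, nm$cols]
        sub[nm$mask] <- sub[nm$mask] + per_px
        ch[[chan]][nm$rows, nm$cols] <<- sub
      }
      add("dna", dna[k] / area)
      add("edu", edu_cell[k])
      add("marker", mark_cell[k])
      # foci inside the nucleus: dart-throwing with a minimum separation so
      # the truth count stays optically recoverable; the realised count
      # (which can fall short of the Poisson draw at high density) is what
      # goes into the truth table
      nf <- nfoci[k]
      if (nf > 0) {
        fx <- fy <- numeric(0)
        tries <- 0L
        while (length(fx) < nf && tries < 60L * nf) {
          tries <- tries + 1L
          pick <- idxm[sample.int(nrow(idxm), 1L), ]
          qx <- nm$cols[pick[2]] - 1 + runif(1) - 0.5
          qy <- nm$rows[pick[1]] - 1 + runif(1) - 0.5
          sep_ok <- !length(fx) ||
            min((fx - qx)^2 + (fy - qy)^2) >= p$foci_min_sep_px^2
          # keep clear of the large central focus when one is present
          big_ok <- !large[k] ||
            (qx - cx[k])^2 + (qy - cy[k])^2 >=
              (p$foci_min_sep_px + 2 * p$large_focus_sigma_px)^2
          if (sep_ok && big_ok) {
            fx <- c(fx, qx); fy <- c(fy, qy)
          }
        }
        nf <- length(fx); nfoci[k] <- nf
        amp <- p$foci_photons * pmax(rnorm(nf, 1, 0.2), 0.3)
        for (q in seq_len(nf))
          ch$foci <- .paint_gaussian(ch$foci, fx[q], fy[q], p$foci_sigma_px, amp[q])
      }
      if (large[k])
        ch$foci <- .paint_gaussian(ch$foci, cx[k], cy[k],
                                   p$large_focus_sigma_px, p$large_focus_photons)
    }
    npla <- rpois(1, p$pla_rate * sum(tile_of == t))
    if (npla > 0) {
      sx <- runif(npla, 0, tp); sy <- runif(npla, 0, tp)
      for (q in seq_len(npla))
        ch$pla <- .paint_gaussian(ch$pla, sx[q], sy[q], p$pla_sigma_px,
                                  p$pla_photons)
    }
    tiles[[t]] <- ch
  }

  set.seed(.substream(seed, "population-noise"))
  for (t in seq_len(n_tiles)) {
    planes <- lapply(.phantom_channels, function(z) {
      sig <- tiles[[t]][[z]] + cam$background
      img <- rpois(length(sig), lambda = sig) +
        rnorm(length(sig), 0, cam$read_noise_sd)
      image_plane(matrix(pmax(img, 0), tp, tp), p$pixel_size_nm, channel = z)
    })
    tiles[[t]] <- image_stack(planes, channel_names = .phantom_channels)
  }

  truth <- data.frame(cell_id = seq_len(n), tile_index = tile_of,
                      phase = phase, centroid_x_px = truth_cx,
                      centroid_y_px = truth_cy, dna_integral = dna,
                      area_px = truth_area, focus_count = nfoci,
                      large_focus = large, stringsAsFactors = FALSE)
  structure(list(tiles = tiles, truth = truth, config = config),
            class = "phantom_population")
}

# drift displacement (nm) at 0-based frame f for a drift model
.drift_at <- function(drift, f, frames, seed = NULL) {
  if (drift$model == "none") return(cbind(dx = 0 * f, dy = 0 * f))
  if (drift$model == "linear") {
    cbind(dx = drift$total_nm[1] * f / frames,
          dy = drift$total_nm[2] * f / frames)
  } else if (drift$model == "random_walk") {
    steps_x <- c(0, cumsum(rnorm(frames, 0, drift$step_sd_nm)))
    steps_y <- c(0, cumsum(rnorm(frames, 0, drift$step_sd_nm)))
    cbind(dx = steps_x[f + 1], dy = steps_y[f + 1])
  } else .stop2("configuration_error", "unknown drift model '%s'", drift$model)
}

#' Generate a blinking-emitter SMLM acquisition with fiducials and drift
#'
#' Emitters switch between a fluorescent and a dark state as a two-state
#' Markov chain (they start fluorescent); every on-frame yields a
#' localization displaced by the stage drift and the emulated localization
#' precision. Always-on fiducial markers are sampled once every `cadence_K`
#' frames (anchors `0, K, 2K, ..., frames`, bracketing the acquisition) with
#' configurable centroid jitter. With `emit = "movie"` the camera frames and
#' fiducial anchor frames are rendered as images (pixel-integrated Gaussian
#' PSF plus Poisson noise) for the localization fitter; with
#' `emit = "localizations"` only the tables are produced, which keeps long
#' drift studies light.
#'
#' @param config a [phantom_config()]; see its `smlm` block.
#' @param seed integer seed.
#' @param emit `"movie"` or `"localizations"`.
#' @return list of class `phantom_smlm`: `movie` and `fiducial_movie`
#'   ([image_stack()]s, `NULL` unless `emit = "movie"`), `anchor_frames`,
#'   `locs` (observed emitter [localization_table()], drift and noise
#'   applied), `fiducial_locs` (observed fiducial localizations at anchors),
#'   `truth` (list: `emitters`, `fiducials` drift-free positions, `drift`
#'   per-anchor displacement, `drift_locs` per-record true displacement).
#' @export
generate_smlm_movie <- function(config = phantom_config(), seed = 1,
                                emit = c("movie", "localizations")) {
  emit <- match.arg(emit)
  s <- config$smlm
  if (s$n_emitters < 1) .stop2("generation_error", "need >= 1 emitter")
  if (s$n_fiducials > 0 && s$frames < 2 * s$cadence_K)
    .stop2("generation_error",
           "frames (%d) must be >= 2 * cadence_K (%d) when fiducials are requested",
           s$frames, 2 * s$cadence_K)
  fov <- s$fov_um * 1000

  set.seed(.substream(seed, "smlm-geometry"))
  ex <- runif(s$n_emitters, 0.1 * fov, 0.9 * fov)
  ey <- runif(s$n_emitters, 0.1 * fov, 0.9 * fov)
  fx <- runif(max(s$n_fiducials, 0), 0.1 * fov, 0.9 * fov)
  fy <- runif(max(s$n_fiducials, 0), 0.1 * fov, 0.9 * fov)

  set.seed(.substream(seed, "smlm-blinking"))
  on <- matrix(FALSE, s$n_emitters, s$frames)
  state <- rep(TRUE, s$n_emitters)   # dyes start in the fluorescent state
  for (f in seq_len(s$frames)) {
    on[, f] <- state
    u <- runif(s$n_emitters)
    state <- ifelse(state, u > s$k_off, u < s$k_on)
  }

  set.seed(.substream(seed, "smlm-drift"))
  frames0 <- seq_len(s$frames) - 1L
  dr <- .drift_at(s$drift, frames0, s$frames)
  anchors <- seq(0L, s$frames, by = s$cadence_K)
  dra <- .drift_at(s$drift, anchors, s$frames)
  if (s$drift$model == "random_walk") {   # one realisation shared by both
    set.seed(.substream(seed, "smlm-drift"))
    full <- .drift_at(s$drift, 0:s$frames, s$frames)
    dr <- full[frames0 + 1, , drop = FALSE]
    dra <- full[anchors + 1, , drop = FALSE]
  }

  set.seed(.substream(seed, "smlm-noise"))
  hits <- which(on, arr.ind = TRUE)
  ord <- order(hits[, 2], hits[, 1])
  hits <- hits[ord, , drop = FALSE]
  fid <- hits[, 1]; ff <- hits[, 2] - 1L
  nh <- nrow(hits)
  photons <- pmax(rnorm(nh, s$photons_mean, s$photons_cv * s$photons_mean),
                  0.05 * s$photons_mean)
  obs_x <- ex[fid] + dr[ff + 1, 1] + rnorm(nh, 0, s$loc_precision_nm)
  obs_y <- ey[fid] + dr[ff + 1, 2] + rnorm(nh, 0, s$loc_precision_nm)
  locs <- localization_table(obs_x, obs_y, frame = ff, channel = "smlm",
                             sigma_nm = s$psf_sigma_nm, photons = photons,
                             background = s$background,
                             precision_nm = s$loc_precision_nm)
  locs$emitter_id <- fid

  na <- length(anchors)
  if (s$n_fiducials > 0) {
    gx <- rep(fx, na) + rep(dra[, 1], each = s$n_fiducials) +
      rnorm(na * s$n_fiducials, 0, s$fiducial_jitter_nm)
    gy <- rep(fy, na) + rep(dra[, 2], each = s$n_fiducials) +
      rnorm(na * s$n_fiducials, 0, s$fiducial_jitter_nm)
    fiducial_locs <- localization_table(gx, gy,
                                        frame = rep(anchors, each = s$n_fiducials),
                                        channel = "fiducial",
                                        sigma_nm = s$psf_sigma_nm,
                                        photons = s$fiducial_photons,
                                        precision_nm = s$fiducial_jitter_nm)
  } else fiducial_locs <- localization_table(numeric(0), numeric(0))

  movie <- fiducial_movie <- NULL
  if (emit == "movie") {
    set.seed(.substream(seed, "smlm-camera"))
    npx <- ceiling(fov / s$pixel_size_nm)
    spx <- s$psf_sigma_nm / s$pixel_size_nm
    render_frame <- function(xs, ys, ph) {
      img <- matrix(0, npx, npx)
      for (q in seq_along(xs))
        img <- .paint_gaussian(img, xs[q] / s$pixel_size_nm - 0.5,
                               ys[q] / s$pixel_size_nm - 0.5, spx, ph[q])
      matrix(pmax(rpois(npx * npx, img + s$background), 0), npx, npx)
    }
    planes <- vector("list", s$frames)
    for (f in frames0) {
      sel <- ff == f
      planes[[f + 1]] <- image_plane(
        render_frame(ex[fid[sel]] + dr[f + 1, 1], ey[fid[sel]] + dr[f + 1, 2],
                     photons[sel]),
        s$pixel_size_nm, channel = "smlm")
    }
    movie <- image_stack(planes, channel_names = "smlm")
    if (s$n_fiducials > 0) {
      fpl <- lapply(seq_len(na), function(i)
        image_plane(render_frame(fx + dra[i, 1], fy + dra[i, 2],
                                 rep(s$fiducial_photons, s$n_fiducials)),
                    s$pixel_size_nm, channel = "fiducial"))
      fiducial_movie <- image_stack(fpl, channel_names = "fiducial")
    }
  }

  truth <- list(
    emitters = data.frame(id = seq_len(s$n_emitters), x_nm = ex, y_nm = ey),
    fiducials = data.frame(id = seq_len(max(s$n_fiducials, 0)),
                           x_nm = fx, y_nm = fy),
    drift = data.frame(frame = anchors, dx_nm = dra[, 1], dy_nm = dra[, 2]),
    drift_locs = data.frame(frame = frames0, dx_nm = dr[, 1], dy_nm = dr[, 2]))
  structure(list(movie = movie, fiducial_movie = fiducial_movie,
                 anchor_frames = anchors, locs = locs,
                 fiducial_locs = fiducial_locs, truth = truth,
                 config = config, fov_nm = fov),
            class = "phantom_smlm")
}

#' Generate two-channel point patterns with a controlled colocalized fraction
#'
#' `round(f_true * min(n1, n2))` channel-2 points are placed at a channel-1
#' position plus isotropic Gaussian jitter; the remainder are uniform over
#' the field. The realised pairing is returned as truth.
#'
#' @param n1,n2 points per channel.
#' @param f_true true colocalized fraction in \[0, 1\].
#' @param area_um2 field area (square), µm².
#' @param jitter_nm isotropic Gaussian jitter sigma for paired points, nm.
#' @param seed integer seed.
#' @return list of class `phantom_points`: `ch1`, `ch2`
#'   ([localization_table()]s), `truth` (list with `pairs` data.frame
#'   (`id1`, `id2`), `f_true`, `side_nm`).
#' @export
generate_two_channel_points <- function(n1, n2, f_true, area_um2 = 100,
                                        jitter_nm = 10, seed = 1) {
  if (f_true < 0 || f_true > 1)
    .stop2("validation_error", "f_true must be in [0, 1]")
  side <- sqrt(area_um2) * 1000
  set.seed(.substream(seed, "points"))
  x1 <- runif(n1, 0, side); y1 <- runif(n1, 0, side)
  npair <- round(f_true * min(n1, n2))
  part <- if (npair > 0) sample.int(n1, npair) else integer(0)
  x2 <- runif(n2, 0, side); y2 <- runif(n2, 0, side)
  if (npair > 0) {
    x2[seq_len(npair)] <- x1[part] + rnorm(npair, 0, jitter_nm)
    y2[seq_len(npair)] <- y1[part] + rnorm(npair, 0, jitter_nm)
  }
  perm <- sample.int(n2)
  x2 <- x2[perm]; y2 <- y2[perm]
  id2_of_pair <- match(seq_len(npair), perm)
  ch1 <- localization_table(x1, y1, channel = "ch1")
  ch2 <- localization_table(x2, y2, channel = "ch2")
  pairs <- data.frame(id1 = part, id2 = id2_of_pair)
  structure(list(ch1 = ch1, ch2 = ch2,
                 truth = list(pairs = pairs, f_true = f_true, side_nm = side)),
            class = "phantom_points")
}

#' Generate a synthetic scene for registration tests
#'
#' Random Gaussian blobs of mixed size on a smooth background; a generic
#' structured field with energy at several spatial scales.
#'
#' @param size_px side length in pixels.
#' @param pixel_size_nm pixel pitch.
#' @param n_blobs number of blobs.
#' @param seed integer seed.
#' @return an [image_plane()].
#' @export
phantom_scene <- function(size_px = 256, pixel_size_nm = 65, n_blobs = 120,
                          seed = 1) {
  set.seed(.substream(seed, "scene"))
  img <- matrix(10, size_px, size_px)
  bx <- runif(n_blobs, 0, size_px); by <- runif(n_blobs, 0, size_px)
  bs <- runif(n_blobs, 1.5, 6); bi <- runif(n_blobs, 500, 5000)
  for (q in seq_len(n_blobs))
    img <- .paint_gaussian(img, bx[q], by[q], bs[q], bi[q])
  image_plane(img, pixel_size_nm, channel = "scene")
}

#' Generate a filament-like confocal phantom with a truth mask
#'
#' Renders randomly oriented straight filaments (microtubule-like) blurred
#' to confocal resolution, plus camera noise, and returns the true filament
#' support for mask-quality checks.
#'
#' @param size_px side length in pixels.
#' @param pixel_size_nm pixel pitch.
#' @param n_filaments number of filaments.
#' @param width_px filament Gaussian half-width in pixels.
#' @param seed integer seed.
#' @return list: `plane` ([image_plane()]), `truth_mask` (logical matrix of
#'   pixels within one Gaussian half-width (`width_px`) of a filament axis,
#'   the support carrying most of the filament signal).
#' @export
phantom_filaments <- function(size_px = 256, pixel_size_nm = 65,
                              n_filaments = 6, width_px = 2, seed = 1) {
  set.seed(.substream(seed, "filaments"))
  img <- matrix(0, size_px, size_px)
  xs <- matrix(rep(seq_len(size_px) - 0.5, each = size_px), size_px)
  ys <- matrix(rep(seq_len(size_px) - 0.5, size_px), size_px)
  dmin <- matrix(Inf, size_px, size_px)
  for (q in seq_len(n_filaments)) {
    x0 <- runif(1, 0, size_px); y0 <- runif(1, 0, size_px)
    th <- runif(1, 0, pi)
    # signed distance from the line through (x0, y0) with direction th
    d <- abs(-sin(th) * (xs - x0) + cos(th) * (ys - y0))
    dmin <- pmin(dmin, d)
    img <- img + 800 * exp(-d^2 / (2 * width_px^2))
  }
  noisy <- matrix(pmax(rpois(size_px^2, img + 5) + rnorm(size_px^2, 0, 2), 0),
                  size_px, size_px)
  list(plane = image_plane(noisy, pixel_size_nm, channel = "tubulin"),
       truth_mask = dmin <= width_px)
}

#' Generate a pair of differently sampled, displaced images
#'
#' Resamples a base scene at two pixel sizes and applies a known physical
#' transform to the second image, emulating the same field viewed by two
#' modalities (e.g. 65 nm widefield vs 160 nm relay-lens sampling).
#'
#' @param base_image an [image_plane()] (fine sampling recommended).
#' @param transform a [transform2d()]; the displacement of image B's content
#'   relative to image A in physical nm.
#' @param pixel_sizes length-2 numeric: pixel size of A and of B, nm.
#' @param noise_sd Gaussian noise sd as a fraction of the scene sd.
#' @param seed integer seed.
#' @return list of class `phantom_regpair`: `A`, `B` ([image_plane()]s) and
#'   `truth` (the injected [transform2d()]).
#' @export
generate_registration_pair <- function(base_image, transform,
                                       pixel_sizes = c(65, 160),
                                       noise_sd = 0.01, seed = 1) {
  stopifnot(inherits(base_image, "image_plane"), inherits(transform, "transform2d"))
  ext <- dim(base_image$pixels) * base_image$pixel_size_nm  # (y, x) nm
  resample <- function(px, tf = NULL) {
    nx <- floor(ext[2] / px); ny <- floor(ext[1] / px)
    gx <- (seq_len(nx) - 0.5) * px; gy <- (seq_len(ny) - 0.5) * px
    X <- matrix(gx, ny, nx, byrow = TRUE); Y <- matrix(gy, ny, nx)
    if (!is.null(tf)) {
      inv <- invert_transform(tf)
      pts <- transform_points(inv, cbind(as.vector(X), as.vector(Y)))
      X <- matrix(pts[, 1], ny, nx); Y <- matrix(pts[, 2], ny, nx)
    }
    out <- .bilinear_sample(base_image$pixels,
                            X / base_image$pixel_size_nm - 0.5,
                            Y / base_image$pixel_size_nm - 0.5)
    list(img = matrix(out, ny, nx), inside = mean(is.finite(out)))
  }
  A <- resample(pixel_sizes[1])
  B <- resample(pixel_sizes[2], transform)
  if (B$inside < 0.5)
    .stop2("generation_error",
           "transform pushes more than 50%% of the content out of frame")
  set.seed(.substream(seed, "regpair"))
  fix <- function(r, px) {
    img <- r$img; img[!is.finite(img)] <- 0
    img <- pmax(img + rnorm(length(img), 0, noise_sd * stats::sd(img)), 0)
    image_plane(img, px, channel = "scene")
  }
  structure(list(A = fix(A, pixel_sizes[1]), B = fix(B, pixel_sizes[2]),
                 truth = transform),
            class = "phantom_regpair")
}
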