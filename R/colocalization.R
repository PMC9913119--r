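#' Image cross-correlation spectroscopy (ICCS)
#'
#' Computes the spatial intensity-fluctuation correlation surfaces
#' `G_ab(xi, eta) = <dI_a(x, y) dI_b(x + xi, y + eta)> / (<I_a> <I_b>)`
#' via FFT for the two auto-correlations and the cross-correlation, fits
#' each central peak with a 2D Gaussian plus offset (the (0,0) lag of the
#' auto-correlations is excluded from the fit: it carries the shot-noise
#' spike), and derives the colocalized fractions from the fitted zero-lag
#' amplitudes: `f1 = Gcc(0) / G22(0)` (fraction of channel 1) and
#' `f2 = Gcc(0) / G11(0)`, both clamped to \[0, 1\].
#'
#' @param image1,image2 [image_plane()]s or matrices on a common grid.
#' @param fit_radius_px half-size of the square fit region around zero lag.
#' @return list of class `correlation_result`: `G11`, `G22`, `Gcc` (fitted
#'   zero-lag amplitudes), `w11`, `w22`, `wcc` (fitted e-squared widths,
#'   px), `f1`, `f2`, `fit_ok`, and the three correlation surfaces
#'   (`surface_11` etc., centred; lag 0 at `fit_radius_px + 1`).
#' @export
compute_iccs <- function(image1, image2, fit_radius_px = 8) {
  m1 <- if (inherits(image1, "image_plane")) image1$pixels else as.matrix(image1)
  m2 <- if (inherits(image2, "image_plane")) image2$pixels else as.matrix(image2)
  if (!identical(dim(m1), dim(m2)))
    .stop2("validation_error", "images must share a common grid")
  mu1 <- mean(m1); mu2 <- mean(m2)
  if (mu1 <= 0 || mu2 <= 0)
    .stop2("normalization_error", "zero-mean channel: ICCS undefined")
  d <- dim(m1); N <- prod(d)
  F1 <- stats::fft(m1 - mu1); F2 <- stats::fft(m2 - mu2)
  corr <- function(Fa, Fb, mua, mub)
    Re(stats::fft(Fa * Conj(Fb), inverse = TRUE)) / (N * N * mua * mub)
  g11 <- corr(F1, F1, mu1, mu1)
  g22 <- corr(F2, F2, mu2, mu2)
  gcc <- corr(F1, F2, mu1, mu2)
  r <- fit_radius_px
  # centre the lag window: rows/cols -r..r via circular indexing
  ix <- function(k, n) ((k %% n) + n) %% n + 1
  rows <- ix(-r:r, d[1]); cols <- ix(-r:r, d[2])
  sub <- function(g) g[rows, cols, drop = FALSE]
  s11 <- sub(g11); s22 <- sub(g22); scc <- sub(gcc)

  fit_peak <- function(s, exclude_center) {
    n <- 2 * r + 1
    xs <- rep(-r:r, each = n); ys <- rep(-r:r, n)
    z <- as.vector(s)
    if (exclude_center) {
      keep <- !(xs == 0 & ys == 0)
      xs <- xs[keep]; ys <- ys[keep]; z <- z[keep]
    }
    g0 <- max(z); off0 <- stats::median(z)
    fit <- tryCatch(
      minpack.lm::nlsLM(z ~ off + g * exp(-(xs^2 + ys^2) / w^2),
                        data = data.frame(z = z, xs = xs, ys = ys),
                        start = list(off = off0, g = max(g0 - off0, 1e-12),
                                     w = r / 2),
                        lower = c(off = -Inf, g = 0, w = 0.3),
                        upper = c(off = Inf, g = Inf, w = 4 * r),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      list(g = max(z) - stats::median(z), w = NA_real_, ok = FALSE)
    } else {
      co <- stats::coef(fit)
      list(g = unname(co["g"]), w = unname(co["w"]), ok = TRUE)
    }
  }
  p11 <- fit_peak(s11, TRUE); p22 <- fit_peak(s22, TRUE)
  pcc <- fit_peak(scc, FALSE)
  clamp01 <- function(x) min(max(x, 0), 1)
  f1 <- if (p22$g > 0) clamp01(pcc$g / p22$g) else 0
  f2 <- if (p11$g > 0) clamp01(pcc$g / p11$g) else 0
  structure(list(G11 = p11$g, G22 = p22$g, Gcc = pcc$g,
                 w11 = p11$w, w22 = p22$w, wcc = pcc$w,
                 f1 = f1, f2 = f2,
                 fit_ok = p11$ok && p22$ok && pcc$ok,
                 surface_11 = s11, surface_22 = s22, surface_cc = scc),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> G11=%.4g G22=%.4g Gcc=%.4g  f1=%.3f f2=%.3f%s\n",
              x$G11, x$G22, x$Gcc, x$f1, x$f2,
              if (x$fit_ok) "" else "  [fit flagged]"))
  invisible(x)
}

#' Single-linkage clustering of localizations
#'
#' Connected components of the graph linking localizations separated by at
#' most `linking_radius_nm` (inclusive, single linkage); components with
#' fewer than `min_points` members are discarded. Neighbour search uses a
#' spatial grid, so the result is identical to the full distance-matrix
#' computation at any size.
#'
#' @param locs a [localization_table()] (or data.frame with `x_nm`,
#'   `y_nm`).
#' @param linking_radius_nm linking distance (default 50).
#' @param min_points minimum members per cluster.
#' @return data.frame of class `cluster_table`: `cluster_id`, `channel`,
#'   `x_nm`, `y_nm` (unweighted centroid), `n`, `r_gyration_nm`; attribute
#'   `assignment` maps each input row to its cluster id (0 = discarded).
#' @export
cluster_localizations <- function(locs, linking_radius_nm = 50,
                                  min_points = 1) {
  if (linking_radius_nm <= 0)
    .stop2("parameter_error", "linking_radius_nm must be > 0")
  n <- nrow(locs)
  empty <- data.frame(cluster_id = integer(0), channel = character(0),
                      x_nm = numeric(0), y_nm = numeric(0), n = integer(0),
                      r_gyration_nm = numeric(0))
  class(empty) <- c("cluster_table", "data.frame")
  if (!n) return(empty)
  x <- locs$x_nm; y <- locs$y_nm
  r <- linking_radius_nm
  gx <- floor(x / r); gy <- floor(y / r)
  key <- paste(gx, gy)
  cellof <- split(seq_len(n), key)
  edges <- vector("list", length(cellof)); e <- 0L
  cells <- do.call(rbind, strsplit(names(cellof), " "))
  cgx <- as.numeric(cells[, 1]); cgy <- as.numeric(cells[, 2])
  lookup <- new.env(hash = TRUE, size = length(cellof))
  for (i in seq_along(cellof)) assign(names(cellof)[i], i, envir = lookup)
  for (i in seq_along(cellof)) {
    pts_i <- cellof[[i]]
    for (ox in -1:1) for (oy in -1:1) {
      k2 <- paste(cgx[i] + ox, cgy[i] + oy)
      j <- if (exists(k2, envir = lookup, inherits = FALSE))
        get(k2, envir = lookup) else next
      if (j < i) next
      pts_j <- cellof[[j]]
      dd <- outer(x[pts_i], x[pts_j], "-")^2 + outer(y[pts_i], y[pts_j], "-")^2
      hit <- which(dd <= r^2, arr.ind = TRUE)
      if (i == j) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (nrow(hit)) {
        e <- e + 1L
        edges[[e]] <- cbind(pts_i[hit[, 1]], pts_j[hit[, 2]])
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (e > 0) {
    em <- do.call(rbind, edges[seq_len(e)])
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_points)
  if (!length(keep)) {
    attr(empty, "assignment") <- rep(0L, n)
    return(empty)
  }
  remap <- integer(length(sizes)); remap[keep] <- seq_along(keep)
  assign_id <- remap[comp]
  cx <- as.vector(tapply(x, comp, mean))[keep]
  cy <- as.vector(tapply(y, comp, mean))[keep]
  rg <- vapply(keep, function(k) {
    i <- which(comp == k)
    sqrt(mean((x[i] - mean(x[i]))^2 + (y[i] - mean(y[i]))^2))
  }, 0)
  chan <- if (!is.null(locs$channel)) locs$channel[match(keep, comp)] else "ch1"
  out <- data.frame(cluster_id = seq_along(keep), channel = chan,
                    x_nm = cx, y_nm = cy, n = sizes[keep],
                    r_gyration_nm = rg)
  class(out) <- c("cluster_table", "data.frame")
  attr(out, "assignment") <- assign_id
  out
}

#' Compartment mask from a registered confocal channel
#'
#' Transforms the confocal plane onto the target grid (the STORM / TIRF
#' rendering grid), thresholds it (Otsu by default) and closes small gaps
#' morphologically.
#'
#' @param plane confocal [image_plane()].
#' @param transform [transform2d()] mapping confocal coordinates onto the
#'   target modality's coordinates.
#' @param target_grid an [image_plane()] (or list with `dim` and
#'   `pixel_size_nm`) defining the output grid.
#' @param threshold `"otsu"` or a numeric value.
#' @param close_radius_px radius of the morphological closing (0 disables).
#' @return logical mask matrix with attribute `pixel_size_nm`.
#' @export
mask_from_confocal <- function(plane, transform, target_grid,
                               threshold = "otsu", close_radius_px = 3) {
  tg_dim <- if (inherits(target_grid, "image_plane")) dim(target_grid$pixels)
  else target_grid$dim
  tg_px <- if (inherits(target_grid, "image_plane")) target_grid$pixel_size_nm
  else target_grid$pixel_size_nm
  gx <- (seq_len(tg_dim[2]) - 0.5) * tg_px
  gy <- (seq_len(tg_dim[1]) - 0.5) * tg_px
  X <- matrix(gx, tg_dim[1], tg_dim[2], byrow = TRUE)
  Y <- matrix(gy, tg_dim[1], tg_dim[2])
  inv <- invert_transform(transform)
  src <- transform_points(inv, cbind(as.vector(X), as.vector(Y)))
  v <- .bilinear_sample(plane$pixels, src[, 1] / plane$pixel_size_nm - 0.5,
                        src[, 2] / plane$pixel_size_nm - 0.5)
  v[!is.finite(v)] <- 0
  m <- matrix(v, tg_dim[1], tg_dim[2])
  thr <- if (identical(threshold, "otsu")) {
    mx <- max(m)
    if (mx <= 0) Inf else EBImage::otsu(EBImage::Image(m / mx), range = c(0, 1)) * mx
  } else threshold
  mask <- m > thr
  if (close_radius_px > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2 * close_radius_px + 1, "disc")
    mask <- EBImage::closing(mask, brush) > 0
  }
  if (!any(mask)) warning("confocal mask is empty")
  attr(mask, "pixel_size_nm") <- tg_px
  mask
}

#' Object-based colocalization of two cluster sets
#'
#' Candidate pairs are centroid pairs at most `adjacency_nm` apart
#' (inclusive); the matching is greedy by ascending distance (ties broken
#' by lowest cluster ids) with mutual exclusivity. Fractions are matched
#' clusters over total per channel; the stoichiometry histogram counts, for
#' each matched cluster, how many opposite-channel clusters lie within the
#' adjacency distance.
#'
#' @param clustersA,clustersB `cluster_table`s (see
#'   [cluster_localizations()]).
#' @param adjacency_nm adjacency limit (50 for STORM-scale analysis, ~250
#'   for TIRF-scale).
#' @return list of class `coloc_result`: `fraction_A`, `fraction_B`,
#'   `pairs` (data.frame `id_A`, `id_B`, `distance_nm`),
#'   `stoichiometry_A`, `stoichiometry_B` (tables of partner counts),
#'   `n_A`, `n_B`.
#' @export
object_colocalization <- function(clustersA, clustersB, adjacency_nm = 50) {
  if (adjacency_nm <= 0) .stop2("parameter_error", "adjacency_nm must be > 0")
  nA <- nrow(clustersA); nB <- nrow(clustersB)
  if (!nA || !nB) {
    return(structure(list(fraction_A = 0, fraction_B = 0,
                          pairs = data.frame(id_A = integer(0),
                                             id_B = integer(0),
                                             distance_nm = numeric(0)),
                          stoichiometry_A = table(integer(0)),
                          stoichiometry_B = table(integer(0)),
                          n_A = nA, n_B = nB), class = "coloc_result"))
  }
  cand <- .pairs_within(clustersA$x_nm, clustersA$y_nm,
                        clustersB$x_nm, clustersB$y_nm, adjacency_nm)
  ord <- order(cand$d, cand$i, cand$j)
  usedA <- rep(FALSE, nA); usedB <- rep(FALSE, nB)
  mi <- mj <- integer(0); md <- numeric(0)
  for (q in ord) {
    i <- cand$i[q]; j <- cand$j[q]
    if (usedA[i] || usedB[j]) next
    usedA[i] <- TRUE; usedB[j] <- TRUE
    mi <- c(mi, i); mj <- c(mj, j); md <- c(md, cand$d[q])
  }
  partnersA <- tabulate(cand$i, nbins = nA)
  partnersB <- tabulate(cand$j, nbins = nB)
  structure(list(
    fraction_A = length(mi) / nA, fraction_B = length(mj) / nB,
    pairs = data.frame(id_A = clustersA$cluster_id[mi],
                       id_B = clustersB$cluster_id[mj], distance_nm = md),
    stoichiometry_A = table(partnersA[usedA]),
    stoichiometry_B = table(partnersB[usedB]),
    n_A = nA, n_B = nB), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d/%d A matched (%.3f), %d/%d B matched (%.3f)\n",
              nrow(x$pairs), x$n_A, x$fraction_A,
              nrow(x$pairs), x$n_B, x$fraction_B))
  invisible(x)
}

# grid-accelerated cross-channel pairs within radius
.pairs_within <- function(xa, ya, xb, yb, r) {
  gxb <- floor(xb / r); gyb <- floor(yb / r)
  keyb <- paste(gxb, gyb)
  byb <- split(seq_along(xb), keyb)
  ii <- jj <- integer(0); dd <- numeric(0)
  for (k in seq_along(xa)) {
    cx <- floor(xa[k] / r); cy <- floor(ya[k] / r)
    for (ox in -1:1) for (oy in -1:1) {
      cand <- byb[[paste(cx + ox, cy + oy)]]
      if (is.null(cand)) next
      d2 <- (xb[cand] - xa[k])^2 + (yb[cand] - ya[k])^2
      hit <- cand[d2 <= r^2]
      if (length(hit)) {
        ii <- c(ii, rep(k, length(hit))); jj <- c(jj, hit)
        dd <- c(dd, sqrt(d2[d2 <= r^2]))
      }
    }
  }
  list(i = ii, j = jj, d = dd)
}

#' Distances from clusters to a reference
#'
#' For a cluster-table reference: nearest-neighbour centroid distance from
#' each A cluster to the reference set. For a mask reference: the value of
#' the Euclidean distance transform (to the nearest mask pixel) at each
#' centroid, 0 inside the mask.
#'
#' @param clustersA a `cluster_table`.
#' @param reference a `cluster_table`, or a logical mask matrix with
#'   attribute `pixel_size_nm` (as from [mask_from_confocal()]).
#' @return numeric vector of distances, nm.
#' @export
distance_distribution <- function(clustersA, reference) {
  if (is.data.frame(reference)) {
    if (!nrow(reference)) .stop2("validation_error", "empty reference")
    vapply(seq_len(nrow(clustersA)), function(k)
      sqrt(min((reference$x_nm - clustersA$x_nm[k])^2 +
                 (reference$y_nm - clustersA$y_nm[k])^2)), 0)
  } else {
    mask <- reference
    px <- attr(mask, "pixel_size_nm")
    if (is.null(px)) .stop2("validation_error", "mask lacks pixel_size_nm")
    if (!any(mask)) .stop2("validation_error", "empty reference mask")
    dm <- as.matrix(EBImage::imageData(EBImage::distmap(!mask))) * px
    ri <- pmin(pmax(floor(clustersA$y_nm / px) + 1L, 1L), nrow(mask))
    ci <- pmin(pmax(floor(clustersA$x_nm / px) + 1L, 1L), ncol(mask))
    dm[cbind(ri, ci)]
  }
}

#' Label clusters by compartment membership
#'
#' A cluster is on-mask iff its mask distance is at most `tolerance_nm`
#' (default 0: centroid inside the mask).
#'
#' @param clusters a `cluster_table`.
#' @param mask logical mask with attribute `pixel_size_nm`.
#' @param tolerance_nm distance tolerance.
#' @return `clusters` with an added logical `on_mask` column.
#' @export
compartment_split <- function(clusters, mask, tolerance_nm = 0) {
  if (!nrow(clusters)) { clusters$on_mask <- logical(0); return(clusters) }
  d <- if (any(mask)) distance_distribution(clusters, mask) else
    rep(Inf, nrow(clusters))
  clusters$on_mask <- d <= tolerance_nm
  clusters
}

#' Object colocalization split by compartment
#'
#' Runs [object_colocalization()] separately for clusters on and off a
#' compartment mask (both channels restricted to the same compartment).
#'
#' @inheritParams object_colocalization
#' @param mask logical mask with `pixel_size_nm` attribute.
#' @param tolerance_nm see [compartment_split()].
#' @return list with `on_mask` and `off_mask` `coloc_result`s.
#' @export
coloc_by_compartment <- function(clustersA, clustersB, mask,
                                 adjacency_nm = 50, tolerance_nm = 0) {
  a <- compartment_split(clustersA, mask, tolerance_nm)
  b <- compartment_split(clustersB, mask, tolerance_nm)
  list(on_mask = object_colocalization(a[a$on_mask, , drop = FALSE],
                                       b[b$on_mask, , drop = FALSE],
                                       adjacency_nm),
       off_mask = object_colocalization(a[!a$on_mask, , drop = FALSE],
                                        b[!b$on_mask, , drop = FALSE],
                                        adjacency_nm))
}
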