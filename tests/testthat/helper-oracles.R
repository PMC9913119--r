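# Independent oracles used by the tests. These deliberately re-derive
# results by the most direct (brute-force) route available and share no
# code with the package implementation.

# single-linkage partition by union-find over the full distance matrix
oracle_single_linkage <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  edges <- which(d2 <= radius^2 & upper.tri(d2), arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 0L)
}

# same partition up to label renaming
same_partition <- function(a, b) {
  isTRUE(all.equal(outer(a, a, "=="), outer(b, b, "==")))
}

# greedy mutually-exclusive matching by ascending distance over the full
# distance matrix; ties broken by lowest row then column index
oracle_greedy_match <- function(xa, ya, xb, yb, radius) {
  d <- sqrt(outer(xa, xb, "-")^2 + outer(ya, yb, "-")^2)
  cand <- which(d <= radius, arr.ind = TRUE)
  if (!nrow(cand)) return(cbind(i = integer(0), j = integer(0)))
  dist <- d[cand]
  ord <- order(dist, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  usedA <- rep(FALSE, length(xa)); usedB <- rep(FALSE, length(xb))
  out <- matrix(0L, 0, 2)
  for (q in seq_len(nrow(cand))) {
    i <- cand[q, 1]; j <- cand[q, 2]
    if (usedA[i] || usedB[j]) next
    usedA[i] <- TRUE; usedB[j] <- TRUE
    out <- rbind(out, c(i, j))
  }
  out
}

# direct grayscale opening with a disc: brute-force min-then-max over all
# offsets inside the disc (small images only)
oracle_opening_disc <- function(m, radius) {
  d <- dim(m)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  sweep_op <- function(src, fun, pad) {
    out <- matrix(pad, d[1], d[2])
    for (q in seq_len(nrow(offs))) {
      i <- seq_len(d[1]) + offs$dy[q]; j <- seq_len(d[2]) + offs$dx[q]
      ok_i <- i >= 1 & i <= d[1]; ok_j <- j >= 1 & j <= d[2]
      sub <- matrix(pad, d[1], d[2])
      sub[ok_i, ok_j] <- src[i[ok_i], j[ok_j]]
      out <- fun(out, sub)
    }
    out
  }
  er <- sweep_op(m, pmin, Inf)
  sweep_op(er, pmax, -Inf)
}

# match measured cells to phantom truth by nearest centroid within the tile
match_cells_to_truth <- function(cells, truth, max_dist_px = 6) {
  idx <- rep(NA_integer_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cand <- which(truth$tile_index == cells$tile_index[i])
    if (!length(cand)) next
    d2 <- (truth$centroid_x_px[cand] - cells$centroid_x_px[i])^2 +
      (truth$centroid_y_px[cand] - cells$centroid_y_px[i])^2
    j <- which.min(d2)
    if (d2[j] <= max_dist_px^2) idx[i] <- cand[j]
  }
  idx
}

# rasterised disc on pixel centres
raster_disc <- function(size, cx, cy, r) {
  xs <- matrix(rep(seq_len(size) - 0.5, each = size), size)
  ys <- matrix(rep(seq_len(size) - 0.5, size), size)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# render a point table as a unit-weight fixed-sigma image (for ICCS tests)
render_points <- function(locs, side_nm, pixel_nm = 100, psf_nm = 150) {
  render(locs, fov_um = side_nm / 1000, pixel_size_nm = pixel_nm,
         sigma_mode = "fixed", sigma_nm = psf_nm, weight = "unit")
}

cli_path <- function() system.file("cli", "cytostorm", package = "cytostorm")

run_cli <- function(...) {
  out <- suppressWarnings(system2("Rscript", c(cli_path(), ...),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(ok = is.null(status) || status == 0, output = out)
}
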