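test_that("rolling-ball background subtraction behaves like the opening oracle", {
  # constant image: background equals the image, output all zero
  expect_equal(subtract_background(matrix(7, 60, 60), 10),
               matrix(0, 60, 60))
  # bright compact spot on flat background: peak kept, background removed
  sp <- matrix(10, 100, 100); sp[50:52, 50:52] <- 500
  out <- subtract_background(sp, 25, presmooth_sigma_px = 0)
  expect_gt(max(out), 0.95 * (500 - 10))
  expect_equal(median(out), 0)
  # against the brute-force opening computation (no smoothing, no shrink)
  set.seed(1)
  m <- matrix(runif(40 * 40, 0, 100), 40)
  got <- subtract_background(m, 6, presmooth_sigma_px = 0, shrink = 1)
  expect_equal(got, pmax(m - oracle_opening_disc(m, 6), 0), tolerance = 1e-12)
  # clamping contract
  expect_gte(min(subtract_background(matrix(rexp(900), 30), 5)), 0)
  expect_error(subtract_background(matrix(0, 10, 10), 20),
               class = "parameter_error")
})

test_that("flat-field correction is exact in its closed-form cases", {
  set.seed(2)
  m <- matrix(runif(400, 10, 100), 20)
  # flatfield = plane: constant output at the plane mean
  expect_equal(flatfield_correct(m, m), matrix(mean(m), 20, 20))
  # constant flatfield: identity
  expect_equal(flatfield_correct(m, matrix(3, 20, 20)), m)
  # synthetic vignette applied then corrected recovers the original (up to
  # the unit-mean normalisation of the flat-field)
  xs <- matrix(rep(seq_len(20) - 10.5, each = 20), 20)
  vign <- 1 - 0.3 * (xs^2 + t(xs)^2) / max(xs^2 + t(xs)^2)
  corrected <- flatfield_correct(m * vign, vign) / mean(vign)
  expect_lt(max(abs(corrected - m) / m), 0.01)
  expect_error(flatfield_correct(m, matrix(0, 20, 20)),
               class = "validation_error")
  expect_error(flatfield_correct(m, matrix(1, 5, 5)),
               class = "validation_error")
})

test_that("nuclei segmentation finds the phantom nuclei exactly", {
  pop <- generate_population(phantom_config(population = list(n_cells = 50)),
                             seed = 21)
  lab <- segment_nuclei(subtract_background(get_plane(pop$tiles[[1]], "dna"), 25))
  expect_equal(max(lab), 50)
  # blank image: zero labels, not an error
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
  # overlapping discs split by watershed, merged without
  two <- matrix(0, 80, 80)
  two[raster_disc(80, 28, 40, 14) | raster_disc(80, 52, 40, 14)] <- 100
  expect_equal(max(segment_nuclei(two, segmentation_params(watershed = TRUE,
                                                           min_area_px = 20))), 2)
  expect_equal(max(segment_nuclei(two, segmentation_params(watershed = FALSE,
                                                           min_area_px = 20))), 1)
})

test_that("cell measurements are exact on constructed objects", {
  sq <- matrix(0, 32, 32); sq[11:20, 11:20] <- 1
  lab <- segment_nuclei(sq, segmentation_params(method = "manual",
                                                threshold = 0.5,
                                                min_area_px = 1,
                                                clear_border = FALSE))
  plane <- image_plane(sq * 7, 1000)
  ct <- measure_cells(lab, plane)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$area_px, 100)
  expect_equal(ct$area_um2, 100 * (1000 / 1000)^2)
  expect_equal(ct$ch1_mean, 7)
  expect_equal(ct$ch1_integrated, 700)
  expect_equal(ct$centroid_x_px, 14.5)  # 0-based centroid of cols 11:20
  expect_equal(ct$centroid_y_px, 14.5)
  # digitised disc: circularity high and clamped at 1
  disc <- matrix(0, 64, 64); disc[raster_disc(64, 32, 32, 20)] <- 50
  labd <- segment_nuclei(disc, segmentation_params(method = "manual",
                                                   threshold = 1))
  ctd <- measure_cells(labd, image_plane(disc, 325))
  expect_gte(ctd$circularity, 0.95)
  expect_lte(ctd$circularity, 1)
  expect_error(measure_cells(lab, image_plane(matrix(0, 8, 8), 65)),
               class = "alignment_error")
})

test_that("integrated intensity is conserved and additive over labels", {
  pop <- generate_population(phantom_config(population = list(n_cells = 30)),
                             seed = 22)
  pre <- subtract_background(get_plane(pop$tiles[[1]], "dna"), 25)
  lab <- segment_nuclei(pre)
  ct <- measure_cells(lab, pre)
  expect_equal(nrow(ct), max(lab))
  expect_equal(sum(ct$dna_integrated), sum(pre$pixels[unclass(lab) > 0]))
  # splitting one label in two leaves the summed integral unchanged
  l2 <- unclass(lab)
  one <- which(l2 == 1)
  l2[one[seq_len(length(one) %/% 2)]] <- max(l2) + 1L
  class(l2) <- class(lab); attributes(l2) <- attributes(lab)
  ct2 <- measure_cells(l2, pre)
  expect_equal(sum(ct2$dna_integrated), sum(ct$dna_integrated))
})

test_that("spot detection recovers phantom foci and the large-focus class", {
  cfg <- phantom_config(population = list(n_cells = 200,
                                          large_focus_fraction = 0.15))
  pop <- generate_population(cfg, seed = 23)
  nspots <- 0; spot_tabs <- list()
  for (t in seq_along(pop$tiles)) {
    pre <- subtract_background(get_plane(pop$tiles[[t]], "foci"), 25)
    lab <- segment_nuclei(subtract_background(get_plane(pop$tiles[[t]], "dna"), 25))
    sp <- detect_spots(pre, lab, tile_index = t)
    spot_tabs[[t]] <- sp
    nspots <- nspots + nrow(sp)
  }
  truth_n <- sum(pop$truth$focus_count) + sum(pop$truth$large_focus)
  expect_lt(abs(nspots - truth_n) / truth_n, 0.05)
  # large foci separate from normal foci by area AND mean intensity
  spots <- do.call(rbind, spot_tabs)
  big <- spots$area_px > 60 & spots$foci_mean > 100
  cells <- do.call(rbind, lapply(seq_along(pop$tiles), function(t) {
    lab <- segment_nuclei(subtract_background(get_plane(pop$tiles[[t]], "dna"), 25))
    measure_cells(lab, pop$tiles[[t]], tile_index = t)
  }))
  mi <- match_cells_to_truth(cells, pop$truth)
  # per-cell: does it own a detected large focus?
  has_big <- vapply(seq_len(nrow(cells)), function(i) {
    any(big[spots$tile_index == cells$tile_index[i] &
              spots$parent_cell_id == cells$cell_id[i]])
  }, TRUE)
  truth_big <- pop$truth$large_focus[mi]
  ok <- !is.na(truth_big)
  expect_lt(mean(has_big[ok] & !truth_big[ok]), 0.05)   # false-positive rate
  expect_lt(sum(!has_big[ok] & truth_big[ok]) / max(sum(truth_big[ok]), 1),
            0.05)
  # spot centroid outside every nucleus gets parent 0
  lone <- matrix(0, 64, 64)
  lone <- cytostorm:::.paint_gaussian(lone, 32, 32, 1.5, 5000)
  sp <- detect_spots(image_plane(lone, 325), matrix(0L, 64, 64))
  expect_equal(sp$parent_cell_id, 0L)
})

test_that("measurements are invariant under label renumbering", {
  pop <- generate_population(phantom_config(population = list(n_cells = 20)),
                             seed = 24)
  pre <- subtract_background(get_plane(pop$tiles[[1]], "dna"), 25)
  lab <- segment_nuclei(pre)
  ct <- measure_cells(lab, pre)
  perm <- sample(max(lab))
  l2 <- unclass(lab)
  l2[l2 > 0] <- perm[l2[l2 > 0]]
  class(l2) <- class(lab); attributes(l2) <- attributes(lab)
  ct2 <- measure_cells(l2, pre)
  ord <- order(perm)
  expect_equal(ct2$dna_integrated[perm], ct$dna_integrated)
  expect_equal(ct2$area_px[perm], ct$area_px)
})
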