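test_that("ICCS fractions behave on identical, mixed and independent channels", {
  pts <- generate_two_channel_points(1000, 1000, 0.5, area_um2 = 400,
                                     jitter_nm = 10, seed = 41)
  i1 <- render_points(pts$ch1, pts$truth$side_nm)
  i2 <- render_points(pts$ch2, pts$truth$side_nm)
  # identical channels: f = 1 within fit tolerance
  rid <- compute_iccs(i1, i1)
  expect_equal(rid$f1, 1, tolerance = 0.02)
  expect_equal(rid$f2, 1, tolerance = 0.02)
  # half-colocalized phantom
  r <- compute_iccs(i1, i2)
  expect_equal(r$f1, 0.5, tolerance = 0.1)
  expect_equal(r$f2, 0.5, tolerance = 0.1)
  # independent channels: fractions near zero
  p0 <- generate_two_channel_points(1000, 1000, 0, area_um2 = 400, seed = 42)
  r0 <- compute_iccs(render_points(p0$ch1, p0$truth$side_nm),
                     render_points(p0$ch2, p0$truth$side_nm))
  expect_lte(r0$f1, 0.1)
  expect_lte(r0$f2, 0.1)
  expect_error(compute_iccs(matrix(0, 16, 16), matrix(1, 16, 16)),
               class = "normalization_error")
  expect_error(compute_iccs(matrix(1, 16, 16), matrix(1, 8, 8)),
               class = "validation_error")
})

test_that("single-linkage clustering equals the brute-force oracle", {
  # inclusive threshold at exactly the linking radius
  expect_equal(nrow(cluster_localizations(
    localization_table(c(0, 49), c(0, 0)), 50)), 1)
  expect_equal(nrow(cluster_localizations(
    localization_table(c(0, 51), c(0, 0)), 50)), 2)
  # random instances vs union-find over the full distance matrix
  for (s in 1:10) {
    set.seed(s)
    n <- sample(50:500, 1)
    x <- runif(n, 0, 3000); y <- runif(n, 0, 3000)
    cl <- cluster_localizations(localization_table(x, y), 50)
    expect_true(same_partition(attr(cl, "assignment"),
                               oracle_single_linkage(x, y, 50)))
  }
  # centroid and member count
  cl <- cluster_localizations(localization_table(c(0, 30, 1000),
                                                 c(0, 40, 1000)), 50)
  expect_equal(cl$n, c(2, 1))
  expect_equal(cl$x_nm, c(15, 1000))
  expect_equal(cl$r_gyration_nm[1], 25)   # half the 30-40-50 separation
  # min_points filter
  expect_equal(nrow(cluster_localizations(localization_table(c(0, 30, 1000),
                                                             c(0, 40, 1000)),
                                          50, min_points = 2)), 1)
  expect_equal(nrow(cluster_localizations(
    localization_table(numeric(0), numeric(0)), 50)), 0)
})

test_that("object colocalization matches the greedy oracle and the truth", {
  set.seed(43)
  xa <- runif(100, 0, 4000); ya <- runif(100, 0, 4000)
  xb <- runif(100, 0, 4000); yb <- runif(100, 0, 4000)
  ca <- data.frame(cluster_id = 1:100, x_nm = xa, y_nm = ya)
  cb <- data.frame(cluster_id = 1:100, x_nm = xb, y_nm = yb)
  res <- object_colocalization(ca, cb, 250)
  oracle <- oracle_greedy_match(xa, ya, xb, yb, 250)
  expect_equal(nrow(res$pairs), nrow(oracle))
  expect_equal(sort(res$pairs$id_A), sort(oracle[, 1]))
  expect_equal(res$pairs$id_B[order(res$pairs$id_A)],
               oracle[order(oracle[, 1]), 2])
  # identical well-separated sets: all 1:1
  grid <- expand.grid(x = seq(0, 1800, 200), y = seq(0, 1800, 200))
  cg <- data.frame(cluster_id = seq_len(nrow(grid)), x_nm = grid$x,
                   y_nm = grid$y)
  same <- object_colocalization(cg, cg, 50)
  expect_equal(same$fraction_A, 1)
  expect_equal(same$fraction_B, 1)
  expect_true(all(names(same$stoichiometry_A) == "1"))
  # disjoint far-apart sets
  far <- cb; far$x_nm <- far$x_nm + 1e6
  none <- object_colocalization(ca, far, 250)
  expect_equal(none$fraction_A, 0)
  expect_equal(nrow(none$pairs), 0)
})

test_that("object colocalization recovers the generator's true fraction", {
  for (f in c(0, 0.5, 1)) {
    pts <- generate_two_channel_points(1000, 1000, f, area_um2 = 2500,
                                       jitter_nm = 10, seed = 44 + round(10 * f))
    ca <- cluster_localizations(pts$ch1, 50)
    cb <- cluster_localizations(pts$ch2, 50)
    res <- object_colocalization(ca, cb, 50)
    expect_lt(abs(res$fraction_A - f), 0.05)
    expect_lt(abs(res$fraction_B - f), 0.05)
  }
  # swap symmetry when n1 = n2
  pts <- generate_two_channel_points(600, 600, 0.5, area_um2 = 2500,
                                     jitter_nm = 10, seed = 45)
  ca <- cluster_localizations(pts$ch1, 50)
  cb <- cluster_localizations(pts$ch2, 50)
  ab <- object_colocalization(ca, cb, 50)
  ba <- object_colocalization(cb, ca, 50)
  expect_equal(ab$fraction_A, ba$fraction_B)
  expect_equal(nrow(ab$pairs), nrow(ba$pairs))
})

test_that("confocal masks cover the true structure on the target grid", {
  fl <- phantom_filaments(seed = 46)
  mask <- mask_from_confocal(fl$plane, transform2d("translation", 0, 0),
                             fl$plane)
  expect_gte(mean(mask[fl$truth_mask]), 0.95)
  expect_lte(mean(mask[!fl$truth_mask]), 0.05)
  # uniform bright plane: full mask
  bright <- image_plane(matrix(100, 32, 32), 65)
  mb <- mask_from_confocal(bright, transform2d("translation", 0, 0), bright,
                           threshold = 50)
  expect_true(all(mb))
  # already-binary input with identity transform is idempotent
  bin <- image_plane(matrix(rep(c(0, 1), each = 512), 32), 65)
  m2 <- mask_from_confocal(bin, transform2d("translation", 0, 0), bin,
                           threshold = 0.5, close_radius_px = 0)
  expect_equal(as.vector(m2), as.vector(bin$pixels > 0.5))
})

test_that("distance distributions agree with the all-pairs minimum", {
  # 3-4-5 triangle
  da <- data.frame(cluster_id = 1, x_nm = 0, y_nm = 0)
  db <- data.frame(cluster_id = 1, x_nm = 300, y_nm = 400)
  expect_equal(distance_distribution(da, db), 500)
  set.seed(47)
  ca <- data.frame(cluster_id = 1:200, x_nm = runif(200, 0, 5000),
                   y_nm = runif(200, 0, 5000))
  cb <- data.frame(cluster_id = 1:200, x_nm = runif(200, 0, 5000),
                   y_nm = runif(200, 0, 5000))
  got <- distance_distribution(ca, cb)
  ora <- apply(sqrt(outer(ca$x_nm, cb$x_nm, "-")^2 +
                      outer(ca$y_nm, cb$y_nm, "-")^2), 1, min)
  expect_equal(got, ora)
  expect_error(distance_distribution(ca, cb[0, ]), class = "validation_error")
})

test_that("compartment split labels clusters against a mask", {
  mask <- matrix(FALSE, 100, 100)
  mask[, 1:50] <- TRUE                       # left half on-compartment
  attr(mask, "pixel_size_nm") <- 100
  cl <- data.frame(cluster_id = 1:3,
                   x_nm = c(2000, 7000, 5050), y_nm = c(5000, 5000, 5000))
  sp <- compartment_split(cl, mask)
  expect_equal(sp$on_mask, c(TRUE, FALSE, FALSE))
  # tolerance extends the compartment
  sp2 <- compartment_split(cl, mask, tolerance_nm = 200)
  expect_equal(sp2$on_mask, c(TRUE, FALSE, TRUE))
  # full and empty masks
  full <- matrix(TRUE, 100, 100); attr(full, "pixel_size_nm") <- 100
  expect_true(all(compartment_split(cl, full)$on_mask))
  empty <- matrix(FALSE, 100, 100); attr(empty, "pixel_size_nm") <- 100
  expect_false(any(compartment_split(cl, empty)$on_mask))
  # phantom with known placement: cluster inside mask has distance 0
  expect_equal(distance_distribution(cl[1, ], full), 0)
  # split colocalization reports both compartments
  cb <- cl; cb$x_nm <- cb$x_nm + 30
  both <- coloc_by_compartment(cl, cb, mask, adjacency_nm = 50)
  expect_equal(both$on_mask$n_A, 1)
  expect_equal(both$off_mask$n_A, 2)
})
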