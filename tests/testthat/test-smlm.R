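test_that("localization fitting is exact on a noiseless emitter", {
  px <- 160
  img <- matrix(0, 32, 32)
  img <- cytostorm:::.paint_gaussian(img, 1000 / px - 0.5, 2000 / px - 0.5,
                                     150 / px, 5000)
  locs <- fit_localizations(image_plane(img, px))
  expect_equal(nrow(locs), 1)
  expect_lt(abs(locs$x_nm - 1000), 1)
  expect_lt(abs(locs$y_nm - 2000), 1)
  expect_equal(locs$photons, 5000, tolerance = 1e-3)
  expect_equal(locs$sigma_nm, 150, tolerance = 1e-3)
  # blank frames give an empty table
  blank <- image_stack(list(image_plane(matrix(5, 32, 32), px)))
  expect_equal(nrow(fit_localizations(blank)), 0)
  expect_error(fit_localizations(list()), class = "input_error")
})

test_that("fitting accuracy is consistent with the reported precision", {
  set.seed(11)
  px <- 160
  errs <- prec <- c()
  for (r in 1:200) {
    x0 <- 2000 + runif(1, -80, 80); y0 <- 2000 + runif(1, -80, 80)
    img <- matrix(0, 25, 25)
    img <- cytostorm:::.paint_gaussian(img, x0 / px - 0.5, y0 / px - 0.5,
                                       150 / px, 3000)
    img <- matrix(rpois(625, img + 5), 25, 25)
    l <- fit_localizations(image_plane(img, px))
    if (nrow(l) == 1) {
      errs <- c(errs, (l$x_nm - x0), (l$y_nm - y0))
      prec <- c(prec, l$precision_nm)
    }
  }
  expect_gt(length(prec), 150)
  # per-axis RMSE within 1.5x the mean reported (Thompson) precision
  expect_lte(sqrt(mean(errs^2)), 1.5 * mean(prec))
})

test_that("fiducial tracking recovers injected drift", {
  # static fiducial: zero drift at every anchor
  stat <- localization_table(rep(1000, 5), rep(2000, 5),
                             frame = seq(0, 4000, 1000), channel = "fiducial")
  traj <- track_fiducials(stat)
  expect_equal(traj$dx_nm, rep(0, 5))
  expect_equal(traj$dy_nm, rep(0, 5))

  # linear drift with jitter over the acquisition of record
  cfg <- phantom_config(smlm = list(frames = 15000, cadence_K = 1000,
                                    n_fiducials = 3, fiducial_jitter_nm = 2,
                                    drift = list(model = "linear",
                                                 total_nm = c(100, 50)),
                                    n_emitters = 2))
  mv <- generate_smlm_movie(cfg, seed = 12, emit = "localizations")
  tr <- track_fiducials(mv$fiducial_locs)
  expect_equal(nrow(tr), 16)
  expect_lt(abs(tr$dx_nm[16] - 100), 3)
  expect_lt(abs(tr$dy_nm[16] - 50), 3)

  # equal and opposite placement noise cancels in the mean
  f <- rbind(
    localization_table(c(0, 1000), c(0, 0), frame = 0, channel = "fiducial"),
    localization_table(c(0 + 13, 1000 - 13), c(5, -5), frame = 1000,
                       channel = "fiducial"))
  class(f) <- c("localization_table", "data.frame")
  t2 <- track_fiducials(f)
  expect_equal(t2$dx_nm[2], 0)
  expect_equal(t2$dy_nm[2], 0)
  expect_error(track_fiducials(stat[1, ]), class = "drift_error")
})

test_that("drift correction interpolates, clamps, and inverts exactly", {
  traj <- structure(data.frame(frame = c(0, 1000, 2000),
                               dx_nm = c(0, 10, 40), dy_nm = c(0, -5, 15)),
                    class = c("drift_trajectory", "data.frame"))
  locs <- localization_table(c(100, 100, 100, 100), c(200, 200, 200, 200),
                             frame = c(0, 500, 1000, 1500))
  out <- correct_drift(locs, traj)
  expect_equal(out$x_nm, 100 - c(0, 5, 10, 25))
  expect_equal(out$y_nm, 200 - c(0, -2.5, -5, 5))
  # zero trajectory is the identity
  z <- traj; z$dx_nm <- z$dy_nm <- 0
  expect_equal(correct_drift(locs, z), locs)
  # correction then re-injection is the identity
  re <- out
  re$x_nm <- re$x_nm + approx(traj$frame, traj$dx_nm, locs$frame)$y
  re$y_nm <- re$y_nm + approx(traj$frame, traj$dy_nm, locs$frame)$y
  expect_lt(max(abs(re$x_nm - locs$x_nm)), 1e-9)

  # phantom: post-correction spread of each emitter matches its precision
  cfg <- phantom_config(smlm = list(frames = 6000, cadence_K = 1000,
                                    n_emitters = 4, k_off = 0.3, k_on = 0.05,
                                    fiducial_jitter_nm = 2,
                                    drift = list(model = "linear",
                                                 total_nm = c(120, 80))))
  mv <- generate_smlm_movie(cfg, seed = 13, emit = "localizations")
  corr <- correct_drift(mv$locs, track_fiducials(mv$fiducial_locs))
  for (e in unique(corr$emitter_id)) {
    s <- corr[corr$emitter_id == e, ]
    if (nrow(s) < 50) next
    spread <- sqrt((var(s$x_nm) + var(s$y_nm)) / 2)
    expect_lte(spread, 1.2 * cfg$smlm$loc_precision_nm)
  }
})

test_that("channel shift estimation averages mutual fiducial pairs", {
  set.seed(14)
  f1 <- localization_table(runif(10, 0, 5000), runif(10, 0, 5000),
                           channel = "fiducial")
  expect_equal(unname(c(estimate_channel_shift(f1, f1)$tx_nm,
                        estimate_channel_shift(f1, f1)$ty_nm)), c(0, 0))
  f2 <- f1; f2$x_nm <- f2$x_nm + 12; f2$y_nm <- f2$y_nm - 7
  tf <- estimate_channel_shift(f1, f2)
  expect_equal(c(tf$tx_nm, tf$ty_nm), c(12, -7))
  # with 2 nm jitter on 10 fiducials: within 3 standard errors
  f2j <- f2
  f2j$x_nm <- f2j$x_nm + rnorm(10, 0, 2); f2j$y_nm <- f2j$y_nm + rnorm(10, 0, 2)
  tfj <- estimate_channel_shift(f1, f2j)
  expect_lt(abs(tfj$tx_nm - 12), 3 * 2 / sqrt(10))
  expect_lt(abs(tfj$ty_nm + 7), 3 * 2 / sqrt(10))
  far <- f1; far$x_nm <- far$x_nm + 1e6
  expect_error(estimate_channel_shift(f1, far), class = "alignment_error")
})

test_that("rendering honours canvas size, photon normalization and linearity", {
  locs <- localization_table(c(2000, 10000), c(3000, 20000),
                             photons = c(100, 200), precision_nm = 5)
  img <- render(locs, fov_um = 41, pixel_size_nm = 10)
  expect_equal(dim(img$pixels), c(4100, 4100))
  expect_equal(sum(img$pixels), 300, tolerance = 1e-3)
  # local integrals in the photon ratio
  w1 <- sum(img$pixels[250:350, 150:250])   # around (2000, 3000) nm
  w2 <- sum(img$pixels[1950:2050, 950:1050])
  expect_equal(w2 / w1, 2, tolerance = 1e-3)
  # linearity is exact
  la <- locs[1, , drop = FALSE]; lb <- locs[2, , drop = FALSE]
  class(la) <- class(lb) <- class(locs)
  expect_identical(render(la, 41, 10)$pixels + render(lb, 41, 10)$pixels,
                   img$pixels)
  # out-of-field molecules are skipped and counted
  out <- localization_table(c(2000, 5e6), c(2000, 5e6), photons = 10)
  r2 <- render(out, fov_um = 41, pixel_size_nm = 10)
  expect_equal(attr(r2, "n_skipped"), 1)
  expect_equal(sum(r2$pixels), 10, tolerance = 1e-3)
  # precision mode uses the per-molecule sigma
  rp <- render(locs, 41, 10, sigma_mode = "precision")
  expect_gt(max(rp$pixels), max(img$pixels))  # 5 nm sigma is tighter than 10
})
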