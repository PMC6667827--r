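test_that("pixels_per_feature reproduces the resolution arithmetic and is bilinear", {
  ## a 125 um newborn feature at a 500 PPI contact scanner: ~2.5 px
  expect_equal(pixels_per_feature(125, 500), 2.46, tolerance = 0.002)
  ## a 50 um infant valley at 3400 PPI: ~7 px
  expect_equal(pixels_per_feature(50, 3400), 6.69, tolerance = 0.002)
  ## a 450 um adult ridge at 3400 PPI: ~60 px/ridge
  expect_equal(pixels_per_feature(450, 3400), 60.24, tolerance = 0.005)
  expect_identical(pixels_per_feature(0, 1234), 0)
  ## linear in both arguments
  f <- pixels_per_feature(130, 700)
  expect_equal(pixels_per_feature(3 * 130, 700), 3 * f)
  expect_equal(pixels_per_feature(130, 5 * 700), 5 * f)
  expect_error(pixels_per_feature(-1, 500))
  expect_error(pixels_per_feature(100, 0))
})

test_that("orientation field recovers grating direction with high coherence", {
  r <- cached("grating_pre", render_grating(20, shape = c(160, 160)))
  ## horizontal ridges in the parallel family run along x; rotate the pose
  ## to get a known oblique angle
  om <- orientation_field(r$image)
  fg <- om$valid
  expect_gt(mean(fg), 0.8)
  expect_true(all(angdiff(om$orientations[fg], 0, mod = pi) < 0.03))

  sp <- clean_spec(1, ridge_period_um = 250, curvature_mode = "flat",
                   n_minutiae = 0, flow_family = "parallel")
  r30 <- render_ridge_pattern(sp, 20 * 25400 / 250, c(160, 160),
                              pose = c(30 * pi / 180, 0, 0))
  om30 <- orientation_field(r30$image)
  ok <- om30$valid
  med <- stats::median(om30$orientations[ok])
  expect_lt(angdiff(med, 30 * pi / 180, mod = pi), 2 * pi / 180)

  ## white noise carries no orientation: low coherence, invalid blocks
  set.seed(2)
  noise <- raw_image(matrix(runif(160 * 160, 0, 4095), 160, 160),
                     ppi = 1000, bit_depth = 12)
  omn <- orientation_field(noise)
  expect_lt(stats::median(omn$coherence), 0.2)
  expect_lt(mean(omn$valid), 0.2)
})

test_that("local period finds constructed periods and rejects blank frames", {
  for (p in c(20, 60)) {
    r <- render_grating(p, shape = c(4 * p + 120, 4 * p + 120))
    expect_equal(global_ridge_period(r$image), p,
                 tolerance = (if (p == 20) 0.5 else 1) / p)
  }
  blank <- raw_image(matrix(2000, 128, 128), ppi = 1000, bit_depth = 12)
  expect_error(local_period(blank), class = "infantprint_unprocessable")

  ## cylindrical phantom: centre blocks have longer periods than edge blocks
  r <- cached("cyl_proj", {
    sp <- clean_spec(11, ridge_period_um = 275, n_minutiae = 12)
    flat <- render_ridge_pattern(sp, 1500,
                                 c(301L, 2L * as.integer(ceiling(pi * 122)) + 9L))
    project_cylinder(flat)
  })
  lp <- local_period(r$image, profile_len = 48L)
  cxo <- r$truth$cylinder$center_col
  bs <- lp$block_size
  xc <- (seq_len(ncol(lp$periods)) - 1) * bs + (bs - 1) / 2
  centre_cols <- abs(xc - cxo) < 0.3 * r$truth$cylinder$radius_px
  edge_cols <- abs(xc - cxo) > 0.75 * r$truth$cylinder$radius_px
  pc <- lp$periods[, centre_cols]; pe <- lp$periods[, edge_cols]
  expect_gt(stats::median(pc, na.rm = TRUE), stats::median(pe, na.rm = TRUE))
})

test_that("frequency normalization lands on 8 px/ridge from any starting period", {
  ## 20 px/ridge raw (newborn-like) resamples by 0.4 to 8 +/- 0.5
  r20 <- cached("grating20_norm", render_grating(20, shape = c(220, 220)))
  n20 <- normalize_ridge_frequency(r20$image)
  expect_equal(n20$scale, 8 / n20$original_period, tolerance = 1e-9)
  expect_equal(n20$original_period, 20, tolerance = 0.025)
  expect_equal(n20$measured_period, 8, tolerance = 0.5 / 8)

  ## an image already at 8 px/ridge passes through unchanged
  r8 <- render_grating(8, shape = c(96, 96))
  n8 <- normalize_ridge_frequency(r8$image)
  expect_equal(n8$scale, 1, tolerance = 0.06)

  ## adult 450 um at 3400 PPI (~60 px/ridge) also lands on 8 +/- 0.5
  r60 <- cached("grating60_norm", render_grating(60, shape = c(400, 400)))
  n60 <- normalize_ridge_frequency(r60$image)
  expect_equal(n60$measured_period, 8, tolerance = 0.5 / 8)
})

test_that("normalization is scale-equivariant and removes age/size differences", {
  ## adult/newborn convergence: 125 um and 450 um phantoms meet at 8 px
  periods <- vapply(c(125, 450), function(um) {
    sp <- clean_spec(9, ridge_period_um = um, curvature_mode = "flat",
                     n_minutiae = 6)
    lam <- pixels_per_feature(um, 3400)
    shp <- as.integer(ceiling(max(200, 6 * lam)))
    r <- render_ridge_pattern(sp, 3400, c(shp, shp), refine_truth = FALSE)
    normalize_ridge_frequency(r$image)$measured_period
  }, numeric(1))
  expect_true(all(abs(periods - 8) <= 0.5))

  ## resampling the input by s in [0.5, 2] leaves the normalized period
  ## within 3%
  r <- cached("grating20_norm", render_grating(20, shape = c(220, 220)))
  base <- normalize_ridge_frequency(r$image)$measured_period
  for (s in c(0.5, 1.6)) {
    px <- t(as.matrix(EBImage::resize(t(r$image$pixels),
                                      w = round(220 * s), h = round(220 * s),
                                      filter = "bilinear")))
    img <- raw_image(clip_dn(px, 4095), ppi = r$image$ppi * s, bit_depth = 12)
    m <- normalize_ridge_frequency(img)$measured_period
    expect_equal(m, base, tolerance = 0.03, label = sprintf("scale %g", s))
  }
})
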