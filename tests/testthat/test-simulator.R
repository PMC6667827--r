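test_that("flat renders hit the analytic ridge period across PPIs", {
  ## 250 um at 3400 PPI is 33.46 px; spectral measurement must agree
  r <- cached("grating_33", {
    sp <- clean_spec(42, ridge_period_um = 250, curvature_mode = "flat",
                     n_minutiae = 0, flow_family = "parallel")
    render_ridge_pattern(sp, 3400, c(300, 300))
  })
  expect_equal(r$truth$lambda_px, 250 * 3400 / 25400, tolerance = 1e-12)
  expect_equal(global_ridge_period(r$image), 33.46, tolerance = 0.5 / 33.46)

  for (case in list(c(125, 1500), c(250, 500), c(450, 3400))) {
    lam <- case[1] * case[2] / 25400
    sp <- clean_spec(3, ridge_period_um = case[1], curvature_mode = "flat",
                     n_minutiae = 0, flow_family = "parallel")
    shp <- max(220L, as.integer(ceiling(6 * lam)))
    r2 <- render_ridge_pattern(sp, case[2], c(shp, shp))
    expect_equal(global_ridge_period(r2$image), lam, tolerance = 0.02,
                 label = sprintf("period %g um at %g PPI", case[1], case[2]))
  }
})

test_that("valley width follows the duty cycle and a defect-free grating has no minutiae", {
  sp <- clean_spec(7, ridge_period_um = 250, duty_cycle = 0.8,
                   curvature_mode = "flat", n_minutiae = 0,
                   flow_family = "parallel")
  ## 0.8 duty on a 250 um period leaves a 50 um valley
  expect_equal((1 - sp$duty_cycle) * sp$ridge_period_um, 50)
  r <- render_ridge_pattern(sp, 3400, c(280, 280))
  ## ridge fraction of the ideal binarized pattern equals the duty cycle
  binary <- r$image$pixels >= (DN_LO + DN_SPAN / 2) * r$image$max_dn
  expect_equal(mean(binary), 0.8, tolerance = 0.02)
  ## no interior minutiae in the thinned defect-free grating
  cn <- crossing_number_map(skeletonize(binary))
  interior <- cn[20:(nrow(cn) - 20), 20:(ncol(cn) - 20)]
  expect_equal(sum(interior == 1 | interior == 3), 0)
})

test_that("rendering rejects rasters smaller than one ridge period", {
  sp <- clean_spec(1, ridge_period_um = 450, curvature_mode = "flat")
  expect_error(render_ridge_pattern(sp, 3400, c(40, 40)), "period")
})

test_that("cylindrical projection foreshortens by cos(theta) and clips the silhouette", {
  r <- cached("cyl_proj", {
    sp <- clean_spec(11, ridge_period_um = 275, n_minutiae = 12)
    flat <- render_ridge_pattern(sp, 1500,
                                 c(301L, 2L * as.integer(ceiling(pi * 122)) + 9L))
    project_cylinder(flat)
  })
  R <- r$truth$cylinder$radius_px
  cxo <- r$truth$cylinder$center_col
  pm <- r$truth$period_map
  bs <- r$truth$period_block
  xc <- seq(1, ncol(r$image$pixels), by = bs) + (bs - 1) / 2 - 1
  ## centre block: apparent period equals the flat period
  centre <- which.min(abs(xc - cxo))
  expect_equal(pm[1, centre], r$truth$lambda_px, tolerance = 0.01)
  ## offset where sin(theta) = 0.5: period shrinks by cos(asin(0.5)) = 0.866
  half <- which.min(abs(xc - (cxo + 0.5 * R)))
  expect_equal(pm[1, half] / r$truth$lambda_px, cos(asin(0.5)),
               tolerance = 0.02)
  ## analytic oracle at every retained block centre: lambda * cos(theta)
  ok <- !is.na(pm[1, ])
  st <- pmin(1, abs(xc[ok] - cxo) / R)
  expect_equal(pm[1, ok], r$truth$lambda_px * cos(asin(st)),
               tolerance = 0.03)
  ## monotone foreshortening away from the axis
  right <- pm[1, xc >= cxo & !is.na(pm[1, ])]
  expect_true(all(diff(right) <= 1e-9))
  ## every remapped minutia stays inside the mask
  gm <- r$truth$minutiae
  idx <- cbind(round(gm$y) + 1, round(gm$x) + 1)
  expect_true(all(r$truth$mask[idx]))
})

test_that("artifact stack saturates halos, is seed-deterministic and identity at zero strength", {
  sp0 <- clean_spec(5, ridge_period_um = 275)
  r0 <- cached("flat_for_artifacts",
               render_ridge_pattern(sp0, 1500, c(200, 200),
                                    refine_truth = FALSE))
  ## identity configuration: all artifact strengths zero
  out0 <- apply_artifacts(r0, seed = 9)
  expect_identical(out0$image$pixels, r0$image$pixels)

  sp2 <- phantom_spec(5, "infant", halo_strength = 2, peeling_fraction = 0,
                      noise_sigma_dn = 0, blur_px = 0, illum_gradient = 0,
                      ridge_period_um = 275)
  r2 <- r0; r2$spec <- sp2
  out2 <- apply_artifacts(r2, seed = 9)
  core <- out2$truth$artifacts$halo$core_cols
  expect_gt(length(core), 0)
  expect_true(all(out2$image$pixels[, core + 1] == out2$image$max_dn))

  ## determinism: same spec and seed give bit-identical rasters; a
  ## different seed moves the noise field
  spn <- phantom_spec(5, "infant", ridge_period_um = 275)
  rn <- r0; rn$spec <- spn
  a <- apply_artifacts(rn, seed = 4)
  b <- apply_artifacts(rn, seed = 4)
  c <- apply_artifacts(rn, seed = 5)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_false(identical(a$image$pixels, c$image$pixels))

  ## peeling flakes cover roughly the requested fraction and are recorded
  spp <- phantom_spec(5, "infant", peeling_fraction = 0.2,
                      noise_sigma_dn = 0, blur_px = 0, halo_strength = 0,
                      illum_gradient = 0, ridge_period_um = 275)
  rp <- r0; rp$spec <- spp
  outp <- apply_artifacts(rp, seed = 3)
  expect_gte(mean(outp$truth$artifacts$flake_mask), 0.2 * 0.95)
})

test_that("out-of-range artifact parameters are clamped with a warning", {
  sp <- clean_spec(5, ridge_period_um = 275)
  sp$blur_px <- -3
  r0 <- cached("flat_for_artifacts",
               render_ridge_pattern(sp, 1500, c(200, 200),
                                    refine_truth = FALSE))
  r0$spec <- sp
  expect_warning(apply_artifacts(r0, seed = 1), "clamped")
})

test_that("ground-truth minutiae lie on ridges and growth pairs share identity", {
  r <- cached("clean_truth_render", {
    sp <- clean_spec(21, ridge_period_um = 300, curvature_mode = "flat",
                     n_minutiae = 10)
    render_ridge_pattern(sp, 1500, c(400, 400))
  })
  gt <- r$truth$minutiae
  expect_gt(nrow(gt), 0)
  ## every refined ground-truth minutia sits in the ridge band of the
  ## noiseless render (on or next to a ridge)
  on_ridge <- vapply(seq_len(nrow(gt)), function(i) {
    ys <- max(1, round(gt$y[i])):min(nrow(r$image$pixels), round(gt$y[i]) + 2)
    xs <- max(1, round(gt$x[i])):min(ncol(r$image$pixels), round(gt$x[i]) + 2)
    max(r$image$pixels[ys, xs]) > (DN_LO + 0.5 * DN_SPAN) * r$image$max_dn
  }, logical(1))
  expect_true(all(on_ridge))

  gp <- cached("growth_pair_2x", {
    sp <- clean_spec(13, ridge_period_um = 150, finger_diameter_mm = 5,
                     n_minutiae = 8)
    growth_pair(sp, 2, seeds = c(31, 32), ppi = 2000, artifacts = FALSE)
  })
  ## same identity topology: equal seeded minutiae counts
  expect_equal(nrow(gp[[1]]$truth$minutiae), nrow(gp[[2]]$truth$minutiae))
  ## dominant period doubles with the growth scale
  p1 <- global_ridge_period(gp[[1]]$image)
  p2 <- global_ridge_period(gp[[2]]$image)
  expect_equal(p2 / p1, 2, tolerance = 0.03)
  ## growth beyond the valid period range is rejected
  expect_error(growth_pair(clean_spec(1, ridge_period_um = 400), 2,
                           c(1, 2), 1500), "600")
})

test_that("renders are reproducible from the seed alone", {
  sp <- phantom_spec(77, "infant")
  a <- render_finger(sp, ppi = 1200, seed = 5)
  b <- render_finger(sp, ppi = 1200, seed = 5)
  expect_identical(a$image$pixels, b$image$pixels)
  d <- render_finger(sp, ppi = 1200, seed = 6)
  expect_false(identical(a$image$pixels, d$image$pixels))
})
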