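test_that("flat-field correction removes a known vignette and preserves uniform gain", {
  r <- cached("grating_pre", render_grating(20, shape = c(160, 160)))
  pat <- r$image$pixels
  ## uniform gain: output equals input up to renormalization
  out_u <- flat_field_correct(r$image, matrix(0.7, 160, 160))
  expect_equal(out_u$pixels, pat, tolerance = 1e-9)

  ## image = pattern x vignette, gain = vignette -> recover the pattern
  xs <- matrix(rep(seq(-1, 1, length.out = 160), each = 160), 160, 160)
  ys <- matrix(rep(seq(-1, 1, length.out = 160), 160), 160, 160)
  vig <- 1 - 0.4 * (xs^2 + ys^2)
  dimmed <- raw_image(clip_dn(pat * vig, 4095), ppi = r$image$ppi,
                      bit_depth = 12, mask = r$image$mask)
  ## correction recovers the pattern up to the documented foreground-mean
  ## renormalization (overall exposure of the input is preserved)
  out <- flat_field_correct(dimmed, vig)
  scale <- mean(out$pixels) / mean(pat)
  expect_lt(max(abs(out$pixels - pat * scale)), 1 + 1e-6)   # within 1 DN

  ## non-positive gain inside the mask: pixel leaves the mask with a warning
  bad <- matrix(1, 160, 160); bad[80, 80] <- 0
  expect_warning(out_b <- flat_field_correct(r$image, bad), "mask")
  expect_false(out_b$mask[80, 80])
})

test_that("background smoothing removes slow gradients but keeps the ridge band", {
  n <- 256
  t <- seq_len(n)
  ridge <- outer(rep(1, n), 800 * sin(2 * pi * t / 33))
  ramp <- outer(rep(1, n), seq(0, 1500, length.out = n))
  img <- raw_image(clip_dn(1200 + ridge + ramp, 4095), ppi = 3400,
                   bit_depth = 12)
  out <- smooth_background(img, 24)
  ## spectral oracle on the central row, restricted to the interior
  ## (> 3 sigma from the edges, where Gaussian cancellation is exact)
  row_amp <- function(px) {
    v <- px[n / 2, 80:(n - 80)]
    sp <- Mod(stats::fft(v - mean(v)))
    k <- round(length(v) / 33) + 1
    sp[k]
  }
  ## ramp oracle: regress out the (kept) ridge sine, then compare the
  ## fitted linear slope before/after — otherwise the sine aliases into
  ## the slope of the short window
  ramp_amp <- function(px) {
    idx <- 80:(n - 80)
    v <- px[n / 2, idx]
    s <- sin(2 * pi * idx / 33); cc <- cos(2 * pi * idx / 33)
    unname(stats::coef(stats::lm(v ~ idx + s + cc))["idx"])
  }
  expect_gt(row_amp(out$pixels) / row_amp(img$pixels), 0.9)
  expect_lt(abs(ramp_amp(out$pixels) / ramp_amp(img$pixels)), 0.05)

  ## constant image maps to constant mid-scale
  flat <- raw_image(matrix(900, 64, 64), ppi = 500, bit_depth = 12)
  outf <- smooth_background(flat, 10)
  expect_true(all(abs(outf$pixels - 4095 / 2) < 1))

  ## degenerate radius warns; radius beyond the raster errors
  expect_warning(smooth_background(img, 1), "radius")
  expect_error(smooth_background(flat, 1000), "extent")
})

test_that("bimodal stretch maps floor to 0 and the upper percentile to 255", {
  ## synthetic bimodal histogram: background mode 300 DN, ridge mode 2500 DN
  set.seed(4)
  px <- matrix(c(rnorm(6000, 300, 40), rnorm(6000, 2500, 80)), 120, 100)
  img <- raw_image(clip_dn(px, 4095), ppi = 3400, bit_depth = 12)
  out <- bimodal_stretch(img, 64, 99.5)
  expect_identical(out$bit_depth, 8L)
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  ## oracle: apply the stated affine map directly
  hi <- stats::quantile(px, 0.995, names = FALSE)
  mapped <- round(clip_dn((px - 64) / (hi - 64) * 255, 255))
  expect_equal(out$pixels, mapped)
  ## the two modes land near the ends of the 8-bit range
  lo_mode <- out$pixels[px < 1000]; hi_mode <- out$pixels[px > 1500]
  expect_true(mean(lo_mode >= 0 & lo_mode <= 30) > 0.95)
  expect_true(mean(hi_mode >= 225) > 0.95)

  ## all pixels at or below the floor: nothing to stretch, loud refusal
  dark <- raw_image(matrix(c(10, 20, 64, 30), 2, 2), ppi = 500, bit_depth = 12)
  expect_error(bimodal_stretch(dark, 64, 100), "floor")

  ## degenerate histogram is rejected
  const <- raw_image(matrix(1000, 8, 8), ppi = 500, bit_depth = 12)
  expect_error(bimodal_stretch(const), "degenerate")
})

test_that("stretch preserves intensity order and is stable when re-applied", {
  set.seed(11)
  px <- matrix(runif(4000, 0, 4000), 80, 50)
  img <- raw_image(px, ppi = 3400, bit_depth = 12)
  out <- bimodal_stretch(img, 64, 99.5)
  ## monotone on unclipped pixels
  hi <- stats::quantile(px, 0.995, names = FALSE)
  un <- px > 64 & px < hi
  o <- order(px[un])
  expect_true(all(diff(out$pixels[un][o]) >= 0))
  ## idempotent-safe: re-stretching the 8-bit image with rescaled floor
  again <- bimodal_stretch(out, 0, 99.5)
  expect_lt(max(abs(again$pixels - out$pixels)), 1 + 1e-9)
})

test_that("foreground segmentation keeps the modulated finger and drops flat background", {
  sp <- clean_spec(3, curvature_mode = "flat", n_minutiae = 8)
  r <- render_finger(sp, ppi = 1500, seed = 5, artifacts = FALSE)
  h <- nrow(r$image$pixels); w <- ncol(r$image$pixels)
  ## embed the finger in a dark flat canvas and segment without a mask
  big <- matrix(20, h + 160, w + 160)
  big[81:(80 + h), 81:(80 + w)] <- r$image$pixels
  bi <- raw_image(big, ppi = 1500, bit_depth = 12)
  m <- segment_foreground(bi)
  inset <- matrix(FALSE, h + 160, w + 160)
  inset[81:(80 + h), 81:(80 + w)] <- TRUE
  expect_gt(mean(m[inset]), 0.9)          # the finger survives
  expect_lt(mean(m[!inset]), 0.3)         # most background is dropped
  ## a fully covered field stays entirely foreground
  g <- render_grating(20, shape = c(160, 160))
  expect_true(all(segment_foreground(g$image)))
  ## preprocess_image adopts the recovered mask for maskless frames
  pp <- preprocess_image(bi)
  expect_false(is.null(pp$mask))
  expect_lt(mean(pp$mask[!inset]), 0.3)
})
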