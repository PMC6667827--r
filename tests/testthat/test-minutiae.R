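test_that("skeletonization thins ribbons to 1-px centrelines and is idempotent", {
  ## 3-px-wide straight stripe -> single centreline
  stripe <- matrix(0L, 20, 30)
  stripe[9:11, 3:28] <- 1L
  sk <- skeletonize(stripe)
  mid <- sk[, 8:24]
  expect_true(all(colSums(mid) == 1))
  ## no 2x2 foreground block anywhere
  has22 <- function(m)
    any(m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] & m[-nrow(m), -1] & m[-1, -1])
  expect_false(has22(sk))
  expect_identical(skeletonize(sk), sk)

  ## Y-shaped ribbon -> exactly one branch point
  y <- matrix(0L, 40, 40)
  for (t in 0:18) {
    y[20, 2 + t] <- 1L                       # stem along x
    y[20 - round(t * 0.6), 20 + t] <- 1L     # upper arm
    y[20 + round(t * 0.6), 20 + t] <- 1L     # lower arm
  }
  yd <- EBImage::dilate(y, EBImage::makeBrush(3, "box"))
  sky <- skeletonize(as.matrix(yd))
  cny <- crossing_number_map(sky)
  expect_equal(sum(cny == 3), 1)
  expect_false(has22(sky))
})

test_that("crossing-number bookkeeping is internally consistent on phantom skeletons", {
  r <- cached("clean_norm_phantom", {
    sp <- clean_spec(6, ridge_period_um = 275, curvature_mode = "flat",
                     n_minutiae = 12)
    rr <- render_finger(sp, ppi = 1500, seed = 61, artifacts = FALSE)
    norm <- normalize_ridge_frequency(preprocess_image(rr$image))
    list(render = rr, norm = norm, eb = enhance_and_binarize(norm$image))
  })
  sk <- skeletonize(r$eb$binary)
  cn <- crossing_number_map(sk)
  ## every skeleton pixel classifies into exactly one CN bucket, and the
  ## ending/bifurcation counts match an independent per-pixel recount
  recount <- c(0L, 0L)
  np <- which(sk == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(np))) {
    y <- np[i, 1]; x <- np[i, 2]
    if (y < 2 || x < 2 || y > nrow(sk) - 1 || x > ncol(sk) - 1) next
    ring <- c(sk[y - 1, x], sk[y - 1, x + 1], sk[y, x + 1], sk[y + 1, x + 1],
              sk[y + 1, x], sk[y + 1, x - 1], sk[y, x - 1], sk[y - 1, x - 1])
    v <- sum(ring == 0L & c(ring[-1], ring[1]) == 1L)
    if (v == 1) recount[1] <- recount[1] + 1L
    if (v == 3) recount[2] <- recount[2] + 1L
  }
  inner <- cn[2:(nrow(cn) - 1), 2:(ncol(cn) - 1)]
  expect_identical(sum(inner == 1L), recount[1])
  expect_identical(sum(inner == 3L), recount[2])
})

test_that("binarization preserves the generative duty cycle and rejects bad input", {
  r <- cached("clean_norm_phantom", {
    sp <- clean_spec(6, ridge_period_um = 275, curvature_mode = "flat",
                     n_minutiae = 12)
    rr <- render_finger(sp, ppi = 1500, seed = 61, artifacts = FALSE)
    norm <- normalize_ridge_frequency(preprocess_image(rr$image))
    list(render = rr, norm = norm, eb = enhance_and_binarize(norm$image))
  })
  duty <- mean(r$eb$binary[r$eb$mask])
  expect_lt(abs(duty - 0.8), 0.15)

  ## blank frame: no dominant ridge band
  blank <- raw_image(matrix(128, 128, 128), ppi = 500, bit_depth = 8,
                     max_dn = 255)
  expect_error(enhance_and_binarize(blank), "band")

  ## unnormalized input is turned away with instructions
  r20 <- cached("grating20_norm", render_grating(20, shape = c(220, 220)))
  expect_error(enhance_and_binarize(r20$image), "normalize")
})

test_that("incoherent regions are excluded from the quality mask", {
  ## structureless (noise) patches have no coherent orientation and no
  ## ridge band: their blocks must be dropped from the quality mask.
  ## (Peeling flakes that keep the ridge period are locally valid ridge
  ## patterns and are deliberately NOT excluded; see enhance_and_binarize.)
  r <- cached("clean_norm_phantom", {
    sp <- clean_spec(6, ridge_period_um = 275, curvature_mode = "flat",
                     n_minutiae = 12)
    rr <- render_finger(sp, ppi = 1500, seed = 61, artifacts = FALSE)
    norm <- normalize_ridge_frequency(preprocess_image(rr$image))
    list(render = rr, norm = norm, eb = enhance_and_binarize(norm$image))
  })
  img <- r$norm$image
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  patch <- matrix(FALSE, h, w)
  py <- seq(round(h * 0.3), round(h * 0.55))
  px_ <- seq(round(w * 0.3), round(w * 0.55))
  patch[py, px_] <- TRUE
  noisy <- img
  noisy$pixels[patch] <- with_seed(4, stats::runif(sum(patch), 0, img$max_dn))
  eb <- enhance_and_binarize(noisy)
  base <- img_mask(img)
  excl_in <- mean(!eb$mask[patch & base])
  excl_out <- mean(!eb$mask[!patch & base])
  expect_gt(excl_in, 0.5)
  expect_gt(excl_in, 2 * excl_out)
})

test_that("extraction classifies constructed endings and bifurcations with border filtering", {
  ## single straight skeleton segment: two endings, but only when clear of
  ## the mask border
  seg <- matrix(0L, 40, 60)
  seg[20, 15:45] <- 1L
  open_mask <- matrix(TRUE, 40, 60)
  tpl <- extract_minutiae(seg, open_mask, spur_px = 2, border_px = 8)
  expect_equal(nrow(tpl$minutiae), 2)
  expect_true(all(tpl$minutiae$type == "ending"))
  ## endings point along the ridge away from the termination
  left <- tpl$minutiae[which.min(tpl$minutiae$x), ]
  expect_lt(angdiff(left$angle, 0), pi / 6)
  ## a tight mask puts the endpoints within 8 px of the border: filtered out
  tight <- matrix(FALSE, 40, 60)
  tight[12:28, 12:48] <- TRUE
  tpl2 <- extract_minutiae(seg, tight, spur_px = 2, border_px = 8)
  expect_equal(nrow(tpl2$minutiae), 0)

  ## constructed interior Y-shape: exactly one bifurcation
  y <- matrix(0L, 48, 48)
  y[24, 4:24] <- 1L
  for (t in 1:18) {
    y[24 - t, 24 + t] <- 1L
    y[24 + t, 24 + t] <- 1L
  }
  tply <- extract_minutiae(y, matrix(TRUE, 48, 48), spur_px = 2,
                           border_px = 2, min_sep_px = 1)
  expect_equal(sum(tply$minutiae$type == "bifurcation"), 1)

  ## empty skeleton: a valid, empty template
  tple <- extract_minutiae(matrix(0L, 30, 30))
  expect_equal(nrow(tple$minutiae), 0)
})

test_that("no two template minutiae are closer than the separation floor", {
  r <- cached("clean_norm_phantom", {
    sp <- clean_spec(6, ridge_period_um = 275, curvature_mode = "flat",
                     n_minutiae = 12)
    rr <- render_finger(sp, ppi = 1500, seed = 61, artifacts = FALSE)
    norm <- normalize_ridge_frequency(preprocess_image(rr$image))
    list(render = rr, norm = norm, eb = enhance_and_binarize(norm$image))
  })
  tpl <- image_to_template(r$norm$image)
  m <- tpl$minutiae
  if (nrow(m) > 1) {
    d <- stats::dist(m[, c("x", "y")])
    expect_gte(min(d), 4)
  }
  expect_true(all(m$x >= 0 & m$x < tpl$image_shape[2]))
  expect_true(all(m$y >= 0 & m$y < tpl$image_shape[1]))
  expect_true(all(m$quality >= 0 & m$quality <= 1))
})

test_that("recovered minutiae rotate with the phantom", {
  sp <- clean_spec(17, ridge_period_um = 275, curvature_mode = "flat",
                   n_minutiae = 10)
  lam <- pixels_per_feature(275, 1500)
  r0 <- render_ridge_pattern(sp, 1500, c(321, 321), pose = c(0, 0, 0),
                             refine_truth = FALSE)
  r90 <- render_ridge_pattern(sp, 1500, c(321, 321), pose = c(pi / 2, 0, 0),
                              refine_truth = FALSE)
  t0 <- image_to_template(normalize_ridge_frequency(preprocess_image(r0$image))$image)
  t90 <- image_to_template(normalize_ridge_frequency(preprocess_image(r90$image))$image)
  ## rotating the phantom 90 deg maps (x, y) -> (c - y, x - c'); check via
  ## the matcher transform, which must recover ~90 deg of rotation
  m <- match_templates(t0, t90, max_rotation = pi)
  expect_gt(nrow(m$paired_minutiae), 4)
  expect_lt(abs(abs(m$transform["rotation"]) - pi / 2), 5 * pi / 180)
})

test_that("templates round-trip bit-exactly through JSON", {
  r <- cached("clean_norm_phantom", {
    sp <- clean_spec(6, ridge_period_um = 275, curvature_mode = "flat",
                     n_minutiae = 12)
    rr <- render_finger(sp, ppi = 1500, seed = 61, artifacts = FALSE)
    norm <- normalize_ridge_frequency(preprocess_image(rr$image))
    list(render = rr, norm = norm, eb = enhance_and_binarize(norm$image))
  })
  tpl <- image_to_template(r$norm$image)
  path <- tempfile(fileext = ".json")
  write_template(tpl, path)
  back <- read_template(path)
  expect_identical(back$minutiae$x, tpl$minutiae$x)
  expect_identical(back$minutiae$y, tpl$minutiae$y)
  expect_identical(back$minutiae$angle, tpl$minutiae$angle)
  expect_identical(back$minutiae$type, tpl$minutiae$type)
  expect_identical(back$resolution, tpl$resolution)
  ## writing the reread template reproduces the same file
  path2 <- tempfile(fileext = ".json")
  write_template(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
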