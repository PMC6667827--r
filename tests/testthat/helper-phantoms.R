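## shared fixtures: rendered phantoms are expensive, so they are built once
## per session and cached by key

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## artifact-free spec for detector-fidelity tests
clean_spec <- function(seed, ...) {
  phantom_spec(seed, "infant", peeling_fraction = 0, noise_sigma_dn = 0,
               blur_px = 0, halo_strength = 0, illum_gradient = 0, ...)
}

## flat parallel grating with an exact period in pixels
render_grating <- function(period_px, shape = c(256, 256), n_minutiae = 0) {
  ppi <- period_px * 25400 / 250
  sp <- clean_spec(1, ridge_period_um = 250, curvature_mode = "flat",
                   n_minutiae = n_minutiae, flow_family = "parallel")
  render_ridge_pattern(sp, ppi, shape, refine_truth = n_minutiae > 0)
}

## count ground-truth minutiae recovered by a template (8 px / 30 deg)
count_recovered <- function(tpl, gt, scale = 1, dist_tol = 8,
                            angle_tol = pi / 6) {
  m <- tpl$minutiae
  hits <- 0L
  used <- rep(FALSE, max(1L, nrow(m)))
  for (i in seq_len(nrow(gt))) {
    if (is.na(gt$angle[i])) next
    d <- sqrt((m$x - gt$x[i] * scale)^2 + (m$y - gt$y[i] * scale)^2)
    a <- pmin(abs(m$angle - gt$angle[i]) %% (2 * pi),
              2 * pi - abs(m$angle - gt$angle[i]) %% (2 * pi))
    ok <- which(d <= dist_tol & a <= angle_tol & !used)
    if (length(ok)) {
      hits <- hits + 1L
      used[ok[which.min(d[ok])]] <- TRUE
    }
  }
  list(known = sum(!is.na(gt$angle)), recovered = hits,
       spurious = sum(!used))
}

## brute-force DET oracle: enumerate every observed threshold and count
brute_force_det <- function(genuine, impostor) {
  thr <- sort(unique(c(genuine, impostor)))
  data.frame(
    threshold = thr,
    far = vapply(thr, function(t) sum(impostor >= t) / length(impostor),
                 numeric(1)),
    frr = vapply(thr, function(t) sum(genuine < t) / length(genuine),
                 numeric(1)))
}
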