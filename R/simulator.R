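#' Generative parameters of one synthetic finger identity
#'
#' A phantom spec fixes everything that defines a synthetic finger: its ridge
#' geometry (period, duty cycle), size and curvature, and the acquisition
#' artifact levels. Age-class presets follow the morphometry of infant
#' friction-ridge skin: newborn ridge periods are around 125-150 um versus
#' roughly 450 um in adults, and infant ridges are typically 4-5x wider than
#' their valleys (duty cycle ~0.8), so a 250 um period leaves only a 50 um
#' valley to resolve.
#'
#' @param identity_seed Integer; fixes the flow-field family and the seeded
#'   minutiae constellation. Two specs with the same identity_seed describe
#'   the same finger.
#' @param age_class One of `"newborn"`, `"neonate"`, `"infant"`, `"adult"`.
#' @param ridge_period_um Ridge-to-ridge distance in micrometres (100-600).
#'   Defaults to the age-class preset midpoint.
#' @param duty_cycle Fraction of the period occupied by the ridge, in (0, 1).
#'   Preset 0.8 for all infant classes, 0.5 for adults.
#' @param finger_diameter_mm Finger diameter in mm (5-10 for infant classes).
#' @param curvature_mode `"flat"` or `"cylindrical"`.
#' @param halo_strength Specular halo amplitude relative to the saturation
#'   value; >= 1 saturates the halo core. The default 0.3 reflects an
#'   acquisition geometry engineered to reject specular reflections; raise
#'   it to emulate the saturated-halo failure mode of naive illumination.
#' @param peeling_fraction Fraction of the foreground occluded by peeling
#'   skin flakes, in [0, 1).
#' @param noise_sigma_dn Additive sensor noise sigma in DN (12-bit scale).
#' @param blur_px Linear motion-blur extent in pixels.
#' @param illum_gradient Relative amplitude of the low-frequency illumination
#'   gradient (0 disables it).
#' @param n_minutiae Number of seeded ridge endings/bifurcations (default
#'   24, a typical density for the central region of a print).
#' @param flow_family Ridge-flow family: `"auto"` (seeded choice among arch,
#'   loop, whorl), or one of `"arch"`, `"loop"`, `"whorl"`, `"parallel"`
#'   (straight grating, used for calibration). All families are distance
#'   functions, so the local ridge period equals `ridge_period_um`
#'   everywhere.
#' @return A `finger_phantom_spec` object.
#' @export
phantom_spec <- function(identity_seed,
                         age_class = c("infant", "newborn", "neonate", "adult"),
                         ridge_period_um = NULL,
                         duty_cycle = NULL,
                         finger_diameter_mm = NULL,
                         curvature_mode = c("cylindrical", "flat"),
                         halo_strength = 0.3,
                         peeling_fraction = NULL,
                         noise_sigma_dn = 30,
                         blur_px = 2,
                         illum_gradient = 0.25,
                         n_minutiae = 24,
                         flow_family = c("auto", "arch", "loop", "whorl",
                                         "parallel")) {
  age_class <- match.arg(age_class)
  curvature_mode <- match.arg(curvature_mode)
  flow_family <- match.arg(flow_family)
  preset <- switch(age_class,
    newborn = list(period = 137.5, duty = 0.8, diam = 5.5, peel = 0.15),
    neonate = list(period = 200,   duty = 0.8, diam = 6.5, peel = 0.10),
    infant  = list(period = 275,   duty = 0.8, diam = 8,   peel = 0.05),
    adult   = list(period = 450,   duty = 0.5, diam = 12,  peel = 0))
  if (is.null(ridge_period_um)) ridge_period_um <- preset$period
  if (is.null(duty_cycle)) duty_cycle <- preset$duty
  if (is.null(finger_diameter_mm)) finger_diameter_mm <- preset$diam
  if (is.null(peeling_fraction)) peeling_fraction <- preset$peel
  if (ridge_period_um < 100 || ridge_period_um > 600)
    stop("ridge_period_um must lie in [100, 600]")
  if (duty_cycle <= 0 || duty_cycle >= 1)
    stop("duty_cycle must lie in (0, 1)")
  if (age_class != "adult" &&
      (finger_diameter_mm < 5 || finger_diameter_mm > 10))
    stop("finger_diameter_mm must lie in [5, 10] for infant age classes")
  if (peeling_fraction < 0 || peeling_fraction >= 1)
    stop("peeling_fraction must lie in [0, 1)")
  structure(
    list(identity_seed = as.integer(identity_seed), age_class = age_class,
         ridge_period_um = ridge_period_um, duty_cycle = duty_cycle,
         finger_diameter_mm = finger_diameter_mm,
         curvature_mode = curvature_mode, halo_strength = halo_strength,
         peeling_fraction = peeling_fraction,
         noise_sigma_dn = noise_sigma_dn, blur_px = blur_px,
         illum_gradient = illum_gradient, n_minutiae = as.integer(n_minutiae),
         flow_family = flow_family),
    class = "finger_phantom_spec")
}

#' @export
print.finger_phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<finger_phantom_spec> id %d, %s: period %.0f um, duty %.2f, diam %.1f mm, %s\n",
    x$identity_seed, x$age_class, x$ridge_period_um, x$duty_cycle,
    x$finger_diameter_mm, x$curvature_mode))
  invisible(x)
}

## identity-space parameters of the ridge flow, deterministic in the seed.
## The flow is the level-set family of a scalar potential g(u, v) expressed in
## ridge-period units, so the same identity rendered at any period or PPI has
## the same topology. Minutiae are spiral phase singularities added to the
## phase 2*pi*g; their positions are sampled >= 3 periods apart.
identity_params <- function(spec) {
  with_seed(spec$identity_seed, {
    family <- if (!is.null(spec$flow_family) && spec$flow_family != "auto")
      spec$flow_family else sample(c("arch", "loop", "whorl"), 1)
    ## every family is a distance function (|grad g| = 1), so the local
    ## ridge period equals the generative period everywhere
    par <- switch(family,
      parallel = list(),
      arch  = list(c0 = c(runif(1, -4, 4), runif(1, 18, 30))),
      whorl = list(c0 = c(runif(1, -2, 2), runif(1, -2, 2))),
      loop  = {
        ctr <- c(runif(1, -2, 2), runif(1, -2, 2))
        th <- runif(1, 0, pi); hl <- runif(1, 1.5, 3)
        list(a = ctr - hl * c(cos(th), sin(th)),
             b = ctr + hl * c(cos(th), sin(th)))
      })
    ## rejection-sample minutia sites in a +-8 period box, spacing >= 3
    core_dist <- function(p) switch(family,
      parallel = Inf,
      arch  = Inf,
      whorl = sqrt(sum((p - par$c0)^2)),
      loop  = dist_point_segment(p[1], p[2], par$a, par$b))
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(pts) < spec$n_minutiae && tries < 4000) {
      tries <- tries + 1
      p <- runif(2, -8, 8)
      ok <- core_dist(p) >= 2
      if (ok && nrow(pts) > 0 &&
          min(sqrt(rowSums(sweep(pts, 2, p)^2))) < 3) ok <- FALSE
      if (ok) pts <- rbind(pts, p)
    }
    signs <- if (nrow(pts)) sample(c(-1, 1), nrow(pts), replace = TRUE)
             else numeric(0)
    list(family = family, par = par, sites = pts, signs = signs)
  })
}

## distance from point(s) to a segment; u, v may be matrices
dist_point_segment <- function(u, v, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t_ <- ((u - a[1]) * ab[1] + (v - a[2]) * ab[2]) / len2
  t_ <- pmin(1, pmax(0, t_))
  sqrt((u - (a[1] + t_ * ab[1]))^2 + (v - (a[2] + t_ * ab[2]))^2)
}

## phase at arbitrary 0-based pixel coordinates (matrices xs, ys) of a
## render with the given raster shape and pose
phase_at <- function(idp, lambda, shape, pose, xs, ys) {
  cx <- (shape[2] - 1) / 2; cy <- (shape[1] - 1) / 2
  rho <- pose[1]; tx <- pose[2]; ty <- pose[3]
  ## inverse pose: pattern appears rotated by rho and translated by (tx, ty)
  dx <- xs - cx - tx; dy <- ys - cy - ty
  u <- ( cos(rho) * dx + sin(rho) * dy) / lambda
  v <- (-sin(rho) * dx + cos(rho) * dy) / lambda
  g <- switch(idp$family,
    parallel = v,
    arch  = sqrt((u - idp$par$c0[1])^2 + (v - idp$par$c0[2])^2),
    whorl = sqrt((u - idp$par$c0[1])^2 + (v - idp$par$c0[2])^2),
    loop  = dist_point_segment(u, v, idp$par$a, idp$par$b))
  phi <- 2 * pi * g
  if (nrow(idp$sites)) {
    for (i in seq_len(nrow(idp$sites))) {
      phi <- phi + idp$signs[i] *
        atan2(v - idp$sites[i, 2], u - idp$sites[i, 1])
    }
  }
  phi
}

## phase field over the whole raster, plus minutia sites in pixel coords
phase_field <- function(spec, ppi, shape, pose = c(0, 0, 0)) {
  lambda <- pixels_per_feature(spec$ridge_period_um, ppi)
  h <- shape[1]; w <- shape[2]
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  idp <- identity_params(spec)
  phi <- phase_at(idp, lambda, shape, pose, xs, ys)
  sites_px <- NULL
  if (nrow(idp$sites)) {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    rho <- pose[1]
    su <- idp$sites[, 1] * lambda; sv <- idp$sites[, 2] * lambda
    sites_px <- cbind(x = cos(rho) * su - sin(rho) * sv + cx + pose[2],
                      y = sin(rho) * su + cos(rho) * sv + cy + pose[3])
  }
  list(phi = phi, lambda = lambda, sites_px = sites_px, family = idp$family,
       idp = idp)
}

## soft ridge pulse: fraction `duty` of each period sits above the 0.5 level
ridge_pulse <- function(phi, duty, softness = 0.25) {
  stats::plogis((cos(phi) - cos(pi * duty)) / softness)
}

DN_LO <- 0.12   # valley level as a fraction of max_dn
DN_SPAN <- 0.72 # ridge-minus-valley span as a fraction of max_dn

#' Render a rectified (flat) ridge texture with exact ground truth
#'
#' Produces the unrolled ridge pattern of one synthetic finger identity: a
#' smooth flow field (arch / tented-arch / whorl family selected by the
#' identity seed) carrying `n_minutiae` seeded phase-singularity anomalies.
#' The spatial period in pixels is `ridge_period_um * ppi / 25400` and the
#' ridge occupies `duty_cycle` of each period.
#'
#' @param spec A [phantom_spec()].
#' @param ppi Rendering resolution in pixels per inch.
#' @param shape `c(height, width)` of the raster in pixels.
#' @param pose Length-3 numeric `c(rotation_rad, tx_px, ty_px)` rigid pose of
#'   the pattern; ground truth is mapped consistently.
#' @param refine_truth If `TRUE` (default) classify each seeded minutia
#'   (type, direction) from the ideal noiseless pattern.
#' @return A list with `image` (a [raw_image()]) and `truth` (ground-truth
#'   minutiae, local-period map, mask).
#' @export
render_ridge_pattern <- function(spec, ppi, shape, pose = c(0, 0, 0),
                                 refine_truth = TRUE) {
  lambda <- pixels_per_feature(spec$ridge_period_um, ppi)
  if (min(shape) < lambda)
    stop(sprintf(
      "raster %d x %d px cannot contain one full ridge period (%.1f px)",
      shape[1], shape[2], lambda))
  pf <- phase_field(spec, ppi, shape, pose)
  pulse <- ridge_pulse(pf$phi, spec$duty_cycle)
  max_dn <- 4095
  px <- (DN_LO + DN_SPAN * pulse) * max_dn
  img <- raw_image(px, ppi = ppi, bit_depth = 12, max_dn = max_dn,
                   mask = matrix(TRUE, shape[1], shape[2]))
  min_df <- data.frame(x = numeric(0), y = numeric(0), angle = numeric(0),
                       type = character(0))
  if (!is.null(pf$sites_px)) {
    inside <- pf$sites_px[, "x"] >= 0 & pf$sites_px[, "x"] <= shape[2] - 1 &
              pf$sites_px[, "y"] >= 0 & pf$sites_px[, "y"] <= shape[1] - 1
    sp <- pf$sites_px[inside, , drop = FALSE]
    if (nrow(sp)) {
      min_df <- data.frame(x = sp[, "x"], y = sp[, "y"],
                           angle = NA_real_, type = NA_character_)
      if (refine_truth)
        min_df <- refine_truth_minutiae(spec, pf$idp, lambda, shape, pose,
                                        min_df)
    }
  }
  bs <- max(16L, as.integer(round(lambda)))
  pm <- matrix(lambda, length(seq(1, shape[1], by = bs)),
               length(seq(1, shape[2], by = bs)))
  truth <- list(minutiae = min_df,
                period_map = pm, period_block = bs,
                mask = img$mask, lambda_px = lambda,
                duty_cycle = spec$duty_cycle, family = pf$family)
  list(image = img, truth = truth, spec = spec, ppi = ppi)
}

## classify each seeded singularity from the ideal pattern. The noiseless
## phase is evaluated analytically on a patch sampled at the normalized
## template resolution (8 px/ridge), binarized at the generative duty
## threshold, thinned, and scanned for the nearest crossing-number feature —
## so ground-truth angles follow exactly the convention (and scale) of the
## extraction stage. Type depends on ridge/valley parity at the site, which
## the spiral-phase sign alone does not determine.
refine_truth_minutiae <- function(spec, idp, lambda, shape, pose, min_df,
                                  target_px_per_ridge = 8) {
  r <- as.integer(ceiling(2.5 * target_px_per_ridge))   # patch half-size, px
  step <- lambda / target_px_per_ridge                  # native px per patch px
  n <- 2L * r + 1L
  off <- matrix(rep((-r):r, each = n), n, n) * step     # native dx (cols)
  offy <- matrix(rep((-r):r, n), n, n) * step           # native dy (rows)
  for (i in seq_len(nrow(min_df))) {
    xs <- min_df$x[i] + off
    ys <- min_df$y[i] + offy
    phi <- phase_at(idp, lambda, shape, pose, xs, ys)
    patch <- ridge_pulse(phi, spec$duty_cycle) >= 0.5
    sk <- skeletonize(patch)
    cn <- crossing_number_map(sk)
    vsk <- skeletonize(!patch)
    vcn <- crossing_number_map(vsk)
    ## ignore features near the patch border (cut-off ridges)
    bw <- 3L
    cn[c(seq_len(bw), n - bw + seq_len(bw)), ] <- 0L
    cn[, c(seq_len(bw), n - bw + seq_len(bw))] <- 0L
    feat <- which(cn == 1L | cn == 3L, arr.ind = TRUE)
    if (!nrow(feat)) next
    d2 <- (feat[, 2] - (r + 1))^2 + (feat[, 1] - (r + 1))^2
    j <- which.min(d2)
    if (d2[j] > (1.5 * target_px_per_ridge)^2) next
    type <- if (cn[feat[j, 1], feat[j, 2]] == 1L) "ending" else "bifurcation"
    ang <- if (type == "bifurcation")
      dual_valley_angle(vsk, vcn, feat[j, 1], feat[j, 2])
    else NA_real_
    if (is.na(ang))
      ang <- minutia_angle(sk, feat[j, 1], feat[j, 2],
                           if (type == "ending") 1L else 3L, steps = 5L)
    ## analytic base-flow orientation at the refined site
    base <- idp; base$sites <- matrix(numeric(0), 0, 2)
    sx <- min_df$x[i] + (feat[j, 2] - (r + 1)) * step
    sy <- min_df$y[i] + (feat[j, 1] - (r + 1)) * step
    eps <- lambda / 16
    gx <- (phase_at(base, lambda, shape, pose, sx + eps, sy) -
           phase_at(base, lambda, shape, pose, sx - eps, sy)) / (2 * eps)
    gy <- (phase_at(base, lambda, shape, pose, sx, sy + eps) -
           phase_at(base, lambda, shape, pose, sx, sy - eps)) / (2 * eps)
    th <- (atan2(gy, gx) + pi / 2) %% pi
    ## map the refined location back to native pixels
    min_df$x[i] <- min_df$x[i] + (feat[j, 2] - (r + 1)) * step
    min_df$y[i] <- min_df$y[i] + (feat[j, 1] - (r + 1)) * step
    if (!is.na(ang)) {
      ## snap to the analytic orientation, keeping the chosen half-plane
      ang <- if (angdiff(ang, th) <= pi / 2) th else (th + pi) %% (2 * pi)
    }
    min_df$type[i] <- type; min_df$angle[i] <- ang
  }
  min_df
}

#' Wrap a flat ridge texture around a cylindrical finger
#'
#' Models the foreshortening of non-contact imaging: the flat (unrolled)
#' texture is wrapped around a cylinder of the spec's finger diameter and
#' viewed orthographically, so the apparent ridge period at transverse offset
#' `x` from the axis scales by `cos(theta)` with `sin(theta) = x / R` —
#' shrinking essentially to zero at the silhouette. Ground-truth minutiae and
#' the local-period map are remapped consistently.
#'
#' @param render Output of [render_ridge_pattern()].
#' @param edge_clip Fraction of the radius beyond which pixels are excluded
#'   from the mask (the extreme silhouette is unresolvable by construction).
#' @return A render list like [render_ridge_pattern()]'s, with the projected
#'   image, remapped truth, and the cylinder geometry in `truth$cylinder`.
#' @export
project_cylinder <- function(render, edge_clip = 0.995) {
  spec <- render$spec
  if (spec$curvature_mode != "cylindrical")
    stop("project_cylinder requires curvature_mode = 'cylindrical'")
  img <- render$image
  R <- (spec$finger_diameter_mm / 2) * img$ppi / 25.4
  h <- nrow(img$pixels); wf <- ncol(img$pixels)
  cxf <- (wf - 1) / 2
  half_out <- floor(R * edge_clip)
  wo <- 2L * as.integer(half_out) + 1L
  cxo <- half_out
  out <- matrix(DN_LO * img$max_dn, h, wo)
  mask <- matrix(FALSE, h, wo)
  for (j in seq_len(wo)) {
    xo <- (j - 1) - cxo
    s <- xo / R
    if (abs(s) >= 1) next
    u <- R * asin(s)            # arc length on the unrolled texture
    xf <- cxf + u               # 0-based flat column
    j0 <- floor(xf); wgt <- xf - j0
    if (j0 < 0 || j0 + 1 > wf - 1) next
    out[, j] <- (1 - wgt) * img$pixels[, j0 + 1] + wgt * img$pixels[, j0 + 2]
    mask[, j] <- TRUE
  }
  pimg <- raw_image(out, ppi = img$ppi, bit_depth = img$bit_depth,
                    max_dn = img$max_dn, mask = mask)
  ## remap minutiae
  tm <- render$truth$minutiae
  if (nrow(tm)) {
    uu <- tm$x - cxf
    th <- uu / R
    keep <- abs(th) < asin(edge_clip)
    tm <- tm[keep, , drop = FALSE]
    th <- th[keep]
    newx <- cxo + R * sin(th)
    if (nrow(tm)) {
      ang <- tm$angle
      ok <- !is.na(ang)
      ## tangent map: d(x_proj)/d(x_flat) = cos(theta), y unchanged
      ang[ok] <- atan2(sin(ang[ok]), cos(ang[ok]) * cos(th[ok]))
      tm$angle <- ang
      tm$x <- newx
    }
    rownames(tm) <- NULL
  }
  ## blockwise apparent period: lambda * cos(theta) at block centre
  bs <- render$truth$period_block
  xc_blocks <- seq(1, wo, by = bs) + (bs - 1) / 2 - 1
  th_b <- asin(pmin(1, pmax(-1, (xc_blocks - cxo) / R)))
  prow <- render$truth$lambda_px * cos(th_b)
  prow[abs((xc_blocks - cxo) / R) >= edge_clip] <- NA
  pm <- matrix(rep(prow, each = length(seq(1, h, by = bs))),
               length(seq(1, h, by = bs)), length(xc_blocks))
  truth <- render$truth
  truth$minutiae <- tm
  truth$period_map <- pm
  truth$mask <- mask
  truth$cylinder <- list(radius_px = R, center_col = cxo)
  list(image = pimg, truth = truth, spec = spec, ppi = img$ppi)
}

#' Apply acquisition artifacts to a rendered finger image
#'
#' Adds, in order: a low-frequency illumination gradient; a specular halo
#' band parallel to the finger axis whose core saturates at `max_dn` when
#' `halo_strength >= 1`; peeling-skin occlusions (decorrelated ridge texture
#' inside random elliptical flakes, footprints recorded in the ground truth);
#' linear motion blur; and additive Gaussian sensor noise, clipped to the DN
#' range. Deterministic given `seed`.
#'
#' @param render A render list (image + truth + spec).
#' @param seed Integer seed for the stochastic artifact fields.
#' @return A render list with the degraded image and augmented truth.
#' @export
apply_artifacts <- function(render, seed) {
  spec <- render$spec
  img <- render$image
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  max_dn <- img$max_dn
  mask <- img_mask(img)
  clamp01 <- function(v, lo, hi, name) {
    if (v < lo || v > hi) {
      warning(sprintf("%s = %g clamped to [%g, %g]", name, v, lo, hi))
      v <- min(max(v, lo), hi)
    }
    v
  }
  halo <- clamp01(spec$halo_strength, 0, 10, "halo_strength")
  peel <- clamp01(spec$peeling_fraction, 0, 0.95, "peeling_fraction")
  nsig <- clamp01(spec$noise_sigma_dn, 0, max_dn, "noise_sigma_dn")
  blur <- round(clamp01(spec$blur_px, 0, 99, "blur_px"))
  grad <- clamp01(spec$illum_gradient, 0, 1, "illum_gradient")
  artifacts <- list()
  with_seed(seed, {
    ## (1) illumination gradient, multiplicative
    if (grad > 0) {
      dir <- runif(1, 0, 2 * pi)
      gx <- cos(dir); gy <- sin(dir)
      xs <- matrix(rep((0:(w - 1)) / max(w - 1, 1) - 0.5, each = h), h, w)
      ys <- matrix(rep((0:(h - 1)) / max(h - 1, 1) - 0.5, w), h, w)
      px <- px * (1 + grad * (gx * xs + gy * ys))
    }
    ## (2) specular halo band (vertical, Gaussian cross-profile)
    if (halo > 0) {
      off <- runif(1, -0.25, 0.25) * w
      sigma <- 0.06 * w
      xh <- (0:(w - 1)) - ((w - 1) / 2 + off)
      prof <- halo * max_dn * exp(-xh^2 / (2 * sigma^2))
      px <- px + matrix(rep(prof, each = h), h, w)
      core <- which(prof >= max_dn)
      artifacts$halo <- list(center_col = (w - 1) / 2 + off, sigma = sigma,
                             core_cols = core - 1L)
    }
    ## (3) peeling flakes with decorrelated ridge texture
    flake_mask <- matrix(FALSE, h, w)
    if (peel > 0) {
      lambda <- render$truth$lambda_px
      fg <- sum(mask)
      xs <- matrix(rep(0:(w - 1), each = h), h, w)
      ys <- matrix(rep(0:(h - 1), w), h, w)
      guard <- 0
      while (sum(flake_mask & mask) < peel * fg && guard < 200) {
        guard <- guard + 1
        ctr <- c(runif(1, 0, w - 1), runif(1, 0, h - 1))
        if (!mask[round(ctr[2]) + 1, round(ctr[1]) + 1]) next
        ## large sheets, as in clinical photos of peeling newborn skin
        a <- runif(1, 3, 7) * lambda; b <- runif(1, 3, 7) * lambda
        al <- runif(1, 0, pi)
        du <- (xs - ctr[1]) * cos(al) + (ys - ctr[2]) * sin(al)
        dv <- -(xs - ctr[1]) * sin(al) + (ys - ctr[2]) * cos(al)
        inside <- (du / a)^2 + (dv / b)^2 <= 1
        beta <- runif(1, 0, pi); ph0 <- runif(1, 0, 2 * pi)
        tex <- ridge_pulse(2 * pi / lambda *
                             (xs * cos(beta) + ys * sin(beta)) + ph0,
                           render$truth$duty_cycle)
        px[inside] <- (DN_LO + DN_SPAN * tex[inside]) * max_dn
        flake_mask <- flake_mask | inside
      }
    }
    artifacts$flake_mask <- flake_mask
    ## (4) linear motion blur (horizontal box kernel)
    if (blur >= 2) {
      B <- matrix(0, w, w)
      half <- (blur - 1) / 2
      for (j in seq_len(w)) {
        cols <- max(1, j - floor(half)):min(w, j + ceiling(half))
        B[cols, j] <- 1 / length(cols)
      }
      px <- px %*% B
    }
    ## (5) sensor noise then clipping
    if (nsig > 0) px <- px + matrix(stats::rnorm(h * w, 0, nsig), h, w)
  })
  px <- clip_dn(px, max_dn)
  out <- raw_image(px, ppi = img$ppi, bit_depth = img$bit_depth,
                   max_dn = max_dn, mask = img$mask)
  truth <- render$truth
  truth$artifacts <- artifacts
  list(image = out, truth = truth, spec = spec, ppi = img$ppi)
}

#' Render a complete synthetic finger acquisition
#'
#' Convenience chain: flat ridge render sized to the finger, cylindrical
#' projection when the spec asks for it, then acquisition artifacts. The
#' raster is sized from the finger diameter so the full silhouette fits.
#'
#' @param spec A [phantom_spec()].
#' @param ppi Acquisition resolution, pixels per inch.
#' @param seed Artifact/pose seed for this impression.
#' @param pose Optional `c(rot, tx, ty)`; by default a small random pose
#'   (rotation within +-15 degrees) drawn from `seed`.
#' @param artifacts Apply the artifact stack (default TRUE).
#' @return A render list (`image`, `truth`, `spec`, `ppi`).
#' @export
render_finger <- function(spec, ppi, seed = 1L, pose = NULL,
                          artifacts = TRUE) {
  R <- (spec$finger_diameter_mm / 2) * ppi / 25.4
  lambda <- pixels_per_feature(spec$ridge_period_um, ppi)
  if (is.null(pose)) {
    pose <- with_seed(child_seed(seed, 17L), c(
      stats::runif(1, -15, 15) * pi / 180,
      stats::runif(2, -1, 1) * lambda))
  }
  if (spec$curvature_mode == "cylindrical") {
    wflat <- 2L * as.integer(ceiling(pi * R / 2)) + 9L
    hflat <- 2L * as.integer(ceiling(1.1 * R)) + 1L
    r <- render_ridge_pattern(spec, ppi, c(hflat, wflat), pose = pose)
    r <- project_cylinder(r)
  } else {
    side <- 2L * as.integer(ceiling(1.1 * R)) + 1L
    r <- render_ridge_pattern(spec, ppi, c(side, side), pose = pose)
  }
  if (artifacts) r <- apply_artifacts(r, seed = child_seed(seed, 29L))
  r
}

#' Render a growth pair: one identity at two ridge periods
#'
#' The canonical genuine pair for size-invariance testing: the same identity
#' (same flow field and minutiae topology) rendered at its native ridge
#' period and at `growth_scale` times that period, each with independent pose
#' perturbation and artifact seeds.
#'
#' @param spec A [phantom_spec()].
#' @param growth_scale Period multiplier >= 1 (scaled period must stay within
#'   the 100-600 um validity range).
#' @param seeds Two integers, one per impression.
#' @param ppi Acquisition resolution.
#' @param artifacts Apply the artifact stack (default TRUE).
#' @return List of two render lists.
#' @export
growth_pair <- function(spec, growth_scale, seeds, ppi, artifacts = TRUE) {
  if (growth_scale < 1) stop("growth_scale must be >= 1")
  p2 <- spec$ridge_period_um * growth_scale
  if (p2 > 600)
    stop(sprintf("scaled ridge period %.0f um exceeds the 600 um limit", p2))
  spec2 <- spec
  spec2$ridge_period_um <- p2
  spec2$finger_diameter_mm <- min(10, spec$finger_diameter_mm * growth_scale)
  if (spec$age_class == "adult")
    spec2$finger_diameter_mm <- spec$finger_diameter_mm * growth_scale
  list(render_finger(spec,  ppi, seed = seeds[1], artifacts = artifacts),
       render_finger(spec2, ppi, seed = seeds[2], artifacts = artifacts))
}
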