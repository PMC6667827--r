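#' Pixels spanned by a physical feature at a given sampling density
#'
#' The resolution arithmetic of contactless infant imaging: a 125 um newborn
#' ridge period at a standard 500 PPI scanner spans only ~2.5 camera pixels,
#' while a 50 um infant valley at 3400 PPI spans ~7 pixels.
#'
#' @param feature_um Feature size in micrometres (>= 0).
#' @param ppi Sampling density in pixels per inch.
#' @return Feature extent in pixels: `feature_um * ppi / 25400`.
#' @export
pixels_per_feature <- function(feature_um, ppi) {
  if (any(feature_um < 0)) stop("feature_um must be >= 0")
  if (any(ppi <= 0)) stop("ppi must be > 0")
  feature_um * ppi / 25400
}

#' Blockwise ridge orientation field
#'
#' Estimates the dominant ridge direction per block with the averaged
#' squared-gradient method: gradients are doubled in angle, block-averaged,
#' and halved back, giving an orientation modulo pi with a coherence score
#' (the anisotropy of the gradient structure tensor) in [0, 1]. Blocks whose
#' coherence falls below `min_coherence` are marked invalid.
#'
#' @param img A [raw_image()].
#' @param block_size Block edge in pixels (default 16).
#' @param min_coherence Validity threshold on coherence (default 0.25).
#' @return A `ridge_map` list: `orientations`, `coherence`, `valid` (block
#'   matrices), `block_size`, and block-centre coordinate vectors.
#' @export
orientation_field <- function(img, block_size = 16L, min_coherence = 0.25) {
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  nby <- h %/% block_size; nbx <- w %/% block_size
  if (nby * nbx < 2) stop("image has fewer than 2 analysis blocks")
  ## central-difference gradients
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (px[, 3:w] - px[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (px[3:h, ] - px[1:(h - 2), ]) / 2
  gxx <- gx * gx; gyy <- gy * gy; gxy <- gx * gy
  mask <- img_mask(img)
  block_sum <- function(m) {
    m <- m[seq_len(nby * block_size), seq_len(nbx * block_size), drop = FALSE]
    ## fold rows then columns
    rs <- rowsum(m, group = rep(seq_len(nby), each = block_size))
    t(rowsum(t(rs), group = rep(seq_len(nbx), each = block_size)))
  }
  fgfrac <- block_sum(mask * 1) / block_size^2
  sxx <- block_sum(gxx); syy <- block_sum(gyy); sxy <- block_sum(gxy)
  denom <- sxx + syy
  coh <- sqrt((sxx - syy)^2 + 4 * sxy^2) / pmax(denom, 1e-12)
  theta_grad <- 0.5 * atan2(2 * sxy, sxx - syy)
  orient <- (theta_grad + pi / 2) %% pi          # ridge direction, mod pi
  valid <- coh >= min_coherence & fgfrac >= 0.6 & denom > 0
  structure(list(
    orientations = orient, coherence = coh, valid = valid,
    block_size = as.integer(block_size),
    centers_x = (seq_len(nbx) - 1) * block_size + (block_size - 1) / 2,
    centers_y = (seq_len(nby) - 1) * block_size + (block_size - 1) / 2,
    periods = NULL, global_period = NULL),
    class = "ridge_map")
}

#' @export
print.ridge_map <- function(x, ...) {
  cat(sprintf("<ridge_map> %d x %d blocks (size %d), %.0f%% valid%s\n",
              nrow(x$orientations), ncol(x$orientations), x$block_size,
              100 * mean(x$valid),
              if (is.null(x$global_period)) "" else
                sprintf(", global period %.2f px", x$global_period)))
  invisible(x)
}

## bilinear sample of matrix m (1-based grid) at 0-based coords (x, y)
bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 2 & y0 <= h - 2
  out <- rep(NA_real_, length(x))
  i <- which(ok)
  if (length(i)) {
    a <- m[cbind(y0[i] + 1, x0[i] + 1)]; b <- m[cbind(y0[i] + 1, x0[i] + 2)]
    cc <- m[cbind(y0[i] + 2, x0[i] + 1)]; d <- m[cbind(y0[i] + 2, x0[i] + 2)]
    out[i] <- (1 - fy[i]) * ((1 - fx[i]) * a + fx[i] * b) +
              fy[i] * ((1 - fx[i]) * cc + fx[i] * d)
  }
  out
}

## dominant period of a 1-D profile by windowed, zero-padded FFT peak with
## parabolic interpolation; band in pixels/cycle. Returns NA when no peak
## stands out of the band.
profile_period <- function(prof, band = c(4, 80), min_prominence = 3) {
  prof <- prof[!is.na(prof)]
  n <- length(prof)
  if (n < 2 * band[1]) return(NA_real_)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), prof)
  res <- fit$residuals
  hann <- 0.5 - 0.5 * cos(2 * pi * (t - 1) / (n - 1))
  pad <- 8L * 2L^ceiling(log2(n))
  sp <- Mod(stats::fft(c(res * hann, rep(0, pad - n))))^2
  freqs <- (seq_len(pad %/% 2) - 1) / pad        # cycles / px
  inband <- which(freqs >= 1 / band[2] & freqs <= 1 / band[1] &
                    freqs >= 1.5 / n)            # need >= 1.5 cycles in window
  if (length(inband) < 3) return(NA_real_)
  pw <- sp[inband]
  k <- which.max(pw)
  if (pw[k] < min_prominence * stats::median(pw)) return(NA_real_)
  ki <- inband[k]
  ## parabolic interpolation on log power around the peak
  if (ki > 1 && ki < pad %/% 2) {
    l <- log(sp[ki - 1] + 1e-300); c0 <- log(sp[ki] + 1e-300)
    r <- log(sp[ki + 1] + 1e-300)
    dd <- l - 2 * c0 + r
    delta <- if (abs(dd) > 1e-12) 0.5 * (l - r) / dd else 0
    delta <- max(-0.5, min(0.5, delta))
  } else delta <- 0
  fpk <- (ki - 1 + delta) / pad
  1 / fpk
}

#' Local ridge period and global period summary
#'
#' For every valid block, samples the intensity profile perpendicular to the
#' local ridge orientation through the block centre and measures the dominant
#' spectral period within the plausible ridge band. The global period is the
#' coherence-weighted median of the block periods.
#'
#' @param img A [raw_image()].
#' @param ridge_map Output of [orientation_field()]; computed when `NULL`.
#' @param band Plausible ridge-period band in pixels (default `c(4, 80)`).
#' @param profile_len Profile length in pixels (default 160, clipped to the
#'   image extent).
#' @return The `ridge_map` with `periods` and `global_period` filled in.
#'   Throws an `infantprint_unprocessable` error when fewer than 25% of
#'   foreground blocks yield a period.
#' @export
local_period <- function(img, ridge_map = NULL, band = c(4, 80),
                         profile_len = 160L) {
  if (is.null(ridge_map)) ridge_map <- orientation_field(img)
  rm_ <- ridge_map
  px <- img$pixels
  L <- min(profile_len, min(dim(px)) - 2L)
  nb <- dim(rm_$orientations)
  periods <- matrix(NA_real_, nb[1], nb[2])
  ## cap the number of profiled blocks; period varies smoothly, so a regular
  ## subgrid of blocks is measured when the raster is large
  stride <- max(1L, as.integer(ceiling(sqrt(sum(rm_$valid) / 400))))
  for (by in seq(1L, nb[1], by = stride)) for (bx in seq(1L, nb[2], by = stride)) {
    if (!rm_$valid[by, bx]) next
    th <- rm_$orientations[by, bx] + pi / 2    # across-ridge direction
    cx <- rm_$centers_x[bx]; cy <- rm_$centers_y[by]
    t <- seq(-L / 2, L / 2, by = 1)
    prof <- bilinear_sample(px, cx + t * cos(th), cy + t * sin(th))
    ## longest contiguous run of in-image samples
    if (anyNA(prof)) {
      r <- rle(!is.na(prof))
      if (!any(r$values)) next
      kk <- which.max(r$lengths * r$values)
      i0 <- sum(r$lengths[seq_len(kk - 1)]) + 1
      prof <- prof[i0:(i0 + r$lengths[kk] - 1)]
    }
    periods[by, bx] <- profile_period(prof, band = band)
  }
  ok <- !is.na(periods)
  attempted <- rm_$valid
  attempted[-seq(1L, nb[1], by = stride), ] <- FALSE
  attempted[, -seq(1L, nb[2], by = stride)] <- FALSE
  total <- max(1, sum(attempted))
  if (sum(ok) == 0 || sum(ok) / total < 0.25 || sum(ok) < 2)
    stop(structure(class = c("infantprint_unprocessable", "error", "condition"),
                   list(message = sprintf(
                     "ridge period unmeasurable: %d/%d valid blocks yielded a spectral peak",
                     sum(ok), total), call = sys.call(-1))))
  rm_$periods <- periods
  rm_$global_period <- weighted_median(periods[ok],
                                       pmax(rm_$coherence[ok], 1e-6))
  rm_
}

#' Resample an image to a fixed ridge period
#'
#' The size/age-removal step: the global ridge period of the image is
#' measured and the image is rescaled by `target / period` so ridge-to-ridge
#' distance becomes `target` pixels (8 by default) regardless of subject age
#' or finger size — a newborn at 20 px/ridge and an adult at 60 px/ridge land
#' in the same template space. Minification applies a Gaussian anti-alias
#' pre-filter before bilinear resampling.
#'
#' @param img A [raw_image()] (typically the enhanced 8-bit image).
#' @param target_px_per_ridge Target ridge period in pixels (default 8).
#' @param ridge_map Optional precomputed [local_period()] result.
#' @return A list: `image` (resampled [raw_image()]), `scale`,
#'   `original_period`, `measured_period` (re-measured on the output), and
#'   `provenance`.
#' @export
normalize_ridge_frequency <- function(img, target_px_per_ridge = 8,
                                      ridge_map = NULL) {
  if (is.null(ridge_map) || is.null(ridge_map$global_period))
    ridge_map <- local_period(img, ridge_map)
  p0 <- ridge_map$global_period
  s <- target_px_per_ridge / p0
  px <- img$pixels
  mask <- img_mask(img)
  if (abs(s - 1) < 1e-9) {
    out <- img
    measured <- p0
  } else {
    if (s < 1) {
      ## anti-alias: suppress content beyond the new Nyquist limit
      sigma <- 0.6 * sqrt(1 / s^2 - 1)
      px <- as.matrix(EBImage::gblur(px, sigma = sigma))
    }
    nh <- max(8L, as.integer(round(nrow(px) * s)))
    nw <- max(8L, as.integer(round(ncol(px) * s)))
    ## EBImage works on x-major arrays; transpose in and out
    rpx <- t(as.matrix(EBImage::resize(t(px), w = nw, h = nh,
                                       filter = "bilinear")))
    rmask <- t(as.matrix(EBImage::resize(t(mask * 1), w = nw, h = nh,
                                         filter = "bilinear"))) > 0.5
    rpx <- clip_dn(rpx, img$max_dn)
    out <- raw_image(rpx, ppi = img$ppi * s, bit_depth = img$bit_depth,
                     max_dn = img$max_dn, mask = rmask)
    measured <- tryCatch(
      local_period(out, band = c(4, max(20, 2.5 * target_px_per_ridge)))$global_period,
      infantprint_unprocessable = function(e) NA_real_)
  }
  list(image = out, scale = s, original_period = p0,
       measured_period = measured,
       provenance = list(op = "normalize_ridge_frequency",
                         target_px_per_ridge = target_px_per_ridge,
                         original_period = p0, scale = s))
}

#' Measure the global ridge period of an image
#'
#' Convenience wrapper: orientation field + local period, returning just the
#' scalar period in pixels/ridge.
#' @param img A [raw_image()].
#' @param block_size Analysis block edge (default 16).
#' @param band Period search band in px (default `c(4, 80)`).
#' @return Global ridge period in pixels.
#' @export
global_ridge_period <- function(img, block_size = 16L, band = c(4, 80)) {
  local_period(img, orientation_field(img, block_size), band = band)$global_period
}
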