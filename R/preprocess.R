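#' Preprocessing parameters
#'
#' Parameters of the enhancement front end that maps a 12-bit raw capture to
#' an 8-bit enhanced image: flat-field gain, background smoothing radius and
#' the bimodal contrast stretch. The defaults (24 px smoothing, 64 DN noise
#' floor) are the operating point selected by the parameter sweep in
#' [parameter_sweep()].
#'
#' @param blur_radius_px Background-estimation Gaussian sigma in px (>= 1).
#' @param noise_floor_dn Bimodal stretch floor in DN on the input scale.
#' @param upper_percentile Stretch ceiling percentile of the foreground
#'   (50, 100].
#' @param gain_map Optional flat-field gain raster.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(blur_radius_px = 24, noise_floor_dn = 64,
                              upper_percentile = 99.5, gain_map = NULL) {
  if (blur_radius_px < 1) stop("blur_radius_px must be >= 1")
  if (noise_floor_dn < 0) stop("noise_floor_dn must be >= 0")
  if (upper_percentile <= 50 || upper_percentile > 100)
    stop("upper_percentile must lie in (50, 100]")
  structure(list(blur_radius_px = blur_radius_px,
                 noise_floor_dn = noise_floor_dn,
                 upper_percentile = upper_percentile,
                 gain_map = gain_map),
            class = "preprocess_params")
}

#' Flat-field correction
#'
#' Divides out a gain raster (illumination and sensor non-uniformity) and
#' renormalizes so the foreground mean is preserved. Pixels with
#' non-positive gain inside the mask are removed from the mask with a
#' warning.
#'
#' @param img A [raw_image()].
#' @param gain_map Numeric raster, same dimensions, strictly positive on the
#'   foreground.
#' @return A corrected [raw_image()].
#' @export
flat_field_correct <- function(img, gain_map) {
  if (!identical(dim(gain_map), dim(img$pixels)))
    stop("gain_map dimensions must match the image")
  mask <- img_mask(img)
  bad <- mask & gain_map <= 0
  if (any(bad)) {
    warning(sprintf(
      "%d foreground pixels have non-positive gain; removed from mask",
      sum(bad)))
    mask[bad] <- FALSE
  }
  g <- gain_map
  g[g <= 0] <- NA
  corrected <- img$pixels / g
  m0 <- mean(img$pixels[mask]); m1 <- mean(corrected[mask], na.rm = TRUE)
  corrected <- corrected * (m0 / m1)
  corrected[is.na(corrected)] <- 0
  raw_image(clip_dn(corrected, img$max_dn), ppi = img$ppi,
            bit_depth = img$bit_depth, max_dn = img$max_dn, mask = mask)
}

#' Background smoothing (shading removal)
#'
#' Estimates the low-frequency background — curvature shading, residual
#' illumination structure — as a Gaussian blur of extent `blur_radius_px`,
#' subtracts it and re-centres the result at mid-scale. Ridge-band content
#' (periods well below the blur radius) passes essentially unattenuated
#' while slow gradients are removed. A radius that does not exceed the ridge
#' period gives no meaningful foreground/background separation; a warning is
#' emitted for radius < 4 px.
#'
#' @param img A [raw_image()].
#' @param blur_radius_px Gaussian sigma of the background estimate (>= 1).
#' @return A background-subtracted [raw_image()] centred at `max_dn / 2`.
#' @export
smooth_background <- function(img, blur_radius_px = 24) {
  if (blur_radius_px < 1) stop("blur_radius_px must be >= 1")
  if (blur_radius_px > min(dim(img$pixels)))
    stop("blur radius exceeds the image extent")
  if (blur_radius_px < 4)
    warning("blur radius below ~half a ridge period; background estimate will track the ridges")
  bg <- as.matrix(EBImage::gblur(img$pixels, sigma = blur_radius_px))
  out <- img$pixels - bg + img$max_dn / 2
  raw_image(clip_dn(out, img$max_dn), ppi = img$ppi,
            bit_depth = img$bit_depth, max_dn = img$max_dn, mask = img$mask)
}

#' Bimodal contrast stretch to 8 bits
#'
#' Linear map sending `noise_floor_dn` to 0 and the `upper_percentile`
#' foreground intensity to 255, clipping outside — expanding the span
#' between the background/noise mode and the ridge mode of the histogram.
#'
#' @param img A [raw_image()].
#' @param noise_floor_dn Floor in DN on the input scale (e.g. 64 on 12-bit).
#' @param upper_percentile Ceiling percentile of foreground intensities.
#' @return An 8-bit [raw_image()].
#' @export
bimodal_stretch <- function(img, noise_floor_dn = 64, upper_percentile = 99.5) {
  mask <- img_mask(img)
  fg <- img$pixels[mask]
  if (length(unique(fg)) < 2)
    stop("degenerate histogram: all foreground pixels equal; unusable frame")
  hi <- stats::quantile(fg, upper_percentile / 100, names = FALSE, type = 7)
  if (noise_floor_dn >= hi)
    stop(sprintf(
      "noise floor %.0f DN is not below the %.4g-percentile intensity %.0f DN",
      noise_floor_dn, upper_percentile, hi))
  out <- (img$pixels - noise_floor_dn) / (hi - noise_floor_dn) * 255
  out <- round(clip_dn(out, 255))
  raw_image(out, ppi = img$ppi, bit_depth = 8L, max_dn = 255, mask = img$mask)
}

#' Run the full preprocessing front end
#'
#' Applies, in pipeline order: flat-field correction (when a gain map is
#' supplied), background smoothing, and the bimodal stretch to 8 bits.
#'
#' @param img A [raw_image()].
#' @param params A [preprocess_params()].
#' @return An 8-bit enhanced [raw_image()].
#' @export
preprocess_image <- function(img, params = preprocess_params()) {
  if (is.null(img$mask))
    img$mask <- segment_foreground(img)
  if (!is.null(params$gain_map))
    img <- flat_field_correct(img, params$gain_map)
  img <- smooth_background(img, params$blur_radius_px)
  bimodal_stretch(img, params$noise_floor_dn, params$upper_percentile)
}

#' Segment the finger foreground of a maskless frame
#'
#' File formats carry no silhouette mask, so one is recovered from ridge
#' modulation: the finger carries strong high-pass texture at the ridge
#' scale while the background (dark field behind the aperture) is flat.
#' The smoothed high-pass energy is thresholded at a fixed fraction of its
#' bright quantile, the largest connected component is kept, holes are
#' filled, and the boundary is eroded slightly to drop the silhouette rim.
#' A fully covered field (e.g. a test grating) comes back entirely
#' foreground.
#'
#' @param img A [raw_image()].
#' @param sigma Smoothing scale in pixels (default 8, about one normalized
#'   ridge period).
#' @return A logical matrix, `TRUE` on the finger.
#' @export
segment_foreground <- function(img, sigma = 8) {
  px <- img$pixels
  hp <- px - as.matrix(EBImage::gblur(px, sigma = sigma))
  energy <- as.matrix(EBImage::gblur(hp^2, sigma = sigma))
  thr <- 0.1 * stats::quantile(energy, 0.9, names = FALSE)
  mask <- energy > thr
  if (!any(mask)) return(matrix(TRUE, nrow(px), ncol(px)))
  lab <- EBImage::bwlabel(mask * 1L)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  mask <- EBImage::fillHull(mask * 1L) == 1L
  if (mean(mask) > 0.98) return(matrix(TRUE, nrow(px), ncol(px)))
  er <- as.matrix(EBImage::erode(mask * 1L, EBImage::makeBrush(9, "disc")))
  er == 1L
}
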