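#' Oriented enhancement and binarization of a normalized image
#'
#' Expects an image already normalized to ~8 px/ridge. Each pixel is smoothed
#' anisotropically along the local ridge orientation (long axis along the
#' ridge, sub-pixel across it), which suppresses noise without eroding the
#' narrow infant valleys, then thresholded adaptively (halfway between the
#' local mean and the local envelope midpoint). The binarized duty cycle
#' therefore tracks the generative duty cycle rather than being forced to
#' 50% as a band-pass quadrature filter would.
#'
#' Blocks with incoherent orientation or a ridge period outside the
#' expected band (noise, saturated or structureless patches) are excluded
#' from the quality mask when they form clusters. Peeling flakes whose
#' displaced texture keeps the ridge period are locally valid ridge
#' patterns and are *not* excluded here; their false features are handled
#' downstream by the extraction filters and match consensus.
#'
#' @param img A [raw_image()] at ~8 px/ridge.
#' @param block_size Orientation block edge (default 16).
#' @param n_orientations Size of the oriented filter bank (default 12).
#' @param expected_period Ridge period the caller normalized to (default 8);
#'   the measured period must fall within +-25% of it.
#' @return A list: `binary` (0/1 matrix), `mask` (quality-pruned foreground),
#'   `ridge_map`, `period`.
#' @export
enhance_and_binarize <- function(img, block_size = 16L, n_orientations = 12L,
                                 expected_period = 8) {
  band <- c(4, max(20, 2.5 * expected_period))
  rmap <- tryCatch(
    local_period(img, orientation_field(img, block_size), band = band,
                 profile_len = as.integer(6 * expected_period)),
    infantprint_unprocessable = function(e)
      stop("no dominant ridge band: ", conditionMessage(e)))
  period <- rmap$global_period
  if (period < 0.75 * expected_period || period > 1.25 * expected_period)
    stop(sprintf(
      "ridge period %.1f px is outside [%.3g, %.3g]; run normalize_ridge_frequency first",
      period, 0.75 * expected_period, 1.25 * expected_period))
  ## drop blocks whose local period left the band (e.g. foreshortened
  ## silhouette margins) or whose orientation is incoherent — but only when
  ## such blocks cluster: a genuine minutia is itself a local orientation /
  ## period anomaly and must not be masked away, whereas peeling flakes and
  ## silhouette margins invalidate contiguous runs of blocks
  pp <- rmap$periods
  ## orientation-disagreement: peeling flakes carry internally coherent but
  ## decorrelated ridge texture, so they agree poorly with the smoothed
  ## surrounding orientation field
  o2c <- smooth_small(cos(2 * rmap$orientations))
  o2s <- smooth_small(sin(2 * rmap$orientations))
  smoothed <- (atan2(o2s, o2c) / 2) %% pi
  dev <- angdiff(rmap$orientations, smoothed, mod = pi)
  ## gate the disagreement rule on the neighbourhood's directional
  ## consistency: near singular flow (whorl cores) the smoothed field is
  ## meaningless and genuinely curved blocks must not be excluded
  mag <- sqrt(o2c^2 + o2s^2)
  bad <- (!is.na(pp) &
            (pp < 0.75 * expected_period | pp > 1.25 * expected_period)) |
         (dev > pi / 5 & mag > 0.6) |
         !rmap$valid
  nbad <- matrix(0L, nrow(bad), ncol(bad))
  nbad[-1, ] <- nbad[-1, ] + bad[-nrow(bad), ]
  nbad[-nrow(bad), ] <- nbad[-nrow(bad), ] + bad[-1, ]
  nbad[, -1] <- nbad[, -1] + bad[, -ncol(bad)]
  nbad[, -ncol(bad)] <- nbad[, -ncol(bad)] + bad[, -1]
  clustered_bad <- bad & nbad >= 2L
  rmap$valid <- !clustered_bad
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  ## oriented filter bank: anisotropic Gaussians
  angles <- (seq_len(n_orientations) - 1) * pi / n_orientations
  ksz <- 9L
  kc <- (ksz + 1) / 2
  responses <- vector("list", n_orientations)
  for (i in seq_len(n_orientations)) {
    th <- angles[i]
    xs <- matrix(rep(seq_len(ksz) - kc, each = ksz), ksz, ksz)  # x along cols
    ys <- matrix(rep(seq_len(ksz) - kc, ksz), ksz, ksz)
    ua <- xs * cos(th) + ys * sin(th)      # along-ridge coordinate
    ub <- -xs * sin(th) + ys * cos(th)
    k <- exp(-ua^2 / (2 * 3^2) - ub^2 / (2 * 0.7^2))
    k <- k / sum(k)
    responses[[i]] <- as.matrix(EBImage::filter2(px, k))
  }
  ## per-pixel orientation: smooth doubled block angles, then nearest bank angle
  o2c <- cos(2 * rmap$orientations); o2s <- sin(2 * rmap$orientations)
  o2c[!rmap$valid] <- 0; o2s[!rmap$valid] <- 0
  upsample <- function(m)
    t(as.matrix(EBImage::resize(t(m), w = w, h = h, filter = "bilinear")))
  pc <- upsample(o2c); ps <- upsample(o2s)
  pang <- (atan2(ps, pc) / 2) %% pi
  idx <- (round(pang / (pi / n_orientations)) %% n_orientations) + 1
  enhanced <- matrix(0, h, w)
  for (i in seq_len(n_orientations)) {
    sel <- idx == i
    if (any(sel)) enhanced[sel] <- responses[[i]][sel]
  }
  ## adaptive threshold between the local mean and the local midrange
  ## (envelope midpoint). The mean alone symmetrizes the blurred signal
  ## toward 50% duty; the midrange alone overshoots for asymmetric infant
  ## profiles; a midrange-weighted blend tracks the generative duty cycle
  ## for both the infant (~0.8) and adult (~0.5) regimes.
  mu <- as.matrix(EBImage::gblur(enhanced, sigma = period))
  br <- EBImage::makeBrush(2L * as.integer(round(period / 2)) + 1L, "disc")
  mx <- t(as.matrix(EBImage::dilate(t(enhanced), br)))
  mn <- t(as.matrix(EBImage::erode(t(enhanced), br)))
  thr <- 0.5 * (mu + (mx + mn) / 2)
  binary <- matrix(as.integer(enhanced >= thr), h, w)
  binary <- break_diagonal_bridges(binary, enhanced)
  ## quality mask: coherent blocks only
  qual <- matrix(FALSE, h, w)
  bs <- rmap$block_size
  for (by in seq_len(nrow(rmap$valid))) for (bx in seq_len(ncol(rmap$valid))) {
    if (!rmap$valid[by, bx]) next
    ys <- ((by - 1) * bs + 1):min(by * bs, h)
    xs <- ((bx - 1) * bs + 1):min(bx * bs, w)
    qual[ys, xs] <- TRUE
  }
  mask <- img_mask(img) & qual
  binary[!mask] <- 0L
  list(binary = binary, mask = mask, ridge_map = rmap, period = period)
}

## Narrow infant valleys (1-2 px at 8 px/ridge) running diagonally reduce to
## 8-connected dotted lines, so the 8-connected ridges bridge straight across
## them. Every 2x2 block holding exactly the two diagonal ridge pixels is an
## ambiguous crossing; valley continuity wins and the dimmer ridge pixel is
## cleared.
break_diagonal_bridges <- function(binary, enhanced, max_pass = 4L) {
  h <- nrow(binary); w <- ncol(binary)
  for (pass in seq_len(max_pass)) {
    tl <- binary[-h, -w]; tr <- binary[-h, -1]
    bl <- binary[-1, -w]; br <- binary[-1, -1]
    typeA <- which(tl == 1L & br == 1L & tr == 0L & bl == 0L)  # "\" ridges
    typeB <- which(tr == 1L & bl == 1L & tl == 0L & br == 0L)  # "/" ridges
    if (!length(typeA) && !length(typeB)) break
    if (length(typeA)) {
      yx <- arrayInd(typeA, c(h - 1L, w - 1L))
      i1 <- cbind(yx[, 1], yx[, 2])          # top-left
      i2 <- cbind(yx[, 1] + 1L, yx[, 2] + 1L)  # bottom-right
      weaker <- ifelse(enhanced[i1] <= enhanced[i2], 1L, 2L)
      binary[rbind(i1[weaker == 1L, , drop = FALSE],
                   i2[weaker == 2L, , drop = FALSE])] <- 0L
    }
    if (length(typeB)) {
      yx <- arrayInd(typeB, c(h - 1L, w - 1L))
      i1 <- cbind(yx[, 1], yx[, 2] + 1L)       # top-right
      i2 <- cbind(yx[, 1] + 1L, yx[, 2])       # bottom-left
      weaker <- ifelse(enhanced[i1] <= enhanced[i2], 1L, 2L)
      binary[rbind(i1[weaker == 1L, , drop = FALSE],
                   i2[weaker == 2L, , drop = FALSE])] <- 0L
    }
  }
  binary
}

## separable 5-tap Gaussian smoothing with edge replication; safe for block
## grids much smaller than any filter2 kernel
smooth_small <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  pad <- function(v) c(v[1], v[1], v, v[length(v)], v[length(v)])
  sm1 <- function(v) {
    p <- pad(v)
    vapply(seq_along(v), function(i) sum(p[i:(i + 4)] * k), numeric(1))
  }
  m2 <- apply(m, 2, sm1)
  if (is.null(dim(m2))) m2 <- matrix(m2, nrow(m), ncol(m))
  t(apply(m2, 1, sm1))
}

## direction of a ridge bifurcation from its dual feature: the valley
## terminating between the forks. Finds the nearest valley-skeleton ending
## within `radius` px and returns its away-from-termination trace direction,
## which points along the valley between the two fork branches.
dual_valley_angle <- function(vsk, vcn, y, x, radius = 8L, steps = 5L) {
  h <- nrow(vsk); w <- ncol(vsk)
  ys <- max(1, y - radius):min(h, y + radius)
  xs <- max(1, x - radius):min(w, x + radius)
  sub <- which(vcn[ys, xs] == 1L, arr.ind = TRUE)
  if (!nrow(sub)) return(NA_real_)
  vy <- ys[sub[, 1]]; vx <- xs[sub[, 2]]
  d2 <- (vy - y)^2 + (vx - x)^2
  ord <- order(d2)
  for (j in ord) {
    if (d2[j] > radius^2) break
    path <- trace_skeleton(vsk, vy[j], vx[j], n = steps + 1L)
    if (nrow(path) < 3) next
    ## direction of the valley as seen from the ridge junction, averaged
    ## over the traced path — more stable than the trace endpoint alone
    ang <- atan2(mean(path[, 1]) - y, mean(path[, 2]) - x) %% (2 * pi)
    if (d2[j] <= 2) return(ang)
    bearing <- atan2(vy[j] - y, vx[j] - x)
    if (angdiff(ang, bearing) < pi / 3) return(ang)
  }
  NA_real_
}

## direction of a minutia from the local skeleton geometry: endings point
## along the ridge away from the termination; bifurcations along the mean of
## the two converging branches
minutia_angle <- function(skel, y, x, cn, steps = 5L) {
  if (cn == 1L) {
    path <- trace_skeleton(skel, y, x, n = steps)
    if (nrow(path) < 2) return(NA_real_)
    tail_ <- path[nrow(path), ]
    atan2(tail_[1] - y, tail_[2] - x) %% (2 * pi)
  } else {
    ## three branch directions
    h <- nrow(skel); w <- ncol(skel)
    nbrs <- list()
    for (d in list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                   c(1, 0), c(1, -1), c(0, -1), c(-1, -1))) {
      yy <- y + d[1]; xx <- x + d[2]
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= w && skel[yy, xx] == 1L)
        nbrs[[length(nbrs) + 1]] <- c(yy, xx)
    }
    if (length(nbrs) < 3) return(NA_real_)
    nbm <- do.call(rbind, nbrs[1:3])
    dirs <- vapply(1:3, function(i) {
      ## keep each branch trace out of the junction and the other branches
      path <- trace_skeleton(skel, nbm[i, 1], nbm[i, 2], n = steps,
                             forbid = rbind(c(y, x), nbm[-i, , drop = FALSE]))
      tail_ <- path[nrow(path), ]
      atan2(tail_[1] - y, tail_[2] - x)
    }, numeric(1))
    ## the two branches with the smallest mutual angle form the fork
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    dd <- apply(pairs, 1, function(p) angdiff(dirs[p[1]], dirs[p[2]]))
    p <- pairs[which.min(dd), ]
    m <- atan2(mean(sin(dirs[p])), mean(cos(dirs[p])))
    m %% (2 * pi)
  }
}

#' Extract a minutiae template from a skeleton
#'
#' Crossing-number scan: CN 1 pixels are ridge endings, CN 3 bifurcations.
#' Filtering removes minutiae within `border_px` of the mask border and spur
#' branches shorter than `spur_px`; of any pair closer than `min_sep_px`
#' only the higher-quality member survives, and facing anti-parallel ending
#' pairs within a ridge period (broken-ridge artifacts) are dropped
#' entirely. Quality is local orientation coherence times a
#' distance-to-border ramp.
#'
#' @param skel 0/1 skeleton matrix (from [skeletonize()]).
#' @param mask Logical foreground mask (same dimensions).
#' @param ridge_map Optional [orientation_field()] result for quality scores.
#' @param binary Optional 0/1 ridge raster the skeleton came from. When
#'   given, bifurcation directions are taken from the dual feature — the
#'   terminating valley between the forks — which is far more stable than
#'   classifying the three skeleton branches.
#' @param resolution Ridge period of the source image in px (recorded in the
#'   template; 8 for normalized images).
#' @param border_px Mask-border exclusion distance (default 8).
#' @param spur_px Minimum branch length (default 8).
#' @param min_sep_px Minimum pairwise separation (default 4).
#' @param min_quality Drop minutiae below this quality (default 0.3);
#'   artifact-induced detections concentrate at low quality.
#' @param max_minutiae Keep at most this many minutiae, ranked by quality
#'   (default 40).
#' @return A `minutiae_template` object.
#' @export
extract_minutiae <- function(skel, mask = NULL, ridge_map = NULL,
                             resolution = 8, border_px = 8, spur_px = 8,
                             min_sep_px = 4, binary = NULL,
                             min_quality = 0.3, max_minutiae = 40L) {
  h <- nrow(skel); w <- ncol(skel)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  skel <- skel * (mask * 1L)
  skel <- prune_spurs(skel, min_len = as.integer(spur_px))
  cn <- crossing_number_map(skel)
  vsk <- NULL
  vcn <- NULL
  if (!is.null(binary)) {
    vsk <- skeletonize((binary == 0L) & mask)
    vcn <- crossing_number_map(vsk)
  }
  feats <- which(cn == 1L | cn == 3L, arr.ind = TRUE)
  ## distance to mask border; the image edge counts as border too
  padm <- matrix(0, h + 2L, w + 2L)
  padm[2:(h + 1L), 2:(w + 1L)] <- mask * 1
  dist <- t(as.matrix(EBImage::distmap(t(padm))))[2:(h + 1L), 2:(w + 1L)]
  rows <- list()
  for (i in seq_len(nrow(feats))) {
    y <- feats[i, 1]; x <- feats[i, 2]
    if (dist[y, x] <= border_px) next
    type <- if (cn[y, x] == 1L) "ending" else "bifurcation"
    ang <- if (type == "bifurcation" && !is.null(vsk))
      dual_valley_angle(vsk, vcn, y, x)
    else NA_real_
    if (is.na(ang)) ang <- minutia_angle(skel, y, x, cn[y, x])
    if (is.na(ang)) next
    q_coh <- 1
    if (!is.null(ridge_map)) {
      bs <- ridge_map$block_size
      by <- min(nrow(ridge_map$coherence), (y - 1) %/% bs + 1)
      bx <- min(ncol(ridge_map$coherence), (x - 1) %/% bs + 1)
      q_coh <- ridge_map$coherence[by, bx]
      ## a minutia direction lies along the ridge flow: snap the traced
      ## angle to the block orientation (mod pi), keeping its half-plane
      if (ridge_map$valid[by, bx]) {
        th <- ridge_map$orientations[by, bx]
        ang <- if (angdiff(ang, th) <= pi / 2) th else (th + pi) %% (2 * pi)
      }
    }
    q <- q_coh * min(1, (dist[y, x] - border_px) / (2 * border_px))
    rows[[length(rows) + 1]] <-
      data.frame(x = x - 1, y = y - 1, angle = ang, type = type,
                 quality = max(0, min(1, q)))
  }
  m <- if (length(rows)) do.call(rbind, rows)
       else data.frame(x = numeric(0), y = numeric(0), angle = numeric(0),
                       type = character(0), quality = numeric(0))
  if (nrow(m)) m <- m[m$quality >= min_quality, , drop = FALSE]
  if (nrow(m) > max_minutiae)
    m <- m[order(m$quality, decreasing = TRUE)[seq_len(max_minutiae)], ,
           drop = FALSE]
  ## enforce minimum separation: keep the better-quality member of any
  ## too-close pair
  if (nrow(m) > 1) {
    o <- order(m$quality, decreasing = TRUE)
    keep <- logical(nrow(m))
    for (i in o) {
      kept <- which(keep)
      if (!length(kept) ||
          min(sqrt((m$x[kept] - m$x[i])^2 + (m$y[kept] - m$y[i])^2)) >=
            min_sep_px)
        keep[i] <- TRUE
    }
    m <- m[keep, , drop = FALSE]
  }
  ## density filter: genuine minutiae are sparse (ridge flow cannot support
  ## many anomalies per few periods); tight clusters are occlusion-boundary
  ## artifacts and are dropped wholesale
  if (nrow(m) > 3) {
    d <- as.matrix(stats::dist(m[, c("x", "y")]))
    crowd <- rowSums(d < 12) - 1
    m <- m[crowd < 3, , drop = FALSE]
  }
  ## broken-ridge / occlusion-boundary filter: ridge flow cannot place two
  ## genuine minutiae within ~2 periods of each other (the simulator seeds
  ## them >= 3 periods apart, and real flow fields behave likewise), so a
  ## roughly anti-parallel same-type pair at short range is a break or
  ## texture-discontinuity artifact; both members are dropped
  if (nrow(m) > 1) {
    drop <- rep(FALSE, nrow(m))
    for (a in seq_len(nrow(m) - 1)) for (b in (a + 1):nrow(m)) {
      if (m$type[a] != m$type[b]) next
      dd <- sqrt((m$x[a] - m$x[b])^2 + (m$y[a] - m$y[b])^2)
      if (dd < 3 * min_sep_px &&
          angdiff(m$angle[a], m$angle[b] + pi) < pi / 3)
        drop[c(a, b)] <- TRUE
    }
    m <- m[!drop, , drop = FALSE]
  }
  rownames(m) <- NULL
  minutiae_template(m, resolution = resolution, image_shape = c(h, w))
}

#' Construct a minutiae template object
#'
#' @param minutiae Data frame with columns x, y (0-based px), angle (radians
#'   mod 2*pi), type ("ending"/"bifurcation"), quality ([0,1]).
#' @param resolution Source ridge period in px/ridge.
#' @param image_shape `c(height, width)` of the source raster.
#' @param provenance Optional list of processing parameters.
#' @return A `minutiae_template`.
#' @export
minutiae_template <- function(minutiae, resolution = 8,
                              image_shape = NULL, provenance = list()) {
  stopifnot(is.data.frame(minutiae),
            all(c("x", "y", "angle", "type") %in% names(minutiae)))
  if (!"quality" %in% names(minutiae))
    minutiae$quality <- rep(1, nrow(minutiae))
  if (nrow(minutiae) && !all(minutiae$type %in% c("ending", "bifurcation")))
    stop("minutia type must be 'ending' or 'bifurcation'")
  minutiae$angle <- minutiae$angle %% (2 * pi)
  structure(list(minutiae = minutiae, resolution = resolution,
                 image_shape = image_shape, provenance = provenance),
            class = "minutiae_template")
}

#' @export
print.minutiae_template <- function(x, ...) {
  tab <- table(x$minutiae$type)
  cat(sprintf("<minutiae_template> %d minutiae (%s) @ %.3g px/ridge\n",
              nrow(x$minutiae),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$resolution))
  invisible(x)
}

#' Write a minutiae template as JSON
#'
#' @param template A `minutiae_template`.
#' @param path Output file path.
#' @export
write_template <- function(template, path) {
  obj <- list(version = "1.0",
              resolution_px_per_ridge = template$resolution,
              image_shape = template$image_shape,
              minutiae = template$minutiae,
              provenance = template$provenance)
  ## 17 significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a minutiae template from JSON
#'
#' @param path Template file written by [write_template()].
#' @return A `minutiae_template`.
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$minutiae
  if (is.null(m) || !length(m))
    m <- data.frame(x = numeric(0), y = numeric(0), angle = numeric(0),
                    type = character(0), quality = numeric(0))
  m <- as.data.frame(m)
  ## JSON carries no integer/double distinction: restore numeric columns
  for (col in c("x", "y", "angle", "quality"))
    if (col %in% names(m)) m[[col]] <- as.numeric(m[[col]])
  minutiae_template(m,
                    resolution = as.numeric(obj$resolution_px_per_ridge),
                    image_shape = as.integer(unlist(obj$image_shape)),
                    provenance = as.list(obj$provenance))
}

#' Binarize, skeletonize and extract minutiae from a normalized image
#'
#' The back half of the processing pipeline in one call.
#'
#' @param img A [raw_image()] normalized to ~8 px/ridge.
#' @param border_px,spur_px,min_sep_px Filter thresholds, see
#'   [extract_minutiae()].
#' @return A `minutiae_template`.
#' @export
image_to_template <- function(img, border_px = 8, spur_px = 8,
                              min_sep_px = 4) {
  eb <- enhance_and_binarize(img)
  sk <- skeletonize(eb$binary)
  extract_minutiae(sk, eb$mask, eb$ridge_map, resolution = 8,
                   border_px = border_px, spur_px = spur_px,
                   min_sep_px = min_sep_px, binary = eb$binary)
}
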