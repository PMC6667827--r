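#' Genuine/impostor score set
#'
#' @param genuine Numeric vector of same-finger comparison scores in [0, 1].
#' @param impostor Numeric vector of different-finger scores in [0, 1].
#' @param metadata Optional campaign description list.
#' @return A `score_set`.
#' @export
score_set <- function(genuine, impostor, metadata = list()) {
  if (any(c(genuine, impostor) < 0 | c(genuine, impostor) > 1))
    stop("all scores must lie in [0, 1]")
  structure(list(genuine = genuine, impostor = impostor, metadata = metadata),
            class = "score_set")
}

#' Detection error tradeoff curve
#'
#' Computes (threshold, FAR, FRR) over all observed score thresholds, with
#' the acceptance convention FAR(t) = fraction of impostor scores >= t and
#' FRR(t) = fraction of genuine scores < t (ties count as acceptances), plus
#' the equal error rate by linear interpolation at the FAR = FRR crossing.
#'
#' @param s A [score_set()] with both lists non-empty.
#' @return A `det_curve`: data frame `points` (threshold, far, frr) and `eer`.
#' @export
det_curve <- function(s) {
  if (!length(s$genuine) || !length(s$impostor))
    stop("both genuine and impostor score lists must be non-empty")
  thr <- sort(unique(c(s$genuine, s$impostor)))
  far <- vapply(thr, function(t) mean(s$impostor >= t), numeric(1))
  frr <- vapply(thr, function(t) mean(s$genuine < t), numeric(1))
  ## EER: FAR is non-increasing, FRR non-decreasing in t; find the crossing
  d <- far - frr
  k <- which(d <= 0)[1]
  eer <- if (is.na(k)) {
    ## never crosses within observed thresholds: take boundary value
    min(far[length(far)], 1)
  } else if (k == 1) {
    ## already crossed at the lowest threshold
    (far[1] + frr[1]) / 2
  } else {
    ## linear interpolation between bracketing thresholds k-1 and k
    d0 <- d[k - 1]; d1 <- d[k]
    w <- if (abs(d0 - d1) < 1e-15) 0.5 else d0 / (d0 - d1)
    f0 <- far[k - 1] + w * (far[k] - far[k - 1])
    r0 <- frr[k - 1] + w * (frr[k] - frr[k - 1])
    (f0 + r0) / 2
  }
  structure(list(points = data.frame(threshold = thr, far = far, frr = frr),
                 eer = eer),
            class = "det_curve")
}

#' @export
print.det_curve <- function(x, ...) {
  cat(sprintf("<det_curve> %d thresholds, EER %.3f\n",
              nrow(x$points), x$eer))
  invisible(x)
}

#' True accept rate at a false accept rate bound
#'
#' TAR = 1 - FRR at the most permissive threshold whose FAR does not exceed
#' `far_target`; 0 when no threshold achieves the bound.
#'
#' @param curve A [det_curve()].
#' @param far_target FAR bound in (0, 1], default 0.001 (i.e. FAR = 0.1%).
#' @return TAR as a fraction in [0, 1].
#' @export
tar_at_far <- function(curve, far_target = 0.001) {
  if (far_target <= 0 || far_target > 1)
    stop("far_target must lie in (0, 1]")
  ok <- which(curve$points$far <= far_target)
  if (!length(ok)) return(0)
  ## smallest threshold satisfying the bound maximizes TAR
  1 - curve$points$frr[ok[1]]
}

#' Multi-finger score fusion
#'
#' Max-rule fusion of per-finger scores for one comparison decision (the
#' fusion rule for multi-finger enrollment is a labeled assumption of this
#' package).
#'
#' @param scores Numeric vector (one score per enrolled finger) or a list of
#'   such vectors.
#' @param rule Currently only `"max"`.
#' @return Fused score(s).
#' @export
fuse_multifinger <- function(scores, rule = c("max")) {
  rule <- match.arg(rule)
  if (is.list(scores)) return(vapply(scores, fuse_multifinger, numeric(1)))
  if (!length(scores)) stop("at least one finger score is required")
  max(scores)
}

#' Run one synthetic verification campaign
#'
#' Generates `n_identities` phantom fingers, each rendered `n_impressions`
#' times with independent pose (rotation within +-15 degrees) and artifact
#' seeds and an optional growth factor between impressions, runs every
#' impression through the processing pipeline, and scores all genuine pairs
#' plus sampled impostor pairs.
#'
#' All randomness derives from `seed` via a counter scheme, so two campaigns
#' with the same seed see identical images — the pairing property the
#' parameter sweep relies on.
#'
#' @param n_identities Number of distinct fingers.
#' @param n_impressions Impressions per finger (>= 2 for genuine pairs).
#' @param seed Master campaign seed.
#' @param age_class Age-class preset for the phantom population.
#' @param ppi Acquisition resolution (default 1500).
#' @param growth_scale Maximum growth factor between first and later
#'   impressions (1 = none; 1.5 means later impressions have up to 1.5x the
#'   ridge period).
#' @param params [preprocess_params()] for the pipeline.
#' @param target_px_per_ridge Normalization target (default 8).
#' @param max_impostor Cap on impostor comparisons (default 600).
#' @param spec_overrides Named list of phantom-spec fields applied to every
#'   identity (e.g. `list(halo_strength = 0, blur_px = 0)`), used to pin a
#'   campaign to an exact artifact condition.
#' @param progress Print per-identity progress lines.
#' @return A [score_set()]; metadata records rejected image count and
#'   per-image template sizes.
#' @export
run_campaign <- function(n_identities = 50, n_impressions = 2, seed = 1,
                         age_class = "infant", ppi = 1500,
                         growth_scale = 1.5,
                         params = preprocess_params(),
                         target_px_per_ridge = 8,
                         max_impostor = 600, spec_overrides = list(),
                         progress = FALSE) {
  pop <- campaign_population(n_identities, n_impressions, seed, age_class,
                             ppi, growth_scale, spec_overrides)
  templates <- vector("list", length(pop$renders))
  rejected <- 0L
  for (i in seq_along(pop$renders)) {
    templates[i] <- list(tryCatch(
      pipeline_template(pop$renders[[i]]$image, params, target_px_per_ridge),
      error = function(e) NULL))
    if (is.null(templates[[i]]) ||
        abs(templates[[i]]$resolution - 8) > 0.5 ||
        nrow(templates[[i]]$minutiae) == 0) {
      templates[i] <- list(NULL)
      rejected <- rejected + 1L
    }
    if (progress && i %% n_impressions == 0)
      message(sprintf("identity %d/%d processed", i %/% n_impressions,
                      n_identities))
  }
  score_pairs(templates, pop$identity, seed = seed,
              max_impostor = max_impostor,
              metadata = list(n_identities = n_identities,
                              n_impressions = n_impressions,
                              age_class = age_class, ppi = ppi,
                              growth_scale = growth_scale, seed = seed,
                              rejected = rejected,
                              n_images = length(pop$renders)))
}

#' Generate the image population of a campaign (shared across sweep cells)
#'
#' @inheritParams run_campaign
#' @return List with `renders` (list of render lists) and `identity`
#'   (integer vector mapping each render to its finger).
#' @export
campaign_population <- function(n_identities, n_impressions, seed,
                                age_class = "infant", ppi = 1500,
                                growth_scale = 1.5, spec_overrides = list()) {
  renders <- list()
  identity <- integer(0)
  preset_range <- switch(age_class,
    newborn = c(125, 150), neonate = c(150, 250),
    infant = c(200, 350), adult = c(420, 480))
  for (id in seq_len(n_identities)) {
    id_seed <- child_seed(seed, 1L, id)
    period <- with_seed(child_seed(seed, 2L, id),
                        stats::runif(1, preset_range[1], preset_range[2]))
    spec <- phantom_spec(identity_seed = id_seed, age_class = age_class,
                         ridge_period_um = period)
    for (nm in names(spec_overrides)) spec[[nm]] <- spec_overrides[[nm]]
    ## keep growth a pure similarity: the finger diameter grows with the
    ## ridge period, so pick a base diameter that stays within the infant
    ## range at maximum growth
    if (age_class != "adult")
      spec$finger_diameter_mm <- min(spec$finger_diameter_mm,
                                     10 / max(1, growth_scale))
    for (imp in seq_len(n_impressions)) {
      gs <- if (imp == 1) 1 else
        with_seed(child_seed(seed, 3L, id, imp),
                  stats::runif(1, 1, max(1, growth_scale)))
      sp <- spec
      sp$ridge_period_um <- min(600, spec$ridge_period_um * gs)
      sp$finger_diameter_mm <- spec$finger_diameter_mm * gs
      r <- render_finger(sp, ppi = ppi, seed = child_seed(seed, 4L, id, imp))
      renders[[length(renders) + 1]] <- r
      identity <- c(identity, id)
    }
  }
  list(renders = renders, identity = identity)
}

## score all genuine pairs and up to max_impostor impostor pairs
score_pairs <- function(templates, identity, seed, max_impostor = 600,
                        metadata = list()) {
  n <- length(templates)
  usable <- !vapply(templates, is.null, logical(1))
  pairs <- utils::combn(n, 2)
  is_gen <- identity[pairs[1, ]] == identity[pairs[2, ]]
  gidx <- which(is_gen)
  iidx <- which(!is_gen)
  if (length(iidx) > max_impostor) {
    iidx <- with_seed(child_seed(seed, 99L),
                      sample(iidx, max_impostor))
    iidx <- sort(iidx)
  }
  one <- function(kk) {
    i <- pairs[1, kk]; j <- pairs[2, kk]
    if (!usable[i] || !usable[j]) return(0)
    tryCatch(match_templates(templates[[i]], templates[[j]])$score,
             error = function(e) 0)
  }
  genuine <- vapply(gidx, one, numeric(1))
  impostor <- vapply(iidx, one, numeric(1))
  score_set(genuine, impostor, metadata = metadata)
}

#' Sweep pipeline parameters over a seeded campaign
#'
#' Re-runs the processing pipeline on one fixed set of campaign images for
#' every cell of a parameter grid and ranks cells by the separation
#' objective `mean(genuine) - mean(impostor)`. Cells whose pipeline rejects
#' more than half of the images (or whose templates cannot be matched, e.g.
#' a sub-Nyquist normalization target) are marked degenerate and sorted
#' last. Deterministic given `seed`.
#'
#' @param grid Data frame with columns `blur_radius_px`, `noise_floor_dn`,
#'   `target_px_per_ridge` (one row per cell).
#' @param n_identities,n_impressions,seed,age_class,ppi,growth_scale
#'   Campaign spec, see [run_campaign()].
#' @param max_impostor Impostor pair cap per cell.
#' @return The grid with `objective`, `mean_genuine`, `mean_impostor`,
#'   `rejected`, `degenerate`, `rank`, sorted best-first.
#' @export
parameter_sweep <- function(grid, n_identities = 8, n_impressions = 2,
                            seed = 1, age_class = "infant", ppi = 1500,
                            growth_scale = 1.2, max_impostor = 200) {
  stopifnot(all(c("blur_radius_px", "noise_floor_dn",
                  "target_px_per_ridge") %in% names(grid)))
  pop <- campaign_population(n_identities, n_impressions, seed, age_class,
                             ppi, growth_scale)
  res <- grid
  res$objective <- NA_real_
  res$mean_genuine <- NA_real_
  res$mean_impostor <- NA_real_
  res$rejected <- NA_integer_
  res$degenerate <- FALSE
  for (cell in seq_len(nrow(grid))) {
    params <- preprocess_params(blur_radius_px = grid$blur_radius_px[cell],
                                noise_floor_dn = grid$noise_floor_dn[cell])
    templates <- vector("list", length(pop$renders))
    rejected <- 0L
    for (i in seq_along(pop$renders)) {
      templates[i] <- list(tryCatch(
        pipeline_template(pop$renders[[i]]$image, params,
                          grid$target_px_per_ridge[cell]),
        error = function(e) NULL))
      if (is.null(templates[[i]]) ||
          abs(templates[[i]]$resolution - 8) > 0.5 ||
          nrow(templates[[i]]$minutiae) == 0) {
        templates[i] <- list(NULL)
        rejected <- rejected + 1L
      }
    }
    res$rejected[cell] <- rejected
    if (rejected > length(pop$renders) / 2) {
      res$degenerate[cell] <- TRUE
      next
    }
    ss <- score_pairs(templates, pop$identity, seed = seed,
                      max_impostor = max_impostor)
    if (!length(ss$genuine) || !length(ss$impostor)) {
      res$degenerate[cell] <- TRUE
      next
    }
    res$mean_genuine[cell] <- mean(ss$genuine)
    res$mean_impostor[cell] <- mean(ss$impostor)
    res$objective[cell] <- res$mean_genuine[cell] - res$mean_impostor[cell]
  }
  ord <- order(res$degenerate, -ifelse(is.na(res$objective), -Inf,
                                       res$objective))
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
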