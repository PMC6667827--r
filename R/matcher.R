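#' Rotation/translation-invariant local minutia descriptors
#'
#' Encodes each minutia by its `k` nearest neighbours as triplets
#' (distance, bearing relative to the minutia direction, neighbour direction
#' relative to the minutia direction) — all invariant to global rotation and
#' translation of the template.
#'
#' @param template A `minutiae_template`.
#' @param k Neighbour count (default 5); templates with fewer minutiae use
#'   all available neighbours.
#' @return A list of descriptor matrices (one per minutia, columns
#'   `dist`, `bearing`, `relangle`), empty matrices when `k = 0`.
#' @export
local_descriptors <- function(template, k = 5L) {
  m <- template$minutiae
  n <- nrow(m)
  out <- vector("list", n)
  if (n == 0) return(out)
  if (k <= 0) {
    for (i in seq_len(n))
      out[[i]] <- matrix(numeric(0), 0, 3,
                         dimnames = list(NULL, c("dist", "bearing", "relangle")))
    return(out)
  }
  d <- as.matrix(stats::dist(m[, c("x", "y")]))
  diag(d) <- Inf
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(min(k, n - 1))]
    dx <- m$x[nb] - m$x[i]; dy <- m$y[nb] - m$y[i]
    desc <- cbind(dist = sqrt(dx^2 + dy^2),
                  bearing = (atan2(dy, dx) - m$angle[i]) %% (2 * pi),
                  relangle = (m$angle[nb] - m$angle[i]) %% (2 * pi))
    out[[i]] <- desc
  }
  out
}

## similarity of two descriptors: greedy neighbour pairing on a normalized
## cost (distance in ridge units, angles in 30-degree units)
descriptor_similarity <- function(da, db) {
  na <- nrow(da); nb <- nrow(db)
  if (na == 0 || nb == 0) return(0)
  cost <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    cost[i, j] <- abs(da[i, "dist"] - db[j, "dist"]) / 8 +
      angdiff(da[i, "bearing"], db[j, "bearing"]) / (pi / 6) +
      angdiff(da[i, "relangle"], db[j, "relangle"]) / (pi / 6)
  }
  s <- 0
  for (r in seq_len(min(na, nb))) {
    ix <- arrayInd(which.min(cost), dim(cost))
    s <- s + exp(-cost[ix[1], ix[2]])
    cost[ix[1], ] <- Inf; cost[, ix[2]] <- Inf
  }
  s / max(na, nb)
}

#' Match two minutiae templates
#'
#' Clean-room minutiae matcher: candidate correspondences are proposed from
#' local-descriptor similarity, a rigid transform is found by consensus
#' voting over (rotation, translation), refined by least squares, and
#' aligned minutiae within `dist_tol` px and `angle_tol` are counted as
#' mated. The score is `n_mated / max(min(|a|, |b|), floor)` with a floor of
#' 8 minutiae to damp tiny templates; it is symmetric and lies in [0, 1].
#'
#' Both templates must be in the normalized 8 px/ridge space — frequency
#' normalization is what makes cross-age comparison valid.
#'
#' @param a,b `minutiae_template` objects at resolution 8.
#' @param k Descriptor neighbour count (default 5).
#' @param dist_tol Mating distance tolerance in px (default 8).
#' @param angle_tol Mating angle tolerance in radians (default pi/6).
#' @param score_floor Denominator floor (default 8).
#' @param max_rotation Largest admissible alignment rotation in radians
#'   (default pi/3); verification compares upright finger presentations, so
#'   unbounded rotation search only admits spurious alignments. Set to pi
#'   to disable the bound.
#' @param max_translation Largest admissible displacement of the template
#'   centroid under the alignment, in px (default 40, i.e. 5 ridge
#'   periods); the acquisition aperture centres the finger, so genuine
#'   alignments are near-concentric. Set to Inf to disable.
#' @return A `match_result`: `score`, `paired_minutiae` (two-column index
#'   matrix), `transform` (rotation, tx, ty), `n_overlap`.
#' @export
match_templates <- function(a, b, k = 5L, dist_tol = 8, angle_tol = pi / 6,
                            score_floor = 8L, max_rotation = pi / 3,
                            max_translation = 40) {
  stopifnot(inherits(a, "minutiae_template"), inherits(b, "minutiae_template"))
  if (abs(a$resolution - 8) > 0.5 || abs(b$resolution - 8) > 0.5)
    stop(sprintf(
      "templates must be in the 8 px/ridge normalized space (got %.3g and %.3g); run normalize_ridge_frequency before extraction",
      a$resolution, b$resolution))
  empty <- list(score = 0, paired_minutiae = matrix(integer(0), 0, 2),
                transform = c(rotation = 0, tx = 0, ty = 0), n_overlap = 0L)
  class(empty) <- "match_result"
  na <- nrow(a$minutiae); nb <- nrow(b$minutiae)
  if (na == 0 || nb == 0) return(empty)
  ## descriptor similarity, vectorized over all pairs: neighbours are
  ## compared rank-by-rank (sorted by distance, as local_descriptors
  ## returns them), which agrees with the greedy pairing for clean
  ## neighbourhoods and is an order of magnitude faster
  da <- local_descriptors(a, k); db <- local_descriptors(b, k)
  sim <- matrix(0, na, nb)
  if (k > 0) {
    kk <- min(k, na - 1, nb - 1)
    if (kk >= 1) {
      for (r in seq_len(kk)) {
        d_a <- vapply(da, function(d) d[r, "dist"], numeric(1))
        d_b <- vapply(db, function(d) d[r, "dist"], numeric(1))
        b_a <- vapply(da, function(d) d[r, "bearing"], numeric(1))
        b_b <- vapply(db, function(d) d[r, "bearing"], numeric(1))
        r_a <- vapply(da, function(d) d[r, "relangle"], numeric(1))
        r_b <- vapply(db, function(d) d[r, "relangle"], numeric(1))
        cost <- abs(outer(d_a, d_b, `-`)) / 8 +
          outer(b_a, b_b, angdiff) / (pi / 6) +
          outer(r_a, r_b, angdiff) / (pi / 6)
        sim <- sim + exp(-cost)
      }
      sim <- sim / kk
    }
  }
  ## candidate pairs: exhaustive for ordinary template sizes, otherwise the
  ## union of top-8 per row and per column by descriptor similarity
  cand <- matrix(FALSE, na, nb)
  if (k <= 0 || na * nb <= 2500) {
    cand[] <- TRUE
  } else {
    topn <- 8L
    for (i in seq_len(na))
      cand[i, order(sim[i, ], decreasing = TRUE)[seq_len(min(topn, nb))]] <- TRUE
    for (j in seq_len(nb))
      cand[order(sim[, j], decreasing = TRUE)[seq_len(min(topn, na))], j] <- TRUE
  }
  idx <- which(cand, arr.ind = TRUE)
  ## each candidate implies a rigid transform: rotation from angle difference
  rot <- (b$minutiae$angle[idx[, 2]] - a$minutiae$angle[idx[, 1]]) %% (2 * pi)
  ax <- a$minutiae$x[idx[, 1]]; ay <- a$minutiae$y[idx[, 1]]
  bx <- b$minutiae$x[idx[, 2]]; by <- b$minutiae$y[idx[, 2]]
  tx <- bx - (cos(rot) * ax - sin(rot) * ay)
  ty <- by - (sin(rot) * ax + cos(rot) * ay)
  ## consensus voting: supporters agree in rotation (15 deg) and translation
  nc <- nrow(idx)
  simv <- sim[idx]
  ca <- c(mean(a$minutiae$x), mean(a$minutiae$y))
  cb <- c(mean(b$minutiae$x), mean(b$minutiae$y))
  cdisp <- sqrt((cos(rot) * ca[1] - sin(rot) * ca[2] + tx - cb[1])^2 +
                (sin(rot) * ca[1] + cos(rot) * ca[2] + ty - cb[2])^2)
  admissible <- abs(vapply(rot, rot_signed, numeric(1))) <= max_rotation &
    cdisp <= max_translation
  stats <- vector("list", nc)
  for (c0 in seq_len(nc)) {
    if (!admissible[c0]) next
    sup <- which(angdiff(rot, rot[c0]) < pi / 12 &
                   abs(tx - tx[c0]) < 12 & abs(ty - ty[c0]) < 12)
    ## one-to-one support: count distinct minutiae, not raw candidate pairs
    n1 <- min(length(unique(idx[sup, 1])), length(unique(idx[sup, 2])))
    stats[[c0]] <- list(n = n1, sc = sum(simv[sup]), sup = sup,
                        rot = rot[c0])
  }
  ok <- which(!vapply(stats, is.null, logical(1)))
  if (!length(ok)) return(empty)
  ord <- ok[order(-vapply(stats[ok], `[[`, numeric(1), "n"),
                  -vapply(stats[ok], `[[`, numeric(1), "sc"),
                  abs(vapply(stats[ok], function(s) rot_signed(s$rot),
                             numeric(1))))]
  ## evaluate the leading clusters through refinement + mating and keep the
  ## outcome with the most mated pairs (ties: summed descriptor similarity,
  ## then smallest rotation) — the initial vote can rank a spurious cluster
  ## first when genuine correspondences are jittered
  greedy_mate <- function(tr, dtol) {
    pa <- cbind(a$minutiae$x, a$minutiae$y) %*% t(rot_mat(tr$rotation))
    pa <- sweep(pa, 2, c(tr$tx, tr$ty), `+`)
    angs_a <- (a$minutiae$angle + tr$rotation) %% (2 * pi)
    dmat <- outer(pa[, 1], b$minutiae$x, `-`)^2 +
            outer(pa[, 2], b$minutiae$y, `-`)^2
    amat <- outer(angs_a, b$minutiae$angle, angdiff)
    dmat[sqrt(dmat) > dtol | amat > angle_tol] <- Inf
    newp <- matrix(integer(0), 0, 2)
    while (any(is.finite(dmat))) {
      ix <- arrayInd(which.min(dmat), dim(dmat))
      newp <- rbind(newp, ix)
      dmat[ix[1], ] <- Inf; dmat[, ix[2]] <- Inf
    }
    newp
  }
  best_res <- NULL
  for (c0 in utils::head(ord, 10L)) {
    sup <- stats[[c0]]$sup
    tr0 <- fit_rigid(cbind(ax[sup], ay[sup]), cbind(bx[sup], by[sup]))
    tr <- tr0
    ## refine on a tight inlier band so random agreements cannot drag the
    ## fit; the final mating uses the full tolerance. The refinement must
    ## stay near the seed cluster's transform — drifting away means the
    ## iteration latched onto a different (chance) configuration
    inl <- matrix(integer(0), 0, 2)
    for (iter in 1:3) {
      newp <- greedy_mate(tr, 0.6 * dist_tol)
      if (nrow(newp) == nrow(inl) &&
          (nrow(newp) == 0 || all(newp == inl))) { inl <- newp; break }
      inl <- newp
      if (nrow(inl) >= 2) {
        tr2 <- fit_rigid(cbind(a$minutiae$x[inl[, 1]], a$minutiae$y[inl[, 1]]),
                         cbind(b$minutiae$x[inl[, 2]], b$minutiae$y[inl[, 2]]))
        if (angdiff(tr2$rotation, tr0$rotation) > pi / 18 ||
            sqrt((tr2$tx - tr0$tx)^2 + (tr2$ty - tr0$ty)^2) > 15) break
        tr <- tr2
      } else break
    }
    pairs <- greedy_mate(tr, dist_tol)
    cd <- sqrt((cos(tr$rotation) * ca[1] - sin(tr$rotation) * ca[2] +
                  tr$tx - cb[1])^2 +
               (sin(tr$rotation) * ca[1] + cos(tr$rotation) * ca[2] +
                  tr$ty - cb[2])^2)
    if (abs(rot_signed(tr$rotation)) > max_rotation ||
        cd > max_translation) next
    cand_res <- list(pairs = pairs, tr = tr, sc = stats[[c0]]$sc)
    if (is.null(best_res) || nrow(pairs) > nrow(best_res$pairs) ||
        (nrow(pairs) == nrow(best_res$pairs) &&
           (cand_res$sc > best_res$sc + 1e-12 ||
              (abs(cand_res$sc - best_res$sc) <= 1e-12 &&
                 abs(rot_signed(tr$rotation)) <
                   abs(rot_signed(best_res$tr$rotation)) - 1e-12))))
      best_res <- cand_res
  }
  if (is.null(best_res)) return(empty)
  pairs <- best_res$pairs
  tr <- best_res$tr
  n_mated <- nrow(pairs)
  score <- n_mated / max(min(na, nb), score_floor)
  structure(list(score = min(1, score), paired_minutiae = pairs,
                 transform = c(rotation = rot_signed(tr$rotation),
                               tx = tr$tx, ty = tr$ty),
                 n_overlap = as.integer(min(na, nb))),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> score %.3f, %d mated, rotation %.1f deg\n",
              x$score, nrow(x$paired_minutiae),
              x$transform["rotation"] * 180 / pi))
  invisible(x)
}

rot_mat <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

rot_signed <- function(th) {
  th <- th %% (2 * pi)
  if (th > pi) th - 2 * pi else th
}

## least-squares rigid transform (Kabsch, 2-D) mapping pts_a onto pts_b
fit_rigid <- function(pts_a, pts_b) {
  ca <- colMeans(pts_a); cb <- colMeans(pts_b)
  A <- sweep(pts_a, 2, ca); B <- sweep(pts_b, 2, cb)
  H <- t(A) %*% B
  th <- atan2(H[1, 2] - H[2, 1], H[1, 1] + H[2, 2])
  t_ <- cb - as.vector(rot_mat(th) %*% ca)
  list(rotation = th, tx = t_[1], ty = t_[2])
}
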