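## Binary thinning and crossing-number machinery.
##
## Zhang-Suen thinning is implemented directly (vectorized over the whole
## raster with shifted copies); it produces the 1-px, 8-connected centerline
## the crossing-number minutiae scan expects.

shift_mat <- function(p, dy, dx) {
  ## p is a zero-padded matrix; returns the 8-neighbour plane of the interior
  h <- nrow(p) - 2L; w <- ncol(p) - 2L
  p[(2L + dy):(1L + dy + h), (2L + dx):(1L + dx + w)]
}

neighbour_planes <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  ## p2..p9 clockwise from north (y decreasing is up)
  list(
    n  = shift_mat(p, -1L,  0L), ne = shift_mat(p, -1L,  1L),
    e  = shift_mat(p,  0L,  1L), se = shift_mat(p,  1L,  1L),
    s  = shift_mat(p,  1L,  0L), sw = shift_mat(p,  1L, -1L),
    w  = shift_mat(p,  0L, -1L), nw = shift_mat(p, -1L, -1L))
}

#' Thin a binary ridge raster to a 1-px skeleton
#'
#' Zhang-Suen thinning followed by a cleanup pass that removes remaining
#' 2x2 foreground blocks while preserving 8-connectivity, so the result is a
#' true 1-px-wide centerline suitable for crossing-number analysis.
#'
#' @param binary Logical or 0/1 matrix, ridge = TRUE/1.
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
skeletonize <- function(binary) {
  m <- matrix(as.integer(binary != 0), nrow(binary), ncol(binary))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      np <- neighbour_planes(m)
      B <- np$n + np$ne + np$e + np$se + np$s + np$sw + np$w + np$nw
      seqs <- list(np$n, np$ne, np$e, np$se, np$s, np$sw, np$w, np$nw, np$n)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + as.integer(seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      if (step == 1L) {
        c1 <- np$n * np$e * np$s; c2 <- np$e * np$s * np$w
      } else {
        c1 <- np$n * np$e * np$w; c2 <- np$n * np$s * np$w
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 == 0L & c2 == 0L
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  ## staircase cleanup: delete simple pixels participating in a 2x2 block
  repeat {
    np <- neighbour_planes(m)
    blk <- m == 1L & ((np$e == 1L & np$s == 1L & np$se == 1L) |
                      (np$w == 1L & np$s == 1L & np$sw == 1L) |
                      (np$e == 1L & np$n == 1L & np$ne == 1L) |
                      (np$w == 1L & np$n == 1L & np$nw == 1L))
    if (!any(blk)) break
    seqs <- list(np$n, np$ne, np$e, np$se, np$s, np$sw, np$w, np$nw, np$n)
    A <- matrix(0L, nrow(m), ncol(m))
    for (i in 1:8) A <- A + as.integer(seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
    cand <- which(blk & A == 1L)
    if (!length(cand)) cand <- which(blk)
    ## remove sequentially, re-checking simpleness locally
    removed <- FALSE
    for (ix in cand) {
      yx <- arrayInd(ix, dim(m))
      if (is_simple_pixel(m, yx[1], yx[2])) { m[ix] <- 0L; removed <- TRUE }
    }
    if (!removed) break
  }
  m
}

## deletable without changing local topology (exactly one 0->1 transition
## around the 8-neighbourhood and more than one neighbour)
is_simple_pixel <- function(m, y, x) {
  h <- nrow(m); w <- ncol(m)
  nb <- function(dy, dx) {
    yy <- y + dy; xx <- x + dx
    if (yy < 1 || yy > h || xx < 1 || xx > w) 0L else m[yy, xx]
  }
  p <- c(nb(-1, 0), nb(-1, 1), nb(0, 1), nb(1, 1),
         nb(1, 0), nb(1, -1), nb(0, -1), nb(-1, -1))
  a <- sum(p == 0L & c(p[-1], p[1]) == 1L)
  a == 1L && sum(p) >= 2L
}

#' Crossing numbers of every skeleton pixel
#'
#' The crossing number (CN) is half the count of 0/1 alternations around a
#' pixel's 8-neighbourhood: CN 1 marks a ridge ending, CN 3 a bifurcation.
#'
#' @param skel 0/1 skeleton matrix.
#' @return Integer matrix; 0 off the skeleton.
#' @export
crossing_number_map <- function(skel) {
  m <- matrix(as.integer(skel != 0), nrow(skel), ncol(skel))
  np <- neighbour_planes(m)
  seqs <- list(np$n, np$ne, np$e, np$se, np$s, np$sw, np$w, np$nw, np$n)
  tr <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) tr <- tr + abs(seqs[[i + 1L]] - seqs[[i]])
  cn <- tr %/% 2L
  cn[m == 0L] <- 0L
  ## isolated pixels have CN 0 but are not features; leave 0
  cn
}

## walk along the skeleton from (y, x) starting into an unvisited neighbour,
## up to n steps; returns the visited path (matrix of y, x)
trace_skeleton <- function(skel, y, x, n = 6L, forbid = NULL) {
  h <- nrow(skel); w <- ncol(skel)
  path <- matrix(c(y, x), ncol = 2)
  visited <- paste(y, x)
  if (!is.null(forbid)) visited <- c(visited, paste(forbid[, 1], forbid[, 2]))
  cy <- y; cx <- x
  for (i in seq_len(n)) {
    found <- FALSE
    for (d in list(c(-1, 0), c(0, 1), c(1, 0), c(0, -1),
                   c(-1, 1), c(1, 1), c(1, -1), c(-1, -1))) {
      yy <- cy + d[1]; xx <- cx + d[2]
      if (yy < 1 || yy > h || xx < 1 || xx > w) next
      if (skel[yy, xx] == 0L) next
      key <- paste(yy, xx)
      if (key %in% visited) next
      path <- rbind(path, c(yy, xx)); visited <- c(visited, key)
      cy <- yy; cx <- xx; found <- TRUE
      break
    }
    if (!found) break
  }
  path
}

## remove skeleton branches shorter than min_len px that end in a ridge ending
prune_spurs <- function(skel, min_len = 8L) {
  m <- skel
  repeat {
    cn <- crossing_number_map(m)
    ends <- which(cn == 1L, arr.ind = TRUE)
    if (!nrow(ends)) break
    removed <- FALSE
    for (i in seq_len(nrow(ends))) {
      y <- ends[i, 1]; x <- ends[i, 2]
      if (m[y, x] == 0L) next
      path <- trace_skeleton(m, y, x, n = min_len)
      ## spur if the walk hits a branch point before min_len steps
      hit <- which(cn[path] >= 3L)
      if (length(hit) && hit[1] <= min_len) {
        drop <- path[seq_len(hit[1] - 1L), , drop = FALSE]
        m[drop] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}
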