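#' Monochrome raw finger image
#'
#' The basic container used throughout the pipeline: a 2-D intensity raster
#' together with its sampling density (pixels per inch), sensor bit depth and
#' an optional boolean foreground mask. Intensities are digital numbers (DN)
#' in `[0, max_dn]`; a 12-bit sensor has `max_dn = 4095`.
#'
#' Coordinates are 0-based with the origin at the top-left pixel center,
#' x to the right and y down, so pixel `(x, y)` is `pixels[y + 1, x + 1]`.
#' Angles are radians measured from the +x axis; ridge orientations are
#' defined modulo pi, minutia directions modulo 2*pi.
#'
#' @param pixels Numeric matrix, rows indexed by y, columns by x.
#' @param ppi Sampling density in pixels per inch (25400 um per inch).
#' @param bit_depth One of 8, 12, 16.
#' @param max_dn Saturation value; defaults to `2^bit_depth - 1`.
#' @param mask Optional logical matrix of the same dimensions marking the
#'   finger foreground. `NULL` means everything is foreground.
#' @return An object of class `raw_image`.
#' @export
raw_image <- function(pixels, ppi, bit_depth = 12, max_dn = NULL, mask = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("bit_depth must be 8, 12 or 16")
  if (!is.numeric(ppi) || length(ppi) != 1L || ppi <= 0)
    stop("ppi must be a single positive number")
  if (is.null(max_dn)) max_dn <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > max_dn, na.rm = TRUE))
    stop("pixel intensities must lie in [0, max_dn]")
  if (!is.null(mask)) {
    stopifnot(is.logical(mask))
    if (!identical(dim(mask), dim(pixels)))
      stop("mask dimensions must match the pixel raster")
  }
  structure(
    list(pixels = pixels, ppi = ppi, bit_depth = as.integer(bit_depth),
         max_dn = max_dn, mask = mask),
    class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raw_image> %d x %d px, %d-bit (max_dn %d), %.0f PPI%s\n",
              d[2], d[1], x$bit_depth, as.integer(x$max_dn), x$ppi,
              if (is.null(x$mask)) "" else
                sprintf(", mask %.0f%% fg", 100 * mean(x$mask))))
  invisible(x)
}

#' @export
dim.raw_image <- function(x) dim(x$pixels)

img_mask <- function(img) {
  if (is.null(img$mask)) matrix(TRUE, nrow(img$pixels), ncol(img$pixels))
  else img$mask
}

clip_dn <- function(v, max_dn) pmin(pmax(v, 0), max_dn)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's random stream.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## derive a child seed from a master seed and counters; keeps all campaign
## randomness reproducible from one integer (kept < 2^31)
child_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) s <- (s * 69069 + as.double(k) * 2654435761 + 1) %% 2147483647
  as.integer(s)
}

angdiff <- function(a, b, mod = 2 * pi) {
  d <- (a - b) %% mod
  pmin(d, mod - d)
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}
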