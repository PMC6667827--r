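#' Read a monochrome finger image
#'
#' Supports PNG, TIFF and PGM (8- or 16-bit containers). Bit depth is taken
#' from a sidecar JSON (`<path>.json`, written by [write_image()]) when
#' present, otherwise inferred from the maximum observed DN (<= 255: 8-bit,
#' <= 4095: 12-bit, else 16-bit). PPI is semantically required: it must come
#' from the sidecar or the `ppi` override.
#'
#' @param path Image file path.
#' @param ppi Optional PPI override.
#' @return A [raw_image()].
#' @export
read_image <- function(path, ppi = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  if (is.null(ppi)) ppi <- meta$ppi
  if (is.null(ppi)) stop("PPI is required: supply a sidecar JSON or the ppi argument")
  if (ext == "pgm") {
    dn <- arr   # read_pgm returns DN directly
  } else {
    ## png/tiff return [0,1]; an 8-bit container yields only multiples of
    ## 1/255 (= 257/65535), a 16-bit container holds the data natively
    v16 <- round(arr * 65535)
    dn <- if (all(v16 %% 257 == 0)) v16 / 257 else v16
  }
  bit_depth <- meta$bit_depth
  if (is.null(bit_depth)) {
    mx <- max(dn)
    bit_depth <- if (mx <= 255) 8L else if (mx <= 4095) 12L else 16L
  }
  max_dn <- as.numeric(if (!is.null(meta$max_dn)) meta$max_dn
                       else 2^bit_depth - 1)
  storage.mode(dn) <- "double"
  raw_image(pmin(dn, max_dn), ppi = as.numeric(ppi),
            bit_depth = as.integer(bit_depth), max_dn = max_dn)
}

#' Write a raw image with its sidecar metadata
#'
#' 8-bit images go to 8-bit containers; 12-bit data is stored natively in a
#' 16-bit container (no left shift) with the true `max_dn` recorded in the
#' sidecar JSON so DN-scale parameters keep their meaning.
#'
#' @param img A [raw_image()].
#' @param path Output path (`.png` or `.pgm`).
#' @param sidecar Write `<path>.json` with ppi/bit_depth/max_dn (default TRUE).
#' @export
write_image <- function(img, path, sidecar = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (img$bit_depth == 8) png::writePNG(img$pixels / 255, path)
    else write_png16(img$pixels, path)
  } else if (ext == "pgm") {
    write_pgm(img$pixels, path,
              maxval = if (img$bit_depth == 8) 255L else 65535L)
  } else stop("unsupported output format: .", ext)
  if (sidecar)
    jsonlite::write_json(list(ppi = img$ppi, bit_depth = img$bit_depth,
                              max_dn = img$max_dn),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

## minimal 16-bit grayscale PNG encoder. The png package only writes 8-bit
## channels, so the 16-bit container (IHDR depth 16, colour type 0, filter 0
## scanlines, zlib IDAT via memCompress) is assembled directly. DN values
## are stored natively (no left shift); the sidecar records the true depth.
write_png16 <- function(px, path) {
  v <- as.integer(round(t(px)))          # row-major sample order
  if (any(v < 0 | v > 65535)) stop("pixels exceed the 16-bit container")
  h <- nrow(px); w <- ncol(px)
  ## scanlines: filter byte 0 + big-endian 16-bit samples
  bytes <- matrix(as.raw(0), nrow = 2 * w + 1, ncol = h)
  vm <- matrix(v, nrow = w, ncol = h)
  bytes[seq(2, 2 * w, by = 2), ] <- as.raw(vm %/% 256L)
  bytes[seq(3, 2 * w + 1, by = 2), ] <- as.raw(vm %% 256L)
  idat <- memCompress(as.vector(bytes), "gzip")   # zlib stream
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(u32(length(data)), body, u32(png_crc32(body)))
  }
  ihdr <- c(u32(w), u32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

.crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    tab[n + 1] <- c
  }
  tab
})

png_crc32 <- function(bytes) {
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints)
    crc <- bitwXor(.crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  bitwXor(crc, -1L)
}

## plain (P2) and binary (P5) PGM; returns/accepts DN matrices
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  toks <- integer(0)
  ## read header tokens (width, height, maxval), skipping comments
  buf <- character(0)
  while (length(toks) < 3) {
    ch <- readChar(con, 1)
    if (ch == "#") { repeat { c2 <- readChar(con, 1); if (c2 == "\n") break } ; next }
    if (grepl("[0-9]", ch)) buf <- c(buf, ch)
    else if (length(buf)) { toks <- c(toks, as.integer(paste(buf, collapse = ""))); buf <- character(0) }
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  n <- w * h
  vals <- if (magic == "P5") {
    if (maxval < 256) as.integer(readBin(con, "raw", n))
    else readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big")
  } else {
    as.integer(scan(con, what = integer(), n = n, quiet = TRUE))
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(px, path, maxval = 65535L) {
  con <- file(path, "wb")
  on.exit(close(con))
  h <- nrow(px); w <- ncol(px)
  writeChar(sprintf("P5\n%d %d\n%d\n", w, h, maxval), con, eos = NULL)
  v <- as.integer(round(t(px)))
  if (maxval < 256) writeBin(as.raw(v), con)
  else writeBin(v, con, size = 2, endian = "big")
  invisible(path)
}

#' Pipeline configuration
#'
#' One serializable object holding every tunable of the processing chain.
#' Unknown keys in a config file are rejected by name.
#'
#' @param blur_radius_px,noise_floor_dn,upper_percentile See
#'   [preprocess_params()].
#' @param target_px_per_ridge Normalization target (default 8).
#' @param border_px,spur_px,min_sep_px Minutiae filter thresholds.
#' @param descriptor_k Matcher descriptor neighbour count.
#' @param seed Default seed for seeded operations.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(blur_radius_px = 24, noise_floor_dn = 64,
                            upper_percentile = 99.5,
                            target_px_per_ridge = 8,
                            border_px = 8, spur_px = 8, min_sep_px = 4,
                            descriptor_k = 5, seed = 1) {
  structure(list(blur_radius_px = blur_radius_px,
                 noise_floor_dn = noise_floor_dn,
                 upper_percentile = upper_percentile,
                 target_px_per_ridge = target_px_per_ridge,
                 border_px = border_px, spur_px = spur_px,
                 min_sep_px = min_sep_px, descriptor_k = descriptor_k,
                 seed = seed),
            class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## internal: raw image -> template under given params/target
pipeline_template <- function(img, params = preprocess_params(),
                              target_px_per_ridge = 8,
                              border_px = 8, spur_px = 8, min_sep_px = 4) {
  enh <- preprocess_image(img, params)
  norm <- normalize_ridge_frequency(enh, target_px_per_ridge)
  eb <- enhance_and_binarize(norm$image, expected_period = target_px_per_ridge)
  sk <- skeletonize(eb$binary)
  tpl <- extract_minutiae(sk, eb$mask, eb$ridge_map,
                          resolution = eb$period,
                          border_px = border_px, spur_px = spur_px,
                          min_sep_px = min_sep_px, binary = eb$binary)
  tpl$provenance <- list(
    blur_radius_px = params$blur_radius_px,
    noise_floor_dn = params$noise_floor_dn,
    upper_percentile = params$upper_percentile,
    target_px_per_ridge = target_px_per_ridge,
    original_period = norm$original_period,
    scale = norm$scale,
    border_px = border_px, spur_px = spur_px, min_sep_px = min_sep_px)
  tpl
}

#' Run the full processing pipeline on one image
#'
#' Executes foreground segmentation (when the image carries no mask),
#' flat-field correction, background smoothing, bimodal stretch,
#' ridge-frequency normalization, oriented binarization, skeletonization and
#' minutiae extraction in order, logging every stage's parameters and
#' measured quantities into the template provenance. Stage failures
#' propagate with the stage name.
#'
#' @param img A [raw_image()] or image file path.
#' @param config A [pipeline_config()].
#' @param gain_map Optional flat-field gain raster.
#' @return A list: `template`, `normalized` (the normalized image), `stages`
#'   (per-stage log).
#' @export
run_pipeline <- function(img, config = pipeline_config(), gain_map = NULL) {
  if (is.character(img)) img <- read_image(img)
  stages <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(img$mask)) {
    img$mask <- step("segment", segment_foreground(img))
    stages$segment <- list(foreground_fraction = mean(img$mask))
  } else stages$segment <- list(foreground_fraction = mean(img$mask))
  if (!is.null(gain_map)) {
    img <- step("flat_field", flat_field_correct(img, gain_map))
    stages$flat_field <- list(applied = TRUE)
  } else stages$flat_field <- list(applied = FALSE)
  img <- step("smooth_background",
              smooth_background(img, config$blur_radius_px))
  stages$smooth_background <- list(blur_radius_px = config$blur_radius_px)
  img <- step("bimodal_stretch",
              bimodal_stretch(img, config$noise_floor_dn,
                              config$upper_percentile))
  stages$bimodal_stretch <- list(noise_floor_dn = config$noise_floor_dn,
                                 upper_percentile = config$upper_percentile)
  norm <- step("normalize_ridge_frequency",
               normalize_ridge_frequency(img, config$target_px_per_ridge))
  stages$normalize <- norm$provenance
  eb <- step("enhance_and_binarize",
             enhance_and_binarize(norm$image,
                                  expected_period = config$target_px_per_ridge))
  stages$binarize <- list(period = eb$period)
  sk <- step("skeletonize", skeletonize(eb$binary))
  stages$skeletonize <- list(pixels = sum(sk))
  tpl <- step("extract_minutiae",
              extract_minutiae(sk, eb$mask, eb$ridge_map,
                               resolution = eb$period,
                               border_px = config$border_px,
                               spur_px = config$spur_px,
                               min_sep_px = config$min_sep_px,
                               binary = eb$binary))
  stages$extract <- list(n_minutiae = nrow(tpl$minutiae))
  tpl$provenance <- c(list(config = unclass(config)), stages)
  list(template = tpl, normalized = norm$image, stages = stages)
}
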