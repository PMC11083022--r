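#' @importFrom stats median quantile sd uniroot lm coef setNames
#' @importFrom utils head tail write.csv read.csv
NULL

# Internal pixel conventions
# ------------------------------------------------------------------
# A fundus image is an integer array dim c(h, w, 3) with channels ordered
# blue, green, red (the order the enhancement chain merges back to) and
# values in 0..255.  Masks are integer matrices [row, col].  EBImage works
# in (x, y) = (col, row) order and on [0, 1] doubles, so every call into it
# transposes on the way in and out.

.as_ebimage <- function(m) t(m) / 255
.from_ebimage <- function(e) {
  m <- t(as.matrix(e)) * 255
  m
}

#' Construct and validate a fundus image array
#'
#' A fundus image is stored as an integer array `c(height, width, 3)` with
#' channels ordered blue, green, red and intensities in 0..255.
#'
#' @param pixels numeric array `c(h, w, 3)`, values 0..255.
#' @return the validated array with class `fundus_image`.
#' @export
fundus_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("fundus image must be an h x w x 3 array")
  d <- dim(pixels)
  if (d[1] < 64L || d[2] < 64L)
    stop("fundus image must be at least 64 x 64 pixels")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  class(pixels) <- c("fundus_image", class(pixels))
  pixels
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<fundus_image %d x %d px, channels B/G/R, range [%d, %d]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Read a fundus photograph
#'
#' Reads an 8-bit PNG/TIFF/JPEG image and returns it in the package's
#' blue/green/red channel order. Grayscale files are replicated to three
#' channels.
#'
#' @param path file path.
#' @return a [fundus_image()].
#' @export
read_fundus <- function(path) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]       # drop alpha
  a <- aperm(a, c(2L, 1L, 3L))                             # (x,y,c) -> (row,col,c)
  a <- a[, , c(3L, 2L, 1L), drop = FALSE]                  # RGB -> BGR
  fundus_image(round(a * 255))
}

#' Write a fundus image to PNG
#'
#' @param img a [fundus_image()] (BGR channel order).
#' @param path output path (PNG).
#' @export
write_fundus <- function(img, path) {
  a <- unclass(img)[, , c(3L, 2L, 1L), drop = FALSE] / 255  # BGR -> RGB
  a <- aperm(a, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path, type = "png")
  invisible(path)
}

#' Read / write label and binary masks
#'
#' Masks are stored as 8-bit grayscale PNG whose raw pixel value is the
#' label itself (0 = background, 1 = artery, 2 = vein for vessel masks;
#' 0/1 for binary masks).
#'
#' @param path file path.
#' @return integer matrix `[row, col]` of labels.
#' @export
read_mask <- function(path) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- t(round(a * 255))
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_mask
#' @param mask integer matrix of labels (small values, < 256).
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(t(mask) / 255, path, type = "png")
  invisible(path)
}

#' Detect the retinal field of view
#'
#' Fundus photographs carry a black border around the circular field of
#' view. A pixel belongs to the border when its brightest channel does not
#' exceed `threshold`; the largest connected bright region, with interior
#' holes filled, is taken as the field of view.
#'
#' @param img a [fundus_image()].
#' @param threshold border intensity threshold on the per-pixel channel
#'   maximum (default 10 of 255).
#' @return binary integer matrix, 1 = field of view.
#' @export
compute_border_mask <- function(img, threshold = 10) {
  stopifnot(length(dim(img)) == 3L)
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  bright <- mx > threshold
  if (!any(bright)) stop("no retinal field of view detected")
  lab <- EBImage::bwlabel(t(bright))
  tabs <- tabulate(as.integer(lab))
  keep <- which.max(tabs)
  fov <- lab == keep
  fov <- EBImage::fillHull(fov)
  m <- t(as.matrix(fov) > 0)
  storage.mode(m) <- "integer"
  m
}

#' Preprocessing configuration
#'
#' Parameters of the fundus enhancement chain: CLAHE on the green channel
#' (relative clip limit and tile grid), a green attenuation factor, and the
#' gamma used for the final lookup-table adjustment.
#'
#' @param clahe_clip_limit relative CLAHE clip limit (> 0; 1.0 leaves a
#'   uniform region untouched).
#' @param clahe_tile integer length-2, tile grid (rows, cols).
#' @param green_scale multiplier applied to the equalized green channel,
#'   in (0, 1].
#' @param gamma gamma for [gamma_adjust()] (> 0).
#' @param border_threshold intensity threshold for [compute_border_mask()].
#' @param crop_margin margin (px) kept around the field-of-view bounding
#'   box when cropping.
#' @return a list with class `preprocess_config`.
#' @export
preprocess_config <- function(clahe_clip_limit = 1.0, clahe_tile = c(25L, 25L),
                              green_scale = 0.8, gamma = 1.2,
                              border_threshold = 10, crop_margin = 5L) {
  stopifnot(clahe_clip_limit > 0, all(clahe_tile >= 1), length(clahe_tile) == 2L,
            green_scale > 0, green_scale <= 1, gamma > 0)
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_tile = as.integer(clahe_tile),
                 green_scale = green_scale, gamma = gamma,
                 border_threshold = border_threshold,
                 crop_margin = as.integer(crop_margin)),
            class = "preprocess_config")
}

#' Enhance a fundus image
#'
#' Applies contrast-limited adaptive histogram equalization (CLAHE) to the
#' green channel, attenuates it by `green_scale`, merges it back with the
#' untouched blue and red channels, and zeroes everything outside the
#' field-of-view mask.
#'
#' @param img a [fundus_image()].
#' @param mask binary field-of-view matrix from [compute_border_mask()].
#' @param cfg a [preprocess_config()].
#' @return enhanced [fundus_image()], same dimensions.
#' @export
enhance <- function(img, mask, cfg = preprocess_config()) {
  d <- dim(img)
  if (!all(dim(mask) == d[1:2])) stop("image and mask shapes differ")
  g <- img[, , 2]
  # the equalizer needs dimensions divisible by the tile grid: pad by edge
  # replication and crop back
  ph <- ceiling(d[1] / cfg$clahe_tile[1]) * cfg$clahe_tile[1]
  pw <- ceiling(d[2] / cfg$clahe_tile[2]) * cfg$clahe_tile[2]
  gp <- g[pmin(seq_len(ph), d[1]), pmin(seq_len(pw), d[2])]
  if (diff(range(gp)) == 0) {
    # zero dynamic range: equalization with a clipped (flat) histogram is
    # the identity
    eqm <- g
  } else {
    eq <- EBImage::clahe(.as_ebimage(gp),
                         nx = cfg$clahe_tile[2], ny = cfg$clahe_tile[1],
                         bins = 256L, limit = cfg$clahe_clip_limit,
                         keep.range = TRUE)
    eqm <- .from_ebimage(eq)[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  }
  g2 <- round(cfg$green_scale * eqm)
  g2 <- pmin(pmax(g2, 0), 255)
  out <- unclass(img)
  out[, , 2] <- g2
  keep <- mask > 0
  for (ch in 1:3) out[, , ch] <- out[, , ch] * keep
  fundus_image(out)
}

#' Gamma adjustment via lookup table
#'
#' Each intensity v maps to `round(255 * (v/255)^(1/gamma))`, applied
#' through a 256-entry lookup table, so gamma > 1 brightens mid-tones.
#'
#' @param img a [fundus_image()] or an intensity matrix.
#' @param gamma gamma value (> 0).
#' @return adjusted image of the same class and dimensions.
#' @export
gamma_adjust <- function(img, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar")
  lut <- as.integer(round(255 * (0:255 / 255)^(1 / gamma)))
  cl <- class(img)
  out <- array(lut[as.integer(img) + 1L], dim = dim(img))
  storage.mode(out) <- "integer"
  class(out) <- cl
  out
}

#' Crop an image and mask to the field of view
#'
#' Crops to the bounding box of the field-of-view mask plus a fixed margin.
#'
#' @param img a [fundus_image()].
#' @param mask binary field-of-view matrix.
#' @param margin margin in pixels.
#' @return list with cropped `image`, `mask`, and the `rows`/`cols` kept.
#' @export
crop_to_field <- function(img, mask, margin = 5L) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no retinal field of view detected")
  r <- max(1L, min(idx[, 1]) - margin):min(nrow(mask), max(idx[, 1]) + margin)
  c <- max(1L, min(idx[, 2]) - margin):min(ncol(mask), max(idx[, 2]) + margin)
  list(image = fundus_image(unclass(img)[r, c, , drop = FALSE]),
       mask = mask[r, c, drop = FALSE], rows = r, cols = c)
}

#' Run the full enhancement chain
#'
#' Border detection, crop, green-channel CLAHE with attenuation, then gamma
#' lookup, in that fixed order. The configuration used is carried in the
#' result for provenance.
#'
#' @param img a [fundus_image()].
#' @param cfg a [preprocess_config()].
#' @param crop crop to the field-of-view bounding box (default TRUE).
#' @return list: `image` (enhanced), `mask` (field of view), `config`,
#'   `rows`, `cols` (indices kept when cropping), and `fov_fraction`.
#' @export
preprocess_fundus <- function(img, cfg = preprocess_config(), crop = TRUE) {
  mask <- compute_border_mask(img, cfg$border_threshold)
  fov_fraction <- mean(mask > 0)
  rows <- seq_len(nrow(mask)); cols <- seq_len(ncol(mask))
  if (crop) {
    cr <- crop_to_field(img, mask, cfg$crop_margin)
    img <- cr$image; mask <- cr$mask; rows <- cr$rows; cols <- cr$cols
  }
  out <- enhance(img, mask, cfg)
  out <- gamma_adjust(out, cfg$gamma)
  # masked-out region stays 0: gamma LUT fixes 0
  list(image = out, mask = mask, config = cfg,
       rows = rows, cols = cols, fov_fraction = fov_fraction)
}
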