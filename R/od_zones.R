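# Optic-disc geometry and measurement zones
# ------------------------------------------------------------------
# Vascular measurements are localized in annuli around the optic disc (OD),
# expressed in optic-disc diameters (ODD) beyond the disc margin:
#   zone A: margin to 0.5 ODD, zone B: 0.5 to 1.0 ODD, zone C: 0.5 to 2.0 ODD.
# Zone C deliberately contains zone B (both start at 0.5 ODD).

#' Optic-disc geometry from a binary mask
#'
#' The disc margin is modelled as the circle with the same area as the mask
#' foreground, centered at its centroid; `odd` is the optic-disc diameter.
#'
#' @param od_mask binary matrix (nonzero = optic disc).
#' @return object of class `od_geometry`: `center` (row, col), `radius`,
#'   `odd` (= 2 * radius), all in pixels.
#' @export
od_geometry_from_mask <- function(od_mask) {
  idx <- which(od_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no optic disc")
  center <- c(mean(idx[, 1]), mean(idx[, 2]))
  radius <- sqrt(nrow(idx) / pi)
  structure(list(center = center, radius = radius, odd = 2 * radius),
            class = "od_geometry")
}

#' @export
print.od_geometry <- function(x, ...) {
  cat(sprintf("<od_geometry center (%.1f, %.1f), radius %.2f px, ODD %.2f px>\n",
              x$center[1], x$center[2], x$radius, x$odd))
  invisible(x)
}

#' Zone radial specifications
#'
#' @param geom an `od_geometry`.
#' @return data frame with `zone`, `inner`, `outer` radii (px from the OD
#'   center); intervals are half-open `[inner, outer)`.
#' @export
zone_specs <- function(geom) {
  m <- geom$radius; odd <- geom$odd
  data.frame(zone = c("A", "B", "C"),
             inner = c(m, m + 0.5 * odd, m + 0.5 * odd),
             outer = c(m + 0.5 * odd, m + 1.0 * odd, m + 2.0 * odd),
             stringsAsFactors = FALSE)
}

#' Rasterize the measurement zones
#'
#' @param geom an `od_geometry`.
#' @param shape integer length-2, image (height, width).
#' @return named list of binary matrices `A`, `B`, `C` (1 = inside zone),
#'   clipped to the image bounds.
#' @export
zone_masks <- function(geom, shape) {
  stopifnot(length(shape) == 2L, all(shape >= 1))
  spec <- zone_specs(geom)
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d <- sqrt((rr - geom$center[1])^2 + (cc - geom$center[2])^2)
  out <- lapply(seq_len(nrow(spec)), function(i) {
    m <- (d >= spec$inner[i]) & (d < spec$outer[i])
    storage.mode(m) <- "integer"
    m
  })
  names(out) <- spec$zone
  out
}

#' Restrict a label mask to a zone
#'
#' @param vessel_mask integer label matrix (0/1/2).
#' @param zone binary zone matrix of the same shape.
#' @return label matrix with labels kept inside the zone, 0 outside.
#' @export
clip_to_zone <- function(vessel_mask, zone) {
  if (!all(dim(vessel_mask) == dim(zone))) stop("mask and zone shapes differ")
  out <- vessel_mask * (zone > 0)
  storage.mode(out) <- "integer"
  out
}
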