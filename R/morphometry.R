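# Vascular morphometry parameters
# ------------------------------------------------------------------
# Junction-level measures (branching coefficient, junction exponent,
# optimality ratio, diameter reduction), segment-level measures (mean
# width, simple tortuosity), tree path statistics, the Knudtson-Parr-
# Hubbard caliber summaries (CRAE/CRVE/AVR) and the box-counting fractal
# dimension.

#' Branching coefficient
#'
#' At a bifurcation with parent width r0 and daughter widths r1, r2:
#' `(r1^2 + r2^2) / r0^2`. Equals 2 at a symmetric equal-width junction.
#'
#' @param j a `junction` (exactly 2 daughters).
#' @return unitless coefficient, or `NA` (with a warning) off-arity.
#' @export
branching_coefficient <- function(j) {
  if (length(j$daughters) != 2L) return(NA_real_)
  sum(j$daughters^2) / j$r0^2
}

#' Junction exponent (printed cubic-difference form)
#'
#' `r0^3 - (r1^3 + r2^3 + r3^3)`, a deviation-from-Murray's-law measure in
#' px^3; a missing third daughter contributes 0. Zero when the cube of the
#' parent width equals the sum of the daughters' cubes. See
#' [junction_exponent_classical()] for the classical exponent.
#'
#' @param j a `junction` with 0-3 daughters.
#' @return junction exponent in px^3.
#' @export
junction_exponent <- function(j) {
  d <- c(j$daughters, 0, 0, 0)[1:3]
  j$r0^3 - sum(d^3)
}

#' Classical junction exponent
#'
#' The exponent x solving `r0^x = sum(ri^x)`, found by root bracketing on
#' [0.5, 10]; `NA` when no root exists in that range (e.g. daughters wider
#' than the parent at every exponent).
#'
#' @param j a `junction` with >= 1 daughter.
#' @return the exponent, or `NA`.
#' @export
junction_exponent_classical <- function(j) {
  d <- j$daughters[j$daughters > 0]
  if (length(d) == 0L || j$r0 <= 0) return(NA_real_)
  f <- function(x) j$r0^x - sum(d^x)
  lo <- 0.5; hi <- 10
  if (f(lo) * f(hi) > 0) return(NA_real_)
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Optimality ratio
#'
#' `((r1^3 + r2^3) / (2 * r0^3))^(1/3)`: 1 at an all-equal junction,
#' about 0.794 under Murray's law.
#'
#' @param j a `junction` (exactly 2 daughters).
#' @return unitless ratio, or `NA` off-arity.
#' @export
optimality_ratio <- function(j) {
  if (length(j$daughters) != 2L) return(NA_real_)
  (sum(j$daughters^3) / (2 * j$r0^3))^(1 / 3)
}

#' Vessel diameter reduction
#'
#' `1 - mean(daughters) / r0`: 0 when daughters match the parent width,
#' positive for narrowing, negative for widening.
#'
#' @param j a `junction` (>= 1 daughter).
#' @return unitless reduction.
#' @export
diameter_reduction <- function(j) {
  if (length(j$daughters) < 1L) return(NA_real_)
  1 - mean(j$daughters) / j$r0
}

#' Mean vessel width
#'
#' Arithmetic mean of all retained width samples pooled across segments.
#'
#' @param segments list of `vessel_segment`s.
#' @return mean width (px), `NA` if no samples.
#' @export
mean_vessel_width <- function(segments) {
  w <- unlist(lapply(segments, `[[`, "widths"))
  if (length(w) == 0L) return(NA_real_)
  mean(w)
}

#' Simple tortuosity
#'
#' Excess arc length over the chord, relative to the chord:
#' `(path_length - chord_length) / chord_length`; 0 for a straight vessel.
#'
#' @param seg a `vessel_segment` with positive chord length.
#' @return unitless tortuosity, `NA` for closed loops (zero chord).
#' @export
simple_tortuosity <- function(seg) {
  if (seg$chord_length <= 0) return(NA_real_)
  max(0, (seg$path_length - seg$chord_length) / seg$chord_length)
}

#' Tree path statistics
#'
#' Treats each connected component of the vessel graph as a rooted tree
#' (cycles broken by dropping the shortest edge of the cycle, flagged) and
#' reports external (root-to-leaf) path lengths: the single largest, the
#' total sum, and the number of exterior-interior paths (= leaf count).
#' The root is the node nearest the optic disc when geometry is given,
#' otherwise an endpoint of the component's longest segment.
#'
#' @param graph a `vessel_graph`.
#' @param od_geom optional `od_geometry` used to pick roots.
#' @return object of class `tree_path_stats`: `largest_external_path`,
#'   `sum_external_paths`, `n_exterior_interior_paths`, `flags`.
#' @export
tree_path_stats <- function(graph, od_geom = NULL) {
  flags <- character(0)
  empty <- structure(list(largest_external_path = 0, sum_external_paths = 0,
                          n_exterior_interior_paths = 0L,
                          flags = "empty_graph"), class = "tree_path_stats")
  if (length(graph$edges) == 0L || nrow(graph$nodes) == 0L) return(empty)
  lens <- vapply(graph$edges, function(e) .arc_length(e$pixels), numeric(1))
  el <- do.call(rbind, lapply(graph$edges, function(e) c(e$from, e$to)))
  keep <- el[, 1] != el[, 2]                       # self-loops cannot be tree edges
  if (any(!keep)) flags <- c(flags, "cycle_edges_removed")
  el <- el[keep, , drop = FALSE]; lens <- lens[keep]
  if (nrow(el) == 0L) return(empty)
  g <- igraph::graph_from_edgelist(cbind(as.character(el[, 1]),
                                         as.character(el[, 2])),
                                   directed = FALSE)
  igraph::E(g)$weight <- lens
  # break remaining cycles: maximum-weight spanning forest keeps the long
  # edges, i.e. removes the shortest edge of each cycle
  if (igraph::ecount(g) > igraph::vcount(g) - igraph::count_components(g)) {
    g <- igraph::mst(g, weights = -igraph::E(g)$weight)
    flags <- c(flags, "cycle_edges_removed")
  }
  comp <- igraph::components(g)
  largest <- 0; total <- 0; nleaf <- 0L
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vids)
    deg <- igraph::degree(sub)
    vnames <- as.integer(igraph::V(sub)$name)
    if (igraph::vcount(sub) == 1L) next
    if (!is.null(od_geom)) {
      nd <- graph$nodes[match(vnames, graph$nodes$id), ]
      dist_od <- sqrt((nd$row - od_geom$center[1])^2 +
                        (nd$col - od_geom$center[2])^2)
      root <- which.min(dist_od)
    } else {
      wmax <- which.max(igraph::E(sub)$weight)
      ends <- igraph::ends(sub, wmax, names = FALSE)
      root <- if (deg[ends[1]] <= deg[ends[2]]) ends[1] else ends[2]
    }
    leaves <- setdiff(which(deg == 1L), root)
    if (length(leaves) == 0L) next
    d <- igraph::distances(sub, v = root, to = leaves,
                           weights = igraph::E(sub)$weight)
    largest <- max(largest, max(d))
    total <- total + sum(d)
    nleaf <- nleaf + length(leaves)
  }
  structure(list(largest_external_path = largest, sum_external_paths = total,
                 n_exterior_interior_paths = nleaf, flags = unique(flags)),
            class = "tree_path_stats")
}

#' @export
print.tree_path_stats <- function(x, ...) {
  cat(sprintf("<tree_path_stats: largest %.1f px, sum %.1f px, %d external paths>\n",
              x$largest_external_path, x$sum_external_paths,
              x$n_exterior_interior_paths))
  invisible(x)
}

#' Knudtson-Parr-Hubbard equivalent caliber
#'
#' Iteratively combines up to six vessel widths into one equivalent
#' caliber: each round sorts the current widths, pairs the largest with
#' the smallest, the second largest with the second smallest, and so on
#' (an odd count carries the median unpaired into the next round); each
#' pair combines to `factor * sqrt(w1^2 + w2^2)` with factor 0.88 for
#' arteries (CRAE) and 0.95 for veins (CRVE).
#'
#' @param widths numeric, 1 to 6 vessel widths (px).
#' @param factor combination factor, 0.88 (arteries) or 0.95 (veins).
#' @return object of class `caliber_equivalent`: `value` (px),
#'   `pairing_trace` (data frame w1, w2, combined per pairing, rounds
#'   annotated), `flags`.
#' @export
knudtson_equivalent <- function(widths, factor) {
  if (length(widths) == 0L) stop("no widths supplied")
  if (length(widths) > 6L) stop("at most six widths enter the pairing")
  stopifnot(all(widths > 0), factor > 0)
  flags <- if (length(widths) == 1L) "insufficient vessels" else character(0)
  trace <- data.frame(round = integer(0), w1 = numeric(0), w2 = numeric(0),
                      combined = numeric(0))
  w <- widths
  round_i <- 0L
  while (length(w) > 1L) {
    round_i <- round_i + 1L
    w <- sort(w, decreasing = TRUE)
    n <- length(w)
    npair <- n %/% 2L
    nxt <- numeric(0)
    for (i in seq_len(npair)) {
      big <- w[i]; small <- w[n - i + 1L]
      comb <- factor * sqrt(big^2 + small^2)
      trace <- rbind(trace, data.frame(round = round_i, w1 = small, w2 = big,
                                       combined = comb))
      nxt <- c(nxt, comb)
    }
    if (n %% 2L == 1L) nxt <- c(nxt, w[npair + 1L])   # median carries over
    w <- nxt
  }
  structure(list(value = w, pairing_trace = trace, factor = factor,
                 flags = flags), class = "caliber_equivalent")
}

#' @export
print.caliber_equivalent <- function(x, ...) {
  cat(sprintf("<caliber_equivalent %.4f px (factor %.2f, %d pairings)%s>\n",
              x$value, x$factor, nrow(x$pairing_trace),
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' Arteriovenous ratio
#'
#' CRAE divided by CRVE; lower values associate with arteriolar narrowing.
#'
#' @param crae central retinal arteriolar equivalent (px).
#' @param crve central retinal venular equivalent (px).
#' @return unitless ratio, `NA` when CRVE is not positive.
#' @export
avr <- function(crae, crve) {
  if (!is.finite(crve) || crve <= 0) return(NA_real_)
  crae / crve
}

#' Box-counting fractal dimension
#'
#' Covers the mask with square grids of side s (powers of two from
#' `floor(min(h, w) / 4)` down to 2, anchored at the origin), counts the
#' occupied cells N(s), and fits `log N(s) = log K + D log(1/s)` by least
#' squares; D is the fractal dimension.
#'
#' @param mask binary matrix (nonzero = foreground).
#' @return object of class `box_count_curve`: `box_sizes`, `counts`,
#'   `slope` (D), `intercept` (log K).
#' @export
fractal_dimension <- function(mask) {
  if (!any(mask > 0)) stop("empty mask")
  h <- nrow(mask); w <- ncol(mask)
  smax <- floor(min(h, w) / 4)
  sizes <- 2^(seq.int(floor(log2(smax)), 1))
  if (length(sizes) < 2L) stop("mask too small for box counting")
  bin <- mask > 0
  counts <- vapply(sizes, function(s) {
    ri <- (which(bin, arr.ind = TRUE) - 1L) %/% s
    nrow(unique(ri))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(1 / sizes))
  structure(list(box_sizes = sizes, counts = counts,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1])),
            class = "box_count_curve")
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat(sprintf("<box_count_curve: D = %.3f over box sizes %s>\n",
              x$slope, paste(x$box_sizes, collapse = ", ")))
  invisible(x)
}

#' @export
plot.box_count_curve <- function(x, ...) {
  plot(log(1 / x$box_sizes), log(x$counts),
       xlab = "log 1/s", ylab = "log N(s)",
       main = sprintf("Box counting, D = %.3f", x$slope), ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
}

# summary stats over junctions inside (optionally) a zone
.junction_summary <- function(junctions, zone = NULL) {
  if (!is.null(zone) && length(junctions)) {
    inz <- vapply(junctions, function(j) {
      r <- round(j$position[1]); c <- round(j$position[2])
      r >= 1 && r <= nrow(zone) && c >= 1 && c <= ncol(zone) && zone[r, c] > 0
    }, logical(1))
    junctions <- junctions[inz]
  }
  bifs <- Filter(function(j) length(j$daughters) == 2L, junctions)
  list(
    n_junctions = length(junctions),
    branching_coefficient = if (length(bifs))
      mean(vapply(bifs, branching_coefficient, numeric(1))) else NA_real_,
    junction_exponent = if (length(junctions))
      mean(vapply(junctions, junction_exponent, numeric(1))) else NA_real_,
    junction_exponent_classical = if (length(junctions)) {
      v <- vapply(junctions, junction_exponent_classical, numeric(1))
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    } else NA_real_,
    optimality_ratio = if (length(bifs))
      mean(vapply(bifs, optimality_ratio, numeric(1))) else NA_real_,
    diameter_reduction = if (length(junctions)) {
      v <- vapply(junctions, diameter_reduction, numeric(1))
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    } else NA_real_)
}

# segment metrics restricted to a zone: width samples whose positions fall
# in the zone; tortuosity over segments that touch the zone
.segment_summary <- function(segments, zone = NULL) {
  if (length(segments) == 0L)
    return(list(mean_width = NA_real_, median_width = NA_real_,
                simple_tortuosity = NA_real_, n_segments = 0L, n_samples = 0L))
  wpool <- numeric(0); tort <- numeric(0); nseg <- 0L
  for (s in segments) {
    if (length(s$widths) == 0L) next
    if (is.null(zone)) sel <- rep(TRUE, length(s$widths))
    else sel <- zone[s$sample_pos] > 0
    if (!any(sel)) next
    nseg <- nseg + 1L
    wpool <- c(wpool, s$widths[sel])
    tv <- simple_tortuosity(s)
    if (is.finite(tv)) tort <- c(tort, tv)
  }
  list(mean_width = if (length(wpool)) mean(wpool) else NA_real_,
       median_width = if (length(wpool)) median(wpool) else NA_real_,
       simple_tortuosity = if (length(tort)) mean(tort) else NA_real_,
       n_segments = nseg, n_samples = length(wpool))
}

# caliber for one class from its ranked segments, widths taken in the
# caliber zone with fallback to the whole-segment mean
.class_caliber_widths <- function(ranked, zone) {
  w <- numeric(0); fb <- FALSE
  for (s in ranked) {
    if (length(s$widths) == 0L) next
    sel <- if (is.null(zone)) rep(TRUE, length(s$widths)) else zone[s$sample_pos] > 0
    if (any(sel)) w <- c(w, mean(s$widths[sel]))
    else { w <- c(w, s$mean_width); fb <- TRUE }
  }
  list(widths = w, fallback = fb)
}

#' Assemble the full morphometry report for one eye
#'
#' Combines graphs, ranked segments and junctions of both vessel classes
#' into the per-class, per-zone parameter report: junction metrics averaged
#' over junctions, segment metrics over the top-ranked segments, CRAE/CRVE
#' from the top-6 widths in the caliber zone, AVR, and the box-counting
#' fractal dimension of the combined vessel mask.
#'
#' @param artery,vein lists with elements `graph`, `segments` (ranked),
#'   `junctions`, `tree_stats` for each class (as produced by [run_eye()]
#'   or assembled manually).
#' @param vessel_mask the full label matrix (for the fractal dimension).
#' @param zones named list of zone masks from [zone_masks()] (may be NULL:
#'   zone-resolved metrics and zone-restricted calibers are then skipped).
#' @param caliber_zone zone feeding the caliber summaries (default "B").
#' @param knudtson_factors numeric length-2, artery and vein combination
#'   factors.
#' @param fd_on compute the fractal dimension on the filled `"mask"`
#'   (default) or on the `"skeleton"`.
#' @param microns_per_pixel optional calibration; reported widths are
#'   multiplied by it when provided (lengths stay in px).
#' @return object of class `morphometry_report`.
#' @export
build_report <- function(artery, vein, vessel_mask, zones = NULL,
                         caliber_zone = "B",
                         knudtson_factors = c(artery = 0.88, vein = 0.95),
                         fd_on = c("mask", "skeleton"),
                         microns_per_pixel = NULL) {
  fd_on <- match.arg(fd_on)
  flags <- character(0)
  zone_names <- c(list(all = NULL),
                  if (!is.null(zones)) zones else list())
  per_class <- list()
  for (cls in c("artery", "vein")) {
    dat <- if (cls == "artery") artery else vein
    zl <- list()
    for (zn in names(zone_names)) {
      zl[[zn]] <- c(.junction_summary(dat$junctions, zone_names[[zn]]),
                    .segment_summary(dat$segments, zone_names[[zn]]))
    }
    per_class[[cls]] <- list(zones = zl, tree_path_stats = dat$tree_stats,
                             n_ranked = length(dat$segments))
    if (length(dat$segments) == 0L)
      flags <- c(flags, paste0("no_", cls, "_segments"))
  }
  # caliber summaries
  cz <- if (!is.null(zones) && caliber_zone %in% names(zones))
    zones[[caliber_zone]] else NULL
  aw <- .class_caliber_widths(artery$segments, cz)
  vw <- .class_caliber_widths(vein$segments, cz)
  if (aw$fallback || vw$fallback)
    flags <- c(flags, "caliber_zone_fallback_widths")
  crae_obj <- if (length(aw$widths))
    knudtson_equivalent(head(aw$widths, 6), knudtson_factors[[1]]) else NULL
  crve_obj <- if (length(vw$widths))
    knudtson_equivalent(head(vw$widths, 6), knudtson_factors[[2]]) else NULL
  crae <- if (is.null(crae_obj)) NA_real_ else crae_obj$value
  crve <- if (is.null(crve_obj)) NA_real_ else crve_obj$value
  if (is.null(crae_obj)) flags <- c(flags, "crae_missing_no_artery_widths")
  if (is.null(crve_obj)) flags <- c(flags, "crve_missing_no_vein_widths")
  av <- avr(crae, crve)
  if (is.na(av) && !is.null(crae_obj)) flags <- c(flags, "avr_missing")
  flags <- c(flags, if (!is.null(crae_obj)) crae_obj$flags,
             if (!is.null(crve_obj)) crve_obj$flags)
  # fractal dimension on both classes combined
  fd_mask <- if (fd_on == "mask") vessel_mask > 0 else
    (artery$graph$skeleton | vein$graph$skeleton)
  fd <- if (any(fd_mask)) fractal_dimension(fd_mask) else NULL
  if (is.null(fd)) flags <- c(flags, "fractal_dimension_missing_empty_mask")
  scale <- if (is.null(microns_per_pixel)) 1 else microns_per_pixel
  structure(list(
    per_class = per_class,
    caliber = list(crae = crae * scale, crve = crve * scale, avr = av,
                   crae_trace = if (is.null(crae_obj)) NULL else crae_obj$pairing_trace,
                   crve_trace = if (is.null(crve_obj)) NULL else crve_obj$pairing_trace,
                   zone = caliber_zone),
    fractal_dimension = if (is.null(fd)) NA_real_ else fd$slope,
    box_count_curve = fd,
    units = if (is.null(microns_per_pixel)) "px" else "micron",
    microns_per_pixel = microns_per_pixel,
    flags = unique(flags)), class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("Retinal morphometry report\n")
  cat(sprintf("  CRAE %.3f %s, CRVE %.3f %s, AVR %.4f (zone %s)\n",
              x$caliber$crae, x$units, x$caliber$crve, x$units,
              x$caliber$avr, x$caliber$zone))
  cat(sprintf("  Fractal dimension (combined vessels): %.3f\n",
              x$fractal_dimension))
  for (cls in names(x$per_class)) {
    pc <- x$per_class[[cls]]
    a <- pc$zones$all
    cat(sprintf(
      "  %s: width %.2f %s, tortuosity %.4f, BC %.3f, JE %.1f, OR %.3f, DR %.3f (%d junctions)\n",
      cls, a$mean_width, x$units, a$simple_tortuosity,
      a$branching_coefficient, a$junction_exponent, a$optimality_ratio,
      a$diameter_reduction, a$n_junctions))
    ts <- pc$tree_path_stats
    if (!is.null(ts))
      cat(sprintf("    paths: largest %.1f px, sum %.1f px, n %d\n",
                  ts$largest_external_path, ts$sum_external_paths,
                  ts$n_exterior_interior_paths))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Flatten a report to one data-frame row
#'
#' @param x a `morphometry_report`.
#' @param ... unused.
#' @return one-row data frame: caliber block, fractal dimension, and every
#'   per-class all-zone parameter with `artery_`/`vein_` prefixes.
#' @export
as.data.frame.morphometry_report <- function(x, ...) {
  out <- data.frame(crae = x$caliber$crae, crve = x$caliber$crve,
                    avr = x$caliber$avr, fractal_dimension = x$fractal_dimension)
  for (cls in names(x$per_class)) {
    a <- x$per_class[[cls]]$zones$all
    ts <- x$per_class[[cls]]$tree_path_stats
    blk <- data.frame(a$mean_width, a$simple_tortuosity,
                      a$branching_coefficient, a$junction_exponent,
                      a$optimality_ratio, a$diameter_reduction,
                      ts$largest_external_path, ts$sum_external_paths,
                      ts$n_exterior_interior_paths)
    names(blk) <- paste0(cls, "_", c("mean_width", "simple_tortuosity",
                                     "branching_coefficient", "junction_exponent",
                                     "optimality_ratio", "diameter_reduction",
                                     "largest_external_path", "sum_external_paths",
                                     "n_exterior_interior_paths"))
    out <- cbind(out, blk)
  }
  out$flags <- paste(x$flags, collapse = ";")
  out
}
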