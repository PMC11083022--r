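# Synthetic fundus phantoms
# ------------------------------------------------------------------
# Parametric vessel trees with known widths, tortuosity and branching,
# rendered to an image + artery/vein label mask + optic-disc mask, so the
# whole measurement pipeline can be validated against ground truth.
# Vessels are constant-width bands around sinusoidal centerlines radiating
# from the optic-disc margin; the image mimics fundus illumination (bright
# disc, radial shading, vessels darker than background).

#' Phantom specification
#'
#' @param image_size integer (height, width) px.
#' @param od_center optic-disc center (row, col); default image center.
#' @param od_radius optic-disc radius (px).
#' @param vessels list of vessel descriptions; each is a list with
#'   `class` ("artery"/"vein"), `width` (px), `amplitude` (px),
#'   `period` (px), `start_angle` (degrees), optional `length` (px,
#'   default 2.5 optic-disc diameters) and optional `branches`: a list of
#'   `position` (fraction of length), `widths` (two daughter widths, px)
#'   and `angles` (two offsets from the local tangent, degrees).
#' @param noise_sd Gaussian intensity noise added to the rendered image
#'   (masks are unaffected).
#' @param seed integer seed making the bundle deterministic.
#' @return list with class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(512L, 512L), od_center = NULL,
                         od_radius = 40, vessels = list(), noise_sd = 8,
                         seed = 1L) {
  if (is.null(od_center)) od_center <- image_size / 2
  for (v in vessels) {
    stopifnot(v$width >= 2, v$class %in% c("artery", "vein"))
  }
  structure(list(image_size = as.integer(image_size), od_center = od_center,
                 od_radius = od_radius, vessels = vessels,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Random phantom specification
#'
#' Draws a 12-vessel phantom (6 arteries, 6 veins) in the study layout:
#' vessels radiate at roughly even angles with jitter, widths 5-12 px,
#' amplitudes up to 20 px, periods 150-300 px. Vessels carrying a
#' bifurcation use odd integer widths so that the rasterized band has a
#' well-defined integer ground-truth width.
#'
#' @param seed integer seed.
#' @param n_arteries,n_veins vessel counts per class.
#' @param with_branches add one bifurcation to two vessels per class.
#' @param image_size,od_radius,noise_sd forwarded to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
random_phantom_spec <- function(seed, n_arteries = 6L, n_veins = 6L,
                                with_branches = FALSE,
                                image_size = c(512L, 512L), od_radius = 40,
                                noise_sd = 8) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- n_arteries + n_veins
  base_ang <- seq(0, 360, length.out = n + 1L)[seq_len(n)]
  cls <- sample(rep(c("artery", "vein"), c(n_arteries, n_veins)))
  branch_idx <- if (with_branches)
    c(which(cls == "artery")[1:2], which(cls == "vein")[1:2]) else integer(0)
  proto <- list(image_size = as.integer(image_size),
                od_center = image_size / 2, od_radius = od_radius)
  len <- 5 * od_radius
  # sampled centerline (and branch) points of a candidate vessel
  trace_pts <- function(v) {
    tt <- seq(0, if (is.null(v$branches)) len else
      v$branches[[1]]$position * len, by = 2)
    pts <- .vessel_curve(proto, v, tt)
    for (b in if (is.null(v$branches)) list() else v$branches) {
      t_stop <- b$position * len
      bp <- .vessel_curve(proto, v, t_stop)
      tangent <- .vessel_curve(proto, v, t_stop + 0.5) - bp
      th0 <- atan2(tangent[1], tangent[2])
      blen <- 0.8 * (len - t_stop)
      for (k in 1:2) {
        th <- th0 + b$angles[k] * pi / 180
        tb <- seq(2, blen, by = 2)
        pts <- rbind(pts, cbind(bp[1] + tb * sin(th), bp[2] + tb * cos(th)))
      }
    }
    pts
  }
  # minimum center-to-center distance between two point sets
  min_dist <- function(a, b) {
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    sqrt(min(d2))
  }
  # vessels must not touch anywhere, the disc margin included: centerlines
  # of distinct vessels keep a gap of at least the two half-widths plus
  # 2 px (at the default 30-degree angular spacing the margin gap is
  # ~21 px, so valid draws exist for every width pair)
  clear_of <- function(v, pts, placed, placed_pts) {
    for (j in seq_along(placed)) {
      lim <- (v$width + placed[[j]]$width) / 2 + 2
      if (min_dist(pts, placed_pts[[j]]) < lim) return(FALSE)
    }
    TRUE
  }
  vessels <- list(); ptss <- list()
  for (i in seq_len(n)) {
    branched <- i %in% branch_idx
    width <- if (branched) sample(c(7, 9, 11), 1L) else sample(5:12, 1L)
    placed <- FALSE
    for (try in 1:50) {
      v <- list(class = cls[i], width = width,
                amplitude = runif(1, 0, 20), period = runif(1, 150, 300),
                start_angle = base_ang[i] + runif(1, -8, 8))
      if (branched) {
        v$branches <- list(list(position = runif(1, 0.55, 0.7),
                                widths = c(7, 5),
                                angles = c(-1, 1) * runif(1, 25, 40)))
      }
      pts <- trace_pts(v)
      if (clear_of(v, pts, vessels, ptss)) {
        placed <- TRUE; break
      }
    }
    if (!placed) {
      # straight radial fallback (and no branch): always renderable
      v <- list(class = cls[i], width = width, amplitude = 0, period = 200,
                start_angle = base_ang[i])
      pts <- trace_pts(v)
    }
    vessels[[i]] <- v
    ptss[[i]] <- pts
  }
  phantom_spec(image_size = image_size, od_radius = od_radius,
               vessels = vessels, noise_sd = noise_sd, seed = seed)
}

# continuous centerline of one vessel at parameters t (arc along the ray)
.vessel_curve <- function(spec, v, t) {
  th <- v$start_angle * pi / 180
  u <- c(sin(th), cos(th))                 # radial direction (row, col)
  p <- c(-cos(th), sin(th))                # perpendicular
  amp <- if (is.null(v$amplitude)) 0 else v$amplitude
  per <- if (is.null(v$period)) 200 else v$period
  off <- amp * sin(2 * pi * t / per)
  r <- spec$od_radius + t
  cbind(spec$od_center[1] + r * u[1] + off * p[1],
        spec$od_center[2] + r * u[2] + off * p[2])
}

# quadrature arc length of the generating curve between t in [t0, t1]
.vessel_arclength <- function(spec, v, t0, t1, n = 4000L) {
  t <- seq(t0, t1, length.out = n)
  xy <- .vessel_curve(spec, v, t)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

# stamp a constant-width band around continuous points into a label matrix
.stamp_band <- function(mask, pts, width, code) {
  rad <- width / 2
  g <- ceiling(rad)
  offs <- expand.grid(dr = -g:g, dc = -g:g)
  n <- nrow(pts); m <- nrow(offs)
  pr <- rep(pts[, 1], each = m); pc <- rep(pts[, 2], each = m)
  rr <- round(pr) + rep(offs$dr, n); cc <- round(pc) + rep(offs$dc, n)
  keep <- (rr - pr)^2 + (cc - pc)^2 < rad^2 &
    rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  mask[cbind(rr[keep], cc[keep])] <- code
  mask
}

#' Generate a phantom bundle
#'
#' Deterministic for a given spec (noise is driven by the spec seed and
#' affects the image only, never the masks). The truth block records, per
#' vessel, the generating width, quadrature path length, chord length and
#' tortuosity, and per bifurcation the generating (r0, r1, r2).
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_bundle`: `image` ([fundus_image()]),
#'   `vessel_mask` (0/1/2), `od_mask`, `truth` (`vessels` and `junctions`
#'   data frames), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  vm <- matrix(0L, h, w)
  odd <- 2 * spec$od_radius
  vt <- list(); jt <- list()
  for (vi in seq_along(spec$vessels)) {
    v <- spec$vessels[[vi]]
    len <- if (!is.null(v$length)) v$length else 2.5 * odd
    t_end <- len
    branches <- if (is.null(v$branches)) list() else v$branches
    t_stop <- if (length(branches)) branches[[1]]$position * len else t_end
    tt <- seq(0, t_stop, by = 0.25)
    pts <- .vessel_curve(spec, v, tt)
    vm <- .stamp_band(vm, pts, v$width, .class_code(v$class))
    # truth over the rendered (parent) extent
    L <- .vessel_arclength(spec, v, 0, t_stop)
    ends <- .vessel_curve(spec, v, c(0, t_stop))
    C <- sqrt(sum((ends[2, ] - ends[1, ])^2))
    vt[[vi]] <- data.frame(id = vi, vessel_class = v$class, width = v$width,
                           path_length = L, chord_length = C,
                           tortuosity = (L - C) / C,
                           start_angle = v$start_angle)
    for (b in branches) {
      bp <- .vessel_curve(spec, v, t_stop)
      eps <- 0.5
      tangent <- .vessel_curve(spec, v, t_stop + eps) - bp
      th0 <- atan2(tangent[1], tangent[2])
      blen <- 0.8 * (len - t_stop)
      for (k in 1:2) {
        th <- th0 + b$angles[k] * pi / 180
        tb <- seq(0, blen, by = 0.25)
        bpts <- cbind(bp[1] + tb * sin(th), bp[2] + tb * cos(th))
        vm <- .stamp_band(vm, bpts, b$widths[k], .class_code(v$class))
      }
      jt[[length(jt) + 1L]] <- data.frame(
        vessel_id = vi, vessel_class = v$class,
        row = bp[1], col = bp[2],
        r0 = v$width, r1 = max(b$widths), r2 = min(b$widths))
    }
  }
  # optic-disc mask
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d_od <- sqrt((rr - spec$od_center[1])^2 + (cc - spec$od_center[2])^2)
  od_mask <- matrix(as.integer(d_od <= spec$od_radius), h, w)
  # illumination: bright field of view with radial falloff, brighter disc
  ctr <- c(h, w) / 2
  d_ctr <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  fov_r <- 0.48 * min(h, w)
  fov <- d_ctr <= fov_r
  shade <- 150 - 60 * pmin(d_ctr / fov_r, 1)^2
  g <- shade * fov
  g[od_mask > 0] <- g[od_mask > 0] + 60
  red <- pmin(g * 1.35, 255); blue <- g * 0.4
  dark <- ifelse(vm == 1L, 55, ifelse(vm == 2L, 75, 0))
  g <- pmax(g - dark, 0); red <- pmax(red - dark, 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    nz <- function(x) pmin(pmax(x + rnorm(length(x), 0, spec$noise_sd) * fov, 0), 255)
    blue <- nz(blue); g <- nz(g); red <- nz(red)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- round(blue); img[, , 2] <- round(g); img[, , 3] <- round(red)
  structure(list(image = fundus_image(img), vessel_mask = vm,
                 od_mask = od_mask,
                 truth = list(vessels = do.call(rbind, vt),
                              junctions = if (length(jt)) do.call(rbind, jt)
                              else NULL),
                 spec = spec),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle %d x %d px: %d vessels (%d junctions), seed %d>\n",
              nrow(x$vessel_mask), ncol(x$vessel_mask),
              nrow(x$truth$vessels),
              if (is.null(x$truth$junctions)) 0L else nrow(x$truth$junctions),
              x$spec$seed))
  invisible(x)
}

#' Deterministic fractal fixtures
#'
#' Canonical binary images with closed-form box-counting dimensions:
#' a one-pixel horizontal line (D = 1), a filled square (D = 2), and a
#' Sierpinski gasket (D = log 3 / log 2, about 1.585) built by recursive
#' triangle subdivision.
#'
#' @param kind `"line"`, `"square"` or `"sierpinski"`.
#' @param size canvas side (px); `>= 27` for the gasket.
#' @param levels recursion depth for the gasket.
#' @return binary integer matrix `size x size`.
#' @export
fractal_fixture <- function(kind = c("line", "square", "sierpinski"),
                            size = 256L, levels = 5L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  m <- matrix(0L, size, size)
  if (kind == "line") {
    m[size %/% 2L, ] <- 1L
  } else if (kind == "square") {
    m[, ] <- 1L
  } else {
    if (size < 27L) stop("sierpinski needs size >= 27")
    fill <- function(r0, c0, s) {
      for (i in 0:(s - 1L)) m[r0 + i, c0:(c0 + s - 1L - i)] <<- 1L
    }
    rec <- function(r0, c0, s, lev) {
      if (lev == 0L || s <= 2L) { fill(r0, c0, s); return(invisible()) }
      a <- as.integer(ceiling(s / 2)); b <- s - a
      rec(r0, c0, a, lev - 1L)
      rec(r0 + a, c0, b, lev - 1L)
      rec(r0, c0 + a, b, lev - 1L)
    }
    rec(1L, 1L, size, as.integer(levels))
  }
  m
}

#' Write a phantom bundle to disk
#'
#' Writes `image.png`, `vessels.png` (label PNG), `od.png` and
#' `truth.json` into a directory.
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fundus(bundle$image, file.path(dir, "image.png"))
  write_mask(bundle$vessel_mask, file.path(dir, "vessels.png"))
  write_mask(bundle$od_mask, file.path(dir, "od.png"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Measure a phantom and match results to ground truth
#'
#' Runs the measurement stages (skeleton, graph, width profiling, junction
#' extraction) on a phantom's vessel mask and pairs each measured segment
#' with its generating vessel (by proximity of centerline midpoints) and
#' each measured junction with its generating bifurcation (by position).
#'
#' @param bundle a `phantom_bundle`.
#' @param config a [run_config()] supplying measurement parameters.
#' @return list of data frames: `vessels` (truth vs measured width,
#'   tortuosity, path length) and `junctions` (truth vs measured r0, r1,
#'   r2), with `NA` rows for unmatched truth entries.
#' @export
phantom_recovery <- function(bundle, config = run_config()) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  spec <- bundle$spec
  meas <- list()
  for (cls in c("artery", "vein")) {
    g <- skeletonize_and_build(bundle$vessel_mask, cls,
                               min_spur_px = config$min_spur_px)
    segs <- segments_with_widths(g, bundle$vessel_mask,
                                 stride = config$width_sample_stride,
                                 angle_step = config$angle_step,
                                 max_r = config$max_r)
    jn <- extract_junctions(g, segs)
    meas[[cls]] <- list(segments = segs, junctions = jn)
  }
  tr <- bundle$truth$vessels
  vres <- lapply(seq_len(nrow(tr)), function(i) {
    v <- spec$vessels[[tr$id[i]]]
    len <- if (!is.null(v$length)) v$length else 5 * spec$od_radius
    t_stop <- if (is.null(v$branches)) len else v$branches[[1]]$position * len
    mid <- .vessel_curve(spec, v, t_stop / 2)
    segs <- meas[[tr$vessel_class[i]]]$segments
    best <- NULL; bestd <- Inf
    for (s in segs) {
      sm <- s$centerline[ceiling(nrow(s$centerline) / 2), ]
      d <- sqrt(sum((sm - mid)^2))
      if (d < bestd) { bestd <- d; best <- s }
    }
    data.frame(id = tr$id[i], vessel_class = tr$vessel_class[i],
               width_true = tr$width[i],
               width_meas = if (is.null(best)) NA_real_ else best$mean_width,
               tortuosity_true = tr$tortuosity[i],
               tortuosity_meas = if (is.null(best)) NA_real_ else
                 simple_tortuosity(best),
               path_length_true = tr$path_length[i],
               path_length_meas = if (is.null(best)) NA_real_ else
                 best$path_length,
               match_dist = bestd)
  })
  jres <- NULL
  tj <- bundle$truth$junctions
  if (!is.null(tj)) {
    jres <- lapply(seq_len(nrow(tj)), function(i) {
      jn <- meas[[tj$vessel_class[i]]]$junctions
      best <- NULL; bestd <- Inf
      for (j in jn) {
        d <- sqrt(sum((j$position - c(tj$row[i], tj$col[i]))^2))
        if (d < bestd) { bestd <- d; best <- j }
      }
      ok <- !is.null(best) && bestd < 10 && length(best$daughters) >= 2
      data.frame(vessel_id = tj$vessel_id[i],
                 r0_true = tj$r0[i], r1_true = tj$r1[i], r2_true = tj$r2[i],
                 r0_meas = if (ok) best$r0 else NA_real_,
                 r1_meas = if (ok) best$daughters[1] else NA_real_,
                 r2_meas = if (ok) best$daughters[2] else NA_real_,
                 match_dist = bestd)
    })
    jres <- do.call(rbind, jres)
  }
  list(vessels = do.call(rbind, vres), junctions = jres)
}
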