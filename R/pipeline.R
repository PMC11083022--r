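# End-to-end eye pipeline
# ------------------------------------------------------------------
# preprocess -> optic-disc zones -> vessel graphs -> morphometry -> risk.
# Everything is deterministic; the configuration travels with the output
# for provenance.

#' Pipeline run configuration
#'
#' @param preprocess a [preprocess_config()].
#' @param caliber_zone zone feeding CRAE/CRVE (default "B", the caliber
#'   convention).
#' @param rank_weights length/intensity/prominence/connectivity weights
#'   for [rank_top_vessels()].
#' @param top_k number of vessels ranked per class (default 6).
#' @param knudtson_factors artery and vein combination factors.
#' @param min_spur_px skeleton spur pruning threshold (px).
#' @param width_sample_stride centerline width sampling stride (px).
#' @param angle_step,max_r width-search resolution (degrees) and radius
#'   cap (px).
#' @param parent_rule junction parent identification, `"widest"` or
#'   `"od_proximal"`.
#' @param fd_on fractal dimension on `"mask"` or `"skeleton"`.
#' @param microns_per_pixel optional width calibration.
#' @param min_fov_fraction quality gate: minimum fraction of image pixels
#'   inside the field of view.
#' @param risk_rule `"any"` or `"all"` over the differentiator parameters.
#' @return list with class `run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       caliber_zone = "B",
                       rank_weights = c(0.4, 0.2, 0.3, 0.1),
                       top_k = 6L,
                       knudtson_factors = c(artery = 0.88, vein = 0.95),
                       min_spur_px = 5, width_sample_stride = 3,
                       angle_step = 1, max_r = 50,
                       parent_rule = "widest",
                       fd_on = "mask",
                       microns_per_pixel = NULL,
                       min_fov_fraction = 0.2,
                       risk_rule = "any") {
  structure(list(preprocess = preprocess, caliber_zone = caliber_zone,
                 rank_weights = rank_weights, top_k = as.integer(top_k),
                 knudtson_factors = knudtson_factors,
                 min_spur_px = min_spur_px,
                 width_sample_stride = width_sample_stride,
                 angle_step = angle_step, max_r = max_r,
                 parent_rule = parent_rule, fd_on = fd_on,
                 microns_per_pixel = microns_per_pixel,
                 min_fov_fraction = min_fov_fraction,
                 risk_rule = risk_rule),
            class = "run_config")
}

.quality_stop <- function(msg) {
  stop(structure(class = c("quality_gate_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# analyze one vessel class end to end
.analyze_class <- function(mask, cls, cfg, image, od_geom) {
  graph <- skeletonize_and_build(mask, cls, min_spur_px = cfg$min_spur_px)
  segs <- segments_with_widths(graph, mask,
                               stride = cfg$width_sample_stride,
                               angle_step = cfg$angle_step, max_r = cfg$max_r)
  ranked <- if (length(segs))
    rank_top_vessels(segs, image = image, k = cfg$top_k,
                     weights = cfg$rank_weights) else list()
  jall <- extract_junctions(graph, segs,
                            parent_rule = cfg$parent_rule, od_geom = od_geom)
  # keep junctions that touch at least one ranked vessel
  if (length(jall) && length(ranked)) {
    rnodes <- unique(unlist(lapply(ranked, function(s) c(s$from, s$to))))
    keep <- vapply(jall, function(j) j$node_id %in% rnodes, logical(1))
    jn <- jall[keep]
  } else jn <- jall
  list(graph = graph, segments = ranked, all_segments = segs,
       junctions = jn, tree_stats = tree_path_stats(graph, od_geom))
}

#' Run the full parameter-based pipeline on one eye
#'
#' Executes the stages in order: enhancement chain, optic-disc geometry
#' and zone construction, per-class vessel graph and width profiling,
#' morphometry report, and (when reference ranges are supplied) the risk
#' verdict with the AND combination against an external classifier flag.
#'
#' @param image a [fundus_image()] or a path to one.
#' @param vessel_mask 0/1/2 label matrix or path to a label PNG.
#' @param od_mask binary optic-disc matrix or path; required — an eye
#'   without a detectable optic disc is rejected.
#' @param config a [run_config()].
#' @param classifier_flag optional external classifier verdict
#'   (`"cardio_suspect"` / `"non_cardio_suspect"`, or logical where TRUE
#'   means cardio suspect).
#' @param ranges optional [reference_ranges()]; without them no verdict is
#'   produced.
#' @return object of class `eye_analysis`: `report`
#'   (a `morphometry_report`), `verdict` (a `risk_verdict` or NULL),
#'   `od_geometry`, `config`, `flags`.
#' @export
run_eye <- function(image, vessel_mask, od_mask, config = run_config(),
                    classifier_flag = NA, ranges = NULL) {
  if (is.character(image)) image <- read_fundus(image)
  if (is.character(vessel_mask)) vessel_mask <- read_mask(vessel_mask)
  if (is.null(od_mask)) .quality_stop("optic disc required")
  if (is.character(od_mask)) od_mask <- read_mask(od_mask)
  d <- dim(image)[1:2]
  if (!all(dim(vessel_mask) == d) || !all(dim(od_mask) == d))
    stop("image and mask dimensions differ")
  if (!all(vessel_mask %in% 0:2)) stop("vessel mask labels must be 0/1/2")
  flags <- character(0)
  pp <- tryCatch(preprocess_fundus(image, config$preprocess, crop = FALSE),
                 error = function(e) {
                   if (grepl("field of view", conditionMessage(e)))
                     .quality_stop(conditionMessage(e))
                   stop(e)
                 })
  if (pp$fov_fraction < config$min_fov_fraction)
    .quality_stop(sprintf(
      "field of view covers %.1f%% of the image (minimum %.0f%%)",
      100 * pp$fov_fraction, 100 * config$min_fov_fraction))
  if (!any(od_mask > 0)) .quality_stop("optic disc required")
  geom <- od_geometry_from_mask(od_mask)
  zones <- zone_masks(geom, d)
  artery <- .analyze_class(vessel_mask, "artery", config, pp$image, geom)
  vein <- .analyze_class(vessel_mask, "vein", config, pp$image, geom)
  for (cls in c("artery", "vein")) {
    dat <- if (cls == "artery") artery else vein
    if (isTRUE(attr(dat$segments, "low_vessel_count")))
      flags <- c(flags, paste0("low_", cls, "_count"))
  }
  report <- build_report(artery, vein, vessel_mask, zones,
                         caliber_zone = config$caliber_zone,
                         knudtson_factors = config$knudtson_factors,
                         fd_on = config$fd_on,
                         microns_per_pixel = config$microns_per_pixel)
  report$flags <- unique(c(report$flags, flags))
  verdict <- NULL
  if (!is.null(ranges)) {
    pf <- parameter_risk_flag(report, ranges, rule = config$risk_rule)
    cf <- if (is.logical(classifier_flag) && !is.na(classifier_flag)) {
      if (classifier_flag) "cardio_suspect" else "non_cardio_suspect"
    } else classifier_flag
    verdict <- combine_verdicts(pf$flag, cf, evidence = pf$evidence)
  }
  structure(list(report = report, verdict = verdict, od_geometry = geom,
                 config = config, flags = flags,
                 artery = artery, vein = vein, zones = zones),
            class = "eye_analysis")
}

#' @export
print.eye_analysis <- function(x, ...) {
  print(x$report)
  if (!is.null(x$verdict)) print(x$verdict)
  invisible(x)
}

#' Write an analysis (or bare report) to JSON
#'
#' Nested JSON by class/zone including the pairing traces, the verdict if
#' present, and the configuration for provenance; floats are serialized at
#' fixed precision so identical runs produce byte-identical files.
#'
#' @param x an `eye_analysis` or `morphometry_report`.
#' @param path output path.
#' @param digits decimal digits for floats (default 6).
#' @export
write_report_json <- function(x, path, digits = 6) {
  if (inherits(x, "eye_analysis")) {
    payload <- list(schema = "retvasc-report/1",
                    report = unclass(x$report),
                    verdict = if (is.null(x$verdict)) NULL else unclass(x$verdict),
                    od_geometry = unclass(x$od_geometry),
                    config = .serializable_config(x$config),
                    flags = x$flags)
  } else {
    payload <- list(schema = "retvasc-report/1", report = unclass(x))
  }
  payload$report$box_count_curve <-
    if (is.null(payload$report$box_count_curve)) NULL else
      unclass(payload$report$box_count_curve)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = digits,
                       null = "null", dataframe = "rows", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

.serializable_config <- function(cfg) {
  out <- unclass(cfg)
  out$preprocess <- unclass(out$preprocess)
  out
}

#' Write the flat one-row CSV report
#'
#' @param x an `eye_analysis` or `morphometry_report`.
#' @param path output path.
#' @param eye_id optional identifier column.
#' @export
write_report_csv <- function(x, path, eye_id = NA) {
  rep <- if (inherits(x, "eye_analysis")) x$report else x
  df <- as.data.frame(rep)
  df <- cbind(data.frame(eye_id = eye_id), df)
  if (inherits(x, "eye_analysis") && !is.null(x$verdict)) {
    df$parameter_flag <- x$verdict$parameter_flag
    df$classifier_flag <- x$verdict$classifier_flag
    df$combined_verdict <- x$verdict$combined
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
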