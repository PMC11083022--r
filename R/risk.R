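# Risk flagging and decision scoring
# ------------------------------------------------------------------
# A parameter-based verdict from clinically sourced reference ranges over
# the three differentiator parameters (CRAE, AVR, mean artery width), an
# AND combination with an external classifier verdict, and confusion-
# matrix performance metrics.

#' Reference ranges for risk flagging
#'
#' Each parameter carries a risk interval `(low, high)`; a value inside
#' the interval fires that parameter's flag. Open ends are expressed with
#' `-Inf` / `Inf`. The shipped defaults are placeholders only: population
#' reference bands for fundus caliber depend on camera, resolution and
#' cohort, so users must supply clinically sourced intervals before any
#' interpretation.
#'
#' @param crae,avr,mean_artery_width numeric length-2 risk intervals.
#' @param warn warn about placeholder intervals (default TRUE).
#' @return object of class `reference_ranges`.
#' @export
reference_ranges <- function(crae = c(-Inf, NA), avr = c(-Inf, NA),
                             mean_artery_width = c(-Inf, NA), warn = TRUE) {
  rng <- list(crae = crae, avr = avr, mean_artery_width = mean_artery_width)
  rng <- Filter(function(x) !anyNA(x), rng)
  for (nm in names(rng)) {
    x <- rng[[nm]]
    if (length(x) != 2L || !(x[1] < x[2]))
      stop("interval for ", nm, " must be (low, high) with low < high")
  }
  if (warn && length(rng) == 0L)
    warning("no usable reference intervals: supply clinically sourced ranges")
  structure(rng, class = "reference_ranges")
}

#' Read / write reference ranges as JSON
#'
#' @param path JSON file with named `[low, high]` arrays (strings "-Inf"
#'   and "Inf" allowed).
#' @return a `reference_ranges` object.
#' @export
read_reference_ranges <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- lapply(x, function(v) as.numeric(v))
  do.call(reference_ranges, c(x, list(warn = FALSE)))
}

#' @rdname read_reference_ranges
#' @param ranges a `reference_ranges` object.
#' @export
write_reference_ranges <- function(ranges, path) {
  jsonlite::write_json(lapply(unclass(ranges), as.character), path,
                       auto_unbox = FALSE)
  invisible(path)
}

# pull the three differentiator parameters out of a report
.report_parameters <- function(report) {
  c(crae = report$caliber$crae,
    avr = report$caliber$avr,
    mean_artery_width = report$per_class$artery$zones$all$mean_width)
}

#' Parameter-based risk flag
#'
#' Flags an eye as cardio suspect when its differentiator parameters
#' (CRAE, AVR, mean artery width — the measurements that separate cardio
#' from healthy cohorts) fall inside their risk intervals. The default
#' decision rule fires on any single parameter; `rule = "all"` requires
#' every covered parameter to fire.
#'
#' @param report a `morphometry_report`.
#' @param ranges a [reference_ranges()] object.
#' @param rule `"any"` (default) or `"all"`.
#' @return list: `flag` (`"cardio_suspect"` / `"non_cardio_suspect"`) and
#'   `evidence` (data frame of parameter, value, low, high for flags that
#'   fired).
#' @export
parameter_risk_flag <- function(report, ranges, rule = c("any", "all")) {
  rule <- match.arg(rule)
  vals <- .report_parameters(report)
  use <- intersect(names(ranges), names(vals)[is.finite(vals)])
  if (length(use) == 0L) stop("ranges do not apply to any reported parameter")
  fired <- vapply(use, function(nm) {
    iv <- ranges[[nm]]
    vals[[nm]] > iv[1] && vals[[nm]] < iv[2]
  }, logical(1))
  flag <- if ((rule == "any" && any(fired)) || (rule == "all" && all(fired)))
    "cardio_suspect" else "non_cardio_suspect"
  ev <- data.frame(parameter = use[fired],
                   value = unname(vals[use[fired]]),
                   low = vapply(use[fired], function(n) ranges[[n]][1], numeric(1)),
                   high = vapply(use[fired], function(n) ranges[[n]][2], numeric(1)),
                   row.names = NULL)
  list(flag = flag, evidence = ev)
}

#' Combine the parameter and classifier verdicts
#'
#' Double-verification AND rule: the combined outcome is cardio suspect
#' only when both the parameter branch and the external classifier branch
#' say cardio suspect. With no classifier verdict the parameter flag
#' stands alone and the verdict is flagged single-branch.
#'
#' @param parameter_flag `"cardio_suspect"` or `"non_cardio_suspect"`.
#' @param classifier_flag same levels, or `NA` when absent.
#' @param evidence optional evidence data frame from
#'   [parameter_risk_flag()].
#' @return object of class `risk_verdict`.
#' @export
combine_verdicts <- function(parameter_flag, classifier_flag = NA,
                             evidence = NULL) {
  lv <- c("cardio_suspect", "non_cardio_suspect")
  stopifnot(parameter_flag %in% lv)
  flags <- character(0)
  if (is.na(classifier_flag)) {
    combined <- parameter_flag
    classifier_flag <- "absent"
    flags <- "single-branch"
  } else {
    stopifnot(classifier_flag %in% lv)
    combined <- if (parameter_flag == "cardio_suspect" &&
                    classifier_flag == "cardio_suspect")
      "cardio_suspect" else "non_cardio_suspect"
  }
  structure(list(parameter_flag = parameter_flag,
                 classifier_flag = classifier_flag,
                 combined = combined, evidence = evidence, flags = flags),
            class = "risk_verdict")
}

#' @export
print.risk_verdict <- function(x, ...) {
  cat(sprintf("<risk_verdict: parameter %s, classifier %s -> %s%s>\n",
              x$parameter_flag, x$classifier_flag, x$combined,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  if (!is.null(x$evidence) && nrow(x$evidence)) {
    cat("  evidence:\n")
    print(x$evidence)
  }
  invisible(x)
}

#' Subject-level verdict from two eyes
#'
#' A subject is cardio suspect when either eye's combined verdict is.
#'
#' @param ... `risk_verdict` objects (one per eye).
#' @return `"cardio_suspect"` or `"non_cardio_suspect"`.
#' @export
subject_verdict <- function(...) {
  vs <- list(...)
  if (any(vapply(vs, function(v) v$combined == "cardio_suspect", logical(1))))
    "cardio_suspect" else "non_cardio_suspect"
}

#' Confusion matrix
#'
#' @param tp,fn,fp,tn non-negative integer counts; the positive class is
#'   the cardio-suspect / risk class.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty confusion matrix")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(predicted = c("positive", "negative"),
                              actual = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Confusion-matrix performance metrics
#'
#' Accuracy, sensitivity (recall of the positive class), specificity,
#' precision and F1, each on the 0-100 scale. F1 is computed from the
#' unrounded precision and sensitivity; `summary` rounds to 2 decimals.
#' A metric whose denominator is zero is returned as `NA` and named in
#' `undefined`.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1` (unrounded, 0-100) and `undefined`.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  total <- tp + fn + fp + tn
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  acc <- safe(tp + tn, total)
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1 <- if (is.finite(sens) && is.finite(prec) && (sens + prec) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  out <- list(accuracy = acc, sensitivity = sens, specificity = spec,
              precision = prec, f1 = f1)
  out$undefined <- names(out)[vapply(out, function(v) !is.finite(v), logical(1))]
  out
}

#' Round metrics for reporting
#'
#' @param metrics result of [confusion_metrics()].
#' @param digits decimal places (default 2, the reporting convention).
#' @return named numeric vector rounded to `digits`.
#' @export
round_metrics <- function(metrics, digits = 2) {
  v <- unlist(metrics[c("accuracy", "sensitivity", "specificity",
                        "precision", "f1")])
  round(v, digits)
}

#' Score predictions against truth
#'
#' @param pred,truth vectors of equal length with levels
#'   `cardio_suspect` / `non_cardio_suspect` (or logical, TRUE = positive).
#' @return list of the [confusion_matrix()] and its [confusion_metrics()].
#' @export
evaluate_predictions <- function(pred, truth) {
  as_pos <- function(x) if (is.logical(x)) x else x == "cardio_suspect"
  p <- as_pos(pred); t <- as_pos(truth)
  stopifnot(length(p) == length(t))
  cm <- confusion_matrix(tp = sum(p & t), fn = sum(!p & t),
                         fp = sum(p & !t), tn = sum(!p & !t))
  list(confusion = cm, metrics = confusion_metrics(cm))
}
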