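test_that("parameter flag fires on any differentiator inside its risk interval", {
  rng <- reference_ranges(crae = c(-Inf, 15), avr = c(-Inf, 0.667),
                          mean_artery_width = c(-Inf, 6), warn = FALSE)
  r1 <- parameter_risk_flag(fake_report(crae = 14.0, avr = 0.8,
                                        mean_artery_width = 8), rng)
  expect_equal(r1$flag, "cardio_suspect")
  expect_equal(r1$evidence$parameter, "crae")
  r2 <- parameter_risk_flag(fake_report(crae = 18, avr = 0.8,
                                        mean_artery_width = 8), rng)
  expect_equal(r2$flag, "non_cardio_suspect")
  expect_equal(nrow(r2$evidence), 0L)
  r3 <- parameter_risk_flag(fake_report(crae = 18, avr = 0.60,
                                        mean_artery_width = 8), rng)
  expect_equal(r3$flag, "cardio_suspect")
  expect_equal(nrow(r3$evidence), 1L)
  expect_equal(r3$evidence$parameter, "avr")
  # all-of rule needs every covered parameter inside its interval
  r4 <- parameter_risk_flag(fake_report(crae = 14, avr = 0.6,
                                        mean_artery_width = 8), rng, rule = "all")
  expect_equal(r4$flag, "non_cardio_suspect")
  expect_error(parameter_risk_flag(fake_report(crae = NA, avr = NA,
                                               mean_artery_width = NA), rng),
               "do not apply")
})

test_that("enlarging a risk interval never un-flags a suspect", {
  set.seed(31)
  for (i in 1:50) {
    crae_hi <- runif(1, 10, 20)
    rng <- reference_ranges(crae = c(-Inf, crae_hi), warn = FALSE)
    rep <- fake_report(crae = runif(1, 5, 25))
    f1 <- parameter_risk_flag(rep, rng)$flag
    rng2 <- reference_ranges(crae = c(-Inf, crae_hi + runif(1, 0, 10)),
                             warn = FALSE)
    f2 <- parameter_risk_flag(rep, rng2)$flag
    if (f1 == "cardio_suspect") expect_equal(f2, "cardio_suspect")
  }
})

test_that("the combined verdict is an AND over both branches", {
  cs <- "cardio_suspect"; ns <- "non_cardio_suspect"
  expect_equal(combine_verdicts(cs, cs)$combined, cs)
  expect_equal(combine_verdicts(cs, ns)$combined, ns)
  expect_equal(combine_verdicts(ns, cs)$combined, ns)
  expect_equal(combine_verdicts(ns, ns)$combined, ns)
  # absent classifier: parameter branch stands alone, flagged
  v <- combine_verdicts(cs, NA)
  expect_equal(v$combined, cs)
  expect_true("single-branch" %in% v$flags)
  expect_equal(subject_verdict(combine_verdicts(ns, NA), combine_verdicts(cs, NA)),
               cs)
  expect_equal(subject_verdict(combine_verdicts(ns, NA), combine_verdicts(ns, NA)),
               ns)
})

test_that("confusion metrics reproduce the worked validation tables", {
  m <- confusion_metrics(confusion_matrix(tp = 28, fn = 4, fp = 5, tn = 29))
  expect_equal(round(m$sensitivity, 2), 87.5)
  expect_equal(round(m$specificity, 2), 85.29)
  expect_equal(round(m$accuracy, 2), 86.36)
  expect_equal(round(m$f1, 2), 86.15)
  m2 <- confusion_metrics(confusion_matrix(tp = 40, fn = 9, fp = 4, tn = 35))
  expect_equal(round(m2$accuracy, 2), 85.23)
  expect_equal(round(m2$accuracy), 85)
  m3 <- confusion_metrics(confusion_matrix(10, 0, 0, 10))
  expect_true(all(unlist(m3[c("accuracy", "sensitivity", "specificity",
                              "precision", "f1")]) == 100))
})

test_that("relabeling the positive class swaps sensitivity and specificity", {
  set.seed(77)
  for (i in 1:20) {
    cm <- confusion_matrix(tp = sample(1:40, 1), fn = sample(1:40, 1),
                           fp = sample(1:40, 1), tn = sample(1:40, 1))
    sw <- confusion_matrix(tp = cm$tn, fn = cm$fp, fp = cm$fn, tn = cm$tp)
    m <- confusion_metrics(cm); ms <- confusion_metrics(sw)
    expect_equal(m$sensitivity, ms$specificity)
    expect_equal(m$specificity, ms$sensitivity)
    expect_equal(m$accuracy, ms$accuracy)
  }
})

test_that("zero denominators flag individual metrics, not the whole result", {
  m <- confusion_metrics(confusion_matrix(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true("sensitivity" %in% m$undefined)
  expect_false(is.na(m$specificity))
  expect_false(is.na(m$accuracy))
})

test_that("predictions are scored end to end and ranges round-trip as JSON", {
  pred <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  truth <- c(TRUE, FALSE, FALSE, TRUE, TRUE)
  ev <- evaluate_predictions(pred, truth)
  expect_equal(ev$confusion$tp, 2)
  expect_equal(ev$confusion$fp, 1)
  expect_equal(ev$confusion$fn, 1)
  expect_equal(ev$confusion$tn, 1)
  expect_equal(ev$metrics$accuracy, 100 * 3 / 5)
  rng <- reference_ranges(crae = c(-Inf, 15), avr = c(0.2, 0.667), warn = FALSE)
  f <- tempfile(fileext = ".json")
  write_reference_ranges(rng, f)
  back <- read_reference_ranges(f)
  expect_equal(back$crae, rng$crae)
  expect_equal(back$avr, rng$avr)
})
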