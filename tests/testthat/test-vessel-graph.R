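test_that("a straight strip becomes one edge between two endpoints", {
  mk <- strip_mask(height = 7, cols = 10:109)
  g <- skeletonize_and_build(mk, "artery")
  expect_equal(length(g$edges), 1L)
  expect_equal(sum(g$nodes$degree == 1L), 2L)
  # medial axis of an L x h rectangle has an axial segment of length L - h
  # (the corner branches are spurs below the pruning threshold)
  len <- sum(sqrt(diff(g$edges[[1]]$pixels[, 1])^2 +
                    diff(g$edges[[1]]$pixels[, 2])^2))
  expect_lt(abs(len - (100 - 7)), 2)
})

test_that("a Y phantom yields one degree-3 junction and three edges", {
  mk <- y_mask(9, 7, 5)
  g <- skeletonize_and_build(mk, "artery")
  expect_equal(sum(g$nodes$degree == 3L), 1L)
  expect_equal(sum(g$nodes$degree == 1L), 3L)
  expect_equal(length(g$edges), 3L)
})

test_that("an empty class yields an empty flagged graph", {
  mk <- matrix(0L, 64, 64)
  g <- skeletonize_and_build(mk, "vein")
  expect_equal(length(g$edges), 0L)
  expect_equal(nrow(g$nodes), 0L)
  expect_true("empty_vessel_class" %in% g$flags)
})

test_that("graph edges partition the skeleton pixels", {
  mk <- y_mask(9, 7, 5)
  g <- skeletonize_and_build(mk, "artery")
  interior <- lapply(g$edges, function(e)
    e$pixels[-c(1, nrow(e$pixels)), , drop = FALSE])
  keys <- unlist(lapply(interior, function(p) paste(p[, 1], p[, 2])))
  expect_equal(anyDuplicated(keys), 0L)           # no pixel in two edges
  allkeys <- unique(unlist(lapply(g$edges, function(e)
    paste(e$pixels[, 1], e$pixels[, 2]))))
  skkeys <- apply(which(g$skeleton, arr.ind = TRUE), 1, paste, collapse = " ")
  expect_true(all(skkeys %in% allkeys))           # every skeleton pixel covered
})

test_that("cross-sectional width recovers strip height at any orientation", {
  mk <- strip_mask(height = 7, cols = 10:109)
  expect_lt(abs(measure_width(mk, c(30, 60)) - 7), 1 + 1e-9)
  # 45-degree strip of width 5
  mk2 <- matrix(0L, 200, 200)
  t <- seq(-90, 90, by = 0.25)
  mk2 <- draw_band(mk2, cbind(100 + t * sin(pi / 4), 100 + t * cos(pi / 4)), 5)
  expect_lt(abs(measure_width(mk2, c(100, 100)) - 5), 1 + 1e-9)
  # isolated single pixel
  mk3 <- matrix(0L, 20, 20); mk3[10, 10] <- 1L
  expect_lte(measure_width(mk3, c(10, 10)), 2)
  expect_error(measure_width(mk3, c(1, 1)), "background")
})

test_that("width measurement is invariant under 90-degree image rotation", {
  mk <- matrix(0L, 160, 160)
  t <- seq(-70, 70, by = 0.25)
  mk <- draw_band(mk, cbind(80 + t * sin(0.5), 80 + t * cos(0.5)), 7)
  w1 <- measure_width(mk, c(80, 80))
  rot <- t(mk[nrow(mk):1, ])                       # clockwise 90 degrees
  w2 <- measure_width(rot, c(80, nrow(mk) + 1 - 80))  # image of (80, 80)
  expect_lt(abs(w1 - w2), 1 + 1e-9)
})

test_that("segment lengths and width profiles match the generating geometry", {
  mk <- strip_mask(height = 7, cols = 10:109)
  g <- skeletonize_and_build(mk, "artery")
  s <- segments_with_widths(g, mk)[[1]]
  expect_true(all(abs(s$widths - 7) <= 1 + 1e-9))
  expect_lt(abs(s$path_length - s$chord_length) / s$chord_length, 0.01)
  # sinusoidal centerline, amplitude 20, one period over 200 px
  tt <- seq(0, 200, by = 0.2)
  cl <- cbind(80 + 20 * sin(2 * pi * tt / 200), 30 + tt)
  mk2 <- draw_band(matrix(0L, 160, 260), cl, 7)
  L <- sum(sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2))
  g2 <- skeletonize_and_build(mk2, "artery")
  segs <- segments_with_widths(g2, mk2)
  s2 <- segs[[which.max(vapply(segs, `[[`, numeric(1), "path_length"))]]
  expect_lt(abs(s2$path_length - L) / L, 0.02)
})

test_that("ranking keeps the k most prominent vessels with documented ties", {
  mk <- matrix(0L, 300, 120)
  for (i in 1:8) mk[(30 * i):(30 * i + 12 - i), 10:109] <- 1L  # widths 13..6 px
  g <- skeletonize_and_build(mk, "artery")
  segs <- segments_with_widths(g, mk)
  expect_equal(length(segs), 8L)
  top <- rank_top_vessels(segs, k = 6)
  expect_equal(length(top), 6L)
  expect_false(attr(top, "low_vessel_count"))
  got <- sort(vapply(top, `[[`, numeric(1), "mean_width"), decreasing = TRUE)
  all8 <- sort(vapply(segs, `[[`, numeric(1), "mean_width"), decreasing = TRUE)
  expect_equal(got, all8[1:6])                     # the six widest survive
  expect_equal(vapply(top, `[[`, integer(1), "rank"), 1:6)
  # k larger than available
  all_back <- rank_top_vessels(segs, k = 20)
  expect_equal(length(all_back), 8L)
  expect_true(attr(all_back, "low_vessel_count"))
  # rank order invariant to uniform score rescaling (weights scaled)
  t2 <- rank_top_vessels(segs, k = 6, weights = 10 * c(0.4, 0.2, 0.3, 0.1))
  expect_equal(vapply(t2, `[[`, integer(1), "id"),
               vapply(top, `[[`, integer(1), "id"))
  expect_error(rank_top_vessels(list()), "no segments")
})

test_that("junction extraction recovers parent and daughter widths", {
  mk <- y_mask(9, 7, 5)
  g <- skeletonize_and_build(mk, "artery")
  segs <- segments_with_widths(g, mk)
  j <- extract_junctions(g, segs)
  expect_equal(length(j), 1L)
  expect_lte(abs(j[[1]]$r0 - 9), 1)
  expect_equal(length(j[[1]]$daughters), 2L)
  expect_lte(abs(j[[1]]$daughters[1] - 7), 1)
  expect_lte(abs(j[[1]]$daughters[2] - 5), 1)
  # graph without junctions
  mk2 <- strip_mask()
  g2 <- skeletonize_and_build(mk2, "artery")
  expect_equal(length(extract_junctions(g2, segments_with_widths(g2, mk2))), 0L)
})
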