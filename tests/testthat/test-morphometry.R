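test_that("junction-level measures follow their closed forms", {
  # branching coefficient
  expect_equal(branching_coefficient(jn(10, c(10, 10))), 2.0)
  expect_equal(branching_coefficient(jn(10, c(8, 6))), (64 + 36) / 100)
  expect_equal(branching_coefficient(jn(12, c(9, 7))), 130 / 144)
  expect_true(is.na(branching_coefficient(jn(10, c(8, 6, 4)))))
  # junction exponent, printed cubic-difference form
  expect_equal(junction_exponent(jn(10, numeric(0))), 1000)
  expect_equal(junction_exponent(jn(10, rep(10 / 2^(1 / 3), 2))), 0,
               tolerance = 1e-9)
  expect_equal(junction_exponent(jn(10, c(8, 8))), 1000 - 1024)
  # classical exponent: Murray's law junction solves to 3
  expect_equal(junction_exponent_classical(jn(10, rep(10 / 2^(1 / 3), 2))), 3,
               tolerance = 1e-6)
  # optimality ratio
  expect_equal(optimality_ratio(jn(10, c(10, 10))), 1.0)
  expect_equal(optimality_ratio(jn(10, rep(10 / 2^(1 / 3), 2))), 0.5^(1 / 3),
               tolerance = 1e-9)
  expect_equal(optimality_ratio(jn(10, c(6, 1e-12))), (216 / 2000)^(1 / 3),
               tolerance = 1e-6)
  # symmetry in the daughters
  expect_equal(branching_coefficient(jn(9, c(7, 4))),
               branching_coefficient(jn(9, c(4, 7))))
  expect_equal(optimality_ratio(jn(9, c(7, 4))),
               optimality_ratio(jn(9, c(4, 7))))
  # diameter reduction
  expect_equal(diameter_reduction(jn(10, c(10, 10))), 0)
  expect_equal(diameter_reduction(jn(10, c(8, 8))), 0.2)
  expect_equal(diameter_reduction(jn(10, c(12, 12))), -0.2)
})

test_that("mean vessel width pools all retained samples", {
  seg <- function(w) structure(list(widths = w), class = "vessel_segment")
  expect_equal(mean_vessel_width(list(seg(c(7, 7, 7)))), 7)
  expect_equal(mean_vessel_width(list(seg(c(6, 8)), seg(10))), 8)
  expect_true(is.na(mean_vessel_width(list(seg(numeric(0))))))
})

test_that("simple tortuosity is excess arc length over the chord", {
  seg <- function(L, C) structure(list(path_length = L, chord_length = C),
                                  class = "vessel_segment")
  expect_equal(simple_tortuosity(seg(100, 100)), 0)
  expect_true(is.na(simple_tortuosity(seg(50, 0))))
  # semicircular arc of radius 60 rendered as a band
  th <- seq(0, pi, length.out = 2000)
  cl <- cbind(100 - 60 * sin(th), 200 + 60 * cos(th))
  mk <- draw_band(matrix(0L, 200, 400), cl, 7)
  g <- skeletonize_and_build(mk, "artery")
  segs <- segments_with_widths(g, mk)
  s <- segs[[which.max(vapply(segs, `[[`, numeric(1), "path_length"))]]
  expect_lt(abs(simple_tortuosity(s) - (pi - 2) / 2) / ((pi - 2) / 2), 0.02)
  # sinusoid amplitude 20, period 200 vs quadrature
  tt <- seq(0, 400, by = 0.2)
  cl2 <- cbind(80 + 20 * sin(2 * pi * tt / 200), 30 + tt)
  mk2 <- draw_band(matrix(0L, 160, 460), cl2, 7)
  L <- sum(sqrt(diff(cl2[, 1])^2 + diff(cl2[, 2])^2))
  C <- sqrt(sum((cl2[nrow(cl2), ] - cl2[1, ])^2))
  g2 <- skeletonize_and_build(mk2, "artery")
  segs2 <- segments_with_widths(g2, mk2)
  s2 <- segs2[[which.max(vapply(segs2, `[[`, numeric(1), "path_length"))]]
  expect_lt(abs(simple_tortuosity(s2) - (L - C) / C) / ((L - C) / C), 0.02)
})

test_that("tree path statistics enumerate root-to-leaf paths", {
  ts <- tree_path_stats(toy_tree_graph())
  expect_equal(ts$largest_external_path, 17)
  expect_equal(ts$sum_external_paths, 32)
  expect_equal(ts$n_exterior_interior_paths, 2L)
  # single segment
  mk <- strip_mask(cols = 30:69)
  g <- skeletonize_and_build(mk, "artery")
  ts2 <- tree_path_stats(g)
  expect_equal(ts2$n_exterior_interior_paths, 1L)
  expect_equal(ts2$largest_external_path, ts2$sum_external_paths)
  expect_gt(ts2$largest_external_path, 25)
  # empty graph
  g0 <- skeletonize_and_build(matrix(0L, 32, 32), "artery")
  ts0 <- tree_path_stats(g0)
  expect_equal(unlist(ts0[1:3], use.names = FALSE), c(0, 0, 0))
  expect_true("empty_graph" %in% ts0$flags)
})

test_that("Knudtson pairing matches the hand-iterated oracle", {
  # closed form for six equal widths w: f^2 * w * sqrt(4 f^2 + 2)
  ka <- knudtson_equivalent(rep(10, 6), 0.88)
  kv <- knudtson_equivalent(rep(10, 6), 0.95)
  expect_equal(ka$value, 0.88^2 * 10 * sqrt(4 * 0.88^2 + 2), tolerance = 1e-9)
  expect_equal(kv$value, 0.95^2 * 10 * sqrt(4 * 0.95^2 + 2), tolerance = 1e-9)
  # hand-iterated round values
  expect_equal(sort(unique(round(ka$pairing_trace$combined[1:3], 4))), 12.4451)
  expect_equal(round(ka$pairing_trace$combined[4], 4), 15.4880)
  expect_equal(round(ka$pairing_trace$combined[5], 4), 17.4843)
  # single-width fallback
  k1 <- knudtson_equivalent(8.5, 0.88)
  expect_equal(k1$value, 8.5)
  expect_true("insufficient vessels" %in% k1$flags)
  expect_error(knudtson_equivalent(numeric(0), 0.88), "no widths")
})

test_that("Knudtson pairing is order-invariant (brute force over permutations)", {
  w <- c(11.2, 9.5, 8.1, 7.4, 6.3)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  vals <- vapply(perms(w),
                 function(p) knudtson_equivalent(p, 0.88)$value, numeric(1))
  expect_equal(length(unique(round(vals, 12))), 1L)
})

test_that("increasing any single width never decreases the equivalent", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:6, 1)
    w <- runif(n, 4, 25)
    j <- sample(n, 1)
    w2 <- w; w2[j] <- w2[j] + runif(1, 0.1, 5)
    expect_gte(knudtson_equivalent(w2, 0.88)$value,
               knudtson_equivalent(w, 0.88)$value)
  }
})

test_that("caliber summaries are scale-equivariant, ratios scale-free", {
  set.seed(55)
  w_a <- runif(6, 6, 12); w_v <- runif(6, 8, 15); cf <- 2.7
  expect_equal(knudtson_equivalent(cf * w_a, 0.88)$value,
               cf * knudtson_equivalent(w_a, 0.88)$value, tolerance = 1e-12)
  expect_equal(knudtson_equivalent(cf * w_v, 0.95)$value,
               cf * knudtson_equivalent(w_v, 0.95)$value, tolerance = 1e-12)
  a1 <- knudtson_equivalent(w_a, 0.88)$value
  v1 <- knudtson_equivalent(w_v, 0.95)$value
  a2 <- knudtson_equivalent(cf * w_a, 0.88)$value
  v2 <- knudtson_equivalent(cf * w_v, 0.95)$value
  expect_equal(avr(a1, v1), avr(a2, v2), tolerance = 1e-12)
  j1 <- jn(10, c(8, 6)); j2 <- jn(cf * 10, cf * c(8, 6))
  expect_equal(branching_coefficient(j1), branching_coefficient(j2))
  expect_equal(optimality_ratio(j1), optimality_ratio(j2), tolerance = 1e-12)
  expect_equal(diameter_reduction(j1), diameter_reduction(j2), tolerance = 1e-12)
})

test_that("arteriovenous ratio behaves as a plain caliber ratio", {
  expect_equal(avr(20, 20), 1.0)
  expect_equal(avr(14, 20), 0.7)
  k <- knudtson_equivalent(rep(10, 6), 0.88)$value /
    knudtson_equivalent(rep(10, 6), 0.95)$value
  expect_equal(k, 0.8180, tolerance = 1e-3)
  expect_true(is.na(avr(14, 0)))
})

test_that("box counting recovers known fractal dimensions", {
  expect_lt(abs(fractal_dimension(fractal_fixture("line", 256))$slope - 1), 0.1)
  expect_lt(abs(fractal_dimension(fractal_fixture("square", 256))$slope - 2), 0.1)
  fd <- fractal_dimension(fractal_fixture("sierpinski", 243, 5))
  expect_lt(abs(fd$slope - log(3) / log(2)), 0.1)
  expect_true(all(diff(fd$box_sizes) < 0))
  expect_true(all(diff(fd$counts) >= 0))
  expect_error(fractal_dimension(matrix(0L, 64, 64)), "empty")
})

test_that("box counts are invariant under whole-grid translations", {
  m <- matrix(0L, 256, 256)
  set.seed(9)
  blob <- matrix(as.integer(runif(32 * 32) > 0.4), 32, 32)
  m1 <- m; m1[17:48, 33:64] <- blob
  m2 <- m; m2[(17 + 64):(48 + 64), (33 + 128):(64 + 128)] <- blob
  f1 <- fractal_dimension(m1); f2 <- fractal_dimension(m2)
  expect_equal(f1$counts, f2$counts)   # offsets are multiples of every box size
  expect_equal(f1$slope, f2$slope)
})
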