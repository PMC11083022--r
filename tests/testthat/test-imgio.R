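test_that("gamma adjustment follows the inverse-gamma lookup table", {
  img <- fundus_image(array(128L, dim = c(64, 64, 3)))
  expect_identical(unclass(gamma_adjust(img, 1.0)), unclass(img))
  # fixed points of the power law, any gamma
  v <- array(0L, dim = c(64, 64, 3)); v[1, 1, ] <- 255L
  for (g in c(0.5, 1.2, 2.0)) {
    out <- gamma_adjust(fundus_image(v), g)
    expect_equal(out[1, 1, 1], 255L)
    expect_equal(out[2, 2, 1], 0L)
  }
  # direct evaluation of the formula at v = 128, gamma = 2
  expect_equal(gamma_adjust(img, 2.0)[5, 5, 2], round(255 * (128 / 255)^0.5))
  expect_equal(gamma_adjust(img, 2.0)[5, 5, 2], 181L)
  # monotone non-decreasing in input intensity
  ramp <- matrix(0:255, 16, 16)
  out <- gamma_adjust(ramp, 1.7)
  expect_true(all(diff(as.vector(out)) >= 0))
  expect_error(gamma_adjust(img, 0), "positive")
  expect_error(gamma_adjust(img, -1), "positive")
})

test_that("border mask finds the retinal field of view", {
  # no border present
  img <- fundus_image(array(128L, dim = c(64, 64, 3)))
  expect_true(all(compute_border_mask(img, 10) == 1L))
  # bright disc of radius 100 in a 256x256 black frame
  a <- array(0L, dim = c(256, 256, 3))
  rr <- matrix(1:256, 256, 256); cc <- t(rr)
  disc <- (rr - 128)^2 + (cc - 128)^2 <= 100^2
  for (ch in 1:3) a[, , ch] <- 200L * disc
  m <- compute_border_mask(fundus_image(a), 10)
  expect_lt(abs(sum(m) - pi * 100^2) / (pi * 100^2), 0.01)
  expect_true(all(m[disc] == 1L))
  # all dark
  expect_error(compute_border_mask(fundus_image(array(0L, dim = c(64, 64, 3)))),
               "no retinal field of view")
})

test_that("enhancement touches only the green channel inside the field", {
  set.seed(7)
  a <- array(sample(30:220, 100 * 100 * 3, TRUE), dim = c(100, 100, 3))
  img <- fundus_image(a)
  ones <- matrix(1L, 100, 100)
  out <- enhance(img, ones)
  expect_identical(out[, , 1], img[, , 1])   # blue untouched
  expect_identical(out[, , 3], img[, , 3])   # red untouched
  expect_equal(dim(out), dim(img))
  # masked-out pixels are zeroed in every channel
  m <- ones; m[1:20, 1:20] <- 0L
  out2 <- enhance(img, m)
  expect_true(all(out2[1:20, 1:20, ] == 0L))
  expect_error(enhance(img, matrix(1L, 50, 50)), "shapes differ")
})

test_that("uniform green field maps to green_scale times the reference value", {
  # CLAHE at clip limit 1.0 redistributes a one-bin histogram to uniform,
  # whose cdf is the identity: the reference value for input 128 is 128
  a <- array(128L, dim = c(100, 100, 3))
  out <- enhance(fundus_image(a), matrix(1L, 100, 100))
  expect_true(all(out[, , 2] == round(0.8 * 128)))
})

test_that("preprocessing chain preserves shape and records config", {
  a <- array(0L, dim = c(128, 128, 3))
  rr <- matrix(1:128, 128, 128); cc <- t(rr)
  fov <- (rr - 64)^2 + (cc - 64)^2 <= 60^2
  for (ch in 1:3) a[, , ch] <- (80L + 20L * ch) * fov
  pp <- preprocess_fundus(fundus_image(a), crop = FALSE)
  expect_equal(dim(pp$image), dim(a))
  expect_s3_class(pp$config, "preprocess_config")
  expect_gt(pp$fov_fraction, 0.5)
  expect_true(all(pp$image[!fov] == 0L))     # masked region stays dark
  cr <- preprocess_fundus(fundus_image(a), crop = TRUE)
  expect_lte(dim(cr$image)[1], 128)
})

test_that("images and masks round-trip through PNG", {
  skip_if_not_installed("EBImage")
  set.seed(11)
  a <- array(sample(0:255, 64 * 80 * 3, TRUE), dim = c(64, 80, 3))
  img <- fundus_image(a)
  f <- tempfile(fileext = ".png")
  write_fundus(img, f)
  back <- read_fundus(f)
  expect_equal(unclass(back), unclass(img), ignore_attr = TRUE)
  mk <- matrix(sample(0:2, 64 * 80, TRUE), 64, 80)
  f2 <- tempfile(fileext = ".png")
  write_mask(mk, f2)
  expect_equal(read_mask(f2), mk, ignore_attr = TRUE)
})
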