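# Pixel-feature operators: DoG, local entropy, membrane projections and the
# assembled feature stack.

test_that("difference of Gaussians annihilates constants and is antisymmetric", {
  const <- matrix(7, 32, 32)
  expect_lt(max(abs(dog_filter(const, 1, 2))), 1e-12)

  set.seed(2)
  x <- matrix(runif(32 * 32) * 255, 32)
  expect_equal(dog_filter(x, 1, 2), -dog_filter(x, 2, 1), tolerance = 1e-12)
  expect_error(dog_filter(x, -1, 2), "positive")
})

test_that("DoG impulse response matches the analytic Gaussian difference", {
  n <- 65
  imp <- matrix(0, n, n)
  imp[33, 33] <- 1
  r <- dog_filter(imp, 1, 2)
  analytic <- 1 / (2 * pi * 1^2) - 1 / (2 * pi * 2^2)
  expect_lt(abs(r[33, 33] - analytic), 1e-6)
})

test_that("DoG is linear: constants drop, scaling passes through", {
  set.seed(3)
  x <- matrix(runif(24 * 24) * 255, 24)
  expect_equal(dog_filter(3 * x + 11, 1, 2), 3 * dog_filter(x, 1, 2),
               tolerance = 1e-9)
})

test_that("local entropy matches a brute-force histogram oracle", {
  # homogeneous neighbourhood
  expect_lt(max(local_entropy(matrix(100, 16, 16), radius = 2, n_bins = 64)),
            1e-12)

  # equal-count histograms score exactly 1 and 2 bits
  expect_identical(shannon_entropy_bits(c(5, 5)), 1)
  expect_identical(shannon_entropy_bits(c(3, 3, 3, 3)), 2)
  expect_identical(shannon_entropy_bits(c(7, 0)), 0)

  # per-pixel values equal a scalar re-computation at interior pixels
  set.seed(4)
  r <- matrix(floor(runif(20 * 20) * 256), 20)
  Hr <- local_entropy(r, radius = 2, n_bins = 16)
  for (pt in list(c(5, 5), c(10, 14), c(16, 7))) {
    win <- r[(pt[1] - 2):(pt[1] + 2), (pt[2] - 2):(pt[2] + 2)]
    bins <- pmin(floor(win / 256 * 16), 15)
    expect_equal(Hr[pt[1], pt[2]],
                 shannon_entropy_bits(tabulate(bins + 1, 16)),
                 tolerance = 1e-9)
  }
  expect_true(all(Hr >= 0 & Hr <= log2(16) + 1e-12))
})

test_that("membrane projections detect oriented lines", {
  const <- matrix(5, 40, 40)
  mp <- membrane_projections(const, 19, 6)
  expect_equal(dim(mp)[3], 6)
  for (p in 1:5) expect_lt(diff(range(mp[10:30, 10:30, p])), 1e-9)
  expect_lt(max(abs(mp[, , 6])), 1e-9)   # std projection of a constant is 0

  line <- matrix(0, 41, 41)
  line[, 21] <- 1
  mp2 <- membrane_projections(line, 19, 6, projections = c("max", "min"))
  mx <- mp2[, , 1]
  expect_true(all(mx[15:27, 21] >= mx[15:27, c(5, 37)]))
  # direct kernel check: the vertical (0 deg) rotation responds at least as
  # strongly as the horizontal one everywhere on the line
  k0 <- stickvision:::membrane_kernel(19, 0)
  k90 <- stickvision:::membrane_kernel(19, 90)
  r0 <- stickvision:::conv2d_same(line, k0)
  r90 <- stickvision:::conv2d_same(line, k90)
  expect_true(all(r0[15:27, 21] >= r90[15:27, 21]))

  expect_error(membrane_projections(line, 18, 6), "odd")
})

test_that("the default feature stack has the documented 18 channels", {
  set.seed(5)
  px <- array(runif(32 * 24 * 3) * 255, c(32, 24, 3))
  px[1, 1, ] <- 0; px[2, 2, ] <- 255   # extremes
  img <- stick_image("f", px, "mid")
  roi <- mask_raster("f", matrix(1, 32, 24))
  st <- build_feature_stack(img, roi, feature_recipe())
  expect_equal(dim(st$features)[3], 18)
  expect_length(st$channel_names, 18)
  expect_true(all(is.finite(st$features)))
})
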