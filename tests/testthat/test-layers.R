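# Building blocks: parameter arithmetic, degenerate configurations and
# behavioural contracts of GhostConv, VanillaNet blocks, DSC, spatial
# attention, the input adapter and spatial dropout.

test_that("GhostConv parameter arithmetic matches weight shapes", {
  g <- build_ghost_conv(16, 32, primary_kernel = 1, ratio = 2,
                        cheap_kernel = 3, normalization = FALSE)
  expect_identical(count_parameters(g), 272L + 160L)
  expect_error(build_ghost_conv(16, 30, ratio = 4), "divisible")

  # ratio 1 degenerates to a standard convolution with identical output
  set.seed(31)
  g1 <- build_ghost_conv(4, 8, primary_kernel = 3, ratio = 1,
                         normalization = FALSE)
  nn_materialize(g1)
  std <- conv_bn(4, 8, k = 3, bias = TRUE, bn = FALSE)
  nn_materialize(std)
  std$params <- g1$params
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1))
  tp <- tape_new()
  xi <- op_leaf(tp, x)
  expect_identical(tp_val(tp, g1$fwd(tp, xi, FALSE)),
                   tp_val(tp, std$fwd(tp, xi, FALSE)))
})

test_that("GhostConv is cheaper than the standard convolution it replaces", {
  set.seed(32)
  for (i in 1:20) {
    cin <- sample(c(8, 16, 32, 64), 1)
    cout <- sample(c(16, 32, 64, 128), 1)
    ghost <- count_parameters(build_ghost_conv(cin, cout, primary_kernel = 3,
                                               ratio = 2, cheap_kernel = 3))
    std <- count_parameters(conv_bn(cin, cout, k = 3))
    expect_lt(ghost, std)
  }
})

test_that("VanillaNet blocks honour shape contracts and grouping arithmetic", {
  vb <- build_vanilla_block(64, 128, groups = 2, downsample = TRUE,
                            activation = "relu")
  nn_materialize(vb)
  tp <- tape_new()
  y <- vb$fwd(tp, op_leaf(tp, array(rnorm(32 * 32 * 64), c(32, 32, 64, 1))), TRUE)
  expect_equal(dim(tp_val(tp, y)), c(16, 16, 128, 1))

  expect_error(build_vanilla_block(10, 16, groups = 4), "divide")

  # grouped convolution halves the weight count at groups = 2
  pg <- count_parameters(conv_bn(32, 64, k = 3, groups = 2, bn = FALSE,
                                 bias = FALSE))
  ps <- count_parameters(conv_bn(32, 64, k = 3, groups = 1, bn = FALSE,
                                 bias = FALSE))
  expect_identical(ps, 2L * pg)
})

test_that("dynamic ReLU at the identity gate equals plain ReLU", {
  set.seed(33)
  dr <- conv_bn(4, 6, k = 3, act = "dynamic_relu")
  nn_materialize(dr)
  pr <- conv_bn(4, 6, k = 3, act = "relu")
  nn_materialize(pr)
  pr$params$w <- dr$params$w
  pr$params$gamma <- dr$params$gamma
  pr$params$beta <- dr$params$beta
  # (a, b) initialise to (1, 0): the identity gating configuration
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  t1 <- tape_new(); t2 <- tape_new()
  expect_equal(tp_val(t1, dr$fwd(t1, op_leaf(t1, x), TRUE)),
               tp_val(t2, pr$fwd(t2, op_leaf(t2, x), TRUE)), tolerance = 1e-12)
})

test_that("depthwise-separable convolution arithmetic and identity construction", {
  expect_identical(count_parameters(build_dsc(64, 128, bn = FALSE)),
                   64L * 9L + 64L * 128L)

  # identity depthwise kernels + identity pointwise reproduce the input
  d <- build_dsc(5, 5, bn = FALSE, act = "none")
  nn_materialize(d)
  dw <- matrix(0, 5, 9); dw[, 5] <- 1    # centre tap of each 3x3 kernel
  d$children[[1]]$params$w <- dw
  d$children[[2]]$params$w <- diag(5)
  x <- array(rnorm(7 * 7 * 5), c(7, 7, 5, 1))
  tp <- tape_new()
  expect_equal(tp_val(tp, d$fwd(tp, op_leaf(tp, x), FALSE)), x,
               tolerance = 1e-12)

  for (i in 1:10) {
    cin <- 8 * i; cout <- 16 * i
    expect_lt(count_parameters(build_dsc(cin, cout, bn = FALSE)),
              count_parameters(conv_bn(cin, cout, k = 3, bn = FALSE)))
  }
})

test_that("spatial attention holds 99 parameters and gates multiplicatively", {
  sa <- build_spatial_attention()
  expect_identical(count_parameters(sa), 99L)
  nn_materialize(sa)
  tp <- tape_new()
  z <- sa$fwd(tp, op_leaf(tp, array(0, c(8, 8, 4, 1))), FALSE)
  expect_true(all(tp_val(tp, z) == 0))

  set.seed(34)
  tp <- tape_new()
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  xi <- op_leaf(tp, x)
  mn <- op_chan_mean(tp, xi)
  mx <- op_chan_max(tp, xi)
  a <- sa$children[[1]]$fwd(tp, op_concat_c(tp, list(mx, mn)), FALSE)
  att <- 1 / (1 + exp(-tp_val(tp, a)))
  expect_true(all(att > 0 & att < 1))
})

test_that("the input adapter matches its printed parameter budget", {
  ad <- build_input_adapter(1)
  expect_identical(count_parameters(ad), 19392L)
  nn_materialize(ad)
  tp <- tape_new()
  y <- ad$fwd(tp, op_leaf(tp, array(runif(32 * 64 * 3), c(32, 64, 3, 1))), FALSE)
  expect_equal(dim(tp_val(tp, y)), c(32, 64, 64, 1))

  # the edge signal (x minus its 3x3 average pool) vanishes on the interior
  # of a constant image
  tp <- tape_new()
  ci <- op_leaf(tp, array(5, c(10, 10, 3, 1)))
  e <- tp_val(tp, op_sub(tp, ci, op_avgpool3(tp, ci)))
  expect_lt(max(abs(e[2:9, 2:9, , ])), 1e-12)
})

test_that("spatial dropout zeroes whole channels at the configured rate", {
  x <- array(1, c(2, 2, 64, 1))
  expect_identical(spatial_dropout(x, 0.3, training = FALSE), x)
  expect_identical(spatial_dropout(x, 0, training = TRUE), x)

  set.seed(35)
  hits <- 0L; total <- 0L
  for (i in 1:2000) {
    y <- spatial_dropout(x, 0.3, training = TRUE)
    ch <- apply(y, 3, function(m) all(m == 0))
    hits <- hits + sum(ch)
    total <- total + 64L
    # survivors are rescaled by 1/(1-p)
    expect_true(all(y[, , !ch, ] * 0.7 - 1 < 1e-12))
  }
  expect_equal(hits / total, 0.3, tolerance = 0.01)
})

test_that("parameter counting respects freezing", {
  m <- conv_bn(3, 16, k = 3, bias = TRUE, bn = FALSE)
  expect_identical(count_parameters(m), 448L)
  nn_freeze(m)
  expect_identical(count_parameters(m), 0L)
})
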