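# Shared building blocks: channel/spatial attention, SE logits, residual
# and decoder blocks.

test_that("channel attention gates identically-distributed channels identically", {
  ca <- new_channel_attention(3, reduction = 4)
  # channel symmetry of the operator requires channel-symmetric weights
  module_fill(ca, 0.1)
  x <- array(2, c(1, 3, 4, 4))           # all channels identical
  y <- module_apply(ca, x)
  factors <- y / x
  expect_equal(max(factors) - min(factors), 0, tolerance = 1e-12)
  expect_true(all(factors > 0 & factors < 1))
})

test_that("channel attention is multiplicative: a zero channel stays zero", {
  ca <- new_channel_attention(4)
  x <- fixture_map(1, 4, 5, 5, seed = 7)
  x[1, 2, , ] <- 0
  y <- module_apply(ca, x)
  expect_true(all(y[1, 2, , ] == 0))
  expect_equal(dim(y), dim(x))
})

test_that("channel attention equals a scalar pool-MLP-sigmoid recomputation", {
  ca <- new_channel_attention(2, reduction = 1)
  ps <- module_params(ca)
  w1 <- matrix(c(1, 0, 0.5, -1, 0, 1, 0.2, 0.3), 2, 4)
  b1 <- c(0.1, -0.2, 0, 0.05)
  w2 <- matrix(seq(-0.4, 0.3, 0.1), 4, 2)
  b2 <- c(0.2, -0.1)
  ps[["fc1.w"]]$value <- w1
  ps[["fc1.b"]]$value <- b1
  ps[["fc2.w"]]$value <- w2
  ps[["fc2.b"]]$value <- b2
  x <- array(0, c(1, 2, 2, 2))
  x[1, 1, , ] <- 0
  x[1, 2, , ] <- 10
  pooled <- c(0, 10)
  gate <- 1 / (1 + exp(-(pmax(pooled %*% w1 + b1, 0) %*% w2 + b2)))
  y <- module_apply(ca, x)
  expect_equal(y[1, 2, 1, 1], 10 * gate[2], tolerance = 1e-6)
  expect_equal(y[1, 1, 1, 1], 0, tolerance = 1e-12)
})

test_that("spatial attention: constant maps get a constant gate; zero conv gives 0.5", {
  sa <- new_spatial_attention()
  x <- array(3, c(1, 2, 12, 12))
  y <- module_apply(sa, x)
  # constant away from the zero-padded border of the 7x7 gate convolution
  inner <- y[, , 4:9, 4:9]
  expect_equal(max(inner) - min(inner), 0, tolerance = 1e-10)
  module_fill(sa, 0)
  y0 <- module_apply(sa, fixture_map(1, 2, 6, 6, seed = 8))
  expect_equal(y0, 0.5 * fixture_map(1, 2, 6, 6, seed = 8),
               tolerance = 1e-10)
})

test_that("spatial attention gate equals a dense 7x7 convolution of the mean/max stack", {
  set.seed(9)
  sa <- new_spatial_attention(7)
  x <- array(0, c(1, 3, 9, 9))
  x[1, 2, 5, 5] <- 2                      # single hot pixel
  wsa <- sa$children$conv$params$w$value
  bsa <- sa$children$conv$params$b$value
  stack <- array(0, c(1, 2, 9, 9))
  stack[1, 1, , ] <- apply(x[1, , , ], c(2, 3), mean)
  stack[1, 2, , ] <- apply(x[1, , , ], c(2, 3), max)
  gate <- 1 / (1 + exp(-oracle_conv2d(stack, wsa, bsa)))
  y <- module_apply(sa, x)
  expect_lt(rel_err(y[1, 2, , ], gate[1, 1, , ] * x[1, 2, , ]), 1e-5)
})

test_that("se_weight is symmetric across identical channels and zero at zero", {
  se <- new_se_weight(4, reduction = 4)
  module_fill(se, 0.1)   # channel-symmetric weights
  x <- array(1.5, c(2, 4, 3, 3))
  lg <- module_apply(se, x)
  expect_equal(max(lg) - min(lg), 0, tolerance = 1e-10)
  module_fill(se, 0)
  expect_equal(module_apply(se, x), matrix(0, 2, 4), tolerance = 1e-12)
})

test_that("residual block with zeroed convolutions and equal channels is the identity", {
  rb <- new_residual_block(3, 3)
  module_fill(rb, 0)
  x <- abs(fixture_map(2, 3, 6, 6, seed = 10))  # positive: final ReLU inert
  y <- module_apply(rb, x, training = FALSE)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("residual block satisfies the shape contract and finite differences", {
  rb <- new_residual_block(3, 16)
  x <- fixture_map(1, 3, 8, 8, seed = 11)
  y <- module_apply(rb, x, training = TRUE)
  expect_equal(dim(y), c(1, 16, 8, 8))
  # gradient of a scalar functional w.r.t. one input pixel
  xn <- lightcf:::new_param(x)
  ctx <- list(training = TRUE)
  out <- lightcf:::tp_sum(lightcf:::tp_mul(rb$fwd(xn, ctx), rb$fwd(xn, ctx)))
  lightcf:::tp_backward(out)
  i <- 17
  eps <- 1e-4
  f <- function(xx) {
    o <- module_apply(rb, xx, training = TRUE)
    sum(o * o)
  }
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  num <- (f(xp) - f(xm)) / (2 * eps)
  expect_equal(xn$grad[i], num, tolerance = 1e-2)
})

test_that("decoder block upsamples, concatenates and respects the shape contract", {
  db <- new_decoder_block(8, 8, 8)
  x <- fixture_map(1, 8, 4, 4, seed = 12)
  skip <- fixture_map(1, 8, 8, 8, seed = 13)
  y <- module_apply(db, x, skip, training = TRUE)
  expect_equal(dim(y), c(1, 8, 8, 8))
  # zero inputs: output is deterministic bias/normalisation propagation
  y0 <- module_apply(db, array(0, dim(x)), array(0, dim(skip)))
  expect_true(all(is.finite(y0)))
  # mismatched spatial ratio errors
  bad <- fixture_map(1, 8, 6, 6, seed = 14)
  expect_error(module_apply(db, x, bad), "twice")
})

test_that("attention gates never change shapes and keep |output| <= |input|", {
  set.seed(15)
  for (C in c(3, 8)) {
    x <- fixture_map(2, C, 5, 5, seed = C)
    for (blk in list(new_channel_attention(C), new_spatial_attention())) {
      y <- module_apply(blk, x)
      expect_equal(dim(y), dim(x))
      expect_true(all(abs(y) <= abs(x) + 1e-12))
    }
  }
})
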