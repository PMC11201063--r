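# Fusion attention encoder and its Large Kernel Attention decomposition.

test_that("lka_config validates kernels and reports the effective receptive field", {
  cfg <- lka_config()
  expect_equal(cfg$erf, 5 + 6 * 3)  # 21x21 with the default decomposition
  expect_error(lka_config(dw_kernel = 4), "odd")
  expect_error(lka_config(dwd_dilation = 0), "positive")
})

test_that("LKA preserves spatial size for arbitrary H, W", {
  lka <- new_lka(3)
  for (hw in list(c(1, 1), c(5, 9), c(16, 12))) {
    x <- fixture_map(1, 3, hw[1], hw[2], seed = sum(hw))
    expect_equal(dim(module_apply(lka, x)), dim(x))
  }
})

test_that("LKA with identity (delta) kernels multiplies the input by itself", {
  lka <- new_lka(2)
  module_fill(lka, 0)
  # delta kernels: centre tap 1 in both depthwise convs, identity pointwise
  dw <- lka$children$dw$params$w
  dw$value[3, 3, 1, ] <- 1
  dwd <- lka$children$dwd$params$w
  dwd$value[4, 4, 1, ] <- 1
  pw <- lka$children$pw$params$w
  for (c in 1:2) pw$value[1, 1, c, c] <- 1
  x <- fixture_map(1, 2, 6, 6, seed = 21)
  y <- module_apply(lka, x)
  expect_equal(y, x * x, tolerance = 1e-5)
})

test_that("LKA attention chain equals the dense-convolution oracle on an impulse", {
  set.seed(22)
  lka <- new_lka(1)
  x <- array(0, c(1, 1, 9, 9))
  x[1, 1, 5, 5] <- 1
  wd <- lka$children$dw$params$w$value
  wdd <- lka$children$dwd$params$w$value
  wp <- lka$children$pw$params$w$value
  bd <- lka$children$dw$params$b$value
  bdd <- lka$children$dwd$params$b$value
  bp <- lka$children$pw$params$b$value
  att <- oracle_conv2d(
    oracle_conv2d(oracle_conv2d(x, wd, bd, 1, 1), wdd, bdd, 3, 1),
    wp, bp, 1, 1)
  expect_lt(rel_err(module_apply(lka, x), att * x), 1e-5)
})

test_that("faencoder_forward satisfies the shape contract", {
  fae <- new_faencoder(16, 32)
  x <- fixture_map(1, 16, 16, 16, seed = 23)
  y <- module_apply(fae, x, training = TRUE)
  expect_equal(dim(y), c(1, 32, 16, 16))
})

test_that("zeroing the attention branch reduces the stage to the plain branch", {
  fae <- new_faencoder(4, 8)
  # zero the final 1x1 of the attention branch -> y1 contributes nothing
  fae$children$pw2$params$w$value[] <- 0
  fae$children$pw2$params$b$value[] <- 0
  x <- fixture_map(1, 4, 8, 8, seed = 24)
  y <- module_apply(fae, x, training = TRUE)
  # recompute expected: CA(relu(bn(fuse(y2)))) with y2 = pw_skip(x2)
  ctx <- list(training = TRUE)
  x2 <- lightcf:::tp_relu(fae$children$bn_in$fwd(
    fae$children$conv_in$fwd(lightcf:::as_node(x), ctx), ctx))
  y2 <- fae$children$pw_skip$fwd(x2, ctx)
  h <- lightcf:::tp_relu(fae$children$bn_fuse$fwd(
    fae$children$fuse$fwd(y2, ctx), ctx))
  expected <- fae$children$ca$fwd(h, ctx)$value
  expect_equal(y, expected, tolerance = 1e-6)
})

test_that("faencoder is deterministic given weights and input", {
  fae <- new_faencoder(3, 8)
  x <- fixture_map(2, 3, 8, 8, seed = 25)
  expect_identical(module_apply(fae, x), module_apply(fae, x))
})

test_that("faencoder matches an independent step-by-step evaluation", {
  fae <- new_faencoder(3, 6)
  x <- fixture_map(1, 3, 6, 6, seed = 26)
  ch <- fae$children
  # step-by-step with the dense oracle and plain R, eval-mode batch norm
  bn_eval <- function(v, bn) {
    g <- bn$params$gamma$value
    b <- bn$params$beta$value
    mu <- bn$buffers$running_mean
    istd <- 1 / sqrt(bn$buffers$running_var + 1e-5)
    out <- v
    for (c in seq_len(dim(v)[2]))
      out[, c, , ] <- (v[, c, , ] - mu[c]) * istd[c] * g[c] + b[c]
    out
  }
  x2 <- bn_eval(oracle_conv2d(x, ch$conv_in$params$w$value), ch$bn_in)
  x2 <- pmax(x2, 0)
  h1 <- oracle_conv2d(x2, ch$pw1$params$w$value, ch$pw1$params$b$value)
  h1 <- h1 * pnorm(h1)  # GELU
  att <- oracle_conv2d(
    oracle_conv2d(
      oracle_conv2d(h1, ch$lka$children$dw$params$w$value,
                    ch$lka$children$dw$params$b$value, 1, 6),
      ch$lka$children$dwd$params$w$value,
      ch$lka$children$dwd$params$b$value, 3, 6),
    ch$lka$children$pw$params$w$value, ch$lka$children$pw$params$b$value)
  y1 <- oracle_conv2d(att * h1, ch$pw2$params$w$value,
                      ch$pw2$params$b$value)
  y2 <- oracle_conv2d(x2, ch$pw_skip$params$w$value,
                      ch$pw_skip$params$b$value)
  h <- pmax(bn_eval(oracle_conv2d(y1 + y2, ch$fuse$params$w$value),
                    ch$bn_fuse), 0)
  pooled <- apply(h, c(1, 2), mean)
  z <- pmax(pooled %*% ch$ca$children$fc1$params$w$value +
              rep(ch$ca$children$fc1$params$b$value, each = 1), 0)
  gate <- 1 / (1 + exp(-(z %*% ch$ca$children$fc2$params$w$value +
                           rep(ch$ca$children$fc2$params$b$value, each = 1))))
  expected <- h
  for (c in seq_len(dim(h)[2])) expected[, c, , ] <- h[, c, , ] * gate[1, c]
  expect_lt(rel_err(module_apply(fae, x, training = FALSE), expected), 1e-5)
})
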