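# Synthetic fixture generator, augmentation, I/O and the resize protocol.

test_that("the generator is deterministic and produces valid pairs", {
  cfg <- synth_config(image_size = 64, seed = 5)
  a <- generate_sample(cfg, 3)
  b <- generate_sample(cfg, 3)
  expect_identical(a, b)
  expect_equal(dim(a$image), c(64, 64, 3))
  expect_true(all(a$mask %in% c(0L, 1L)))
  expect_true(all(a$image >= 0 & a$image <= 255))
  c1 <- generate_sample(cfg, 4)
  expect_false(identical(a$image, c1$image))
})

test_that("zero contrast hides the polyp in the image but not in the mask", {
  cfg0 <- synth_config(image_size = 64, contrast_delta = 0, seed = 9)
  cfg1 <- synth_config(image_size = 64, contrast_delta = 0.5, seed = 9)
  s0 <- generate_sample(cfg0, 1)
  s1 <- generate_sample(cfg1, 1)
  expect_gt(sum(s0$mask), 0)
  # with zero contrast the polyp region looks like background; with strong
  # contrast the same region differs visibly between the two renderings
  expect_identical(s0$mask, s1$mask)
  diff_in <- mean(abs(s0$image[s0$mask == 1] - s1$image[s1$mask == 1]))
  expect_gt(diff_in, 1)
})

test_that("mask area stays within the bounds implied by the radius range", {
  cfg <- synth_config(image_size = 64, n_polyps = c(1, 3),
                      radius_frac = c(0.08, 0.25), seed = 11)
  fr <- vapply(1:100, function(i) mean(generate_sample(cfg, i)$mask),
               numeric(1))
  r_lo <- 0.08 * (1 - cfg$boundary_amp)
  r_hi <- 0.25 * (1 + cfg$boundary_amp)
  expect_gt(min(fr), 0.5 * pi * r_lo^2)     # at least half of one small polyp
  expect_lt(max(fr), 3 * pi * r_hi^2)       # at most three large polyps
})

test_that("radius ranges exceeding the image are rejected", {
  expect_error(synth_config(radius_frac = c(0.3, 0.6)), "exceeds")
})

test_that("a horizontal flip applied twice is the identity", {
  s <- generate_sample(synth_config(image_size = 32, seed = 2), 1)
  p <- list(hflip = TRUE, vflip = FALSE, angle = 0)
  s2 <- augment(augment(s, params = p), params = p)
  expect_identical(s2$image, s$image)
  expect_identical(s2$mask, s$mask)
})

test_that("image and mask stay co-registered under sampled transforms", {
  n <- 33
  base <- list(image = array(0L, c(n, n, 3)), mask = matrix(0L, n, n),
               id = "marker")
  class(base) <- c("lcf_sample", "list")
  base$image[10, 21, ] <- 255L
  base$mask[10, 21] <- 1L
  # pure flips are exact
  pf <- augment(base, params = list(hflip = TRUE, vflip = TRUE, angle = 0))
  expect_equal(which(pf$mask == 1), which(pf$image[, , 1] == 255L))
  # under rotation the image marker is interpolated bilinearly while the
  # mask uses nearest neighbour: positions agree to within one pixel
  set.seed(61)
  for (i in 1:10) {
    out <- augment(base, seed = 1000 + i)
    expect_equal(sum(out$mask), 1)
    mpos <- which(out$mask == 1, arr.ind = TRUE)
    ipos <- which(out$image[, , 1] == max(out$image[, , 1]), arr.ind = TRUE)
    expect_lte(max(abs(as.numeric(mpos) - as.numeric(ipos[1, ]))), 1)
  }
})

test_that("sampled rotation angles lie in [-90, 90] degrees", {
  set.seed(62)
  angles <- vapply(1:10000, function(i) augment_params()$angle, numeric(1))
  expect_gte(min(angles), -90)
  expect_lte(max(angles), 90)
  expect_gt(max(angles), 45)    # the range is actually exercised
  expect_lt(min(angles), -45)
})

test_that("the 8:1:1 split is disjoint and exhaustive", {
  sp <- split_dataset(100, seed = 3)
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_equal(sort(all_idx), 1:100)
  expect_equal(length(sp$train), 80)
  expect_equal(length(sp$val), 10)
  sp2 <- split_dataset(100, seed = 3)
  expect_identical(sp, sp2)
})

test_that("the resize protocol crops training samples to 256 after resizing to 320", {
  # ETIS-like native resolution, downsampled content
  s <- list(image = array(as.integer(runif(245 * 193 * 3, 0, 255)),
                          c(245, 193, 3)),
            mask = matrix(rbinom(245 * 193, 1, 0.2), 245, 193),
            id = "etis_like")
  class(s) <- c("lcf_sample", "list")
  tr <- resize_protocol(s, "train", seed = 7)
  expect_equal(dim(tr$image), c(256, 256, 3))
  expect_equal(dim(tr$mask), c(256, 256))
  expect_true(all(tr$mask %in% c(0L, 1L)))
  tr2 <- resize_protocol(s, "train", seed = 7)
  expect_identical(tr, tr2)
  ev <- resize_protocol(s, "val", eval_size = c(288, 384))
  expect_equal(dim(ev$image), c(288, 384, 3))
})

test_that("PNG round trip through the folder layout binarises masks", {
  dir <- tempfile("synthds")
  cfg <- synth_config(image_size = 32, seed = 8)
  synth_dataset(cfg, 3, dir)
  manifest <- load_pairs(file.path(dir, "images"), file.path(dir, "masks"))
  expect_equal(nrow(manifest), 3)
  s <- read_pair(manifest$image[1], manifest$mask[1], manifest$id[1])
  orig <- generate_sample(cfg, 1)
  expect_identical(s$mask, orig$mask)
  expect_identical(s$image, orig$image)
  # missing mask is a named-file error
  unlink(manifest$mask[2])
  expect_error(load_pairs(file.path(dir, "images"), file.path(dir, "masks")),
               manifest$id[2])
  unlink(dir, recursive = TRUE)
})

test_that("samples_to_tensors produces network-ready arrays", {
  data <- synth_dataset(synth_config(image_size = 32, seed = 4), 2)
  tb <- samples_to_tensors(data)
  expect_equal(dim(tb$x), c(2, 3, 32, 32))
  expect_equal(dim(tb$y), c(2, 1, 32, 32))
  expect_true(all(tb$x >= 0 & tb$x <= 1))
  expect_true(all(tb$y %in% c(0, 1)))
})
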