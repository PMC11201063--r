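# ---------------------------------------------------------------------------
# Dataset I/O, geometric augmentation, the resize/crop protocol and the
# train/val/test split.
# ---------------------------------------------------------------------------

#' List co-registered image/mask pairs in two directories
#'
#' Follows the Kvasir-SEG-style layout: an `images/` and a `masks/`
#' directory with shared basenames. Only PNG files are read (masks must be
#' PNG; images are matched by basename).
#'
#' @param image_dir directory of images
#' @param mask_dir directory of masks
#' @return data.frame with columns id, image, mask (file paths)
#' @export
load_pairs <- function(image_dir, mask_dir) {
  imgs <- sort(list.files(image_dir, pattern = "\\.png$", ignore.case = TRUE))
  if (!length(imgs)) stop(sprintf("no PNG images found in %s", image_dir))
  ids <- sub("\\.[^.]*$", "", imgs)
  masks <- file.path(mask_dir, paste0(ids, ".png"))
  missing <- !file.exists(masks)
  if (any(missing))
    stop(sprintf("missing mask for image(s): %s",
                 paste(ids[missing], collapse = ", ")))
  data.frame(id = ids, image = file.path(image_dir, imgs), mask = masks,
             stringsAsFactors = FALSE)
}

#' Read one image/mask pair
#'
#' Masks are binarised at intensity > 127 (of 255).
#'
#' @param image_path PNG image path
#' @param mask_path PNG mask path
#' @param id sample id (defaults to the basename)
#' @return an `lcf_sample`
#' @export
read_pair <- function(image_path, mask_path,
                      id = sub("\\.[^.]*$", "", basename(image_path))) {
  if (!file.exists(image_path)) stop(sprintf("cannot read %s", image_path))
  if (!file.exists(mask_path)) stop(sprintf("cannot read %s", mask_path))
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  msk <- png::readPNG(mask_path)
  if (length(dim(msk)) == 3) msk <- msk[, , 1]
  out <- list(image = array(as.integer(round(img * 255)), dim(img)),
              mask = matrix(as.integer(msk * 255 > 127), nrow(msk), ncol(msk)),
              id = id)
  class(out) <- c("lcf_sample", "list")
  out
}

# bilinear resize of an (H, W, 3) image; nearest for a mask matrix
resize_image <- function(img, oh, ow) {
  out <- array(0, c(oh, ow, dim(img)[3]))
  for (k in seq_len(dim(img)[3]))
    out[, , k] <- cpp_resize_bilinear(img[, , k], oh, ow)
  out
}

resize_mask_nearest <- function(mask, oh, ow) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- pmin(pmax(floor((seq_len(oh) - 0.5) * H / oh + 0.5), 1), H)
  ci <- pmin(pmax(floor((seq_len(ow) - 0.5) * W / ow + 0.5), 1), W)
  mask[ri, ci, drop = FALSE]
}

#' Resize/crop protocol
#'
#' Training samples are resized to `train_resize` (default 320) and then
#' randomly cropped to `train_crop` (default 256); validation/test samples
#' are resized to `eval_size`. Images use bilinear interpolation, masks
#' nearest neighbour.
#'
#' @param s an `lcf_sample`
#' @param split `"train"`, `"val"` or `"test"`
#' @param train_resize,train_crop training protocol sizes
#' @param eval_size length-2 (H, W) evaluation size; per-dataset settings in
#'   the source protocol are 320x320 (Kvasir-SEG, ETIS), 288x384
#'   (CVC-ClinicDB) and 480x480 (BKAI-IGH)
#' @param seed optional seed making the random crop reproducible
#' @return the transformed `lcf_sample`
#' @export
resize_protocol <- function(s, split = c("train", "val", "test"),
                            train_resize = 320, train_crop = 256,
                            eval_size = c(320, 320), seed = NULL) {
  split <- match.arg(split)
  img <- s$image / 255
  if (split == "train") {
    img <- resize_image(img, train_resize, train_resize)
    msk <- resize_mask_nearest(s$mask, train_resize, train_resize)
    run <- function() {
      r0 <- sample.int(train_resize - train_crop + 1L, 1)
      c0 <- sample.int(train_resize - train_crop + 1L, 1)
      list(r0 = r0, c0 = c0)
    }
    off <- if (is.null(seed)) run() else with_seed(seed, run())
    rs <- off$r0:(off$r0 + train_crop - 1L)
    cs <- off$c0:(off$c0 + train_crop - 1L)
    img <- img[rs, cs, , drop = FALSE]
    msk <- msk[rs, cs, drop = FALSE]
  } else {
    img <- resize_image(img, eval_size[1], eval_size[2])
    msk <- resize_mask_nearest(s$mask, eval_size[1], eval_size[2])
  }
  out <- list(image = array(as.integer(round(img * 255)), dim(img)),
              mask = msk, id = s$id)
  class(out) <- c("lcf_sample", "list")
  out
}

#' Sample augmentation parameters
#'
#' Horizontal and vertical flips each with probability one half, and a
#' rotation angle drawn uniformly from \[-90, 90\] degrees.
#'
#' @param seed optional seed
#' @return list with `hflip`, `vflip` (logical) and `angle` (degrees)
#' @export
augment_params <- function(seed = NULL) {
  run <- function() list(hflip = runif(1) < 0.5, vflip = runif(1) < 0.5,
                         angle = runif(1, -90, 90))
  if (is.null(seed)) run() else with_seed(seed, run())
}

# rotate a matrix by `angle` degrees around the centre (inverse mapping);
# bilinear = FALSE uses nearest neighbour; outside pixels are filled with 0
rotate_matrix <- function(m, angle, bilinear = TRUE) {
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gr <- matrix(rep(seq_len(H), times = W), H, W)
  gc <- matrix(rep(seq_len(W), each = H), H, W)
  # inverse rotation of output coordinates into the source frame
  sy <- cos(th) * (gr - cy) + sin(th) * (gc - cx) + cy
  sx <- -sin(th) * (gr - cy) + cos(th) * (gc - cx) + cx
  if (!bilinear) {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(0, H, W)
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sy); c0 <- floor(sx)
  fr <- sy - r0; fc <- sx - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- matrix(0, H, W)
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * val(r0, c0) + fr * (1 - fc) * val(r0 + 1, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) + fr * fc * val(r0 + 1, c0 + 1)
}

#' Augment an image/mask pair
#'
#' Applies the identical geometric transform to image and mask: random
#' horizontal/vertical flips and a random rotation in \[-90, 90\] degrees.
#' The image is interpolated bilinearly, the mask with nearest neighbour
#' (re-binarised by construction).
#'
#' @param s an `lcf_sample`
#' @param seed optional seed; same seed, same transform
#' @param params optional transform list from [augment_params()],
#'   overriding `seed`
#' @return the augmented `lcf_sample`
#' @export
augment <- function(s, seed = NULL, params = NULL) {
  if (is.null(params)) params <- augment_params(seed)
  img <- s$image / 255
  msk <- s$mask
  if (params$hflip) {
    img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  if (params$vflip) {
    img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
    msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  if (abs(params$angle) > 1e-12) {
    for (k in seq_len(dim(img)[3]))
      img[, , k] <- rotate_matrix(img[, , k], params$angle, bilinear = TRUE)
    msk <- rotate_matrix(msk, params$angle, bilinear = FALSE)
  }
  out <- list(image = array(as.integer(round(pmin(pmax(img, 0), 1) * 255)),
                            dim(img)),
              mask = matrix(as.integer(msk > 0.5), nrow(msk), ncol(msk)),
              id = s$id)
  class(out) <- c("lcf_sample", "list")
  out
}

#' Split sample indices 8:1:1
#'
#' Seeded random permutation at the granularity of whole images; the three
#' parts are disjoint and exhaustive.
#'
#' @param n number of samples (or a vector of ids)
#' @param ratios length-3 positive weights (default `c(8, 1, 1)`)
#' @param seed permutation seed
#' @return list with integer index vectors `train`, `val`, `test`
#' @export
split_dataset <- function(n, ratios = c(8, 1, 1), seed = 1L) {
  ids <- if (length(n) == 1L && is.numeric(n)) seq_len(n) else seq_along(n)
  perm <- with_seed(seed, sample(ids))
  k <- length(ids)
  n_train <- floor(k * ratios[1] / sum(ratios))
  n_val <- floor(k * ratios[2] / sum(ratios))
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1):k]))
}

#' Stack samples into network input tensors
#'
#' @param samples list of `lcf_sample` objects with identical sizes
#' @return list with `x` ((B, 3, H, W) array, intensities in 0-1) and
#'   `y` ((B, 1, H, W) binary array)
#' @export
samples_to_tensors <- function(samples) {
  H <- nrow(samples[[1]]$mask); W <- ncol(samples[[1]]$mask)
  B <- length(samples)
  x <- array(0, c(B, 3, H, W))
  y <- array(0, c(B, 1, H, W))
  for (i in seq_len(B)) {
    x[i, , , ] <- aperm(samples[[i]]$image / 255, c(3, 1, 2))
    y[i, 1, , ] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}
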