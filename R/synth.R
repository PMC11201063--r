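# ---------------------------------------------------------------------------
# Seeded synthetic colonoscopy-like fixture generator.
#
# The generator emulates the qualitative challenges of endoscopic polyp
# imagery — polyps of varying size/shape/colour, low contrast against the
# mucosa, uneven illumination, specular highlights, sensor noise — without
# claiming visual realism. Every sample is a pure function of
# (configuration, index).
# ---------------------------------------------------------------------------

#' Synthetic dataset configuration
#'
#' @param image_size output size in pixels (square)
#' @param n_polyps integer range (min, max) of polyps per image
#' @param radius_frac polyp base radius range as a fraction of image size
#' @param boundary_amp total amplitude of the radial harmonics perturbing
#'   each polyp boundary (0 = perfect ellipses)
#' @param contrast_delta strength of the polyp tint against the mucosa in
#'   \[0, 1\]; 0 renders the polyp invisible in the image while the mask
#'   still marks it (a deliberately pathological fixture)
#' @param illum_strength strength of the smooth illumination gradient
#' @param n_specular integer range of specular highlight spots
#' @param noise_sigma additive Gaussian noise standard deviation (intensity
#'   scale 0-1)
#' @param seed integer seed fixing the whole sample stream
#' @return a `lcf_synth_config` list
#' @export
synth_config <- function(image_size = 256,
                         n_polyps = c(1, 3),
                         radius_frac = c(0.08, 0.25),
                         boundary_amp = 0.15,
                         contrast_delta = 0.25,
                         illum_strength = 0.35,
                         n_specular = c(2, 6),
                         noise_sigma = 0.02,
                         seed = 1L) {
  if (max(radius_frac) * (1 + boundary_amp) >= 0.5)
    stop("invalid config: radius range exceeds the image")
  cfg <- list(image_size = as.integer(image_size),
              n_polyps = as.integer(n_polyps),
              radius_frac = radius_frac,
              boundary_amp = boundary_amp,
              contrast_delta = contrast_delta,
              illum_strength = illum_strength,
              n_specular = as.integer(n_specular),
              noise_sigma = noise_sigma,
              seed = as.integer(seed))
  class(cfg) <- c("lcf_synth_config", "list")
  cfg
}

# smooth value-noise field in [-1, 1] via bilinear upsampling of coarse grids
value_noise <- function(n, cells = c(4, 8, 16), weights = c(1, 0.5, 0.25)) {
  z <- matrix(0, n, n)
  for (i in seq_along(cells)) {
    coarse <- matrix(rnorm(cells[i]^2), cells[i], cells[i])
    z <- z + weights[i] * cpp_resize_bilinear(coarse, n, n)
  }
  z / max(abs(z))
}

#' Generate one synthetic image/mask pair
#'
#' The background is a mucosa-toned texture under a radial illumination
#' gradient with a few specular highlights. Each polyp is an ellipse whose
#' boundary radius is modulated by random low-order harmonics,
#' tinted against the background with strength `contrast_delta` and a rim
#' shading of the same strength. The mask is the exact polyp support.
#'
#' @param cfg a [synth_config()] list
#' @param index sample index (>= 1); same (cfg, index) gives a byte-identical
#'   pair
#' @return a `lcf_sample`: list with `image` ((H, W, 3) integer array,
#'   0-255), `mask` ((H, W) 0/1 matrix) and `id`
#' @export
generate_sample <- function(cfg, index) {
  stopifnot(inherits(cfg, "lcf_synth_config"), index >= 1)
  n <- cfg$image_size
  with_seed((cfg$seed * 10007L + as.integer(index)) %% 2147483587L, {
    # mucosa background: pink-red base with smooth texture
    base <- c(0.72, 0.43, 0.38) + rnorm(3, 0, 0.03)
    tex <- value_noise(n)
    img <- array(0, c(n, n, 3))
    for (k in 1:3) img[, , k] <- base[k] + 0.06 * tex * (1 + 0.3 * (k == 1))

    # radial illumination gradient
    cx <- runif(1, 0.25, 0.75) * n; cy <- runif(1, 0.25, 0.75) * n
    gx <- matrix(rep(seq_len(n), each = n), n, n)      # column index
    gy <- matrix(rep(seq_len(n), times = n), n, n)     # row index
    dist <- sqrt((gy - cy)^2 + (gx - cx)^2) / (n * sqrt(2) / 2)
    illum <- 1 + cfg$illum_strength * (0.5 - dist)
    for (k in 1:3) img[, , k] <- img[, , k] * illum

    # polyps
    mask <- matrix(0L, n, n)
    npol <- if (cfg$n_polyps[1] == cfg$n_polyps[2]) cfg$n_polyps[1] else
      sample(cfg$n_polyps[1]:cfg$n_polyps[2], 1)
    for (q in seq_len(npol)) {
      r0 <- runif(1, cfg$radius_frac[1], cfg$radius_frac[2]) * n
      rmax <- r0 * (1 + cfg$boundary_amp)
      pcx <- runif(1, rmax + 1, n - rmax - 1)
      pcy <- runif(1, rmax + 1, n - rmax - 1)
      ecc <- runif(1, 0.7, 1)          # ellipse axis ratio
      rot <- runif(1, 0, pi)
      m_orders <- 2:5
      amps <- cfg$boundary_amp * {
        a <- abs(rnorm(length(m_orders))); a / max(sum(a), 1e-8)
      }
      phases <- runif(length(m_orders), 0, 2 * pi)
      dy <- gy - pcy; dx <- gx - pcx
      u <- cos(rot) * dx + sin(rot) * dy
      v <- -sin(rot) * dx + cos(rot) * dy
      rr <- sqrt(u^2 + (v / ecc)^2)
      th <- atan2(v / ecc, u)
      rb <- r0
      for (j in seq_along(m_orders))
        rb <- rb + r0 * amps[j] * cos(m_orders[j] * th + phases[j])
      inside <- rr < rb
      mask[inside] <- 1L
      # tint and rim shading, both scaled by the contrast
      tint <- cfg$contrast_delta * rnorm(3, c(0.10, 0.03, -0.02), 0.03)
      rel <- pmin(rr / pmax(rb, 1e-8), 1)
      shade <- 1 - cfg$contrast_delta * 0.5 * rel^2
      for (k in 1:3) {
        ch <- img[, , k]
        ch[inside] <- (ch[inside] + tint[k]) * shade[inside]
        img[, , k] <- ch
      }
    }

    # specular highlights: small bright Gaussian spots
    nspec <- if (cfg$n_specular[1] == cfg$n_specular[2]) cfg$n_specular[1]
      else sample(cfg$n_specular[1]:cfg$n_specular[2], 1)
    for (q in seq_len(nspec)) {
      sx <- runif(1, 1, n); sy <- runif(1, 1, n)
      sr <- runif(1, 0.004, 0.015) * n
      blob <- exp(-((gy - sy)^2 + (gx - sx)^2) / (2 * sr^2))
      for (k in 1:3) img[, , k] <- img[, , k] + 0.9 * blob
    }

    if (cfg$noise_sigma > 0)
      img <- img + array(rnorm(length(img), 0, cfg$noise_sigma), dim(img))
    img <- pmin(pmax(img, 0), 1)
    out <- list(image = array(as.integer(round(img * 255)), c(n, n, 3)),
                mask = mask,
                id = sprintf("synth_%05d", as.integer(index)))
    class(out) <- c("lcf_sample", "list")
    out
  })
}

#' Generate a synthetic dataset
#'
#' @param cfg a [synth_config()] list
#' @param n number of samples
#' @param out_dir optional directory; when given, samples are materialised
#'   as `images/<id>.png` and `masks/<id>.png` (masks stored as 0/255)
#' @return invisibly when writing to disk, otherwise a list of `lcf_sample`
#' @export
synth_dataset <- function(cfg, n, out_dir = NULL) {
  samples <- lapply(seq_len(n), function(i) generate_sample(cfg, i))
  if (is.null(out_dir)) return(samples)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in samples) {
    png::writePNG(s$image / 255,
                  file.path(out_dir, "images", paste0(s$id, ".png")))
    png::writePNG(s$mask + 0, file.path(out_dir, "masks", paste0(s$id, ".png")))
  }
  invisible(samples)
}
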