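# Independent oracles used across the suite. These deliberately share no
# code with the package internals: dense direct convolution, a naive scan
# recurrence, closed-form bilinear interpolation and brute-force pairwise
# AUC.

# dense direct 2-d convolution, stride 1, same padding
oracle_conv2d <- function(x, w, bias = NULL, dil = 1, groups = 1) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  wd <- dim(w); kh <- wd[1]; kw <- wd[2]; cg <- wd[3]; Cout <- wd[4]
  coutg <- Cout / groups
  ph <- dil * (kh - 1) / 2; pw <- dil * (kw - 1) / 2
  y <- array(0, c(B, Cout, H, W))
  for (b in 1:B) for (o in 1:Cout) {
    g <- ceiling(o / coutg)
    for (h in 1:H) for (ww in 1:W) {
      s <- if (is.null(bias)) 0 else bias[o]
      for (c in 1:cg) for (i in 1:kh) for (j in 1:kw) {
        hh <- h + (i - 1) * dil - ph
        w2 <- ww + (j - 1) * dil - pw
        if (hh >= 1 && hh <= H && w2 >= 1 && w2 <= W)
          s <- s + w[i, j, c, o] * x[b, (g - 1) * cg + c, hh, w2]
      }
      y[b, o, h, ww] <- s
    }
  }
  y
}

# literal per-step recurrence for the selective scan
oracle_scan <- function(u, delta, A, Bm, Cm, Dv) {
  d <- dim(u); B <- d[1]; L <- d[2]; D <- d[3]; N <- ncol(A)
  y <- array(0, d)
  for (b in 1:B) {
    h <- matrix(0, D, N)
    for (l in 1:L) for (dd in 1:D) {
      Ab <- exp(delta[b, l, dd] * A[dd, ])
      h[dd, ] <- Ab * h[dd, ] + delta[b, l, dd] * Bm[b, l, ] * u[b, l, dd]
      y[b, l, dd] <- sum(Cm[b, l, ] * h[dd, ]) + Dv[dd] * u[b, l, dd]
    }
  }
  y
}

# closed-form bilinear 2x upsampling with half-pixel centres
oracle_upsample2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, 2 * H, 2 * W)
  for (i in seq_len(2 * H)) for (j in seq_len(2 * W)) {
    sy <- min(max((i - 0.5) / 2 - 0.5, 0), H - 1)
    sx <- min(max((j - 0.5) / 2 - 0.5, 0), W - 1)
    i0 <- floor(sy); i1 <- min(i0 + 1, H - 1)
    j0 <- floor(sx); j1 <- min(j0 + 1, W - 1)
    fy <- sy - i0; fx <- sx - j0
    out[i, j] <- (1 - fy) * (1 - fx) * m[i0 + 1, j0 + 1] +
      fy * (1 - fx) * m[i1 + 1, j0 + 1] +
      (1 - fy) * fx * m[i0 + 1, j1 + 1] +
      fy * fx * m[i1 + 1, j1 + 1]
  }
  out
}

# brute-force pairwise AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# relative maximum difference
rel_err <- function(a, b) max(abs(a - b)) / max(1e-12, max(abs(b)))

# tiny deterministic feature map
fixture_map <- function(B = 1, C = 2, H = 4, W = 4, seed = 1) {
  set.seed(seed)
  array(rnorm(B * C * H * W), c(B, C, H, W))
}

# the smoke-scale full-model configuration used in training tests
smoke_model_config <- function() {
  model_config(variant = "full",
               stage_channels = c(4L, 8L, 16L, 32L, 32L),
               decoder_channels = c(16L, 16L, 8L, 4L),
               psa = psa_config(4, c(1L, 2L, 4L, 8L)))
}
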