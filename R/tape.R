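#' @useDynLib lightcf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
NULL

# ---------------------------------------------------------------------------
# Reverse-mode autodiff tape.
#
# A node is an environment holding a value (an R array), an optional gradient,
# its parent nodes and a backward closure mapping the node's gradient to the
# gradients of its parents. Feature maps are (B, C, H, W) arrays, sequence
# features are (B, L, C) arrays; the batch axis is always first.
# ---------------------------------------------------------------------------

.lcf <- new.env(parent = emptyenv())
.lcf$id <- 0L
.lcf$grad_on <- TRUE

tape_grad_enabled <- function() .lcf$grad_on

#' Evaluate an expression with gradient recording disabled
#'
#' Forward passes run inside `without_grad()` skip all backward bookkeeping
#' (including the selective-scan state cache), which reduces memory and time
#' for pure inference.
#'
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
without_grad <- function(expr) {
  old <- .lcf$grad_on
  .lcf$grad_on <- FALSE
  on.exit(.lcf$grad_on <- old)
  force(expr)
}

new_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  .lcf$id <- .lcf$id + 1L
  e$id <- .lcf$id
  e$value <- value
  e$grad <- NULL
  e$is_param <- FALSE
  if (.lcf$grad_on && length(parents)) {
    keep <- vapply(parents, function(p) isTRUE(p$needs), logical(1))
    if (any(keep)) {
      e$parents <- parents
      e$backfn <- backfn
      e$needs <- TRUE
    } else {
      e$parents <- list()
      e$needs <- FALSE
    }
  } else {
    e$parents <- list()
    e$needs <- FALSE
  }
  class(e) <- "lcf_node"
  e
}

#' Create a trainable parameter node
#' @param value numeric array with the initial value
#' @param name optional label used in diagnostics
#' @return a parameter node (environment of class `lcf_node`)
#' @keywords internal
new_param <- function(value, name = NULL) {
  e <- new_node(value)
  e$is_param <- TRUE
  e$needs <- TRUE
  e$name <- name
  e
}

is_node <- function(x) inherits(x, "lcf_node")

as_node <- function(x) if (is_node(x)) x else new_node(x)

#' Extract the value array from a tape node
#' @param x a node or plain array
#' @return the underlying numeric array
#' @keywords internal
nv <- function(x) if (is_node(x)) x$value else x

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar node
#'
#' Accumulates gradients into every reachable parameter node's `$grad`.
#'
#' @param root scalar output node
#' @param seed gradient seeded at the root (default 1)
#' @keywords internal
tp_backward <- function(root, seed = 1) {
  stopifnot(is_node(root))
  # iterative post-order DFS for a topological order
  topo <- vector("list", 256L)
  nt <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) { ns <- ns - 1L; next }
      stack[[ns]]$stage <- 2L
      for (p in nd$parents) {
        if (isTRUE(p$needs) && is.null(seen[[as.character(p$id)]])) {
          ns <- ns + 1L
          stack[[ns]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        nt <- nt + 1L
        if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
        topo[[nt]] <- nd
      }
      ns <- ns - 1L
    }
  }
  root$grad <- if (length(root$value) == 1L) seed else array(seed, dim(root$value))
  for (i in seq(nt, 1L)) {
    nd <- topo[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (isTRUE(p$needs) && !is.null(gs[[j]])) acc_grad(p, gs[[j]])
    }
    if (!nd$is_param) nd$grad <- NULL  # free intermediate gradients early
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# elementwise ops
# ---------------------------------------------------------------------------

tp_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

tp_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

tp_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  new_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

tp_div <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  new_node(av / bv, list(a, b),
           function(g) list(g / bv, -g * av / (bv * bv)))
}

tp_cmul <- function(a, k) {
  a <- as_node(a)
  new_node(a$value * k, list(a), function(g) list(g * k))
}

tp_cadd <- function(a, k) {
  a <- as_node(a)
  new_node(a$value + k, list(a), function(g) list(g))
}

# fused elementwise activations evaluated in C++ (value and derivative)
tp_act <- function(a, kind) {
  a <- as_node(a)
  r <- cpp_act_fw(a$value, kind)
  d <- r$d
  new_node(r$y, list(a), function(g) list(g * d))
}

tp_relu <- function(a) tp_act(a, 1L)

tp_sigmoid <- function(a) tp_act(a, 2L)

tp_silu <- function(a) tp_act(a, 3L)

# exact (erf-based) GELU, x * Phi(x)
tp_gelu <- function(a) tp_act(a, 4L)

tp_softplus <- function(a) tp_act(a, 5L)

tp_exp <- function(a) {
  a <- as_node(a)
  v <- exp(a$value)
  new_node(v, list(a), function(g) list(g * v))
}

tp_log <- function(a) {
  a <- as_node(a)
  x <- a$value
  new_node(log(x), list(a), function(g) list(g / x))
}

tp_clamp <- function(a, lo, hi) {
  a <- as_node(a)
  x <- a$value
  m <- x >= lo & x <= hi
  v <- pmin(pmax(x, lo), hi)
  dim(v) <- dim(x)
  new_node(v, list(a), function(g) list(g * m))
}

tp_neg <- function(a) tp_cmul(a, -1)

tp_sum <- function(a) {
  a <- as_node(a)
  d <- dim(a$value)
  new_node(sum(a$value), list(a), function(g) list(array(g, d)))
}

tp_mean <- function(a) {
  a <- as_node(a)
  d <- dim(a$value)
  n <- length(a$value)
  new_node(mean(a$value), list(a), function(g) list(array(g / n, d)))
}

# ---------------------------------------------------------------------------
# feature-map ops (B, C, H, W)
# ---------------------------------------------------------------------------

#' 2-d convolution (stride 1, same padding) as a tape op
#' @param x input node, (B, Cin, H, W)
#' @param w weight node, (kh, kw, Cin/groups, Cout)
#' @param b bias node of length Cout, or NULL
#' @param dilation integer dilation (both axes)
#' @param groups number of groups
#' @keywords internal
tp_conv2d <- function(x, w, b = NULL, dilation = 1L, groups = 1L) {
  x <- as_node(x); w <- as_node(w)
  has_b <- !is.null(b)
  if (has_b) b <- as_node(b)
  bv <- if (has_b) b$value else NULL
  y <- cpp_conv2d_fw(x$value, w$value,
                     if (has_b) bv else NULL,
                     as.integer(dilation), as.integer(dilation),
                     as.integer(groups))
  xv <- x$value; wv <- w$value
  parents <- if (has_b) list(x, w, b) else list(x, w)
  new_node(y, parents, function(g) {
    r <- cpp_conv2d_bw(xv, wv, g, as.integer(dilation), as.integer(dilation),
                       as.integer(groups), has_b)
    if (has_b) list(r$dx, r$dw, r$db) else list(r$dx, r$dw)
  })
}

tp_maxpool2 <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  r <- cpp_maxpool2_fw(x$value)
  idx <- r$idx
  new_node(r$y, list(x),
           function(g) list(cpp_maxpool2_bw(g, idx, d[3], d[4])))
}

tp_upsample2 <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  new_node(cpp_upsample2_fw(x$value), list(x),
           function(g) list(cpp_upsample2_bw(g, d[3], d[4])))
}

#' Global average pooling, (B, C, H, W) -> (B, C)
#' @keywords internal
tp_gap <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; hw <- d[3] * d[4]
  v <- matrix(rowMeans(matrix(x$value, B * C, hw)), B, C)
  new_node(v, list(x), function(g) {
    array(rep(as.vector(g) / hw, times = hw), d) -> dx
    list(dx)
  })
}

# multiply feature map by per-channel gate g (B, C)
tp_scale_ch <- function(x, g) {
  x <- as_node(x); g <- as_node(g)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; hw <- d[3] * d[4]
  xv <- x$value; gv <- g$value
  y <- xv * as.vector(gv)  # (b, c) fastest axes -> recycling tiles over H, W
  dim(y) <- d
  new_node(y, list(x, g), function(gr) {
    dx <- gr * as.vector(gv)
    dim(dx) <- d
    dg <- matrix(rowSums(matrix(gr * xv, B * C, hw)), B, C)
    list(dx, dg)
  })
}

# add per-channel bias b (length C)
tp_bias_ch <- function(x, b) {
  x <- as_node(x); b <- as_node(b)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; hw <- d[3] * d[4]
  y <- x$value + rep(b$value, each = B)
  dim(y) <- d
  new_node(y, list(x, b), function(g) {
    db <- rowSums(matrix(colSums(matrix(g, B, C * hw)), C, hw))
    list(g, db)
  })
}

# multiply by a single-channel spatial gate s (B, 1, H, W)
tp_scale_sp <- function(x, s) {
  x <- as_node(x); s <- as_node(s)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; hw <- d[3] * d[4]
  xv <- x$value; sv <- matrix(s$value, B, hw)
  sbig <- aperm(array(as.vector(sv), c(B, hw, C)), c(1, 3, 2))
  dim(sbig) <- d
  y <- xv * sbig
  new_node(y, list(x, s), function(g) {
    dx <- g * sbig
    m <- aperm(array(g * xv, c(B, C, hw)), c(2, 1, 3))
    ds <- array(colSums(matrix(m, C, B * hw)), c(B, 1, d[3], d[4]))
    list(dx, ds)
  })
}

# concatenate along the channel axis
tp_concat_ch <- function(xs) {
  xs <- lapply(xs, as_node)
  ds <- lapply(xs, function(x) dim(x$value))
  B <- ds[[1]][1]; H <- ds[[1]][3]; W <- ds[[1]][4]
  Cs <- vapply(ds, function(d) d[2], numeric(1))
  Ct <- sum(Cs)
  y <- array(0, c(B, Ct, H, W))
  at <- 0L
  for (i in seq_along(xs)) {
    y[, at + seq_len(Cs[i]), , ] <- xs[[i]]$value
    at <- at + Cs[i]
  }
  new_node(y, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      gi <- g[, at + seq_len(Cs[i]), , , drop = FALSE]
      dim(gi) <- c(B, Cs[i], H, W)
      out[[i]] <- gi
      at <- at + Cs[i]
    }
    out
  })
}

# (B, C, H, W) -> (B, L, C), raster order (row by row, left to right)
tp_to_sequence <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  new_node(cpp_to_seq(x$value), list(x),
           function(g) list(cpp_to_map(g, d[3], d[4])))
}

# (B, L, C) -> (B, C, H, W), inverse of tp_to_sequence
tp_to_map <- function(x, H, W) {
  x <- as_node(x)
  if (dim(x$value)[2] != H * W) stop("sequence length does not equal H*W")
  new_node(cpp_to_map(x$value, H, W), list(x),
           function(g) list(cpp_to_seq(g)))
}

# ---------------------------------------------------------------------------
# sequence ops (B, L, C)
# ---------------------------------------------------------------------------

# dense layer applied position-wise: x (B, L, Cin), W (Cin, Cout), b (Cout)|NULL
tp_linear <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  has_b <- !is.null(b)
  if (has_b) b <- as_node(b)
  d <- dim(x$value)
  B <- d[1]; L <- d[2]; Cin <- d[3]
  wv <- w$value
  xm <- matrix(x$value, B * L, Cin)
  ym <- xm %*% wv
  if (has_b) ym <- sweep(ym, 2, b$value, "+")
  y <- array(ym, c(B, L, ncol(wv)))
  parents <- if (has_b) list(x, w, b) else list(x, w)
  new_node(y, parents, function(g) {
    gm <- matrix(g, B * L, ncol(wv))
    dx <- array(gm %*% t(wv), d)
    dw <- crossprod(xm, gm)
    if (has_b) list(dx, dw, colSums(gm)) else list(dx, dw)
  })
}

# dense layer on plain matrices: x (B, Cin)
tp_dense <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  has_b <- !is.null(b)
  if (has_b) b <- as_node(b)
  xv <- x$value; wv <- w$value
  y <- xv %*% wv
  if (has_b) y <- sweep(y, 2, b$value, "+")
  parents <- if (has_b) list(x, w, b) else list(x, w)
  new_node(y, parents, function(g) {
    dx <- g %*% t(wv)
    dw <- crossprod(xv, g)
    if (has_b) list(dx, dw, colSums(g)) else list(dx, dw)
  })
}

# layer normalization over the channel axis of (B, L, C)
tp_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value)
  B <- d[1]; L <- d[2]; C <- d[3]
  xm <- matrix(x$value, B * L, C)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  ym <- sweep(xhat, 2, gamma$value, "*")
  ym <- sweep(ym, 2, beta$value, "+")
  new_node(array(ym, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, B * L, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxh <- sweep(gm, 2, gamma$value, "*")
    dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * istd
    list(array(dx, d), dgamma, dbeta)
  })
}

# causal depthwise 1-d convolution over (B, L, D)
tp_conv1d_dw <- function(x, w, b) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xv <- x$value; wv <- w$value
  y <- cpp_conv1d_dw_fw(xv, wv, b$value)
  new_node(y, list(x, w, b), function(g) {
    r <- cpp_conv1d_dw_bw(xv, wv, g)
    list(r$dx, r$dw, r$db)
  })
}

#' Selective state-space scan as a tape op
#'
#' Implements the recurrence `h_t = exp(delta_t A) * h_{t-1} + delta_t B_t u_t`,
#' `y_t = C_t . h_t + D * u_t` independently per channel, with input-dependent
#' `delta`, `B`, `C`.
#'
#' @param u input node (B, L, D)
#' @param delta positive per-step per-channel timestep node (B, L, D)
#' @param A state matrix node (D, N), expected non-positive
#' @param Bm,Cm input/output projection nodes (B, L, N)
#' @param Dv skip-gain node (D)
#' @keywords internal
tp_scan <- function(u, delta, A, Bm, Cm, Dv) {
  u <- as_node(u); delta <- as_node(delta); A <- as_node(A)
  Bm <- as_node(Bm); Cm <- as_node(Cm); Dv <- as_node(Dv)
  if (any(delta$value <= 0)) stop("selective scan requires positive delta")
  y <- cpp_scan_fw(u$value, delta$value, A$value, Bm$value, Cm$value,
                   Dv$value)
  uv <- u$value; dv <- delta$value; Av <- A$value
  Bv <- Bm$value; Cv <- Cm$value; Dvv <- Dv$value
  new_node(y, list(u, delta, A, Bm, Cm, Dv), function(g) {
    bw <- cpp_scan_bw(uv, dv, Av, Bv, Cv, Dvv, g)
    list(bw$du, bw$ddelta, bw$dA, bw$dB, bw$dC, bw$dD)
  })
}

# softmax across the branch axis of (B, S, C) logits
tp_softmax_branch <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  B <- d[1]; S <- d[2]; C <- d[3]
  xv <- x$value
  mx <- apply(xv, c(1, 3), max)
  e <- exp(xv - aperm(array(mx, c(B, C, S)), c(1, 3, 2)))
  s <- apply(e, c(1, 3), sum)
  y <- e / aperm(array(s, c(B, C, S)), c(1, 3, 2))
  new_node(y, list(x), function(g) {
    dot <- apply(g * y, c(1, 3), sum)
    dx <- y * (g - aperm(array(dot, c(B, C, S)), c(1, 3, 2)))
    list(dx)
  })
}
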