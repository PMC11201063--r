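# ---------------------------------------------------------------------------
# Module abstraction and basic trainable layers.
#
# A module is a list with named parameter nodes, named child modules, an
# optional buffer environment (batch-norm running statistics) and a forward
# closure `fwd(x, ctx)` where ctx = list(training = TRUE/FALSE).
# ---------------------------------------------------------------------------

new_module <- function(kind, params = list(), children = list(), fwd = NULL,
                       buffers = NULL, meta = list()) {
  m <- list(kind = kind, params = params, children = children, fwd = fwd,
            buffers = buffers, meta = meta)
  class(m) <- "lcf_module"
  m
}

#' Collect all trainable parameters of a module
#'
#' @param m a module (e.g. a built model, or any sub-block)
#' @param prefix internal name prefix
#' @return named list of parameter nodes; each node's `$value` is the weight
#'   array and `$grad` its accumulated gradient
#' @export
module_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$children))
    out <- c(out, module_params(m$children[[nm]], paste0(prefix, nm, ".")))
  out
}

#' Apply a module to a plain array input
#'
#' Convenience wrapper used in examples and tests; wraps the input in a tape
#' node, runs the module forward pass and returns the resulting array.
#'
#' @param m module
#' @param x input array (or list of arrays for two-input blocks)
#' @param training logical; use batch statistics in batch norm and record
#'   gradients when TRUE
#' @param ... further inputs passed to the module forward
#' @return output array
#' @export
module_apply <- function(m, x, ..., training = FALSE) {
  ctx <- list(training = training)
  run <- function() {
    extra <- lapply(list(...), as_node)
    out <- do.call(m$fwd, c(list(as_node(x)), extra, list(ctx = ctx)))
    out$value
  }
  if (training) run() else without_grad(run())
}

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# Kaiming-normal fan-in initialisation for convolutions
init_conv_w <- function(kh, kw, cing, cout) {
  sd <- sqrt(2 / (kh * kw * cing))
  array(rnorm(kh * kw * cing * cout, 0, sd), c(kh, kw, cing, cout))
}

init_linear_w <- function(cin, cout) {
  matrix(rnorm(cin * cout, 0, 1 / sqrt(cin)), cin, cout)
}

# ---- conv2d layer --------------------------------------------------------

layer_conv2d <- function(cin, cout, k, dilation = 1L, groups = 1L,
                         bias = TRUE) {
  if (k %% 2 == 0) stop("conv kernels must be odd for same padding")
  if (cin %% groups != 0 || cout %% groups != 0)
    stop("channels not divisible by groups")
  params <- list(w = new_param(init_conv_w(k, k, cin / groups, cout)))
  if (bias) params$b <- new_param(numeric(cout))
  p <- params
  new_module("conv2d", params = params,
             fwd = function(x, ctx) {
               tp_conv2d(x, p$w, if (bias) p$b else NULL,
                         dilation = dilation, groups = groups)
             },
             meta = list(cin = cin, cout = cout, k = k,
                         dilation = dilation, groups = groups, bias = bias))
}

# ---- batch normalisation -------------------------------------------------

# train mode uses batch statistics (biased variance in the normaliser,
# unbiased in the running estimate); eval mode uses the running estimates.
tp_batchnorm <- function(x, gamma, beta, buf, training, momentum = 0.1,
                         eps = 1e-5) {
  x <- as_node(x)
  d <- dim(x$value)
  m <- d[1] * d[3] * d[4]
  if (training) {
    mu <- cpp_chan_sum(x$value) / m
    xc <- cpp_bn_apply(x$value, mu, rep(1, d[2]), rep(1, d[2]),
                       numeric(d[2]), FALSE)$y
    v <- cpp_chan_sum(xc * xc) / m
    istd <- 1 / sqrt(v + eps)
    if (m > 1) {
      buf$running_mean <- (1 - momentum) * buf$running_mean + momentum * mu
      buf$running_var <- (1 - momentum) * buf$running_var +
        momentum * v * m / (m - 1)
    }
  } else {
    mu <- buf$running_mean
    istd <- 1 / sqrt(buf$running_var + eps)
  }
  r <- cpp_bn_apply(x$value, mu, istd, gamma$value, beta$value, TRUE)
  xhat <- r$xhat
  gv <- gamma$value
  new_node(r$y, list(x, gamma, beta), function(g) {
    bw <- cpp_bn_bw(g, xhat, gv, istd, training)
    list(bw$dx, bw$dgamma, bw$dbeta)
  })
}

layer_bn2d <- function(C, momentum = 0.1, eps = 1e-5) {
  buf <- new.env(parent = emptyenv())
  buf$running_mean <- numeric(C)
  buf$running_var <- rep(1, C)
  params <- list(gamma = new_param(rep(1, C)), beta = new_param(numeric(C)))
  p <- params
  new_module("bn2d", params = params, buffers = buf,
             fwd = function(x, ctx) {
               tp_batchnorm(x, p$gamma, p$beta, buf,
                            training = isTRUE(ctx$training),
                            momentum = momentum, eps = eps)
             },
             meta = list(C = C))
}

# ---- linear / layernorm / depthwise conv1d -------------------------------

layer_linear <- function(cin, cout, bias = TRUE) {
  params <- list(w = new_param(init_linear_w(cin, cout)))
  if (bias) params$b <- new_param(numeric(cout))
  p <- params
  new_module("linear", params = params,
             fwd = function(x, ctx) tp_linear(x, p$w, if (bias) p$b else NULL),
             meta = list(cin = cin, cout = cout, bias = bias))
}

layer_layernorm <- function(C) {
  params <- list(gamma = new_param(rep(1, C)), beta = new_param(numeric(C)))
  p <- params
  new_module("layernorm", params = params,
             fwd = function(x, ctx) tp_layernorm(x, p$gamma, p$beta))
}

layer_conv1d_dw <- function(D, k = 4L) {
  params <- list(w = new_param(matrix(rnorm(D * k, 0, 1 / sqrt(k)), D, k)),
                 b = new_param(numeric(D)))
  p <- params
  new_module("conv1d_dw", params = params,
             fwd = function(x, ctx) tp_conv1d_dw(x, p$w, p$b))
}

# ---------------------------------------------------------------------------
# additional tape ops used by attention blocks
# ---------------------------------------------------------------------------

# per-pixel channel mean, (B, C, H, W) -> (B, 1, H, W)
tp_chmean <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; hw <- d[3] * d[4]
  m3 <- aperm(array(x$value, c(B, C, hw)), c(2, 1, 3))
  v <- array(colSums(matrix(m3, C, B * hw)) / C, c(B, 1, d[3], d[4]))
  new_node(v, list(x), function(g) {
    gb <- array(as.vector(matrix(g, B, hw)), c(B, hw, C))
    dx <- aperm(gb, c(1, 3, 2)) / C
    dim(dx) <- d
    list(dx)
  })
}

# per-pixel channel max, (B, C, H, W) -> (B, 1, H, W)
tp_chmax <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; hw <- d[3] * d[4]
  m <- t(matrix(aperm(array(x$value, c(B, C, hw)), c(2, 1, 3)), C, B * hw))
  idx <- max.col(m, ties.method = "first")  # (B*hw) winning channel
  v <- array(m[cbind(seq_len(B * hw), idx)], c(B, 1, d[3], d[4]))
  new_node(v, list(x), function(g) {
    dx <- array(0, d)
    gm <- as.vector(matrix(g, B, hw))
    bi <- rep(seq_len(B), times = hw)
    si <- rep(seq_len(hw), each = B)
    h <- (si - 1) %% d[3] + 1
    w <- (si - 1) %/% d[3] + 1
    dx[cbind(bi, idx, h, w)] <- gm
    list(dx)
  })
}

# slice channels [from..to] of a (B, L, C) sequence
tp_slice3 <- function(x, from, to) {
  x <- as_node(x)
  d <- dim(x$value)
  v <- x$value[, , from:to, drop = FALSE]
  dim(v) <- c(d[1], d[2], to - from + 1L)
  new_node(v, list(x), function(g) {
    dx <- array(0, d)
    dx[, , from:to] <- g
    list(dx)
  })
}

# stack S matrices (B, C) into (B, S, C)
tp_stack_branch <- function(xs) {
  xs <- lapply(xs, as_node)
  B <- nrow(xs[[1]]$value); C <- ncol(xs[[1]]$value)
  S <- length(xs)
  y <- array(0, c(B, S, C))
  for (i in seq_len(S)) y[, i, ] <- xs[[i]]$value
  new_node(y, xs, function(g) {
    lapply(seq_len(S), function(i) {
      gi <- g[, i, , drop = FALSE]
      dim(gi) <- c(B, C)
      gi
    })
  })
}

# take branch i of (B, S, C) -> (B, C)
tp_take_branch <- function(x, i) {
  x <- as_node(x)
  d <- dim(x$value)
  v <- x$value[, i, , drop = FALSE]
  dim(v) <- c(d[1], d[3])
  new_node(v, list(x), function(g) {
    dx <- array(0, d)
    dx[, i, ] <- g
    list(dx)
  })
}
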