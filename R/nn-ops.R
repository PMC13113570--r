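# Minimal dense/convolutional neural-network primitives with manual
# backpropagation, in base R matrix algebra. Feature maps are arrays of
# dim (H, W, C, N); vector activations are matrices of dim (D, N).
# Each *_fwd returns list(y, cache); the matching *_bwd takes (cache, dy)
# and returns list(dx, <param gradients>). Gradient correctness is enforced
# by finite-difference tests.

conv_geom <- function(d, kh, kw, stride, dil) {
  list(pad_h = ((kh - 1L) * dil) %/% 2L,
       pad_w = ((kw - 1L) * dil) %/% 2L,
       Ho = (d[1] - 1L) %/% stride + 1L,
       Wo = (d[2] - 1L) %/% stride + 1L)
}

#' @keywords internal
conv2d_init <- function(kh, kw, cin, cout, gain = sqrt(2)) {
  W <- matrix(stats::rnorm(kh * kw * cin * cout, 0,
                           gain / sqrt(kh * kw * cin)),
              kh * kw * cin, cout)
  attr(W, "kh") <- kh; attr(W, "kw") <- kw; attr(W, "cin") <- cin
  list(W = W, b = numeric(cout))
}

conv2d_fwd <- function(x, W, b, stride = 1L, dil = 1L) {
  d <- dim(x)
  stride <- as.integer(stride); dil <- as.integer(dil)
  kh <- attr(W, "kh"); kw <- attr(W, "kw")
  g <- conv_geom(d, kh, kw, stride, dil)
  cols <- cpp_im2col(as.vector(x), d[1], d[2], d[3], d[4], kh, kw,
                     stride, dil, g$pad_h, g$pad_w, g$Ho, g$Wo)
  ym <- cols %*% W
  ym <- sweep(ym, 2, b, `+`)
  cout <- ncol(W)
  # rows are (output position within image, image); reorder to (H, W, C, N)
  y <- aperm(array(ym, c(g$Ho, g$Wo, d[4], cout)), c(1, 2, 4, 3))
  list(y = y, cache = list(cols = cols, W = W, g = g, dims = d,
                           kh = kh, kw = kw, stride = stride, dil = dil))
}

conv2d_bwd <- function(cache, dy) {
  g <- cache$g; d <- cache$dims
  cout <- ncol(cache$W)
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), g$Ho * g$Wo * d[4], cout)
  dW <- crossprod(cache$cols, dym)
  attributes(dW) <- attributes(cache$W)
  db <- colSums(dym)
  dcols <- tcrossprod(dym, cache$W)
  dx <- array(cpp_col2im(dcols, d[1], d[2], d[3], d[4], cache$kh, cache$kw,
                         cache$stride, cache$dil, g$pad_h, g$pad_w,
                         g$Ho, g$Wo), d)
  list(dx = dx, dW = dW, db = db)
}

# Transposed convolution, stride 2, as zero-stuffing + stride-1 conv.
convT2_fwd <- function(x, W, b) {
  d <- dim(x)
  xs <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  xs[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- x
  out <- conv2d_fwd(xs, W, b)
  out$cache$orig_dims <- d
  out
}

convT2_bwd <- function(cache, dy) {
  g <- conv2d_bwd(cache, dy)
  d <- cache$orig_dims
  g$dx <- g$dx[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE]
  g
}

maxpool2_fwd <- function(x) {
  d <- dim(x)
  oi <- seq(1, d[1], 2); ei <- seq(2, d[1], 2)
  oj <- seq(1, d[2], 2); ej <- seq(2, d[2], 2)
  a <- list(x[oi, oj, , , drop = FALSE], x[oi, ej, , , drop = FALSE],
            x[ei, oj, , , drop = FALSE], x[ei, ej, , , drop = FALSE])
  y <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  arg <- ifelse(a[[1]] == y, 1L, ifelse(a[[2]] == y, 2L,
                ifelse(a[[3]] == y, 3L, 4L)))
  list(y = y, cache = list(arg = arg, dims = d))
}

maxpool2_bwd <- function(cache, dy) {
  d <- cache$dims
  dx <- array(0, d)
  oi <- seq(1, d[1], 2); ei <- seq(2, d[1], 2)
  oj <- seq(1, d[2], 2); ej <- seq(2, d[2], 2)
  dx[oi, oj, , ] <- dy * (cache$arg == 1L)
  dx[oi, ej, , ] <- dx[oi, ej, , , drop = FALSE] + dy * (cache$arg == 2L)
  dx[ei, oj, , ] <- dx[ei, oj, , , drop = FALSE] + dy * (cache$arg == 3L)
  dx[ei, ej, , ] <- dx[ei, ej, , , drop = FALSE] + dy * (cache$arg == 4L)
  list(dx = dx)
}

# Nearest-neighbor upsample by integer factor f; backward sum-pools.
upnn_fwd <- function(x, f) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = f)
  ci <- rep(seq_len(d[2]), each = f)
  list(y = x[ri, ci, , , drop = FALSE], cache = list(dims = d, f = f))
}

upnn_bwd <- function(cache, dy) {
  d <- cache$dims; f <- cache$f
  dd <- dim(dy)
  # sum over each f x f block
  m <- array(dy, c(f, d[1], dd[2], dd[3], dd[4]))
  m <- colSums(m)                                   # (d1, f*d2?, C, N)
  m <- aperm(m, c(2, 1, 3, 4))                      # (W*f?, H, C, N)
  m2 <- array(m, c(f, d[2], d[1], dd[3], dd[4]))
  m2 <- colSums(m2)                                 # (d2, d1, C, N)
  list(dx = aperm(m2, c(2, 1, 3, 4)))
}

# Batch normalization on (rows = batch-like axis, cols = channels).
bn_fwd <- function(xm, gamma, beta, eps = 1e-5, training = TRUE,
                   run_mean = NULL, run_var = NULL) {
  if (training || is.null(run_mean)) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
  } else {
    mu <- run_mean; v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu, `-`), 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma,
                           mu = mu, v = v))
}

bn_bwd <- function(cache, dy) {
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  n <- nrow(dy)
  t1 <- sweep(dy, 2, colMeans(dy), `-`)
  t2 <- sweep(cache$xhat, 2, colMeans(dy * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$gamma * cache$inv, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# 4D batch norm (per channel over H, W, N) by reshaping through bn_fwd.
bn4_fwd <- function(x, gamma, beta, eps = 1e-5, training = TRUE,
                    run_mean = NULL, run_var = NULL) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  out <- bn_fwd(xm, gamma, beta, eps, training, run_mean, run_var)
  out$cache$dims <- d
  out$y <- aperm(array(out$y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  out
}

bn4_bwd <- function(cache, dy) {
  d <- cache$dims
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  g <- bn_bwd(cache, dym)
  g$dx <- aperm(array(g$dx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  g
}

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, cache = m)
}
relu_bwd <- function(cache, dy) list(dx = dy * cache)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Global average pooling (H, W, C, N) -> (C, N).
gap_fwd <- function(x) {
  d <- dim(x)
  y <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  list(y = y, cache = d)
}

gap_bwd <- function(cache, dy) {
  d <- cache
  hw <- d[1] * d[2]
  list(dx = array(rep(as.vector(dy) / hw, each = hw), d))
}

# Broadcast a (C, N) matrix over the spatial axes of an (H, W, C, N) map.
bcast_cn <- function(s, H, W) {
  array(rep(as.vector(s), each = H * W), c(H, W, dim(s)[1], dim(s)[2]))
}

# Channel-wise spatial sum of an (H, W, C, N) map -> (C, N).
chan_sum <- function(x) {
  d <- dim(x)
  matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

dense_init <- function(din, dout, gain = sqrt(2)) {
  list(W = matrix(stats::rnorm(dout * din, 0, gain / sqrt(din)), dout, din),
       b = numeric(dout))
}

dense_fwd <- function(x, W, b) {
  list(y = W %*% x + b, cache = list(x = x, W = W))
}

dense_bwd <- function(cache, dy) {
  list(dx = crossprod(cache$W, dy),
       dW = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

#' Numerically stable softmax
#'
#' Exponential normalization with max-subtraction. For a matrix, softmax is
#' taken over rows within each column (columns are samples).
#'
#' @param logits numeric vector or matrix of finite scores.
#' @return Probabilities of the same shape, summing to 1 (per column).
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) {
    z <- sweep(logits, 2, apply(logits, 2, max), `-`)
    e <- exp(z)
    sweep(e, 2, colSums(e), `/`)
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

# Adam optimizer over a flat named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    gv <- as.vector(g)
    mv <- beta1 * as.vector(state$m[[k]]) + (1 - beta1) * gv
    vv <- beta2 * as.vector(state$v[[k]]) + (1 - beta2) * gv^2
    state$m[[k]] <- array(mv, dim(state$m[[k]]) %||% length(mv))
    state$v[[k]] <- array(vv, dim(state$v[[k]]) %||% length(vv))
    upd <- lr * (mv / bc1) / (sqrt(vv / bc2) + eps)
    attrs <- attributes(params[[k]])
    params[[k]] <- params[[k]] -
      array(upd, dim(params[[k]]) %||% length(upd))
    attributes(params[[k]]) <- attrs
  }
  list(params = params, state = state)
}

# accumulate gradient lists (sum by name)
acc_grads <- function(acc, g, prefix) {
  for (nm in names(g)) {
    key <- paste0(prefix, nm)
    acc[[key]] <- if (is.null(acc[[key]])) g[[nm]] else acc[[key]] + g[[nm]]
  }
  acc
}
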