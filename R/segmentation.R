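#' Selective-kernel attention fusion
#'
#' Fuses three same-shape feature-map branches (different receptive fields)
#' by per-channel softmax attention. The branches are summed element-wise
#' into an integrated map `F`; global average pooling of `F` gives a channel
#' descriptor `g`; a fully connected bottleneck (reduction ratio `r`)
#' produces three per-channel logits, softmax-normalized into weights
#' `(p_m, q_m, r_m)` with `p_m + q_m + r_m = 1` for every channel `m`; the
#' output is the weighted sum of the branches.
#'
#' @param branches list of exactly three arrays, each `H x W x C` or
#'   `H x W x C x N`, identical shapes.
#' @param weights fusion parameters as created by [sk_fuse_init()]: a list
#'   `Wr, br, Wa, ba` (bottleneck and expansion layers).
#' @return A list with `fused` (same shape as a branch) and
#'   `attention` (`C x 3 x N` weight array).
#' @export
sk_attention_fuse <- function(branches, weights) {
  if (length(branches) != 3) stop("sk_attention_fuse: need exactly 3 branches")
  d1 <- dim(branches[[1]])
  for (b in branches)
    if (!identical(dim(b), d1)) stop("sk_attention_fuse: shape mismatch")
  squeeze <- length(d1) == 3
  if (squeeze) branches <- lapply(branches, function(b) array(b, c(d1, 1L)))
  out <- sk_fuse_fwd(branches, weights)
  fused <- out$y
  if (squeeze) fused <- array(fused, d1)
  list(fused = fused, attention = out$cache$w)
}

#' @rdname sk_attention_fuse
#' @param channels channel count `C`.
#' @param reduction bottleneck reduction ratio (default 8).
#' @export
sk_fuse_init <- function(channels, reduction = 8L) {
  hidden <- max(1L, channels %/% reduction)
  c(stats::setNames(dense_init(channels, hidden), c("Wr", "br")),
    stats::setNames(dense_init(hidden, 3L * channels, gain = 1),
                    c("Wa", "ba")))
}

# forward of the attention fusion given evaluated branches
sk_fuse_fwd <- function(branches, wts) {
  Fm <- branches[[1]] + branches[[2]] + branches[[3]]
  d <- dim(Fm)
  gp <- gap_fwd(Fm)
  d1 <- dense_fwd(gp$y, wts$Wr, wts$br)
  r1 <- relu_fwd(d1$y)
  d2 <- dense_fwd(r1$y, wts$Wa, wts$ba)
  C <- d[3]; N <- d[4]
  A <- array(d2$y, c(C, 3L, N))                 # rows channel-fastest
  Am <- matrix(apply(A, c(1, 3), max), C, N)
  E <- exp(sweep_c3(A, Am, `-`))
  S <- E[, 1, , drop = FALSE] + E[, 2, , drop = FALSE] + E[, 3, , drop = FALSE]
  w <- sweep_c3(E, array(S, c(C, N)), `/`)
  y <- bcast_cn(matrix(w[, 1, ], C, N), d[1], d[2]) * branches[[1]] +
    bcast_cn(matrix(w[, 2, ], C, N), d[1], d[2]) * branches[[2]] +
    bcast_cn(matrix(w[, 3, ], C, N), d[1], d[2]) * branches[[3]]
  list(y = y, cache = list(branches = branches, w = w, gp = gp, d1 = d1,
                           r1 = r1, d2 = d2, dims = d))
}

# apply op between a (C, 3, N) array and a (C, N) matrix along the branch axis
sweep_c3 <- function(A, M, op) {
  d <- dim(A)
  arr <- array(0, d)
  for (k in 1:3) arr[, k, ] <- op(matrix(A[, k, ], d[1], d[3]), M)
  arr
}

sk_fuse_bwd <- function(cache, dy) {
  d <- cache$dims; C <- d[3]; N <- d[4]
  w <- cache$w
  br <- cache$branches
  dB <- vector("list", 3)
  dw <- array(0, c(C, 3L, N))
  for (k in 1:3) {
    wk <- matrix(w[, k, ], C, N)
    dB[[k]] <- dy * bcast_cn(wk, d[1], d[2])
    dw[, k, ] <- chan_sum(dy * br[[k]])
  }
  # softmax backward over the branch axis
  dot <- matrix(0, C, N)
  for (k in 1:3) dot <- dot + matrix(w[, k, ] * dw[, k, ], C, N)
  dA <- array(0, c(C, 3L, N))
  for (k in 1:3)
    dA[, k, ] <- matrix(w[, k, ], C, N) * (matrix(dw[, k, ], C, N) - dot)
  g2 <- dense_bwd(cache$d2$cache, matrix(dA, C * 3L, N))
  gr <- relu_bwd(cache$r1$cache, g2$dx)
  g1 <- dense_bwd(cache$d1$cache, gr$dx)
  dF <- gap_bwd(cache$gp$cache, g1$dx)$dx
  for (k in 1:3) dB[[k]] <- dB[[k]] + dF
  list(dbranches = dB,
       grads = list(Wr = g1$dW, br = g1$db, Wa = g2$dW, ba = g2$db))
}

# squeeze-and-excitation channel re-weighting: x * sigmoid(W2 relu(W1 gap(x)))
se_fwd <- function(x, wts) {
  d <- dim(x)
  gp <- gap_fwd(x)
  d1 <- dense_fwd(gp$y, wts$W1, wts$b1)
  r1 <- relu_fwd(d1$y)
  d2 <- dense_fwd(r1$y, wts$W2, wts$b2)
  s <- sigmoid(d2$y)
  y <- x * bcast_cn(s, d[1], d[2])
  list(y = y, cache = list(x = x, s = s, gp = gp, d1 = d1, r1 = r1,
                           d2 = d2, dims = d))
}

se_bwd <- function(cache, dy) {
  d <- cache$dims
  ds <- chan_sum(dy * cache$x)
  dx <- dy * bcast_cn(cache$s, d[1], d[2])
  dz2 <- ds * cache$s * (1 - cache$s)
  g2 <- dense_bwd(cache$d2$cache, dz2)
  gr <- relu_bwd(cache$r1$cache, g2$dx)
  g1 <- dense_bwd(cache$d1$cache, gr$dx)
  dx <- dx + gap_bwd(cache$gp$cache, g1$dx)$dx
  list(dx = dx, grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db))
}

se_init <- function(channels, reduction = 8L) {
  hidden <- max(1L, channels %/% reduction)
  c(stats::setNames(dense_init(channels, hidden), c("W1", "b1")),
    stats::setNames(dense_init(hidden, channels, gain = 1), c("W2", "b2")))
}

#' Build a selective-kernel U-Net
#'
#' Encoder of `stages` spatial resolutions; each stage is a
#' `1x1 -> 3x3 -> 1x1` convolution bottleneck with batch normalization and
#' ReLU, squeeze-and-excitation channel re-weighting, and a residual
#' projection shortcut. Downsampling mixes max-pooling (stages 1-2) with
#' 1x1 stride-2 projections (later stages) — for the 6-stage full
#' configuration that is two poolings and three strided projections. The
#' decoder upsamples with transposed convolutions, concatenates the matching
#' encoder output, convolves, and ends each stage with a selective-kernel
#' fusion over three dilated-convolution branches. The head upsamples all
#' decoder outputs to input resolution, concatenates them, and applies
#' `1x1 conv -> BN -> ReLU -> 1x1 conv -> softmax` for per-pixel class
#' probabilities.
#'
#' @param config segmentation config list (see [default_config()]
#'   `$segmentation`): `stages`, `base_channels`, `sk_dilations`,
#'   `se_reduction`, `sk_reduction`, `classes`, `head_channels`.
#' @param in_channels input channel count (3 for RGB).
#' @param seed seed for parameter initialization.
#' @return An `sk_unet` model object (parameters, running batch-norm
#'   statistics, config).
#' @export
build_sk_unet <- function(config = default_config()$segmentation,
                          in_channels = 3L, seed = 1L) {
  S <- config$stages
  if (S < 2) stop("build_sk_unet: stages must be >= 2")
  ch <- config$base_channels * 2^(seq_len(S) - 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  P <- list(); bn <- list()
  add_conv <- function(name, kh, kw, cin, cout, gain = sqrt(2)) {
    w <- conv2d_init(kh, kw, cin, cout, gain)
    P[[paste0(name, ".W")]] <<- w$W
    P[[paste0(name, ".b")]] <<- w$b
  }
  add_bn <- function(name, c) {
    P[[paste0(name, ".gamma")]] <<- rep(1, c)
    P[[paste0(name, ".beta")]] <<- rep(0, c)
    bn[[name]] <<- list(mean = rep(0, c), var = rep(1, c))
  }
  add_dense_set <- function(prefix, wts) {
    for (nm in names(wts)) P[[paste0(prefix, ".", nm)]] <<- wts[[nm]]
  }
  cin <- in_channels
  for (s in seq_len(S)) {
    p <- paste0("enc", s)
    add_conv(paste0(p, ".c1"), 1, 1, cin, ch[s]); add_bn(paste0(p, ".bn1"), ch[s])
    add_conv(paste0(p, ".c2"), 3, 3, ch[s], ch[s]); add_bn(paste0(p, ".bn2"), ch[s])
    add_conv(paste0(p, ".c3"), 1, 1, ch[s], ch[s]); add_bn(paste0(p, ".bn3"), ch[s])
    add_dense_set(paste0(p, ".se"), se_init(ch[s], config$se_reduction))
    add_conv(paste0(p, ".sc"), 1, 1, cin, ch[s], gain = 1)
    if (s < S && s > 2)
      add_conv(paste0(p, ".down"), 1, 1, ch[s], ch[s])
    cin <- ch[s]
  }
  for (s in seq(S - 1, 1)) {
    p <- paste0("dec", s)
    add_conv(paste0(p, ".up"), 3, 3, ch[s + 1], ch[s])
    add_conv(paste0(p, ".c"), 3, 3, 2 * ch[s], ch[s])
    add_bn(paste0(p, ".bn"), ch[s])
    for (k in 1:3)
      add_conv(paste0(p, ".skb", k), 3, 3, ch[s], ch[s])
    add_dense_set(paste0(p, ".sk"), sk_fuse_init(ch[s], config$sk_reduction))
  }
  ccat <- sum(ch[seq_len(S - 1)])
  add_conv("head.c1", 1, 1, ccat, config$head_channels)
  add_bn("head.bn", config$head_channels)
  add_conv("head.c2", 1, 1, config$head_channels, config$classes, gain = 1)
  structure(list(params = P, bn = bn, config = config,
                 in_channels = in_channels, channels = ch, seed = seed),
            class = "sk_unet")
}

# Full forward pass. Returns per-pixel class probabilities, caches for the
# backward pass, and (in training mode) updated running BN statistics.
sk_unet_fwd <- function(model, x, training = TRUE, momentum = 0.1) {
  P <- model$params
  S <- model$config$stages
  dil <- model$config$sk_dilations
  caches <- list()
  bn_run <- model$bn
  conv_l <- function(name, x, stride = 1L, d = 1L) {
    o <- conv2d_fwd(x, P[[paste0(name, ".W")]], P[[paste0(name, ".b")]],
                    stride, d)
    caches[[name]] <<- o$cache
    o$y
  }
  bn_l <- function(name, x) {
    if (training) {
      o <- bn4_fwd(x, P[[paste0(name, ".gamma")]], P[[paste0(name, ".beta")]])
      bn_run[[name]]$mean <<- (1 - momentum) * bn_run[[name]]$mean +
        momentum * o$cache$mu
      bn_run[[name]]$var <<- (1 - momentum) * bn_run[[name]]$var +
        momentum * o$cache$v
    } else {
      o <- bn4_fwd(x, P[[paste0(name, ".gamma")]], P[[paste0(name, ".beta")]],
                   training = FALSE, run_mean = bn_run[[name]]$mean,
                   run_var = bn_run[[name]]$var)
    }
    caches[[name]] <<- o$cache
    o$y
  }
  relu_l <- function(name, x) {
    o <- relu_fwd(x)
    caches[[name]] <<- o$cache
    o$y
  }
  se_l <- function(prefix, x) {
    wts <- list(W1 = P[[paste0(prefix, ".W1")]], b1 = P[[paste0(prefix, ".b1")]],
                W2 = P[[paste0(prefix, ".W2")]], b2 = P[[paste0(prefix, ".b2")]])
    o <- se_fwd(x, wts)
    caches[[prefix]] <<- o$cache
    o$y
  }

  enc_out <- vector("list", S)
  z <- x
  for (s in seq_len(S)) {
    p <- paste0("enc", s)
    h <- relu_l(paste0(p, ".r1"), bn_l(paste0(p, ".bn1"),
                                       conv_l(paste0(p, ".c1"), z)))
    h <- relu_l(paste0(p, ".r2"), bn_l(paste0(p, ".bn2"),
                                       conv_l(paste0(p, ".c2"), h)))
    h <- bn_l(paste0(p, ".bn3"), conv_l(paste0(p, ".c3"), h))
    h <- se_l(paste0(p, ".se"), h)
    sc <- conv_l(paste0(p, ".sc"), z)
    h <- relu_l(paste0(p, ".rout"), h + sc)
    enc_out[[s]] <- h
    if (s < S) {
      if (s <= 2) {
        o <- maxpool2_fwd(h)
        caches[[paste0(p, ".pool")]] <- o$cache
        z <- o$y
      } else {
        z <- conv_l(paste0(p, ".down"), h, stride = 2L)
      }
    }
  }

  dec_out <- vector("list", S - 1)
  z <- enc_out[[S]]
  for (s in seq(S - 1, 1)) {
    p <- paste0("dec", s)
    o <- convT2_fwd(z, P[[paste0(p, ".up.W")]], P[[paste0(p, ".up.b")]])
    caches[[paste0(p, ".up")]] <- o$cache
    up <- o$y
    skip <- enc_out[[s]]
    cat <- abind4(up, skip)
    h <- relu_l(paste0(p, ".r"), bn_l(paste0(p, ".bn"),
                                      conv_l(paste0(p, ".c"), cat)))
    branches <- lapply(1:3, function(k)
      conv_l(paste0(p, ".skb", k), h, d = dil[k]))
    wts <- list(Wr = P[[paste0(p, ".sk.Wr")]], br = P[[paste0(p, ".sk.br")]],
                Wa = P[[paste0(p, ".sk.Wa")]], ba = P[[paste0(p, ".sk.ba")]])
    o <- sk_fuse_fwd(branches, wts)
    caches[[paste0(p, ".sk")]] <- o$cache
    dec_out[[s]] <- o$y
    z <- o$y
  }

  ups <- vector("list", S - 1)
  for (s in seq_len(S - 1)) {
    f <- 2^(s - 1)
    if (f == 1) {
      ups[[s]] <- dec_out[[s]]
    } else {
      o <- upnn_fwd(dec_out[[s]], f)
      caches[[paste0("headup", s)]] <- o$cache
      ups[[s]] <- o$y
    }
  }
  hcat <- ups[[1]]
  if (S - 1 >= 2) for (s in 2:(S - 1)) hcat <- abind4(hcat, ups[[s]])
  h <- relu_l("head.r", bn_l("head.bn", conv_l("head.c1", hcat)))
  logits <- conv_l("head.c2", h)
  prob <- pixel_softmax(logits)
  list(prob = prob, logits = logits, caches = caches, bn = bn_run,
       enc_dims = lapply(enc_out, dim))
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

pixel_softmax <- function(logits) {
  d <- dim(logits)
  xm <- matrix(aperm(logits, c(3, 1, 2, 4)), d[3], d[1] * d[2] * d[4])
  pm <- softmax(xm)
  aperm(array(pm, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

# Backward pass; dlogits is the gradient at the pre-softmax head output.
sk_unet_bwd <- function(model, fw, dlogits) {
  P <- model$params
  S <- model$config$stages
  dil <- model$config$sk_dilations
  caches <- fw$caches
  G <- list()
  conv_b <- function(name, dy) {
    g <- conv2d_bwd(caches[[name]], dy)
    G[[paste0(name, ".W")]] <<- g$dW
    G[[paste0(name, ".b")]] <<- g$db
    g$dx
  }
  bn_b <- function(name, dy) {
    g <- bn4_bwd(caches[[name]], dy)
    G[[paste0(name, ".gamma")]] <<- g$dgamma
    G[[paste0(name, ".beta")]] <<- g$dbeta
    g$dx
  }
  relu_b <- function(name, dy) relu_bwd(caches[[name]], dy)$dx
  se_b <- function(prefix, dy) {
    g <- se_bwd(caches[[prefix]], dy)
    for (nm in names(g$grads)) G[[paste0(prefix, ".", nm)]] <<- g$grads[[nm]]
    g$dx
  }

  dh <- conv_b("head.c2", dlogits)
  dhcat <- bn_b("head.bn", relu_b("head.r", dh))
  dhcat <- conv_b("head.c1", dhcat)

  ch <- model$channels
  ddec <- vector("list", S - 1)
  off <- 0L
  for (s in seq_len(S - 1)) {
    sl <- dhcat[, , off + seq_len(ch[s]), , drop = FALSE]
    off <- off + ch[s]
    f <- 2^(s - 1)
    ddec[[s]] <- if (f == 1) sl else
      upnn_bwd(caches[[paste0("headup", s)]], sl)$dx
  }

  denc <- vector("list", S)        # gradients flowing into encoder outputs
  # walk the decoder in reverse construction order (s = 1 up to S-1): dec s
  # consumed dec_out[s+1], so its input gradient accumulates into the chain.
  dz <- ddec[[1]]
  for (s in seq_len(S - 1)) {
    p <- paste0("dec", s)
    skc <- caches[[paste0(p, ".sk")]]
    g <- sk_fuse_bwd(skc, dz)
    for (nm in names(g$grads))
      G[[paste0(p, ".sk.", nm)]] <- g$grads[[nm]]
    dh <- 0
    for (k in 1:3)
      dh <- dh + conv_b(paste0(p, ".skb", k), g$dbranches[[k]])
    dcat <- conv_b(paste0(p, ".c"), bn_b(paste0(p, ".bn"),
                                         relu_b(paste0(p, ".r"), dh)))
    nup <- ch[s]
    dup <- dcat[, , seq_len(nup), , drop = FALSE]
    dskip <- dcat[, , nup + seq_len(nup), , drop = FALSE]
    denc[[s]] <- dskip
    gup <- convT2_bwd(caches[[paste0(p, ".up")]], dup)
    G[[paste0(p, ".up.W")]] <- gup$dW
    G[[paste0(p, ".up.b")]] <- gup$db
    dz <- gup$dx
    if (s < S - 1) dz <- dz + ddec[[s + 1]]
  }
  denc[[S]] <- dz                   # decoder chain starts at enc_out[[S]]

  dnext <- NULL
  for (s in seq(S, 1)) {
    p <- paste0("enc", s)
    dy <- denc[[s]] %||% 0
    if (!is.null(dnext)) {
      # gradient arriving through the downsampling path of stage s
      if (s <= 2) {
        dy <- dy + maxpool2_bwd(caches[[paste0(p, ".pool")]], dnext)$dx
      } else {
        dy <- dy + conv_b(paste0(p, ".down"), dnext)
      }
    }
    dy <- relu_b(paste0(p, ".rout"), dy)
    dsc <- dy
    dse <- se_b(paste0(p, ".se"), dy)
    dh <- bn_b(paste0(p, ".bn3"), dse)
    dh <- conv_b(paste0(p, ".c3"), dh)
    dh <- bn_b(paste0(p, ".bn2"), relu_b(paste0(p, ".r2"), dh))
    dh <- conv_b(paste0(p, ".c2"), dh)
    dh <- bn_b(paste0(p, ".bn1"), relu_b(paste0(p, ".r1"), dh))
    dz_in <- conv_b(paste0(p, ".c1"), dh) + conv_b(paste0(p, ".sc"), dsc)
    dnext <- dz_in
  }
  G
}

# Cross-entropy (optionally + soft-Dice) loss on per-pixel probabilities.
# masks: (H, W, N) integer array of class ids 0..K-1.
seg_loss_grad <- function(prob, masks, dice = FALSE) {
  d <- dim(prob)
  K <- d[3]
  n <- d[1] * d[2] * d[4]
  onehot <- array(0, d)
  for (k in seq_len(K))
    onehot[, , k, ] <- (masks == (k - 1)) * 1
  p <- pmax(prob, 1e-12)
  loss <- -sum(onehot * log(p)) / n
  dlogits <- (prob - onehot) / n
  if (dice && K == 2) {
    pf <- prob[, , 2, , drop = FALSE]
    yf <- onehot[, , 2, , drop = FALSE]
    inter <- sum(pf * yf); tot <- sum(pf) + sum(yf)
    dl <- 1 - 2 * inter / (tot + 1e-8)
    loss <- loss + dl
    dpf <- -(2 * yf * (tot + 1e-8) - 2 * inter) / (tot + 1e-8)^2
    # route through softmax: dlogit_k = p_k * (dp_k - sum_j p_j dp_j)
    dp <- array(0, d); dp[, , 2, ] <- dpf
    sm <- prob[, , 1, , drop = FALSE] * dp[, , 1, , drop = FALSE] +
      prob[, , 2, , drop = FALSE] * dp[, , 2, , drop = FALSE]
    for (k in 1:2)
      dlogits[, , k, ] <- dlogits[, , k, ] +
        prob[, , k, ] * (dp[, , k, ] - sm[, , 1, ])
  }
  list(loss = loss, dlogits = dlogits)
}

#' Train the SK-UNet segmenter
#'
#' Minimizes pixel-wise cross-entropy (optional soft-Dice term) with Adam.
#' Deterministic given the seed: shuffling, initialization and batch order
#' all derive from it. Returns the trained model with an attached loss
#' history.
#'
#' @param model an [build_sk_unet()] model.
#' @param dataset list of items with `image` ([rgb_image()]) and `mask`
#'   ([lesion_mask()]) at the model's resolution.
#' @param train list: `learning_rate`, `batch_size`, `epochs`, `dice_loss`.
#' @param seed integer seed.
#' @return The trained `sk_unet` with `$loss_history`.
#' @export
train_segmenter <- function(model, dataset,
                            train = default_config()$segmentation$train,
                            seed = 1L) {
  if (!length(dataset)) stop("train_segmenter: empty dataset")
  imgs <- lapply(dataset, function(it) strip_raster(it$image))
  msks <- lapply(dataset, function(it) strip_raster(it$mask))
  d1 <- dim(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d1) ||
        !identical(dim(msks[[i]]), d1[1:2]))
      stop("train_segmenter: image/mask shape mismatch at item ", i)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  opt <- adam_init(model$params)
  n <- length(imgs)
  bs <- min(train$batch_size, n)
  history <- numeric(0)
  for (ep in seq_len(train$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      xb <- array(0, c(d1[1], d1[2], d1[3], length(idx)))
      yb <- array(0, c(d1[1], d1[2], length(idx)))
      for (j in seq_along(idx)) {
        xb[, , , j] <- imgs[[idx[j]]]
        yb[, , j] <- msks[[idx[j]]]
      }
      fw <- sk_unet_fwd(model, xb, training = TRUE)
      model$bn <- fw$bn
      lg <- seg_loss_grad(fw$prob, yb, dice = isTRUE(train$dice_loss))
      G <- sk_unet_bwd(model, fw, lg$dlogits)
      st <- adam_step(model$params, G, opt, lr = train$learning_rate)
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    history <- c(history, ep_loss / nb)
  }
  model$loss_history <- history
  model
}

#' Predict a lesion mask
#'
#' Runs the model in inference mode (running batch-norm statistics) and
#' takes the per-pixel argmax of the class probabilities; ties are broken
#' toward the background class (index 0), so a 0.5/0.5 pixel is background.
#'
#' @param model a trained `sk_unet`.
#' @param image an [rgb_image()] at the model's training resolution.
#' @return A [lesion_mask()] (foreground = class 2 for the 2-class default).
#' @export
predict_mask <- function(model, image) {
  x <- strip_raster(image)
  xb <- array(x, c(dim(x)[1], dim(x)[2], dim(x)[3], 1L))
  fw <- sk_unet_fwd(model, xb, training = FALSE)
  prob_to_mask(fw$prob[, , , 1])
}

# argmax with ties toward class 1 (background)
prob_to_mask <- function(prob_hwk) {
  d <- dim(prob_hwk)
  pm <- matrix(prob_hwk, d[1] * d[2], d[3])
  best <- max.col(pm, ties.method = "first")
  lesion_mask(matrix((best != 1L) * 1, d[1], d[2]))
}

#' Segmentation overlap metrics
#'
#' Dice `2|A&B| / (|A|+|B|)`, IoU `|A&B| / |A|B|union`, and pixel accuracy.
#' Two empty masks count as perfect agreement (dice = iou = 1). Dice always
#' dominates IoU.
#'
#' @param pred,truth [lesion_mask()] objects of equal shape.
#' @return Named list `dice`, `iou`, `pixel_accuracy`.
#' @export
segmentation_metrics <- function(pred, truth) {
  p <- strip_raster(pred); t <- strip_raster(truth)
  if (!all(dim(p) == dim(t)))
    stop("segmentation_metrics: shape mismatch")
  inter <- sum(p == 1 & t == 1)
  sa <- sum(p); sb <- sum(t)
  uni <- sa + sb - inter
  list(dice = if (sa + sb == 0) 1 else 2 * inter / (sa + sb),
       iou = if (uni == 0) 1 else inter / uni,
       pixel_accuracy = mean(p == t))
}
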