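#' Batch normalization
#'
#' `y = scale * (x - mean) / sqrt(var + eps) + shift`. In training mode the
#' batch statistics (mean and population variance) are used; supplying
#' `mean`/`var` switches to inference mode with those running statistics.
#' Columns of a matrix are treated as independent features.
#'
#' @param x numeric vector, or matrix with samples in rows.
#' @param scale,shift learnable resize/shift factors (default 1 / 0).
#' @param eps stability constant added to the variance (default 1e-5).
#' @param mean,var optional running statistics (inference mode).
#' @return Normalized values, same shape as `x`.
#' @export
batch_norm <- function(x, scale = 1, shift = 0, eps = 1e-5,
                       mean = NULL, var = NULL) {
  vec <- !is.matrix(x)
  xm <- if (vec) matrix(x, ncol = 1) else x
  mu <- if (is.null(mean)) colMeans(xm) else rep_len(mean, ncol(xm))
  v <- if (is.null(var)) colMeans(xm^2) - mu^2 else rep_len(var, ncol(xm))
  y <- sweep(sweep(xm, 2, mu, `-`), 2, sqrt(v + eps), `/`)
  y <- sweep(sweep(y, 2, rep_len(scale, ncol(xm)), `*`), 2,
             rep_len(shift, ncol(xm)), `+`)
  if (vec) as.vector(y) else y
}

#' One gated-recurrent-unit step
#'
#' \deqn{U = \sigma(W_u s + X_u H_{prev} + B_u)}
#' \deqn{R = \sigma(W_r s + X_r H_{prev} + B_r)}
#' \deqn{E = \tanh(W_e s + X_e (R \odot H_{prev}) + B_e)}
#' \deqn{H = (1 - U) \odot E + U \odot H_{prev}}
#' so each coordinate of the new hidden state is a convex combination of the
#' candidate state and the previous state.
#'
#' @param params list with input weights `Wu, Wr, We` (hidden x input),
#'   recurrent weights `Xu, Xr, Xe` (hidden x hidden), biases `Bu, Br, Be`.
#' @param input input column(s) `s` (input-dim x batch matrix or vector).
#' @param hidden previous hidden state `H` (hidden x batch or vector).
#' @return A list `H` (new hidden), and gates `U`, `R`, `E`.
#' @export
gru_step <- function(params, input, hidden) {
  s <- if (is.matrix(input)) input else matrix(input, ncol = 1)
  h <- if (is.matrix(hidden)) hidden else matrix(hidden, ncol = 1)
  U <- sigmoid(params$Wu %*% s + params$Xu %*% h + params$Bu)
  R <- sigmoid(params$Wr %*% s + params$Xr %*% h + params$Br)
  E <- tanh(params$We %*% s + params$Xe %*% (R * h) + params$Be)
  Hn <- (1 - U) * E + U * h
  list(H = Hn, U = U, R = R, E = E)
}

gru_init <- function(input_dim, hidden) {
  g <- function(dout, din) matrix(stats::rnorm(dout * din, 0, 1 / sqrt(din)),
                                  dout, din)
  list(Wu = g(hidden, input_dim), Xu = g(hidden, hidden), Bu = numeric(hidden),
       Wr = g(hidden, input_dim), Xr = g(hidden, hidden), Br = numeric(hidden),
       We = g(hidden, input_dim), Xe = g(hidden, hidden), Be = numeric(hidden))
}

# GRU over a sequence: x (L, D, N) -> final hidden (H, N), with caches.
gru_seq_fwd <- function(params, x) {
  d <- dim(x)
  L <- d[1]; N <- d[3]
  Hdim <- nrow(params$Wu)
  h <- matrix(0, Hdim, N)
  caches <- vector("list", L)
  for (t in seq_len(L)) {
    s <- matrix(x[t, , ], d[2], N)
    st <- gru_step(params, s, h)
    caches[[t]] <- list(s = s, hprev = h, U = st$U, R = st$R, E = st$E)
    h <- st$H
  }
  list(h = h, caches = caches, dims = d)
}

gru_seq_bwd <- function(params, fw, dh) {
  d <- fw$dims
  L <- d[1]; N <- d[3]
  G <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  dx <- array(0, d)
  for (t in rev(seq_len(L))) {
    cc <- fw$caches[[t]]
    U <- cc$U; R <- cc$R; E <- cc$E; hp <- cc$hprev; s <- cc$s
    dU <- dh * (hp - E)
    dE <- dh * (1 - U)
    dhp <- dh * U
    dae <- dE * (1 - E^2)
    dau <- dU * U * (1 - U)
    drh <- crossprod(params$Xe, dae)
    dR <- drh * hp
    dhp <- dhp + drh * R
    dar <- dR * R * (1 - R)
    G$We <- G$We + tcrossprod(dae, s)
    G$Xe <- G$Xe + tcrossprod(dae, R * hp)
    G$Be <- G$Be + rowSums(dae)
    G$Wu <- G$Wu + tcrossprod(dau, s)
    G$Xu <- G$Xu + tcrossprod(dau, hp)
    G$Bu <- G$Bu + rowSums(dau)
    G$Wr <- G$Wr + tcrossprod(dar, s)
    G$Xr <- G$Xr + tcrossprod(dar, hp)
    G$Br <- G$Br + rowSums(dar)
    dhp <- dhp + crossprod(params$Xu, dau) + crossprod(params$Xr, dar)
    ds <- crossprod(params$Wu, dau) + crossprod(params$Wr, dar) +
      crossprod(params$We, dae)
    dx[t, , ] <- ds
    dh <- dhp
  }
  list(dx = dx, grads = G)
}

# ---- 1D convolution over (L, C, N) sequences, "same" zero padding ----

conv1d_init <- function(k, cin, cout, gain = sqrt(2)) {
  W <- matrix(stats::rnorm(k * cin * cout, 0, gain / sqrt(k * cin)),
              k * cin, cout)
  attr(W, "k") <- k; attr(W, "cin") <- cin
  list(W = W, b = numeric(cout))
}

conv1d_fwd <- function(x, W, b) {
  d <- dim(x)
  k <- attr(W, "k")
  p <- (k - 1) %/% 2
  xp <- array(0, c(d[1] + 2 * p, d[2], d[3]))
  xp[p + seq_len(d[1]), , ] <- x
  cols <- matrix(0, d[1] * d[3], k * d[2])
  for (j in seq_len(k)) {
    sl <- xp[j:(j + d[1] - 1), , , drop = FALSE]
    cols[, j + k * (seq_len(d[2]) - 1)] <-
      matrix(aperm(sl, c(1, 3, 2)), d[1] * d[3], d[2])
  }
  ym <- sweep(cols %*% W, 2, b, `+`)
  y <- aperm(array(ym, c(d[1], d[3], ncol(W))), c(1, 3, 2))
  list(y = y, cache = list(cols = cols, W = W, dims = d, p = p, k = k))
}

conv1d_bwd <- function(cache, dy) {
  d <- cache$dims
  k <- cache$k; p <- cache$p
  cout <- ncol(cache$W)
  dym <- matrix(aperm(dy, c(1, 3, 2)), d[1] * d[3], cout)
  dW <- crossprod(cache$cols, dym)
  attributes(dW) <- attributes(cache$W)
  db <- colSums(dym)
  dcols <- tcrossprod(dym, cache$W)
  dxp <- array(0, c(d[1] + 2 * p, d[2], d[3]))
  for (j in seq_len(k)) {
    dm <- dcols[, j + k * (seq_len(d[2]) - 1), drop = FALSE]
    dxp[j:(j + d[1] - 1), , ] <- dxp[j:(j + d[1] - 1), , , drop = FALSE] +
      aperm(array(dm, c(d[1], d[3], d[2])), c(1, 3, 2))
  }
  list(dx = dxp[p + seq_len(d[1]), , , drop = FALSE], dW = dW, db = db)
}

bn1d_fwd <- function(x, gamma, beta, training = TRUE, run_mean = NULL,
                     run_var = NULL) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])
  out <- bn_fwd(xm, gamma, beta, training = training, run_mean = run_mean,
                run_var = run_var)
  out$cache$dims <- d
  out$y <- aperm(array(out$y, c(d[1], d[3], d[2])), c(1, 3, 2))
  out
}

bn1d_bwd <- function(cache, dy) {
  d <- cache$dims
  dym <- matrix(aperm(dy, c(1, 3, 2)), d[1] * d[3], d[2])
  g <- bn_bwd(cache, dym)
  g$dx <- aperm(array(g$dx, c(d[1], d[3], d[2])), c(1, 3, 2))
  g
}

#' Build the hybrid 1D-CNN-GRU classifier
#'
#' Stack: two 1D convolution blocks (conv -> batch norm -> ReLU, "same"
#' padding, no pooling) over the feature sequence, a GRU along the sequence
#' axis whose final hidden state feeds a fully connected layer, and a
#' softmax output. With `use_gru = FALSE` (ablation) the GRU is replaced by
#' global average pooling over the sequence.
#'
#' @param input_length length of the (selected) feature sequence.
#' @param n_classes number of output classes `N`.
#' @param config classifier config (see [default_config()] `$classifier`).
#' @param seed seed for initialization.
#' @return A `cnn_gru` model object.
#' @export
build_classifier <- function(input_length, n_classes,
                             config = default_config()$classifier,
                             seed = 1L) {
  if (input_length < 1) stop("build_classifier: input_length must be >= 1")
  stopifnot(n_classes >= 2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  f <- config$conv_filters
  k <- min(config$kernel_size, max(1L, input_length))
  P <- list()
  c1 <- conv1d_init(k, 1L, f[1])
  P$conv1.W <- c1$W; P$conv1.b <- c1$b
  P$bn1.gamma <- rep(1, f[1]); P$bn1.beta <- rep(0, f[1])
  c2 <- conv1d_init(k, f[1], f[2])
  P$conv2.W <- c2$W; P$conv2.b <- c2$b
  P$bn2.gamma <- rep(1, f[2]); P$bn2.beta <- rep(0, f[2])
  use_gru <- isTRUE(config$use_gru)
  if (use_gru) {
    gp <- gru_init(f[2], config$gru_hidden)
    for (nm in names(gp)) P[[paste0("gru.", nm)]] <- gp[[nm]]
    hd <- config$gru_hidden
  } else {
    hd <- f[2]
  }
  fc <- dense_init(hd, n_classes, gain = 1)
  P$fc.W <- fc$W; P$fc.b <- fc$b
  structure(list(params = P, config = config, input_length = input_length,
                 n_classes = n_classes, use_gru = use_gru, seed = seed,
                 bn = list(bn1 = list(mean = rep(0, f[1]), var = rep(1, f[1])),
                           bn2 = list(mean = rep(0, f[2]), var = rep(1, f[2]))),
                 feat_mean = NULL, feat_sd = NULL, levels = NULL),
            class = "cnn_gru")
}

gru_params_of <- function(P) {
  list(Wu = P$gru.Wu, Xu = P$gru.Xu, Bu = P$gru.Bu,
       Wr = P$gru.Wr, Xr = P$gru.Xr, Br = P$gru.Br,
       We = P$gru.We, Xe = P$gru.Xe, Be = P$gru.Be)
}

# x: (L, 1, N) standardized feature sequences
clf_fwd <- function(model, x, training = TRUE, momentum = 0.1) {
  P <- model$params
  bn <- model$bn
  o1 <- conv1d_fwd(x, P$conv1.W, P$conv1.b)
  if (training) {
    b1 <- bn1d_fwd(o1$y, P$bn1.gamma, P$bn1.beta)
    bn$bn1$mean <- (1 - momentum) * bn$bn1$mean + momentum * b1$cache$mu
    bn$bn1$var <- (1 - momentum) * bn$bn1$var + momentum * b1$cache$v
  } else {
    b1 <- bn1d_fwd(o1$y, P$bn1.gamma, P$bn1.beta, training = FALSE,
                   run_mean = bn$bn1$mean, run_var = bn$bn1$var)
  }
  r1 <- relu_fwd(b1$y)
  o2 <- conv1d_fwd(r1$y, P$conv2.W, P$conv2.b)
  if (training) {
    b2 <- bn1d_fwd(o2$y, P$bn2.gamma, P$bn2.beta)
    bn$bn2$mean <- (1 - momentum) * bn$bn2$mean + momentum * b2$cache$mu
    bn$bn2$var <- (1 - momentum) * bn$bn2$var + momentum * b2$cache$v
  } else {
    b2 <- bn1d_fwd(o2$y, P$bn2.gamma, P$bn2.beta, training = FALSE,
                   run_mean = bn$bn2$mean, run_var = bn$bn2$var)
  }
  r2 <- relu_fwd(b2$y)
  if (model$use_gru) {
    gf <- gru_seq_fwd(gru_params_of(P), r2$y)
    feat <- gf$h
  } else {
    d <- dim(r2$y)
    feat <- matrix(colMeans(matrix(r2$y, d[1], d[2] * d[3])), d[2], d[3])
    gf <- NULL
  }
  fc <- dense_fwd(feat, P$fc.W, P$fc.b)
  prob <- softmax(fc$y)
  list(prob = prob, caches = list(o1 = o1, b1 = b1, r1 = r1, o2 = o2,
                                  b2 = b2, r2 = r2, gf = gf, fc = fc,
                                  xdims = dim(x)),
       bn = bn)
}

clf_bwd <- function(model, fw, dlogits) {
  P <- model$params
  cc <- fw$caches
  G <- list()
  gfc <- dense_bwd(cc$fc$cache, dlogits)
  G$fc.W <- gfc$dW; G$fc.b <- gfc$db
  if (model$use_gru) {
    gg <- gru_seq_bwd(gru_params_of(P), cc$gf, gfc$dx)
    for (nm in names(gg$grads)) G[[paste0("gru.", nm)]] <- gg$grads[[nm]]
    dr2 <- gg$dx
  } else {
    d <- dim(cc$r2$y)
    dr2 <- array(0, d)
    for (n in seq_len(d[3]))
      dr2[, , n] <- matrix(gfc$dx[, n], d[1], d[2], byrow = TRUE) / d[1]
  }
  db2 <- relu_bwd(cc$r2$cache, dr2)$dx
  g2 <- bn1d_bwd(cc$b2$cache, db2)
  G$bn2.gamma <- g2$dgamma; G$bn2.beta <- g2$dbeta
  gc2 <- conv1d_bwd(cc$o2$cache, g2$dx)
  G$conv2.W <- gc2$dW; G$conv2.b <- gc2$db
  db1 <- relu_bwd(cc$r1$cache, gc2$dx)$dx
  g1 <- bn1d_bwd(cc$b1$cache, db1)
  G$bn1.gamma <- g1$dgamma; G$bn1.beta <- g1$dbeta
  gc1 <- conv1d_bwd(cc$o1$cache, g1$dx)
  G$conv1.W <- gc1$dW; G$conv1.b <- gc1$db
  G
}

#' Train the hybrid classifier
#'
#' Cross-entropy minimized with Adam (defaults: learning rate 1e-4, batch
#' size 32, 30 epochs). Features are z-score standardized with statistics
#' fitted on the training data only (stored in the model and re-applied at
#' prediction time). Deterministic given the seed.
#'
#' @param model a [build_classifier()] model (or `NULL` to build one from
#'   the data dimensions).
#' @param table numeric feature matrix (rows = samples), columns ordered
#'   color -> texture -> shape as produced by [extract_features()].
#' @param labels class labels (factor or integer).
#' @param train training sub-config (`learning_rate`, `batch_size`,
#'   `epochs`).
#' @param seed integer seed.
#' @return The trained `cnn_gru` with `$loss_history`.
#' @export
train_classifier <- function(model, table, labels,
                             train = default_config()$classifier$train,
                             seed = 1L) {
  table <- as.matrix(table)
  if (!nrow(table)) stop("train_classifier: empty table")
  lev <- sort(unique(as.character(labels)))
  if (length(lev) < 2) stop("train_classifier: single-class data")
  y <- match(as.character(labels), lev)
  if (is.null(model))
    model <- build_classifier(ncol(table), length(lev), seed = seed)
  model$levels <- lev
  mu <- colMeans(table)
  sdv <- apply(table, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1
  model$feat_mean <- mu; model$feat_sd <- sdv
  X <- sweep(sweep(table, 2, mu, `-`), 2, sdv, `/`)
  n <- nrow(X); L <- ncol(X)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  opt <- adam_init(model$params)
  bs <- min(train$batch_size, n)
  K <- length(lev)
  history <- numeric(0)
  for (ep in seq_len(train$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      xb <- array(t(X[idx, , drop = FALSE]), c(L, 1L, length(idx)))
      fw <- clf_fwd(model, xb, training = TRUE)
      model$bn <- fw$bn
      onehot <- matrix(0, K, length(idx))
      onehot[cbind(y[idx], seq_along(idx))] <- 1
      p <- pmax(fw$prob, 1e-12)
      loss <- -sum(onehot * log(p)) / length(idx)
      dlogits <- (fw$prob - onehot) / length(idx)
      G <- clf_bwd(model, fw, dlogits)
      st <- adam_step(model$params, G, opt, lr = train$learning_rate)
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    history <- c(history, ep_loss / nb)
  }
  model$loss_history <- history
  model
}

#' Predict class probabilities / labels
#'
#' @param object a trained `cnn_gru`.
#' @param table numeric feature matrix.
#' @param type `"prob"` for a samples x classes probability matrix,
#'   `"class"` for labels.
#' @param ... unused.
#' @return Matrix of probabilities or a vector of predicted labels.
#' @export
predict.cnn_gru <- function(object, table, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  table <- as.matrix(table)
  X <- sweep(sweep(table, 2, object$feat_mean, `-`), 2, object$feat_sd, `/`)
  xb <- array(t(X), c(ncol(X), 1L, nrow(X)))
  fw <- clf_fwd(object, xb, training = FALSE)
  prob <- t(fw$prob)
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  object$levels[max.col(prob, ties.method = "first")]
}

#' Classification metrics report
#'
#' Accuracy, macro precision/recall/F1 (classes absent from both prediction
#' and truth contribute 0 with a warning), macro one-vs-rest AUC from
#' predicted probabilities, and the confusion matrix (rows = truth).
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param prob optional samples x classes probability matrix with class
#'   column names (enables AUC).
#' @param levels class levels (default: union of truth and predictions).
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(truth, predicted, prob = NULL, levels = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (!length(truth)) stop("metrics_report: empty data")
  if (is.null(levels)) levels <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels), factor(predicted, levels))
  cm <- matrix(as.numeric(cm), length(levels), length(levels),
               dimnames = list(truth = levels, predicted = levels))
  prec <- rec <- f1 <- numeric(length(levels))
  warned <- FALSE
  for (i in seq_along(levels)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    if (sum(cm[i, ]) == 0) warned <- TRUE
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  if (warned) warning("metrics_report: zero-support class contributes 0")
  auc <- NA_real_
  if (!is.null(prob)) {
    aucs <- c()
    for (lv in levels) {
      pos <- truth == lv
      if (!any(pos) || all(pos) || !(lv %in% colnames(prob))) next
      sc <- prob[, lv]
      r <- rank(sc)
      np <- sum(pos); nn <- sum(!pos)
      aucs <- c(aucs, (sum(r[pos]) - np * (np + 1) / 2) / (np * nn))
    }
    if (length(aucs)) auc <- mean(aucs)
  }
  structure(list(accuracy = sum(diag(cm)) / sum(cm),
                 precision = mean(prec), recall = mean(rec), f1 = mean(f1),
                 auc = auc, confusion = cm,
                 per_class = data.frame(class = levels, precision = prec,
                                        recall = rec, f1 = f1)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | macro precision %.3f recall %.3f F1 %.3f | AUC %s\n",
    x$accuracy, x$precision, x$recall, x$f1,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Evaluate a trained classifier
#'
#' @param model a trained `cnn_gru`.
#' @param table numeric feature matrix.
#' @param labels true labels.
#' @return A [metrics_report()].
#' @export
evaluate_classifier <- function(model, table, labels) {
  if (!nrow(as.matrix(table))) stop("evaluate_classifier: empty data")
  prob <- predict(model, table, type = "prob")
  pred <- model$levels[max.col(prob, ties.method = "first")]
  metrics_report(as.character(labels), pred, prob, levels = model$levels)
}
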