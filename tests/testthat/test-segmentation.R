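test_that("sk_attention_fuse normalizes weights and averages symmetric logits", {
  set.seed(1)
  # zero fusion parameters -> identical logits -> weights 1/3, fused = mean
  wts <- sk_fuse_init(4, 2)
  wts$Wr[] <- 0; wts$br[] <- 0; wts$Wa[] <- 0; wts$ba[] <- 0
  brs <- lapply(1:3, function(k) array(rnorm(6 * 6 * 4), c(6, 6, 4)))
  out <- sk_attention_fuse(brs, wts)
  expect_equal(out$fused, (brs[[1]] + brs[[2]] + brs[[3]]) / 3,
               tolerance = 1e-12)
  expect_true(all(abs(out$attention - 1 / 3) < 1e-12))

  # random parameters: nonnegative weights, per-channel sum 1
  for (rep in 1:100) {
    wts <- sk_fuse_init(3, 2)
    brs <- lapply(1:3, function(k) array(rnorm(4 * 4 * 3), c(4, 4, 3)))
    at <- sk_attention_fuse(brs, wts)$attention
    expect_true(all(at >= 0 & at <= 1))
    expect_lt(max(abs(apply(at, c(1, 3), sum) - 1)), 1e-6)
  }

  # 2-channel toy with fixed logits (2,0,0) and (0,0,0)
  wts <- sk_fuse_init(2, 2)
  wts$Wr[] <- 0; wts$br[] <- 0; wts$Wa[] <- 0
  wts$ba <- c(2, 0, 0, 0, 0, 0)   # channel-fastest: ch1=(2,0,0), ch2=(0,0,0)
  brs <- lapply(1:3, function(k) array(rnorm(4 * 4 * 2), c(4, 4, 2)))
  at <- sk_attention_fuse(brs, wts)$attention
  expect_equal(at[1, , 1], c(exp(2), 1, 1) / (exp(2) + 2), tolerance = 1e-9)
  expect_equal(at[2, , 1], rep(1 / 3, 3), tolerance = 1e-9)

  expect_error(sk_attention_fuse(brs[1:2], wts), "3 branches")
  brs[[2]] <- array(0, c(3, 3, 2))
  expect_error(sk_attention_fuse(brs, wts), "shape mismatch")
})

test_that("the full 6-stage network exposes six resolutions and 3-branch SK", {
  cfg <- default_config()$segmentation
  cfg$stages <- 6L
  cfg$base_channels <- 2L
  cfg$head_channels <- 4L
  model <- build_sk_unet(cfg, seed = 2)
  # every decoder stage carries exactly 3 SK branches
  for (s in 1:5)
    expect_length(grep(sprintf("^dec%d\\.skb", s),
                       names(model$params), value = TRUE), 6) # W and b x 3
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  fw <- lesionkit:::sk_unet_fwd(model, x, training = TRUE)
  res <- vapply(fw$enc_dims, function(d) d[1], numeric(1))
  expect_equal(res, c(64, 32, 16, 8, 4, 2))     # six distinct resolutions
  # per-pixel class probabilities sum to 1
  expect_lt(max(abs(apply(fw$prob, c(1, 2, 4), sum) - 1)), 1e-9)
})

test_that("predict_mask takes the argmax with ties toward background", {
  p <- array(0, c(2, 2, 2))
  p[, , 1] <- matrix(c(0.1, 0.5, 0.9, 0.4), 2, 2)
  p[, , 2] <- 1 - p[, , 1]
  m <- lesionkit:::prob_to_mask(p)
  expect_equal(matrix(as.numeric(m), 2, 2),
               matrix(c(1, 0, 0, 1), 2, 2))     # 0.5 tie -> background
})

test_that("segmentation metrics match counting oracles and invariants", {
  a <- lesion_mask(matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(segmentation_metrics(a, a), list(dice = 1, iou = 1,
                                                pixel_accuracy = 1))
  b <- lesion_mask(matrix(c(0, 0, 1, 1), 2, 2))
  m <- segmentation_metrics(a, b)
  expect_equal(m$dice, 0); expect_equal(m$iou, 0)
  # equal-area half-overlap: dice 0.5, iou 1/3
  p <- matrix(0, 4, 4); p[1:2, 1:2] <- 1
  t <- matrix(0, 4, 4); t[2:3, 1:2] <- 1
  m2 <- segmentation_metrics(lesion_mask(p), lesion_mask(t))
  expect_equal(m2$dice, 0.5)
  expect_equal(m2$iou, 1 / 3)
  expect_equal(m2$pixel_accuracy, 12 / 16)
  # both empty -> perfect
  e <- lesion_mask(matrix(0, 3, 3))
  expect_equal(segmentation_metrics(e, e)$dice, 1)
  expect_error(segmentation_metrics(a, e), "shape mismatch")
  # dice >= iou and symmetry on random pairs
  set.seed(6)
  for (i in 1:20) {
    x <- lesion_mask(matrix(rbinom(64, 1, 0.4), 8, 8))
    y <- lesion_mask(matrix(rbinom(64, 1, 0.4), 8, 8))
    mx <- segmentation_metrics(x, y)
    my <- segmentation_metrics(y, x)
    expect_gte(mx$dice, mx$iou)
    expect_equal(mx$dice, my$dice)
    expect_equal(mx$iou, my$iou)
  }
})

test_that("training descends and is bit-reproducible under a fixed seed", {
  sp <- synth_image_params(size = 24L)
  ds <- make_image_dataset(5, sp, seed = 3)
  cfg <- default_config()$segmentation
  cfg$stages <- 3L; cfg$base_channels <- 4L; cfg$head_channels <- 6L
  tr <- list(learning_rate = 1e-3, batch_size = 2L, epochs = 4L,
             dice_loss = FALSE)
  m1 <- train_segmenter(build_sk_unet(cfg, seed = 9), ds, tr, seed = 9)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  m2 <- train_segmenter(build_sk_unet(cfg, seed = 9), ds, tr, seed = 9)
  expect_identical(m1$loss_history, m2$loss_history)
  pred <- predict_mask(m1, ds[[1]]$image)
  expect_s3_class(pred, "lesion_mask")
  expect_equal(dim(pred), c(24L, 24L))
  expect_error(train_segmenter(m1, list(), tr), "empty dataset")
})
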