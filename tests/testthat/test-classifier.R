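test_that("batch_norm matches hand-computed values and identities", {
  # constant batch -> shift everywhere
  expect_equal(batch_norm(rep(4, 8), scale = 3, shift = 0.5), rep(0.5, 8),
               tolerance = 1e-3)
  # normalized batch has mean 0, variance ~ 1
  set.seed(1)
  x <- rnorm(500, 5, 2)
  y <- batch_norm(x)
  expect_lt(abs(mean(y)), 1e-12)
  expect_equal(stats::var(y) * 499 / 500, 1, tolerance = 1e-4)
  # batch {1,2,3}, scale 2, shift 1, eps 0: mean 2, population var 2/3
  y2 <- batch_norm(c(1, 2, 3), scale = 2, shift = 1, eps = 0)
  expect_equal(y2, 2 * (c(1, 2, 3) - 2) / sqrt(2 / 3) + 1, tolerance = 1e-12)
  # inference mode uses the supplied running statistics
  y3 <- batch_norm(c(1, 2, 3), mean = 0, var = 1, eps = 0)
  expect_equal(y3, c(1, 2, 3))
})

test_that("gru_step follows the gate equations", {
  h <- 3
  p <- lesionkit:::gru_init(2, h)
  s <- matrix(rnorm(2), 2, 1)
  h0 <- matrix(rnorm(h), h, 1)
  # update gate forced to 1 -> hidden state carried through
  p1 <- p; p1$Bu[] <- 50
  expect_equal(gru_step(p1, s, h0)$H, h0, tolerance = 1e-9)
  # all-zero parameters and hidden state -> zero output
  p0 <- lapply(p, function(m) { m[] <- 0; m })
  expect_equal(gru_step(p0, s, matrix(0, h, 1))$H, matrix(0, h, 1))
  # scalar hand computation: omega = X = 1, B = 0, s = 1, H_prev = 0.5
  ps <- list(Wu = matrix(1), Xu = matrix(1), Bu = 0,
             Wr = matrix(1), Xr = matrix(1), Br = 0,
             We = matrix(1), Xe = matrix(1), Be = 0)
  st <- gru_step(ps, 1, 0.5)
  U <- 1 / (1 + exp(-1.5)); R <- U
  E <- tanh(1 + R * 0.5)
  expect_equal(as.numeric(st$H), (1 - U) * E + U * 0.5, tolerance = 1e-9)
  # reset gate forced to 0 makes the candidate independent of H_prev
  pr <- p; pr$Br[] <- -50
  e1 <- gru_step(pr, s, h0)$E
  e2 <- gru_step(pr, s, h0 + 5)$E
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("the new hidden state is a convex combination per coordinate", {
  set.seed(2)
  p <- lesionkit:::gru_init(3, 4)
  for (i in 1:20) {
    s <- matrix(rnorm(3), 3, 1)
    h0 <- matrix(rnorm(4), 4, 1)
    st <- gru_step(p, s, h0)
    lo <- pmin(st$E, h0); hi <- pmax(st$E, h0)
    expect_true(all(st$H >= lo - 1e-12 & st$H <= hi + 1e-12))
  }
})

test_that("softmax closed forms hold", {
  expect_equal(softmax(rep(1.7, 4)), rep(0.25, 4))
  expect_equal(softmax(c(0, log(2))), c(1 / 3, 2 / 3), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) expect_equal(sum(softmax(rnorm(5) * 10)), 1)
  m <- softmax(matrix(rnorm(12), 3, 4))
  expect_equal(colSums(m), rep(1, 4))
  expect_equal(softmax(c(1000, 1001)), softmax(c(0, 1)))  # stabilized
})

test_that("classifier builds, is seed-deterministic, handles edge shapes", {
  m1 <- build_classifier(277, 3, seed = 4)
  m2 <- build_classifier(277, 3, seed = 4)
  expect_identical(m1$params, m2$params)
  xb <- array(rnorm(277), c(277, 1, 1))
  fw <- lesionkit:::clf_fwd(m1, xb, training = FALSE)
  expect_equal(sum(fw$prob), 1, tolerance = 1e-9)
  expect_equal(nrow(fw$prob), 3L)
  # degenerate single-feature sequence
  ms <- build_classifier(1, 2, seed = 1)
  fws <- lesionkit:::clf_fwd(ms, array(0.3, c(1, 1, 2)), training = FALSE)
  expect_equal(colSums(fws$prob), rep(1, 2), tolerance = 1e-9)
})

test_that("training descends, is deterministic, and recovers easy classes", {
  # well-separated table (class mean gap 3 sd, n = 300): held-out >= 0.9
  tb <- make_feature_table(n = 300, p = 8, k = 3, r = 0, separation = 3,
                           n_classes = 3, seed = 15)
  tr <- list(learning_rate = 1e-3, batch_size = 32L, epochs = 30L)
  cfg <- default_config()$classifier
  cfg$conv_filters <- c(8L, 16L); cfg$gru_hidden <- 16L
  c1 <- build_classifier(8, 3, cfg, seed = 2)
  c1 <- train_classifier(c1, tb$table[1:210, ], tb$labels[1:210], tr,
                         seed = 2)
  expect_lt(tail(c1$loss_history, 1), c1$loss_history[1])
  rep <- evaluate_classifier(c1, tb$table[211:300, ], tb$labels[211:300])
  expect_gte(rep$accuracy, 0.9)
  # bit-identical retraining under the same seed
  c2 <- build_classifier(8, 3, cfg, seed = 2)
  c2 <- train_classifier(c2, tb$table[1:210, ], tb$labels[1:210], tr,
                         seed = 2)
  expect_identical(c1$loss_history, c2$loss_history)
  expect_error(train_classifier(NULL, tb$table, rep(1, 300), tr),
               "single-class")
})

test_that("metrics match counting oracles and are order-invariant", {
  truth <- c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3)
  pred  <- c(1, 1, 2, 1, 2, 2, 3, 3, 3, 1)
  r <- metrics_report(truth, pred)
  # hand-tabulated confusion: class1 3/4, class2 2/3, class3 2/3
  expect_equal(unname(r$confusion),
               matrix(c(3, 0, 1,  1, 2, 0,  0, 1, 2), 3, 3))
  expect_equal(r$accuracy, 7 / 10)
  p1 <- 3 / 4; r1 <- 3 / 4
  p2 <- 2 / 3; r2 <- 2 / 3
  p3 <- 2 / 3; r3 <- 2 / 3
  expect_equal(r$precision, mean(c(p1, p2, p3)))
  expect_equal(r$recall, mean(c(r1, r2, r3)))
  expect_equal(r$f1, mean(c(2 * p1 * r1 / (p1 + r1), 2 * p2 * r2 / (p2 + r2),
                            2 * p3 * r3 / (p3 + r3))))
  expect_equal(sum(r$confusion), 10)
  expect_equal(unname(rowSums(r$confusion)), c(4, 3, 3))  # class supports
  # order invariance
  o <- sample(10)
  r2o <- metrics_report(truth[o], pred[o])
  expect_equal(r2o$confusion, r$confusion)
  # perfect predictions
  rp <- metrics_report(truth, truth)
  expect_equal(rp$accuracy, 1); expect_equal(rp$f1, 1)
  expect_true(all(diag(rp$confusion) == c(4, 3, 3)))
  # constant predictor on balanced binary labels
  rc <- metrics_report(rep(1:2, each = 5), rep(1, 10),
                       levels = c("1", "2"))
  expect_equal(rc$accuracy, 0.5)
  expect_equal(rc$per_class$recall[1], 1)
  # AUC from probabilities: perfect ranking -> 1
  prob <- cbind("1" = c(0.9, 0.8, 0.2, 0.1), "2" = c(0.1, 0.2, 0.8, 0.9))
  ra <- metrics_report(c(1, 1, 2, 2), c(1, 1, 2, 2), prob)
  expect_equal(ra$auc, 1)
})
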