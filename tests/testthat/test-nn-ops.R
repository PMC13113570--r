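# Finite-difference gradient checks for every backprop primitive, at tiny
# sizes. These guard the hand-derived backward passes that training relies
# on.

test_that("conv2d forward matches brute-force convolution", {
  set.seed(1)
  x <- array(rnorm(6 * 5 * 2 * 2), c(6, 5, 2, 2))
  w <- lesionkit:::conv2d_init(3, 3, 2, 3)
  y <- lesionkit:::conv2d_fwd(x, w$W, w$b)$y
  Wt <- array(w$W, c(3, 3, 2, 3))
  ref <- array(0, dim(y))
  for (n in 1:2) for (co in 1:3) for (i in 1:6) for (j in 1:5) {
    s <- w$b[co]
    for (ci in 1:2) for (ki in 1:3) for (kj in 1:3) {
      ri <- i + ki - 2; cj <- j + kj - 2
      if (ri >= 1 && ri <= 6 && cj >= 1 && cj <= 5)
        s <- s + x[ri, cj, ci, n] * Wt[ki, kj, ci, co]
    }
    ref[i, j, co, n] <- s
  }
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("2D primitives pass finite-difference gradient checks", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  w <- lesionkit:::conv2d_init(3, 3, 2, 2)
  fw <- lesionkit:::conv2d_fwd(x, w$W, w$b)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  g <- lesionkit:::conv2d_bwd(fw$cache, dy)
  f <- function(z) sum(lesionkit:::conv2d_fwd(z, w$W, w$b)$y * dy)
  expect_lt(rel_err(g$dx, num_grad(f, x)), 1e-6)
  fW <- function(z) {
    attr(z, "kh") <- 3L; attr(z, "kw") <- 3L; attr(z, "cin") <- 2L
    sum(lesionkit:::conv2d_fwd(x, z, w$b)$y * dy)
  }
  expect_lt(rel_err(as.vector(g$dW), as.vector(num_grad(fW, w$W))), 1e-6)

  # dilated + strided variant
  fw2 <- lesionkit:::conv2d_fwd(x, w$W, w$b, stride = 2L, dil = 2L)
  dy2 <- array(rnorm(length(fw2$y)), dim(fw2$y))
  g2 <- lesionkit:::conv2d_bwd(fw2$cache, dy2)
  f2 <- function(z)
    sum(lesionkit:::conv2d_fwd(z, w$W, w$b, stride = 2L, dil = 2L)$y * dy2)
  expect_lt(rel_err(g2$dx, num_grad(f2, x)), 1e-6)

  # transposed conv
  ft <- lesionkit:::convT2_fwd(x, w$W, w$b)
  dyt <- array(rnorm(length(ft$y)), dim(ft$y))
  gt <- lesionkit:::convT2_bwd(ft$cache, dyt)
  expect_lt(rel_err(gt$dx, num_grad(function(z)
    sum(lesionkit:::convT2_fwd(z, w$W, w$b)$y * dyt), x)), 1e-6)

  # max pooling and nearest upsampling
  fp <- lesionkit:::maxpool2_fwd(x)
  dyp <- array(rnorm(length(fp$y)), dim(fp$y))
  expect_lt(rel_err(lesionkit:::maxpool2_bwd(fp$cache, dyp)$dx,
                    num_grad(function(z)
                      sum(lesionkit:::maxpool2_fwd(z)$y * dyp), x)), 1e-6)
  fu <- lesionkit:::upnn_fwd(x, 2L)
  dyu <- array(rnorm(length(fu$y)), dim(fu$y))
  expect_lt(rel_err(lesionkit:::upnn_bwd(fu$cache, dyu)$dx,
                    num_grad(function(z)
                      sum(lesionkit:::upnn_fwd(z, 2L)$y * dyu), x)), 1e-6)

  # batch norm (4D)
  gam <- runif(2, 0.5, 1.5); bet <- rnorm(2)
  fb <- lesionkit:::bn4_fwd(x, gam, bet)
  dyb <- array(rnorm(length(fb$y)), dim(fb$y))
  gb <- lesionkit:::bn4_bwd(fb$cache, dyb)
  expect_lt(rel_err(gb$dx, num_grad(function(z)
    sum(lesionkit:::bn4_fwd(z, gam, bet)$y * dyb), x)), 1e-5)
  expect_lt(rel_err(gb$dgamma, num_grad(function(z)
    sum(lesionkit:::bn4_fwd(x, z, bet)$y * dyb), gam)), 1e-6)
})

test_that("SE and SK blocks pass gradient checks", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  sew <- lesionkit:::se_init(2, 2)
  fse <- lesionkit:::se_fwd(x, sew)
  dys <- array(rnorm(length(fse$y)), dim(fse$y))
  gs <- lesionkit:::se_bwd(fse$cache, dys)
  expect_lt(rel_err(gs$dx, num_grad(function(z)
    sum(lesionkit:::se_fwd(z, sew)$y * dys), x)), 1e-6)

  skw <- sk_fuse_init(2, 2)
  brs <- lapply(1:3, function(k) array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2)))
  fsk <- lesionkit:::sk_fuse_fwd(brs, skw)
  dyk <- array(rnorm(length(fsk$y)), dim(fsk$y))
  gk <- lesionkit:::sk_fuse_bwd(fsk$cache, dyk)
  for (k in 1:3) {
    nb <- num_grad(function(z) {
      b2 <- brs; b2[[k]] <- z
      sum(lesionkit:::sk_fuse_fwd(b2, skw)$y * dyk)
    }, brs[[k]])
    expect_lt(rel_err(gk$dbranches[[k]], nb), 1e-6)
  }
  expect_lt(rel_err(as.vector(gk$grads$Wa), as.vector(num_grad(function(z) {
    s2 <- skw; s2$Wa <- z
    sum(lesionkit:::sk_fuse_fwd(brs, s2)$y * dyk)
  }, skw$Wa))), 1e-6)
})

test_that("1D conv and GRU sequence pass gradient checks", {
  set.seed(4)
  x1 <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  c1 <- lesionkit:::conv1d_init(3, 2, 4)
  f1 <- lesionkit:::conv1d_fwd(x1, c1$W, c1$b)
  dy1 <- array(rnorm(length(f1$y)), dim(f1$y))
  g1 <- lesionkit:::conv1d_bwd(f1$cache, dy1)
  expect_lt(rel_err(g1$dx, num_grad(function(z)
    sum(lesionkit:::conv1d_fwd(z, c1$W, c1$b)$y * dy1), x1)), 1e-6)

  gp <- lesionkit:::gru_init(3, 4)
  xg <- array(rnorm(5 * 3 * 2), c(5, 3, 2))
  fg <- lesionkit:::gru_seq_fwd(gp, xg)
  dh <- matrix(rnorm(8), 4, 2)
  gg <- lesionkit:::gru_seq_bwd(gp, fg, dh)
  expect_lt(rel_err(gg$dx, num_grad(function(z)
    sum(lesionkit:::gru_seq_fwd(gp, z)$h * dh), xg)), 1e-6)
  for (nm in c("Wu", "Xr", "Be")) {
    ng <- num_grad(function(z) {
      p2 <- gp; p2[[nm]] <- z
      sum(lesionkit:::gru_seq_fwd(p2, xg)$h * dh)
    }, gp[[nm]])
    expect_lt(rel_err(as.vector(gg$grads[[nm]]), as.vector(ng)), 1e-6)
  }
})
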