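# shared in-code fixtures and oracles

rel_err <- function(a, b) max(abs(a - b)) / max(abs(a) + abs(b), 1e-8)

# central-difference numeric gradient of scalar f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rasterized disk mask of radius r centered in an odd frame
disk_mask <- function(r, n = 2 * r + 9) {
  cx <- (n + 1) / 2
  lesion_mask(outer(seq_len(n), seq_len(n),
                    function(i, j) ((i - cx)^2 + (j - cx)^2) <= r^2) * 1)
}

# brute-force GLCM + Haralick oracle (nested loops, independent of glcm())
oracle_glcm <- function(g, mask, levels, d, angle) {
  off <- switch(as.character(angle), "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  sel <- mask == 1
  lo <- min(g[sel]); hi <- max(g[sel])
  q <- if (hi > lo) pmin(floor((g - lo) / (hi - lo) * levels) + 1, levels) else
    matrix(1, nrow(g), ncol(g))
  q[g <= lo] <- 1
  m <- matrix(0, levels, levels)
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= nrow(g) && j2 >= 1 && j2 <= ncol(g) &&
        sel[i, j] && sel[i2, j2])
      m[q[i, j], q[i2, j2]] <- m[q[i, j], q[i2, j2]] + 1
  }
  m <- m + t(m)
  m / sum(m)
}

oracle_haralick <- function(p) {
  g <- nrow(p)
  out <- c(contrast = 0, dissimilarity = 0, asm = 0, homogeneity = 0)
  mu_m <- 0; mu_n <- 0
  for (m in 1:g) for (n in 1:g) {
    out["contrast"] <- out["contrast"] + p[m, n] * (m - n)^2
    out["dissimilarity"] <- out["dissimilarity"] + p[m, n] * abs(m - n)
    out["asm"] <- out["asm"] + p[m, n]^2
    out["homogeneity"] <- out["homogeneity"] + p[m, n] / (1 + (m - n)^2)
    mu_m <- mu_m + m * p[m, n]; mu_n <- mu_n + n * p[m, n]
  }
  v_m <- 0; v_n <- 0; cov <- 0
  for (m in 1:g) for (n in 1:g) {
    v_m <- v_m + (m - mu_m)^2 * p[m, n]
    v_n <- v_n + (n - mu_n)^2 * p[m, n]
    cov <- cov + (m - mu_m) * (n - mu_n) * p[m, n]
  }
  corr <- if (v_m <= 1e-12 || v_n <= 1e-12) 1 else cov / sqrt(v_m * v_n)
  c(out, energy = sqrt(out[["asm"]]), correlation = corr)
}

# per-pixel LBP code oracle (full-window pixels only)
oracle_lbp_codes <- function(g) {
  h <- nrow(g); w <- ncol(g)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  codes <- matrix(NA_integer_, h, w)
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    code <- 0L
    for (k in 1:8) {
      nb <- g[i + offs[[k]][1], j + offs[[k]][2]]
      if (nb - g[i, j] >= 0) code <- code + 2L^(8L - k)
    }
    codes[i, j] <- code
  }
  codes
}

# quick miniature pipeline config for smoke/determinism tests
mini_config <- function(seed = 1L) {
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  cfg$synthetic$n <- 12L
  cfg$synthetic$size <- 32L
  cfg$segmentation$stages <- 3L
  cfg$segmentation$base_channels <- 4L
  cfg$segmentation$head_channels <- 8L
  cfg$segmentation$train$epochs <- 2L
  cfg$foa$population <- 6L
  cfg$foa$iterations <- 3L
  cfg$classifier$conv_filters <- c(8L, 8L)
  cfg$classifier$gru_hidden <- 8L
  cfg$classifier$train$epochs <- 3L
  cfg$classifier$train$learning_rate <- 1e-3
  cfg
}
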