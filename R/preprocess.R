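#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with clipping. The image is divided into
#' tiles of `tile_size x tile_size` pixels; each tile's histogram (over
#' `levels` gray levels) is clipped at the limit
#' \deqn{\beta = \frac{R}{g}\left(1 + \frac{\phi}{100}(s_{max}-1)\right)}
#' where `R` is the tile pixel count, `g = levels`, `s_max = g - 1` and
#' `phi = clip_factor` in `[0, 100]`. Clipped excess is redistributed
#' uniformly (iterated until the residual excess is below one count), the
#' per-tile cumulative mappings are computed, and each pixel is remapped by
#' bilinear interpolation between the four nearest tile mappings. With
#' `clip_factor = 0` the clipped histogram is fully flattened, so the mapping
#' collapses to the identity ramp; with `clip_factor = 100` no clipping
#' occurs and a single tile reduces to global histogram equalization.
#'
#' @param image a [gray_image()] or [rgb_image()]. Color images are enhanced
#'   on the HSV value channel only, leaving hue and saturation untouched.
#' @param tile_size pixels per tile side (>= 2); must not exceed the image.
#' @param clip_factor clip factor `phi` in `[0, 100]`.
#' @param levels number of gray levels `g` (default 256).
#' @return Same type as `image`, values in `[0, 1]`.
#' @export
clahe <- function(image, tile_size = 8L, clip_factor = 2, levels = 256L) {
  stopifnot(tile_size >= 2, clip_factor >= 0, clip_factor <= 100, levels >= 2)
  if (inherits(image, "rgb_image")) {
    hsv <- rgb_to_hsv_array(image)
    hsv[, , 3] <- strip_raster(clahe(gray_image(hsv[, , 3]), tile_size,
                                     clip_factor, levels))
    return(rgb_image(pmin(pmax(hsv_to_rgb_array(hsv), 0), 1)))
  }
  x <- strip_raster(image)
  h <- nrow(x); w <- ncol(x)
  if (tile_size > h || tile_size > w)
    stop("clahe: tile larger than image")
  g <- as.integer(levels)
  lev <- matrix(pmin(pmax(as.integer(round(x * (g - 1))), 0L), g - 1L), h, w)

  row_start <- seq(1L, h, by = tile_size)
  col_start <- seq(1L, w, by = tile_size)
  ntr <- length(row_start); ntc <- length(col_start)
  row_end <- c(row_start[-1] - 1L, h)
  col_end <- c(col_start[-1] - 1L, w)

  maps <- array(0, c(g, ntr, ntc))
  for (ti in seq_len(ntr)) {
    for (tj in seq_len(ntc)) {
      tl <- lev[row_start[ti]:row_end[ti], col_start[tj]:col_end[tj]]
      hist <- tabulate(as.vector(tl) + 1L, nbins = g)
      n <- length(tl)
      beta <- (n / g) * (1 + clip_factor / 100 * (g - 2))
      hist <- clip_redistribute(hist, beta)
      cdf <- cumsum(hist)
      nz <- cdf[cdf > 1e-12]
      cdfmin <- if (length(nz)) nz[1] else 0
      maps[, ti, tj] <- if (n - cdfmin < 1e-9) {
        (seq_len(g) - 1) / (g - 1)                 # degenerate: identity ramp
      } else {
        pmin(pmax((cdf - cdfmin) / (n - cdfmin), 0), 1)
      }
    }
  }

  centers_r <- (row_start + row_end) / 2
  centers_c <- (col_start + col_end) / 2
  out <- interp_tile_maps(lev, maps, centers_r, centers_c)
  gray_image(matrix(pmin(pmax(out, 0), 1), h, w))
}

# Uniform redistribution of clipped histogram excess, iterated until the
# residual excess is negligible (so a clip factor of 0 flattens exactly).
clip_redistribute <- function(hist, beta) {
  g <- length(hist)
  excess <- sum(pmax(hist - beta, 0))
  hist <- pmin(hist, beta)
  for (iter in 1:1000) {
    if (excess < 1e-6) break
    hist <- hist + excess / g
    over <- pmax(hist - beta, 0)
    hist <- pmin(hist, beta)
    excess <- sum(over)
  }
  hist
}

# Bilinear interpolation of per-tile mappings at each pixel.
interp_tile_maps <- function(lev, maps, centers_r, centers_c) {
  h <- nrow(lev); w <- ncol(lev)
  g <- dim(maps)[1]; ntr <- dim(maps)[2]; ntc <- dim(maps)[3]
  pos_idx <- function(coord, centers) {
    n <- length(centers)
    i0 <- findInterval(coord, centers)          # 0..n
    i0 <- pmin(pmax(i0, 1L), max(n - 1L, 1L))
    i1 <- pmin(i0 + 1L, n)
    denom <- centers[i1] - centers[i0]
    t <- ifelse(denom > 0, (coord - centers[i0]) / denom, 0)
    t <- pmin(pmax(t, 0), 1)
    list(i0 = i0, i1 = i1, t = t)
  }
  pr <- pos_idx(seq_len(h), centers_r)
  pc <- pos_idx(seq_len(w), centers_c)
  R0 <- matrix(pr$i0, h, w); R1 <- matrix(pr$i1, h, w)
  TR <- matrix(pr$t, h, w)
  C0 <- matrix(pc$i0, h, w, byrow = TRUE); C1 <- matrix(pc$i1, h, w, byrow = TRUE)
  TC <- matrix(pc$t, h, w, byrow = TRUE)
  look <- function(ri, ci) maps[(lev + 1L) + (ri - 1L) * g + (ci - 1L) * g * ntr]
  (1 - TR) * (1 - TC) * look(R0, C0) + (1 - TR) * TC * look(R0, C1) +
    TR * (1 - TC) * look(R1, C0) + TR * TC * look(R1, C1)
}

#' Adaptive local Wiener (Lee) filter
#'
#' For each pixel, the local mean \eqn{\mu} and variance \eqn{\sigma^2} are
#' computed over a `window x window` neighborhood (reflective padding at the
#' borders) and the output is
#' \deqn{Q = \mu + \frac{\max(0, \sigma^2 - \nu^2)}{\sigma^2}(P - \mu)}
#' where \eqn{\nu^2} is the noise variance, estimated as the mean of the
#' local variances when not supplied. Pixels with \eqn{\sigma^2 = 0} return
#' the local mean (gain 0). The gain lies in `[0, 1]` pointwise, so output
#' values stay within the input range.
#'
#' @param image a [gray_image()].
#' @param window odd window side (>= 3).
#' @param noise_variance optional nonnegative noise variance \eqn{\nu^2};
#'   estimated from the image when `NULL`.
#' @return A [gray_image()].
#' @export
wiener <- function(image, window = 3L, noise_variance = NULL) {
  if (window %% 2 == 0 || window < 3) stop("wiener: window must be odd and >= 3")
  if (!is.null(noise_variance) && noise_variance < 0)
    stop("wiener: noise_variance must be >= 0")
  p <- strip_raster(to_gray_matrix(image))
  mu <- box_mean(p, window)
  sigma2 <- pmax(box_mean(p * p, window) - mu * mu, 0)
  nu2 <- if (is.null(noise_variance)) mean(sigma2) else noise_variance
  gain <- ifelse(sigma2 > 0, pmax(sigma2 - nu2, 0) / sigma2, 0)
  q <- mu + gain * (p - mu)
  gray_image(pmin(pmax(q, 0), 1))
}

to_gray_matrix <- function(image) {
  if (inherits(image, "gray_image")) image else to_gray(image)
}

# Box-window local mean with reflective padding, via integral images.
box_mean <- function(m, window) {
  r <- (window - 1L) %/% 2L
  pm <- pad_reflect(m, r)
  s <- rbind(0, apply(pm, 2, cumsum))
  s <- cbind(0, t(apply(s, 1, cumsum)))
  h <- nrow(m); w <- ncol(m)
  i1 <- seq_len(h); i2 <- i1 + window - 1L
  j1 <- seq_len(w); j2 <- j1 + window - 1L
  (s[i2 + 1L, j2 + 1L, drop = FALSE] - s[i1, j2 + 1L, drop = FALSE] -
     s[i2 + 1L, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / (window^2)
}

pad_reflect <- function(m, r) {
  if (r == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  ri <- c(pmin(r:1 + 1L, h), seq_len(h), pmax(h - (1:r), 1L))
  ci <- c(pmin(r:1 + 1L, w), seq_len(w), pmax(w - (1:r), 1L))
  m[ri, ci, drop = FALSE]
}

#' Resize an image
#'
#' Bilinear interpolation (pixel-center convention) by default; nearest
#' neighbor behind a flag. Resizing to the input size is pixel-identical.
#'
#' @param image a [gray_image()] or [rgb_image()].
#' @param target integer `(height, width)`; the pipeline default is
#'   `c(224, 224)`.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return Same type as `image` with dimensions `target`.
#' @export
resize <- function(image, target = c(224L, 224L), method = "bilinear") {
  if (any(target < 1)) stop("resize: target must be positive")
  ho <- as.integer(target[1]); wo <- as.integer(target[2])
  if (inherits(image, "rgb_image")) {
    x <- strip_raster(image)
    out <- array(0, c(ho, wo, 3L))
    for (c in 1:3) out[, , c] <- resize_plane(x[, , c], ho, wo, method)
    return(rgb_image(pmin(pmax(out, 0), 1)))
  }
  gray_image(pmin(pmax(resize_plane(strip_raster(image), ho, wo, method), 0), 1))
}

resize_plane <- function(m, ho, wo, method = "bilinear") {
  Wr <- resize_weights(nrow(m), ho, method)
  Wc <- resize_weights(ncol(m), wo, method)
  Wr %*% m %*% t(Wc)
}

# n_out x n_in interpolation weight matrix (pixel-center convention).
resize_weights <- function(n_in, n_out, method) {
  s <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5   # 0-based src coords
  s <- pmin(pmax(s, 0), n_in - 1)
  W <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    W[cbind(seq_len(n_out), pmin(floor(s + 0.5), n_in - 1) + 1)] <- 1
  } else {
    i0 <- floor(s); f <- s - i0
    i1 <- pmin(i0 + 1, n_in - 1)
    W[cbind(seq_len(n_out), i0 + 1)] <- W[cbind(seq_len(n_out), i0 + 1)] + 1 - f
    W[cbind(seq_len(n_out), i1 + 1)] <- W[cbind(seq_len(n_out), i1 + 1)] + f
  }
  W
}

#' Full preprocessing stage
#'
#' Fixed order: CLAHE (luminance/value channel) -> Wiener (per RGB channel)
#' -> resize. Each stage can be disabled in the config; with all three
#' disabled the input is returned unchanged.
#'
#' @param image an [rgb_image()].
#' @param config a `pipeline_config` (or its `preprocess` sub-list).
#' @return An [rgb_image()], `224 x 224` under the defaults.
#' @export
preprocess <- function(image, config = default_config()) {
  pc <- if (!is.null(config$preprocess)) config$preprocess else config
  out <- image
  if (isTRUE(pc$clahe$enabled))
    out <- clahe(out, pc$clahe$tile_size, pc$clahe$clip_factor, pc$clahe$levels)
  if (isTRUE(pc$wiener$enabled)) {
    x <- strip_raster(out)
    for (c in 1:3)
      x[, , c] <- strip_raster(wiener(gray_image(x[, , c]), pc$wiener$window,
                                      pc$wiener$noise_variance))
    out <- rgb_image(x)
  }
  if (isTRUE(pc$resize$enabled))
    out <- resize(out, c(pc$resize$height, pc$resize$width))
  out
}
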