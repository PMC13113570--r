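#' Color features over a lesion mask
#'
#' Mean and (population) standard deviation of the R, G, B and H, S, V
#' components over masked pixels: 12 values. Hue is treated circularly: its
#' mean is the direction of the resultant vector on the unit circle (mapped
#' back to `[0, 1)`) and its spread is the circular standard deviation
#' \eqn{\sqrt{-2\log \bar R}/(2\pi)} in hue units.
#'
#' @param image an [rgb_image()].
#' @param mask a [lesion_mask()] of the same height/width.
#' @return Named numeric vector of length 12.
#' @export
color_features <- function(image, mask) {
  check_aligned(image, mask)
  sel <- strip_raster(mask) == 1
  if (!any(sel)) stop("color_features: empty mask")
  hsv <- rgb_to_hsv_array(image)
  chans <- list(r = image[, , 1][sel], g = image[, , 2][sel],
                b = image[, , 3][sel], s = hsv[, , 2][sel],
                v = hsv[, , 3][sel])
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  hue <- hsv[, , 1][sel] * 2 * pi
  cmean <- atan2(mean(sin(hue)), mean(cos(hue))) / (2 * pi)
  cmean <- cmean %% 1
  rbar <- min(sqrt(mean(sin(hue))^2 + mean(cos(hue))^2), 1)
  csd <- if (rbar <= 0) 0.5 else sqrt(max(-2 * log(rbar), 0)) / (2 * pi)
  out <- c(r_mean = mean(chans$r), r_sd = pop_sd(chans$r),
           g_mean = mean(chans$g), g_sd = pop_sd(chans$g),
           b_mean = mean(chans$b), b_sd = pop_sd(chans$b),
           h_mean = cmean, h_sd = csd,
           s_mean = mean(chans$s), s_sd = pop_sd(chans$s),
           v_mean = mean(chans$v), v_sd = pop_sd(chans$v))
  names(out) <- paste0("color_", names(out))
  out
}

check_aligned <- function(image, mask) {
  di <- dim(image)[1:2]; dm <- dim(mask)[1:2]
  if (!all(di == dm)) stop("image and mask shapes differ")
  invisible(TRUE)
}

# angle -> (row, col) offset at distance d; 0 deg points along columns,
# angles measured counter-clockwise as is conventional for GLCM.
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("glcm: angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrices over a mask
#'
#' The masked intensity range is quantized uniformly into `levels` bins and,
#' for each `(distance, angle)` offset, pairs of levels are counted over
#' pixel pairs that both lie inside the mask. Matrices are symmetrized (both
#' pair directions counted) and normalized to sum 1 when the corresponding
#' flags are set.
#'
#' @param image a [gray_image()] (an [rgb_image()] is converted to
#'   luminance).
#' @param mask a [lesion_mask()]; `NULL` means the whole image.
#' @param levels gray quantization count (default 8).
#' @param distances integer pixel offsets (default 1).
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @param symmetric,normalized symmetrization / normalization flags.
#' @return A list of `levels x levels` matrices, one per
#'   `(distance, angle)`, named `"d<d>_a<angle>"`.
#' @export
glcm <- function(image, mask = NULL, levels = 8L, distances = 1L,
                 angles = c(0L, 45L, 90L, 135L), symmetric = TRUE,
                 normalized = TRUE) {
  g <- strip_raster(to_gray_matrix(image))
  if (is.null(mask)) mask <- lesion_mask(matrix(1, nrow(g), ncol(g)))
  check_aligned(g, mask)
  sel <- strip_raster(mask) == 1
  if (sum(sel) < 2) stop("glcm: need at least 2 masked pixels")
  q <- quantize_gray(g, sel, levels)
  h <- nrow(g); w <- ncol(g)
  out <- list()
  for (d in distances) {
    for (a in angles) {
      off <- glcm_offset(a, d)
      r1 <- max(1L, 1L - off[1]):min(h, h - off[1])
      c1 <- max(1L, 1L - off[2]):min(w, w - off[2])
      r2 <- r1 + off[1]; c2 <- c1 + off[2]
      ok <- sel[r1, c1, drop = FALSE] & sel[r2, c2, drop = FALSE]
      li <- q[r1, c1, drop = FALSE][ok]
      lj <- q[r2, c2, drop = FALSE][ok]
      m <- matrix(0, levels, levels)
      if (length(li)) {
        tab <- table(factor(li, levels = 1:levels),
                     factor(lj, levels = 1:levels))
        m <- matrix(as.numeric(tab), levels, levels)
      }
      if (symmetric) m <- m + t(m)
      if (normalized && sum(m) > 0) m <- m / sum(m)
      out[[paste0("d", d, "_a", a)]] <- m
    }
  }
  out
}

# Uniform binning of the masked intensity range into `levels` levels (1-based).
quantize_gray <- function(g, sel, levels) {
  lo <- min(g[sel]); hi <- max(g[sel])
  q <- matrix(1L, nrow(g), ncol(g))
  if (hi > lo) {
    q <- pmin(floor((g - lo) / (hi - lo) * levels) + 1L, levels)
    q[g <= lo] <- 1L
  }
  q
}

#' Haralick descriptors of a normalized co-occurrence matrix
#'
#' Six scalars from a normalized GLCM `p(m, n)`:
#' contrast \eqn{\sum p(m,n)(m-n)^2}, dissimilarity \eqn{\sum p(m,n)|m-n|},
#' angular second moment \eqn{\sum p^2}, homogeneity
#' \eqn{\sum p/(1+(m-n)^2)}, energy \eqn{\sqrt{ASM}}, and correlation
#' \eqn{\sum (m-\mu_m)(n-\mu_n)p/(\sigma_m\sigma_n)} (defined as 1 when
#' either marginal is degenerate).
#'
#' @param p a normalized `levels x levels` co-occurrence matrix (sum 1).
#' @return Named numeric vector of length 6: `contrast`, `dissimilarity`,
#'   `asm`, `homogeneity`, `energy`, `correlation`.
#' @export
haralick_features <- function(p) {
  if (abs(sum(p) - 1) > 1e-6) stop("haralick_features: matrix must sum to 1")
  g <- nrow(p)
  m <- matrix(1:g, g, g); n <- t(m)
  mu_m <- sum(m * p); mu_n <- sum(n * p)
  var_m <- sum((m - mu_m)^2 * p); var_n <- sum((n - mu_n)^2 * p)
  asm <- sum(p^2)
  corr <- if (var_m <= 1e-12 || var_n <= 1e-12) 1 else
    sum((m - mu_m) * (n - mu_n) * p) / sqrt(var_m * var_n)
  c(contrast = sum(p * (m - n)^2),
    dissimilarity = sum(p * abs(m - n)),
    asm = asm,
    homogeneity = sum(p / (1 + (m - n)^2)),
    energy = sqrt(asm),
    correlation = corr)
}

#' Local binary pattern histogram
#'
#' For each masked pixel whose full 3x3 window lies inside the mask, an
#' 8-bit code is formed from the signs of (neighbor - center): a difference
#' `>= 0` contributes bit 1. Bits are taken clockwise starting at the
#' top-left neighbor, top-left being the most significant bit. The 256-bin
#' histogram over codes is normalized to sum 1. A constant region therefore
#' lands entirely in bin 255 (ties count as 1).
#'
#' @param image a [gray_image()] (an [rgb_image()] is converted).
#' @param mask a [lesion_mask()]; `NULL` means the whole image.
#' @param block_size optional block side `N`: the image is cut into
#'   `N x N` pixel blocks and per-block normalized histograms are averaged.
#'   Default is a single whole-region histogram.
#' @return Numeric vector of length 256 summing to 1, names `lbp_0` ...
#'   `lbp_255`.
#' @export
lbp_histogram <- function(image, mask = NULL, block_size = NULL) {
  g <- strip_raster(to_gray_matrix(image))
  if (is.null(mask)) mask <- lesion_mask(matrix(1, nrow(g), ncol(g)))
  check_aligned(g, mask)
  codes <- lbp_codes(g, strip_raster(mask) == 1)
  valid <- !is.na(codes)
  if (!any(valid)) stop("lbp_histogram: no masked pixel has a full 3x3 window")
  hist <- if (is.null(block_size)) {
    tabulate(codes[valid] + 1L, nbins = 256L) / sum(valid)
  } else {
    lbp_block_histogram(codes, block_size)
  }
  names(hist) <- paste0("lbp_", 0:255)
  hist
}

# 8-bit LBP code per pixel; NA where the 3x3 window leaves the mask/image.
# Clockwise from top-left; top-left is the most significant bit.
lbp_codes <- function(g, sel) {
  h <- nrow(g); w <- ncol(g)
  codes <- matrix(NA_integer_, h, w)
  if (h < 3 || w < 3) return(codes)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  ctr <- g[ri, ci, drop = FALSE]
  acc <- matrix(0L, length(ri), length(ci))
  ok <- sel[ri, ci, drop = FALSE]
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    nb <- g[ri + o[1], ci + o[2], drop = FALSE]
    ok <- ok & sel[ri + o[1], ci + o[2], drop = FALSE]
    acc <- acc + bitwShiftL(as.integer(nb - ctr >= 0), 8L - k)
  }
  acc[!ok] <- NA_integer_
  codes[ri, ci] <- acc
  codes
}

lbp_block_histogram <- function(codes, block_size) {
  h <- nrow(codes); w <- ncol(codes)
  rs <- seq(1L, h, by = block_size); cs <- seq(1L, w, by = block_size)
  acc <- numeric(256); nb <- 0L
  for (r in rs) for (cc in cs) {
    blk <- codes[r:min(r + block_size - 1L, h), cc:min(cc + block_size - 1L, w)]
    v <- blk[!is.na(blk)]
    if (length(v)) {
      acc <- acc + tabulate(v + 1L, nbins = 256L) / length(v)
      nb <- nb + 1L
    }
  }
  if (nb == 0L) stop("lbp_histogram: no block contains valid codes")
  acc / nb
}

#' Shape descriptors of a binary mask
#'
#' Computed on the largest 8-connected foreground component. With area
#' \eqn{\Lambda} (pixel count) and perimeter \eqn{\rho} (contour-following
#' arc length, diagonal steps weighted \eqn{\sqrt 2}):
#' dispersity \eqn{= \rho^2/\Lambda}, saturation \eqn{= \Lambda/\rho},
#' roundness \eqn{= 4\pi\Lambda/\rho^2}. For a disk these converge to
#' \eqn{4\pi^2 \approx 39.48}, \eqn{r/2} and 1 as the radius grows.
#'
#' @param mask a [lesion_mask()] with at least one foreground pixel.
#' @return Named numeric vector `c(area, perimeter, dispersity, saturation,
#'   roundness)`.
#' @export
shape_features <- function(mask) {
  m <- strip_raster(mask)
  if (!any(m == 1)) stop("shape_features: empty mask")
  comp <- largest_component(m)
  area <- sum(comp)
  per <- contour_perimeter(comp)
  c(area = area, perimeter = per,
    dispersity = per^2 / area,
    saturation = area / per,
    roundness = 4 * pi * area / per^2)
}

# Largest 8-connected component via BFS flood fill.
largest_component <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  cur <- 0L
  best <- NULL; best_n <- 0L
  idx_all <- which(m == 1 & lab == 0L)
  while (length(idx_all)) {
    cur <- cur + 1L
    queue <- idx_all[1]
    lab[queue] <- cur
    members <- queue
    while (length(queue)) {
      r <- ((queue - 1L) %% h) + 1L
      cc <- ((queue - 1L) %/% h) + 1L
      rr <- rep(r, times = 8) + rep(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                                    each = length(r))
      ccx <- rep(cc, times = 8) + rep(c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
                                      each = length(cc))
      keep <- rr >= 1L & rr <= h & ccx >= 1L & ccx <= w
      ni <- unique((ccx[keep] - 1L) * h + rr[keep])
      ni <- ni[m[ni] == 1 & lab[ni] == 0L]
      lab[ni] <- cur
      members <- c(members, ni)
      queue <- ni
    }
    if (length(members) > best_n) {
      best_n <- length(members)
      best <- members
    }
    idx_all <- which(m == 1 & lab == 0L)
  }
  out <- matrix(0, h, w)
  out[best] <- 1
  out
}

# Moore-neighbor contour tracing. Raw chain-code length (1 / sqrt(2) steps)
# overestimates smooth boundaries by ~5%, which would break the analytic
# circle checks; the Vossepoel-Smeulders corrected estimator
# 0.980*N_even + 1.406*N_odd - 0.091*N_corner is used instead.
contour_perimeter <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (sum(m) == 1) return(1)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  # start: first foreground pixel in column-major scan
  start <- which(pad == 1)[1]
  sr <- ((start - 1) %% (h + 2)) + 1
  sc <- ((start - 1) %/% (h + 2)) + 1
  # Moore neighborhood, clockwise starting from W
  dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  n_even <- 0L; n_odd <- 0L; n_corner <- 0L
  prev_k <- NA_integer_
  cr <- sr; cc <- sc
  backtrack <- 1  # came from the west
  steps <- 0L
  repeat {
    found <- FALSE
    k <- backtrack
    for (step in 1:8) {
      k <- (k %% 8) + 1
      nr <- cr + dirs[k, 1]; nc <- cc + dirs[k, 2]
      if (pad[nr, nc] == 1) {
        if (sum(abs(dirs[k, ])) == 1L) n_even <- n_even + 1L else
          n_odd <- n_odd + 1L
        if (!is.na(prev_k) && prev_k != k) n_corner <- n_corner + 1L
        prev_k <- k
        backtrack <- ((k + 3) %% 8) + 1   # points back to previous pixel
        cr <- nr; cc <- nc
        found <- TRUE
        break
      }
    }
    if (!found) return(1)  # isolated pixel (no neighbors)
    steps <- steps + 1L
    if (cr == sr && cc == sc) break
    if (steps > 8L * (h + w)) break  # safety
  }
  max(0.980 * n_even + 1.406 * n_odd - 0.091 * n_corner, 1)
}

#' Extract the full feature vector for one lesion
#'
#' Concatenates, in a fixed order with stable names: 12 color features,
#' GLCM Haralick descriptors (by default averaged over the four angles,
#' giving 6 values per distance; per-angle behind
#' `features$glcm$average_angles = FALSE`), the 256-bin LBP histogram, and 3
#' shape descriptors. Under the defaults the vector has
#' `12 + 6 + 256 + 3 = 277` entries.
#'
#' @param image an [rgb_image()].
#' @param mask a [lesion_mask()] aligned with `image`.
#' @param config a `pipeline_config` (its `features` block is used).
#' @return Named numeric vector.
#' @export
extract_features <- function(image, mask, config = default_config()) {
  fc <- if (!is.null(config$features)) config$features else config
  col <- color_features(image, mask)
  gl <- glcm(to_gray(image), mask, levels = fc$glcm$levels,
             distances = fc$glcm$distances, angles = fc$glcm$angles,
             symmetric = fc$glcm$symmetric, normalized = fc$glcm$normalized)
  har <- vapply(gl, haralick_features, numeric(6))
  tex <- c()
  if (isTRUE(fc$glcm$average_angles)) {
    for (d in fc$glcm$distances) {
      cols <- grep(paste0("^d", d, "_"), colnames(har))
      avg <- rowMeans(har[, cols, drop = FALSE])
      names(avg) <- paste0("glcm_d", d, "_", rownames(har))
      tex <- c(tex, avg)
    }
  } else {
    for (j in seq_len(ncol(har))) {
      v <- har[, j]
      names(v) <- paste0("glcm_", colnames(har)[j], "_", rownames(har))
      tex <- c(tex, v)
    }
  }
  lbp <- lbp_histogram(to_gray(image), mask, block_size = fc$lbp$block_size)
  shp <- shape_features(mask)[c("dispersity", "saturation", "roundness")]
  names(shp) <- paste0("shape_", names(shp))
  out <- c(col, tex, lbp, shp)
  if (anyDuplicated(names(out))) stop("extract_features: duplicate names")
  out
}
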