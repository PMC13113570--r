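#' Synthetic lesion image parameters
#'
#' Describes the stated world the image generator emulates: a skin-toned
#' background with an illumination gradient and sensor noise, plus one
#' elliptical lesion per image whose boundary is perturbed by low-order
#' Fourier harmonics of the polar radius. Classes differ in lesion color
#' (hue/darkness), texture correlation length (Gaussian smoothing sigma of
#' the value-channel noise field), boundary irregularity amplitude, and mean
#' radius. Optional dark hair-like arcs exercise preprocessing robustness
#' (off by default).
#'
#' @param size image side in pixels (default 96).
#' @param classes list of per-class parameter lists with elements `hue`,
#'   `saturation`, `darkness`, `texture_sigma`, `texture_amp`,
#'   `irregularity`, `radius` (fraction of `size`).
#' @param background RGB skin tone.
#' @param illumination amplitude of the linear illumination gradient.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param hair_prob probability of adding a hair artifact.
#' @return A `synth_image_params` list.
#' @export
synth_image_params <- function(size = 96L,
                               classes = default_lesion_classes(),
                               background = c(0.91, 0.75, 0.65),
                               illumination = 0.08,
                               noise_sd = 0.02,
                               hair_prob = 0) {
  stopifnot(size >= 16, length(background) == 3, illumination >= 0,
            noise_sd >= 0, hair_prob >= 0, hair_prob <= 1)
  for (cl in classes)
    stopifnot(cl$radius > 0, cl$radius < 0.45, cl$irregularity >= 0)
  structure(list(size = as.integer(size), classes = classes,
                 background = background, illumination = illumination,
                 noise_sd = noise_sd, hair_prob = hair_prob),
            class = "synth_image_params")
}

#' @rdname synth_image_params
#' @export
default_lesion_classes <- function() {
  list(
    list(hue = 0.07, saturation = 0.55, darkness = 0.55, texture_sigma = 3,
         texture_amp = 0.05, irregularity = 0.04, radius = 0.28),
    list(hue = 0.02, saturation = 0.65, darkness = 0.38, texture_sigma = 1,
         texture_amp = 0.09, irregularity = 0.14, radius = 0.32),
    list(hue = 0.58, saturation = 0.40, darkness = 0.50, texture_sigma = 2,
         texture_amp = 0.07, irregularity = 0.28, radius = 0.23)
  )
}

#' Generate one synthetic lesion image
#'
#' The lesion is an ellipse (random orientation and eccentricity) whose
#' normalized polar radius is modulated by Fourier harmonics `k = 2..4` with
#' total amplitude set by the class `irregularity`; amplitude 0 yields an
#' exact rasterized ellipse. Fill color comes from the class hue/saturation/
#' darkness with a spatially correlated texture field added to the value
#' channel. The exact mask used for rasterization is returned, so ground
#' truth is perfect by construction.
#'
#' @param class_id 1-based class index into `params$classes`.
#' @param params a [synth_image_params()].
#' @param seed integer seed; the generator is a pure function of
#'   `(params, class_id, seed)`.
#' @return A list with elements `image` ([rgb_image()]), `mask`
#'   ([lesion_mask()]), and `label` (the class id).
#' @export
make_lesion_image <- function(class_id, params = synth_image_params(),
                              seed = 1L) {
  if (class_id < 1 || class_id > length(params$classes))
    stop("make_lesion_image: undefined class_id ", class_id)
  cl <- params$classes[[class_id]]
  n <- params$size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  cx <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  cy <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  ecc <- stats::runif(1, 0, 0.35)
  a <- cl$radius * n * (1 + ecc / 2)
  b <- cl$radius * n * (1 - ecc / 2)
  alpha <- stats::runif(1, 0, pi)
  amp <- if (cl$irregularity > 0)
    cl$irregularity * stats::runif(3, 0.3, 1) / (1:3) else c(0, 0, 0)
  phs <- stats::runif(3, 0, 2 * pi)

  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), n), n, n)          # row index
  dx <- xs - cx; dy <- ys - cy
  u <- (dx * cos(alpha) + dy * sin(alpha)) / a
  v <- (-dx * sin(alpha) + dy * cos(alpha)) / b
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rlim <- 1
  for (k in 1:3) rlim <- rlim + amp[k] * cos((k + 1) * theta + phs[k])
  mask <- (rho <= rlim) * 1

  # background with illumination gradient
  ang <- stats::runif(1, 0, 2 * pi)
  ramp <- ((xs / n - 0.5) * cos(ang) + (ys / n - 0.5) * sin(ang))
  img <- array(0, c(n, n, 3))
  for (c in 1:3)
    img[, , c] <- params$background[c] * (1 + params$illumination * ramp)

  # lesion fill: class color + correlated texture on the value channel
  tex <- gauss_blur(matrix(stats::rnorm(n * n), n, n), cl$texture_sigma)
  tex <- tex / max(stats::sd(tex), 1e-8) * cl$texture_amp
  val <- pmin(pmax(cl$darkness + tex, 0), 1)
  hsv <- array(0, c(n, n, 3))
  hsv[, , 1] <- cl$hue; hsv[, , 2] <- cl$saturation; hsv[, , 3] <- val
  les <- hsv_to_rgb_array(hsv)
  for (c in 1:3) img[, , c] <- ifelse(mask == 1, les[, , c], img[, , c])

  if (params$hair_prob > 0 && stats::runif(1) < params$hair_prob)
    img <- draw_hair(img)

  if (params$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim(img))
  list(image = rgb_image(pmin(pmax(img, 0), 1)),
       mask = lesion_mask(mask), label = class_id)
}

# Separable Gaussian blur with reflective padding; sigma <= 0 is identity.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pm <- pad_reflect(m, r)
  # rows
  out <- matrix(0, nrow(m), ncol(pm))
  for (i in seq_along(k))
    out <- out + k[i] * pm[i:(i + nrow(m) - 1L), , drop = FALSE]
  res <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k))
    res <- res + k[i] * out[, i:(i + ncol(m) - 1L), drop = FALSE]
  res
}

# A dark quadratic arc of ~1 px thickness, crossing the frame.
draw_hair <- function(img) {
  n <- dim(img)[1]
  p0 <- stats::runif(2, 0, n); p1 <- stats::runif(2, 0, n)
  pc <- stats::runif(2, 0, n)
  t <- seq(0, 1, length.out = 4L * n)
  bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * pc[1] + t^2 * p1[1]
  by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * pc[2] + t^2 * p1[2]
  ri <- round(by); ci <- round(bx)
  keep <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
  idx <- cbind(ri[keep], ci[keep])
  for (c in 1:3) {
    ch <- img[, , c]
    ch[idx] <- ch[idx] * 0.25
    img[, , c] <- ch
  }
  img
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic lesion image dataset
#'
#' Labels are drawn from the class priors; each item gets a seed derived
#' deterministically from the master seed, so the whole dataset is a pure
#' function of `(n, params, priors, seed)`.
#'
#' @param n number of images.
#' @param params a [synth_image_params()].
#' @param priors class prior probabilities (default uniform).
#' @param seed master seed.
#' @return A list of `n` items, each as returned by [make_lesion_image()].
#' @export
make_image_dataset <- function(n, params = synth_image_params(),
                               priors = NULL, seed = 1L) {
  stopifnot(n >= 1)
  k <- length(params$classes)
  if (is.null(priors)) priors <- rep(1 / k, k)
  if (length(priors) != k || any(priors < 0) || abs(sum(priors) - 1) > 1e-9)
    stop("make_image_dataset: invalid priors")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  labels <- sample.int(k, n, replace = TRUE, prob = priors)
  lapply(seq_len(n), function(i)
    make_lesion_image(labels[i], params,
                      seed = derive_seed(seed, paste0("img", i))))
}

#' Synthetic feature table with known informative structure
#'
#' Generates an `n x p` table: `k` informative columns are class-conditional
#' Gaussians (unit variance) whose class means are `separation` standard
#' deviations apart; `r` redundant columns are noisy linear copies of
#' randomly chosen informative parents (`parent + N(0, redundancy_sd)`);
#' the remaining columns are pure standard Gaussian noise. The informative
#' index set is returned so recovery experiments can score selections
#' against ground truth.
#'
#' @param n samples.
#' @param p total features.
#' @param k informative features (`k + r <= p`).
#' @param r redundant features.
#' @param separation class-mean separation `d` in sd units.
#' @param redundancy_sd noise sd of the redundant copies.
#' @param n_classes number of classes.
#' @param priors class priors (default uniform).
#' @param seed integer seed.
#' @return A list with `table` (numeric matrix with column names),
#'   `labels` (integer vector), `informative` (column indices),
#'   `redundant` (column indices).
#' @export
make_feature_table <- function(n = 300L, p = 20L, k = 5L, r = 5L,
                               separation = 2, redundancy_sd = 0.1,
                               n_classes = 2L, priors = NULL, seed = 1L) {
  if (k + r > p) stop("make_feature_table: k + r must be <= p")
  stopifnot(separation >= 0, k >= 1, n >= n_classes)
  if (is.null(priors)) priors <- rep(1 / n_classes, n_classes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  labels <- sample.int(n_classes, n, replace = TRUE, prob = priors)
  X <- matrix(stats::rnorm(n * p), n, p)
  informative <- seq_len(k)
  for (j in informative) {
    class_means <- separation * (sample.int(n_classes) - 1)
    X[, j] <- X[, j] + class_means[labels]
  }
  redundant <- if (r > 0) k + seq_len(r) else integer(0)
  for (j in redundant) {
    parent <- sample(informative, 1)
    X[, j] <- X[, parent] + stats::rnorm(n, 0, redundancy_sd)
  }
  perm <- sample.int(p)   # shuffle so informative indices are not all first
  X <- X[, perm, drop = FALSE]
  informative <- match(informative, perm)
  redundant <- match(redundant, perm)
  colnames(X) <- paste0("f", seq_len(p))
  list(table = X, labels = labels, informative = sort(informative),
       redundant = sort(redundant))
}
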