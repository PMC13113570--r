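#' Image and mask containers
#'
#' `lesionkit` carries raster data as plain numeric arrays wrapped in light
#' S3 classes. An `rgb_image` is a `height x width x 3` array with values in
#' `[0, 1]` and fixed red/green/blue channel order; a `gray_image` is a
#' `height x width` matrix in `[0, 1]`; a `lesion_mask` is a binary
#' `height x width` matrix with values in `{0, 1}`. 8-bit conversion happens
#' only at file boundaries so no precision is lost between pipeline stages.
#'
#' @param pixels numeric array (`h x w x 3` for [rgb_image()], `h x w`
#'   matrix for [gray_image()] and [lesion_mask()]).
#' @return An object of the corresponding class.
#' @name image-types
NULL

#' @rdname image-types
#' @export
rgb_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("rgb_image: 'pixels' must be a height x width x 3 array")
  check_unit_range(pixels, "rgb_image")
  structure(pixels, class = c("rgb_image", "lesionkit_raster"))
}

#' @rdname image-types
#' @export
gray_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  check_unit_range(pixels, "gray_image")
  structure(pixels, class = c("gray_image", "lesionkit_raster"))
}

#' @rdname image-types
#' @export
lesion_mask <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels)) || !all(pixels %in% c(0, 1)))
    stop("lesion_mask: values must be exactly 0 or 1")
  storage.mode(pixels) <- "double"
  structure(pixels, class = c("lesion_mask", "lesionkit_raster"))
}

check_unit_range <- function(x, what) {
  if (!all(is.finite(x))) stop(what, ": non-finite pixel values")
  if (min(x) < 0 || max(x) > 1) stop(what, ": values must lie in [0, 1]")
  invisible(TRUE)
}

#' @export
print.lesionkit_raster <- function(x, ...) {
  d <- dim(x)
  cat("<", class(x)[1], "> ", d[1], " x ", d[2],
      if (length(d) == 3L) paste0(" x ", d[3]), "\n", sep = "")
  invisible(x)
}

strip_raster <- function(x) {
  attr(x, "class") <- NULL
  x
}

#' Read an image file
#'
#' Reads a PNG or JPEG file into an [rgb_image()]. Values are rescaled to
#' `[0, 1]`; single-channel (grayscale) files are replicated across the three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = try(png::readPNG(path), silent = TRUE),
    jpg  = ,
    jpeg = try(jpeg::readJPEG(path), silent = TRUE),
    stop("read_image: unsupported extension '", ext, "' (PNG/JPEG only)")
  )
  if (inherits(px, "try-error"))
    stop("read_image: could not decode ", path)
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]
  rgb_image(pmin(pmax(px, 0), 1))
}

#' Write an image to PNG
#'
#' @param image an [rgb_image()] or [gray_image()].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(strip_raster(image), target = path)
  invisible(path)
}

#' Write / read a binary lesion mask as PNG
#'
#' Masks are serialized as single-channel 8-bit PNG with foreground stored as
#' 255, a lossless round trip: `read_mask(write_mask(m, p))` equals `m`
#' exactly. `read_mask()` refuses files whose decoded values are not binary.
#'
#' @param mask a [lesion_mask()].
#' @param path path to a PNG file.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` a
#'   [lesion_mask()].
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "lesion_mask")) mask <- lesion_mask(mask)
  ok <- try(png::writePNG(strip_raster(mask), target = path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("write_mask: cannot write ", path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("read_mask: no such file: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  v <- round(px * 255)
  if (!all(v %in% c(0, 255)))
    stop("read_mask: file is not a binary mask (values other than 0/255)")
  lesion_mask(v / 255)
}

#' Color-space helpers
#'
#' `to_gray()` converts an RGB image to luminance (Rec. 601 weights
#' 0.299/0.587/0.114); `rgb_to_hsv_array()` and `hsv_to_rgb_array()` convert
#' between RGB and HSV rasters with all components in `[0, 1]`.
#'
#' @param image an [rgb_image()].
#' @return `to_gray()`: a [gray_image()]; the HSV helpers: a plain
#'   `h x w x 3` array.
#' @export
to_gray <- function(image) {
  if (inherits(image, "gray_image")) return(image)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  gray_image(pmin(pmax(g, 0), 1))
}

#' @rdname to_gray
#' @export
rgb_to_hsv_array <- function(image) {
  d <- dim(image)
  m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  array(c(hsv[1, ], hsv[2, ], hsv[3, ]), c(d[1], d[2], 3L))
}

#' @rdname to_gray
#' @param hsv a `h x w x 3` array of hue/saturation/value in `[0, 1]`.
#' @export
hsv_to_rgb_array <- function(hsv) {
  d <- dim(hsv)
  cols <- grDevices::hsv(pmin(pmax(as.vector(hsv[, , 1]), 0), 1),
                         pmin(pmax(as.vector(hsv[, , 2]), 0), 1),
                         pmin(pmax(as.vector(hsv[, , 3]), 0), 1))
  m <- grDevices::col2rgb(cols) / 255
  array(c(m[1, ], m[2, ], m[3, ]), c(d[1], d[2], 3L))
}
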