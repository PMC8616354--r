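#' Grayscale image container
#'
#' A 2-D scalar intensity field with physical pixel size. Rows are y, columns
#' are x; coordinates used throughout the package are 0-based pixel-centre
#' coordinates, so a pixel at matrix position `[i, j]` sits at
#' `(x, y) = (j - 1, i - 1)` pixels.
#'
#' @param pixels numeric matrix of non-negative intensities, at least 16x16.
#' @param pixel_size physical pixel size in micrometres per pixel (> 0).
#' @param channel one of `"phase_contrast"` or `"fluorescence"`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, pixel_size = 1,
                       channel = c("phase_contrast", "fluorescence")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 16 || ncol(pixels) < 16)
    stop("gray_image must be at least 16x16 pixels")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(list(pixels = pixels, pixel_size = pixel_size, channel = channel),
            class = "gray_image")
}

#' Binary platelet mask
#'
#' @param pixels logical matrix, `TRUE` = platelet foreground.
#' @param pixel_size micrometres per pixel.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size = 1) {
  if (is.numeric(pixels)) pixels <- pixels > 0.5
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix")
  if (any(is.na(pixels))) stop("mask must not contain NA")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "binary_mask")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d px, %.4g um/px, %s, range [%.3g, %.3g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d px, %.4g um/px, %d foreground px>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, sum(x$pixels)))
  invisible(x)
}

as_pixels <- function(x) {
  if (inherits(x, "gray_image") || inherits(x, "binary_mask")) x$pixels else x
}

#' Gaussian blur of an intensity matrix
#'
#' Separable Gaussian filter with mirror boundary handling.
#'
#' @param img numeric matrix or `gray_image`.
#' @param sigma standard deviation in pixels; `sigma <= 0` is a no-op.
#' @return A numeric matrix.
#' @export
gauss_blur <- function(img, sigma) {
  cpp_gauss_blur(as_pixels(img), sigma)
}

#' Otsu threshold of an intensity matrix
#'
#' @param img numeric matrix or `gray_image` with nonzero intensity range.
#' @param n_bins histogram resolution.
#' @return The scalar threshold.
#' @export
otsu_threshold <- function(img, n_bins = 256) {
  v <- as.vector(as_pixels(img))
  rng <- range(v)
  if (diff(rng) == 0)
    stop("degenerate input: constant image has no Otsu threshold")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(v, breaks, all.inside = TRUE), n_bins),
                nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  w0 <- w[-n_bins]; m0 <- m[-n_bins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1)
  between[valid] <- (mt * w0[valid] / n - m0[valid])^2 /
    (w0[valid] / n * w1[valid] / n) / n
  mids[which.max(between)]
}

# binary dilation/erosion by one 8- or 4-connected step (helper)
binary_dilate1 <- function(m, connectivity = 8) {
  off <- se_offsets(connectivity)
  cpp_grey_dilate(m * 1, off, rep(0, nrow(off))) > 0.5
}

binary_erode1 <- function(m, connectivity = 8) {
  off <- se_offsets(connectivity)
  cpp_grey_erode(m * 1, off, rep(0, nrow(off))) > 0.5
}

se_offsets <- function(connectivity) {
  if (connectivity == 8)
    rbind(c(0, 0), c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  else
    rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
}

# run RNG-consuming code under a local seed, restoring global RNG state
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
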