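#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' hemispherical ("rolling ball") structuring element of the given radius
#' and subtracts it, clipping at zero. Constant regions map to zero and the
#' result is invariant to adding a constant to the input. Out-of-image ball
#' positions are ignored, so border pixels use the partial ball.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param radius ball radius in pixels (>= 1, not larger than the image).
#' @return Same type as the input (`gray_image` in, `gray_image` out).
#' @export
rolling_ball_subtract <- function(img, radius = 50) {
  px <- as_pixels(img)
  if (radius < 1) stop("parameter error: radius must be >= 1")
  if (radius > max(dim(px)))
    stop("parameter error: ball radius larger than the image")
  se <- ball_element(radius)
  bg <- cpp_grey_dilate(cpp_grey_erode(px, se$off, se$h), se$off, se$h)
  out <- pmax(px - bg, 0)
  if (inherits(img, "gray_image"))
    gray_image(out, img$pixel_size, img$channel)
  else out
}

# hemisphere structuring element: integer offsets within the radius plus the
# ball height at each offset
ball_element <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(di = -r:r, dj = -r:r)
  d2 <- g$di^2 + g$dj^2
  keep <- d2 <= radius^2
  list(off = as.matrix(g[keep, c("di", "dj")]),
       h = sqrt(radius^2 - d2[keep]))
}

#' Threshold an image and fill holes
#'
#' Pixels strictly above the threshold become foreground; every background
#' region not 4-connected to the image border is then filled.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param threshold numeric cutoff, or `"otsu"` for Otsu's method (requires a
#'   non-constant image).
#' @return A [binary_mask()].
#' @export
threshold_and_fill <- function(img, threshold = "otsu") {
  px <- as_pixels(img)
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(px)
  if (!is.numeric(threshold) || length(threshold) != 1)
    stop("`threshold` must be a single number or \"otsu\"")
  m <- cpp_fill_holes(px > threshold)
  ps <- if (inherits(img, "gray_image")) img$pixel_size else 1
  binary_mask(m, ps)
}

#' Derive a ground-truth mask from a fluorescence image
#'
#' The three-step ground-truth recipe: rolling-ball background removal, then
#' thresholding, then hole filling. Manual error correction is supported as
#' an external override mask rather than an interactive step.
#'
#' @param fluor fluorescence [gray_image()].
#' @param radius rolling-ball radius in pixels.
#' @param threshold numeric or `"otsu"`.
#' @param override_mask optional pre-corrected [binary_mask()] returned
#'   as-is (dimension-checked) in place of the automatic result.
#' @return A [binary_mask()].
#' @export
make_ground_truth <- function(fluor, radius = 50, threshold = "otsu",
                              override_mask = NULL) {
  if (!is.null(override_mask)) {
    if (!identical(dim(as_pixels(override_mask)), dim(as_pixels(fluor))))
      stop("override mask dimensions do not match the image")
    return(override_mask)
  }
  sub <- rolling_ball_subtract(fluor, radius)
  if (diff(range(as_pixels(sub))) == 0 && identical(threshold, "otsu")) {
    # empty field: background removal flattened everything
    return(binary_mask(matrix(FALSE, nrow(as_pixels(fluor)),
                              ncol(as_pixels(fluor))),
                       if (inherits(fluor, "gray_image")) fluor$pixel_size else 1))
  }
  threshold_and_fill(sub, threshold)
}
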