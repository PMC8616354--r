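#' Min-max intensity normalization
#'
#' `I' = (I - I_min) / (I_max - I_min)`: output range is exactly `[0, 1]` and
#' pixel ordering is preserved. Affine transforms of the input normalize to
#' the same output.
#'
#' @param img a [gray_image()] or numeric matrix with `I_max > I_min`.
#' @return Same type as the input.
#' @export
normalize_minmax <- function(img) {
  px <- as_pixels(img)
  rng <- range(px)
  if (diff(rng) == 0)
    stop("degenerate input: constant image cannot be min-max normalized")
  out <- (px - rng[1]) / (rng[2] - rng[1])
  if (inherits(img, "gray_image")) gray_image(out, img$pixel_size, img$channel)
  else out
}

# index vector implementing mirror (edge-excluding) reflection padding
reflect_indices <- function(n, before, after) {
  idx <- (1 - before):(n + after)
  while (any(idx < 1 | idx > n)) {
    idx <- ifelse(idx < 1, 2 - idx, idx)
    idx <- ifelse(idx > n, 2 * n - idx, idx)
  }
  idx
}

#' Reflection-pad an image to a square target
#'
#' Centres the image on a `target x target` canvas and fills the borders with
#' mirror reflections of the edge content. [crop_back()] inverts the
#' operation bit-exactly.
#'
#' @param img a [gray_image()] or numeric/logical matrix.
#' @param target side length in pixels; must be >= both image dimensions.
#' @return Padded image, same type as the input.
#' @export
pad_reflect <- function(img, target = 2048) {
  px <- as_pixels(img)
  h <- nrow(px); w <- ncol(px)
  if (target < h || target < w)
    stop("parameter error: target smaller than the image")
  pt <- floor((target - h) / 2); pb <- target - h - pt
  pl <- floor((target - w) / 2); pr <- target - w - pl
  out <- px[reflect_indices(h, pt, pb), reflect_indices(w, pl, pr),
            drop = FALSE]
  rewrap(img, out)
}

#' Crop a padded image back to its native resolution
#'
#' @param img padded image (matrix or [gray_image()]/[binary_mask()]).
#' @param orig_dim `c(nrow, ncol)` of the original image.
#' @return The central `orig_dim` region, same type as the input.
#' @export
crop_back <- function(img, orig_dim) {
  px <- as_pixels(img)
  h <- orig_dim[1]; w <- orig_dim[2]
  if (h > nrow(px) || w > ncol(px))
    stop("parameter error: original dimensions exceed the padded image")
  pt <- floor((nrow(px) - h) / 2)
  pl <- floor((ncol(px) - w) / 2)
  out <- px[(pt + 1):(pt + h), (pl + 1):(pl + w), drop = FALSE]
  rewrap(img, out)
}

rewrap <- function(template, px) {
  if (inherits(template, "gray_image"))
    gray_image(px, template$pixel_size, template$channel)
  else if (inherits(template, "binary_mask"))
    binary_mask(px, template$pixel_size)
  else px
}

#' Jointly augment a phase-contrast/ground-truth training pair
#'
#' Draws one geometric transform (90-degree rotation multiples, horizontal
#' and vertical flips, optionally bounded rescaling) and applies it to both
#' the image and the mask; the mask stays boolean (nearest-neighbour
#' interpolation). Rescaled pairs are centre-cropped or reflection-padded
#' back to the original size so that augmented pairs keep their dimensions.
#'
#' @param pair list with `phase` (a [gray_image()] or matrix) and `truth`
#'   (a [binary_mask()] or logical matrix) of identical dimensions.
#' @param toggles named logical vector with entries `rotation`, `flipping`,
#'   `resizing`.
#' @param scale_range rescaling factor bounds when `resizing` is enabled.
#' @return The augmented pair (same structure; transform draw consumes the
#'   caller's RNG stream).
#' @export
augment_pair <- function(pair,
                         toggles = c(rotation = TRUE, flipping = TRUE,
                                     resizing = FALSE),
                         scale_range = c(0.9, 1.1)) {
  px <- as_pixels(pair$phase)
  mk <- as_pixels(pair$truth)
  if (!identical(dim(px), dim(mk)))
    stop("phase and truth dimensions differ")
  if (isTRUE(toggles[["rotation"]])) {
    k <- sample.int(4, 1) - 1
    if (k > 0) { px <- rot90(px, k); mk <- rot90(mk, k) }
  }
  if (isTRUE(toggles[["flipping"]])) {
    if (runif(1) < 0.5) { px <- px[nrow(px):1, , drop = FALSE]
                          mk <- mk[nrow(mk):1, , drop = FALSE] }
    if (runif(1) < 0.5) { px <- px[, ncol(px):1, drop = FALSE]
                          mk <- mk[, ncol(mk):1, drop = FALSE] }
  }
  if (isTRUE(toggles[["resizing"]])) {
    s <- runif(1, scale_range[1], scale_range[2])
    h0 <- nrow(px); w0 <- ncol(px)
    nh <- max(2, round(h0 * s)); nw <- max(2, round(w0 * s))
    px <- cpp_resize_bilinear(px, nh, nw)
    mk <- cpp_resize_nearest(mk, nh, nw)
    if (nh >= h0) {
      top <- floor((nh - h0) / 2); left <- floor((nw - w0) / 2)
      px <- px[(top + 1):(top + h0), (left + 1):(left + w0), drop = FALSE]
      mk <- mk[(top + 1):(top + h0), (left + 1):(left + w0), drop = FALSE]
    } else {
      px <- as_pixels(pad_reflect(px, max(h0, w0)))
      mkp <- matrix(FALSE, max(h0, w0), max(h0, w0))
      top <- floor((max(h0, w0) - nh) / 2); left <- floor((max(h0, w0) - nw) / 2)
      mkp[(top + 1):(top + nh), (left + 1):(left + nw)] <- mk
      mk <- mkp
      px <- px[1:h0, 1:w0, drop = FALSE]; mk <- mk[1:h0, 1:w0, drop = FALSE]
    }
  }
  pair$phase <- rewrap(pair$phase, px)
  pair$truth <- rewrap(pair$truth, mk)
  pair
}

# 90-degree counter-clockwise rotation, k times
rot90 <- function(m, k = 1) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}
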