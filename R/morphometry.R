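#' Label platelets in a binary mask
#'
#' Finds 8-connected foreground components, drops components smaller than
#' `min_area` or touching the image border (partial platelets bias every
#' shape parameter), and orders them row-major by centroid.
#'
#' @param mask a [binary_mask()].
#' @param min_area minimum component area in um^2.
#' @param exclude_border drop border-touching components (default `TRUE`).
#' @return A list of components; each is a list with `pixels` (cropped
#'   logical matrix with a 1-px empty frame), `offset` (0-based `(row, col)`
#'   of the crop in the full image), `area_px`, and `centroid` (0-based
#'   `(x, y)` pixel coordinates in the full image).
#' @export
label_platelets <- function(mask, min_area = 0, exclude_border = TRUE) {
  px <- as_pixels(mask)
  ps <- mask$pixel_size
  lab <- cpp_label(px, 8L)
  n <- max(lab)
  if (n == 0) return(list())
  comps <- list()
  for (k in seq_len(n)) {
    w <- which(lab == k, arr.ind = TRUE)
    area_um2 <- nrow(w) * ps^2
    touches <- any(w[, 1] == 1 | w[, 1] == nrow(px) |
                   w[, 2] == 1 | w[, 2] == ncol(px))
    if (area_um2 < min_area) next
    if (exclude_border && touches) next
    rr <- range(w[, 1]); cc <- range(w[, 2])
    sub <- matrix(FALSE, diff(rr) + 3, diff(cc) + 3)
    sub[cbind(w[, 1] - rr[1] + 2, w[, 2] - cc[1] + 2)] <- TRUE
    comps[[length(comps) + 1]] <- list(
      pixels = sub,
      offset = c(rr[1] - 2, cc[1] - 2),  # 0-based offset of sub[1,1]
      area_px = nrow(w),
      centroid = c(mean(w[, 2]) - 1, mean(w[, 1]) - 1))
  }
  ord <- order(vapply(comps, function(cp) cp$centroid[2], numeric(1)),
               vapply(comps, function(cp) cp$centroid[1], numeric(1)))
  comps[ord]
}

#' Trace the outline of a single platelet component
#'
#' Moore-neighbour boundary tracing; the returned contour visits every
#' boundary pixel in order and is oriented counter-clockwise (positive
#' shoelace area), so that convex outline curvature is positive.
#'
#' @param component one element of [label_platelets()] output, or a logical
#'   matrix containing a single 8-connected component.
#' @param pixel_size micrometres per pixel.
#' @return An `outline` object: `points` (n x 2 matrix of 0-based `(x, y)`
#'   pixel coordinates in the full image), `pixel_size`.
#' @export
trace_contour <- function(component, pixel_size = 1) {
  if (is.matrix(component)) component <- list(pixels = component,
                                              offset = c(0, 0))
  px <- component$pixels
  lab <- cpp_label(px, 8L)
  if (max(lab) != 1)
    stop("input error: contour tracing needs exactly one connected component")
  pts <- cpp_trace_contour(px)
  if (nrow(pts) < 8)
    stop("input error: component too small for a closed outline (< 8 boundary points)")
  pts[, 1] <- pts[, 1] + component$offset[2]
  pts[, 2] <- pts[, 2] + component$offset[1]
  # enforce counter-clockwise orientation (positive shoelace area)
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  if (sum(x * y2 - x2 * y) / 2 < 0) pts <- pts[nrow(pts):1, ]
  structure(list(points = pts, pixel_size = pixel_size), class = "outline")
}

#' Smooth an outline with a circular Gaussian
#'
#' Subpixel contour smoothing before perimeter and curvature measurement;
#' raw pixel-edge contours inflate the perimeter and bias circularity low.
#'
#' @param outline an `outline`.
#' @param sigma Gaussian SD in contour points (default 1).
#' @return The smoothed `outline`.
#' @export
smooth_outline <- function(outline, sigma = 1) {
  pts <- outline$points
  n <- nrow(pts)
  r <- max(1, ceiling(3 * sigma))
  if (2 * r + 1 >= n) r <- floor((n - 1) / 2)
  kern <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  kern <- kern / sum(kern)
  csm <- function(v) {
    ext <- c(tail(v, r), v, head(v, r))
    as.numeric(stats::filter(ext, kern, sides = 2))[(r + 1):(r + n)]
  }
  outline$points <- cbind(csm(pts[, 1]), csm(pts[, 2]))
  outline$smoothed <- TRUE
  outline
}

# arc length of a closed polygon
closed_arc_length <- function(pts) {
  d <- pts - pts[c(2:nrow(pts), 1), ]
  sum(sqrt(rowSums(d^2)))
}

#' Per-platelet shape parameters
#'
#' Computes area `A` (pixel count x pixel_size^2), perimeter `P` (arc length
#' of the Gaussian-smoothed outline), circularity `c = 4*pi*A / P^2`
#' (1 for a perfect circle), and aspect ratio `e = a/b >= 1` from an ellipse
#' fitted by normalized second central image moments of the filled component.
#'
#' @param outline an `outline` (smoothed internally if not already).
#' @param component matching element of [label_platelets()] output.
#' @param smooth_sigma contour smoothing SD used when the outline is raw.
#' @return One-row data frame: `x`, `y` (centroid, um), `area` (um^2),
#'   `perimeter` (um), `circularity`, `aspect_ratio`, plus `major`/`minor`
#'   full axis lengths (um).
#' @export
shape_parameters <- function(outline, component, smooth_sigma = 1) {
  ps <- outline$pixel_size
  if (!isTRUE(outline$smoothed))
    outline <- smooth_outline(outline, smooth_sigma)
  A <- component$area_px * ps^2
  # boundary pixel centres sit ~0.5 px inside the object boundary; outsetting
  # a simple closed curve by 0.5 px adds exactly 2*pi*0.5 = pi to its length
  # (total turning of a simple curve is 2*pi)
  P <- (closed_arc_length(outline$points) + pi) * ps
  circ <- 4 * pi * A / P^2
  w <- which(component$pixels, arr.ind = TRUE)
  xs <- w[, 2] - 1 + component$offset[2]
  ys <- w[, 1] - 1 + component$offset[1]
  mx <- mean(xs); my <- mean(ys)
  # +1/12: second moment of the unit pixel itself
  mu20 <- mean((xs - mx)^2) + 1 / 12
  mu02 <- mean((ys - my)^2) + 1 / 12
  mu11 <- mean((xs - mx) * (ys - my))
  cov <- matrix(c(mu20, mu11, mu11, mu02), 2, 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  if (ev[2] <= 0)
    stop("degenerate-shape error: collinear component has no ellipse fit")
  semi_major <- 2 * sqrt(ev[1]); semi_minor <- 2 * sqrt(ev[2])
  data.frame(x = mx * ps, y = my * ps, area = A, perimeter = P,
             circularity = circ, aspect_ratio = semi_major / semi_minor,
             major = 2 * semi_major * ps, minor = 2 * semi_minor * ps)
}

#' Signed curvature along a (smoothed) outline
#'
#' Point-wise curvature from first and second derivatives along the contour
#' (circular central differences); the counter-clockwise orientation makes
#' convex (outward-bulging) stretches positive and concave necks negative.
#'
#' @param outline a smoothed `outline` (smoothed internally otherwise).
#' @param smooth_sigma smoothing SD applied to raw outlines.
#' @return Numeric vector of per-point curvature in 1/um.
#' @export
curvature_profile <- function(outline, smooth_sigma = 1) {
  if (!isTRUE(outline$smoothed))
    outline <- smooth_outline(outline, smooth_sigma)
  pts <- outline$points
  n <- nrow(pts)
  if (n < 5) stop("input error: outline shorter than the derivative stencil")
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  dx <- (pts[ip, 1] - pts[im, 1]) / 2
  dy <- (pts[ip, 2] - pts[im, 2]) / 2
  ddx <- pts[ip, 1] - 2 * pts[, 1] + pts[im, 1]
  ddy <- pts[ip, 2] - 2 * pts[, 2] + pts[im, 2]
  denom <- (dx^2 + dy^2)^1.5
  denom[denom < 1e-12] <- 1e-12
  (dx * ddy - dy * ddx) / denom / outline$pixel_size
}

#' Count filopodia on a platelet outline
#'
#' Filopodia are detected as high-curvature convex tips whose protrusion
#' extends at least `min_length` from the cell body, the body attachment
#' being marked by concave (negative-curvature) necks flanking the tip.
#' Candidate tips are maximal arcs with curvature `>= min_tip_curvature`;
#' the tip apex is the within-arc curvature maximum; candidates sharing both
#' flanking necks are merged.
#'
#' @param outline a smoothed `outline`.
#' @param curvature output of [curvature_profile()] for the same outline.
#' @param min_length minimum apex-to-neck-base protrusion length, um.
#' @param min_tip_curvature minimum apex curvature, 1/um.
#' @param neck_curvature curvature below which a point counts as a concave
#'   neck, 1/um; defaults to `-min_tip_curvature / 4`. Small negative
#'   wiggles along a protrusion's straight flanks must not terminate the
#'   neck search, so this is deliberately below zero.
#' @return List with `count` and `endpoints` (matrix of apex `(x, y)` um
#'   coordinates, 0 rows when none).
#' @export
count_filopodia <- function(outline, curvature, min_length = 0.5,
                            min_tip_curvature = 2,
                            neck_curvature = -min_tip_curvature / 4) {
  if (!isTRUE(outline$smoothed)) outline <- smooth_outline(outline)
  pts <- outline$points * outline$pixel_size
  n <- length(curvature)
  hi <- curvature >= min_tip_curvature
  if (!any(hi) || !any(curvature < neck_curvature))
    return(list(count = 0L, endpoints = matrix(numeric(0), 0, 2)))
  # maximal circular runs of high curvature
  runs <- circular_runs(hi)
  kept <- list()
  for (rn in runs) {
    arc <- rn
    apex <- arc[which.max(curvature[arc])]
    # walk both ways to the nearest genuinely concave point
    neckL <- walk_to_concave(curvature, apex, -1L, neck_curvature)
    neckR <- walk_to_concave(curvature, apex, +1L, neck_curvature)
    if (is.na(neckL) || is.na(neckR)) next
    # protrusion length: apex to the farther flanking neck (robust when one
    # walk terminates early at a shallow concave dip on the flank)
    len <- max(sqrt(sum((pts[apex, ] - pts[neckL, ])^2)),
               sqrt(sum((pts[apex, ] - pts[neckR, ])^2)))
    if (len < min_length) next
    key <- paste(sort(c(neckL, neckR)), collapse = "-")
    if (is.null(kept[[key]]) || curvature[apex] > kept[[key]]$k)
      kept[[key]] <- list(apex = apex, k = curvature[apex])
  }
  if (length(kept) == 0)
    return(list(count = 0L, endpoints = matrix(numeric(0), 0, 2)))
  apexes <- vapply(kept, function(z) z$apex, numeric(1))
  list(count = length(kept), endpoints = pts[apexes, , drop = FALSE])
}

# maximal runs of TRUE on a circular index, as a list of index vectors
circular_runs <- function(flag) {
  n <- length(flag)
  if (all(flag)) return(list(1:n))
  # rotate so the sequence starts on FALSE, then use rle
  s <- which(!flag)[1]
  rot <- c(s:n, seq_len(s - 1))
  r <- rle(flag[rot])
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  out <- list()
  for (i in seq_along(r$values))
    if (r$values[i]) out[[length(out) + 1]] <- rot[starts[i]:ends[i]]
  out
}

walk_to_concave <- function(curvature, from, dir, threshold = 0) {
  n <- length(curvature)
  i <- from
  for (s in seq_len(n - 1)) {
    i <- ((i - 1 + dir) %% n) + 1
    if (curvature[i] < threshold) return(i)
  }
  NA_integer_
}

#' Full morphometry of one mask (or mask sequence)
#'
#' Labels platelets and emits one shape record per platelet per frame.
#'
#' @param masks a [binary_mask()] or list of them (frames of a time lapse).
#' @param min_area minimum platelet area, um^2.
#' @param smooth_sigma contour smoothing SD (px) for the perimeter; kept
#'   light so corners are preserved.
#' @param curvature_sigma heavier smoothing SD (px) for the curvature
#'   profile and filopodia detection, where derivative noise dominates.
#' @param min_filopodium_length,min_tip_curvature filopodia thresholds
#'   (um and 1/um).
#' @param exclude_border drop border-touching components.
#' @return Data frame of shape records: `frame`, `platelet_id`, `x`, `y`,
#'   `area`, `perimeter`, `circularity`, `aspect_ratio`, `n_filopodia`.
#' @export
measure_masks <- function(masks, min_area = 0, smooth_sigma = 1,
                          curvature_sigma = 2,
                          min_filopodium_length = 0.5,
                          min_tip_curvature = 2, exclude_border = TRUE) {
  if (inherits(masks, "binary_mask")) masks <- list(masks)
  rows <- list()
  for (f in seq_along(masks)) {
    comps <- label_platelets(masks[[f]], min_area = min_area,
                             exclude_border = exclude_border)
    for (k in seq_along(comps)) {
      cp <- comps[[k]]
      rec <- tryCatch({
        raw <- trace_contour(cp, masks[[f]]$pixel_size)
        sp <- shape_parameters(smooth_outline(raw, smooth_sigma), cp)
        olc <- smooth_outline(raw, curvature_sigma)
        kap <- curvature_profile(olc)
        fil <- count_filopodia(olc, kap, min_filopodium_length,
                               min_tip_curvature)
        cbind(data.frame(frame = f - 1L, platelet_id = k), sp,
              n_filopodia = fil$count)
      }, error = function(e) NULL)
      if (!is.null(rec)) rows[[length(rows) + 1]] <- rec
    }
  }
  if (length(rows) == 0)
    return(data.frame(frame = integer(), platelet_id = integer(),
                      x = numeric(), y = numeric(), area = numeric(),
                      perimeter = numeric(), circularity = numeric(),
                      aspect_ratio = numeric(), major = numeric(),
                      minor = numeric(), n_filopodia = integer()))
  do.call(rbind, rows)
}
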