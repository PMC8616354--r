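#' Phantom platelet specification
#'
#' Describes a synthetic platelet: an ellipse body with optional filopodia
#' (thin protrusions drawn as capsules radiating from the body boundary).
#' Designed values (semi-axes, filopodia count) are carried as ground truth
#' through every downstream validation.
#'
#' @param a,b ellipse semi-axes in pixels, `a >= b > 0`.
#' @param orientation body rotation in radians (counter-clockwise in x/y).
#' @param n_filopodia non-negative integer.
#' @param filopodium_length protrusion length beyond the body boundary, px.
#' @param filopodium_width protrusion width in px; must be `< b`.
#' @param centroid `(x, y)` centre in 0-based pixel coordinates, or `NULL`
#'   to centre on the canvas.
#' @param seed integer seed controlling the (bounded) angular jitter of the
#'   filopodia positions.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(a, b, orientation = 0, n_filopodia = 0,
                         filopodium_length = 12, filopodium_width = 4,
                         centroid = NULL, seed = 1L) {
  if (!(a >= b && b > 0)) stop("phantom invariant violated: need a >= b > 0")
  if (n_filopodia < 0 || n_filopodia != round(n_filopodia))
    stop("`n_filopodia` must be a non-negative integer")
  if (n_filopodia > 0 && filopodium_width >= b)
    stop("phantom invariant violated: filopodium_width must be < b")
  structure(list(a = a, b = b, orientation = orientation,
                 n_filopodia = as.integer(n_filopodia),
                 filopodium_length = filopodium_length,
                 filopodium_width = filopodium_width,
                 centroid = centroid, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Rendering specification for phantom images
#'
#' Emulates the two imaging channels: phase contrast (dark platelet body with
#' a bright halo around the outline) and fluorescence (bright body, blurred,
#' with optional uneven background and noise).
#'
#' @param halo_amplitude peak halo intensity relative to the 0..1 range
#'   (phase-contrast mode only).
#' @param blur_sigma Gaussian blur of the rendered image, px.
#' @param noise_sd additive Gaussian noise SD, relative intensity.
#' @param background_gradient linear intensity ramp per pixel along the
#'   image diagonal.
#' @param mode `"phase_contrast"` or `"fluorescence"`.
#' @return A `render_spec` object.
#' @export
render_spec <- function(halo_amplitude = 0.3, blur_sigma = 1,
                        noise_sd = 0.05, background_gradient = 0,
                        mode = c("phase_contrast", "fluorescence")) {
  mode <- match.arg(mode)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0")
  structure(list(halo_amplitude = halo_amplitude, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, background_gradient = background_gradient,
                 mode = mode),
            class = "render_spec")
}

#' Motion specification for phantom migration sequences
#'
#' @param path_kind `"straight"`, `"persistent_random"`,
#'   `"isotropic_random"` or `"stationary"`.
#' @param speed step length in pixels per frame.
#' @param persistence in `[0, 1]`; heading increments for
#'   `persistent_random` are drawn from N(0, (pi * (1 - persistence))^2), so
#'   1 is perfectly straight and 0 close to isotropic.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds between frames.
#' @param seed integer seed for the random headings.
#' @return A `motion_spec` object.
#' @export
motion_spec <- function(path_kind = c("straight", "persistent_random",
                                      "isotropic_random", "stationary"),
                        speed = 5, persistence = 0.8, n_frames = 10,
                        frame_interval = 30, seed = 1L) {
  path_kind <- match.arg(path_kind)
  if (n_frames < 2) stop("`n_frames` must be >= 2")
  if (speed < 0) stop("`speed` must be >= 0")
  if (persistence < 0 || persistence > 1) stop("`persistence` must be in [0,1]")
  structure(list(path_kind = path_kind, speed = speed,
                 persistence = persistence, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "motion_spec")
}

# maximal radial extent of the phantom from its centroid, px
phantom_reach <- function(spec) {
  r <- spec$a
  if (spec$n_filopodia > 0)
    r <- spec$a + spec$filopodium_length + spec$filopodium_width / 2
  r
}

# angular positions of filopodia (equally spaced + bounded seeded jitter)
filopodia_angles <- function(spec) {
  nf <- spec$n_filopodia
  if (nf == 0) return(numeric(0))
  base_angle <- 2 * asin(pmin(1, (spec$filopodium_width / 2) / spec$b))
  spacing <- 2 * pi / nf
  if (nf > 1 && spacing <= 2 * base_angle)
    stop("phantom invariant violated: filopodia too crowded to stay separated")
  jitter_max <- if (nf > 1) 0.25 * (spacing - 2 * base_angle) else pi / 4
  with_local_seed(spec$seed, {
    phase <- runif(1, 0, 2 * pi)
    phase + (0:(nf - 1)) * spacing + runif(nf, -jitter_max, jitter_max)
  })
}

#' Rasterize a phantom platelet mask with designed ground truth
#'
#' The body is a rotated ellipse; each filopodium is a capsule (rectangle
#' with rounded tip) of the designed width extending the designed length
#' beyond the body boundary along the local outward normal. The returned
#' truth row carries the designed aspect ratio, filopodia count and the
#' analytic ellipse-plus-spikes area.
#'
#' @param spec a [phantom_spec()].
#' @param canvas `c(nrow, ncol)` canvas size in pixels, or `NULL` for a
#'   tight canvas with a 10-pixel margin.
#' @param pixel_size micrometres per pixel for the emitted mask.
#' @return A list with elements `mask` (a [binary_mask()]) and `truth`
#'   (one-row data frame: `platelet_id`, `frame_index`, `x`, `y`, `area`,
#'   `aspect_ratio`, `n_filopodia`).
#' @export
make_platelet_mask <- function(spec, canvas = NULL, pixel_size = 1) {
  reach <- phantom_reach(spec)
  need <- ceiling(2 * (reach + 10)) + 1
  if (is.null(canvas)) canvas <- c(need, need)
  if (is.null(spec$centroid))
    spec$centroid <- c((canvas[2] - 1) / 2, (canvas[1] - 1) / 2)
  cx <- spec$centroid[1]; cy <- spec$centroid[2]
  if (cx - reach < 0 || cy - reach < 0 ||
      cx + reach > canvas[2] - 1 || cy + reach > canvas[1] - 1)
    stop(sprintf(
      "canvas too small: need at least %dx%d px to contain the phantom",
      need, need))
  H <- canvas[1]; W <- canvas[2]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  u <- (xs - cx) * co + (ys - cy) * si
  v <- -(xs - cx) * si + (ys - cy) * co
  m <- (u / spec$a)^2 + (v / spec$b)^2 <= 1
  angles <- filopodia_angles(spec)
  for (t in angles) {
    # boundary point and outward normal of the ellipse at parameter t
    p0b <- c(spec$a * cos(t), spec$b * sin(t))
    nrm <- c(spec$b * cos(t), spec$a * sin(t))
    nrm <- nrm / sqrt(sum(nrm^2))
    rot <- function(p) c(p[1] * co - p[2] * si, p[1] * si + p[2] * co)
    p0 <- rot(p0b - 1.5 * nrm) + c(cx, cy)
    p1 <- rot(p0b + spec$filopodium_length * nrm) + c(cx, cy)
    # distance of each pixel centre to the segment p0-p1
    dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
    len2 <- dx^2 + dy^2
    tt <- pmin(1, pmax(0, ((xs - p0[1]) * dx + (ys - p0[2]) * dy) / len2))
    d2 <- (xs - (p0[1] + tt * dx))^2 + (ys - (p0[2] + tt * dy))^2
    m <- m | d2 <= (spec$filopodium_width / 2)^2
  }
  w <- spec$filopodium_width
  designed_area <- pi * spec$a * spec$b + spec$n_filopodia *
    (spec$filopodium_length * w + pi * (w / 2)^2 / 2)
  truth <- data.frame(platelet_id = 1L, frame_index = 0L,
                      x = cx * pixel_size, y = cy * pixel_size,
                      area = designed_area * pixel_size^2,
                      aspect_ratio = spec$a / spec$b,
                      n_filopodia = spec$n_filopodia)
  list(mask = binary_mask(m, pixel_size), truth = truth)
}

#' Render a phantom mask as a microscopy-like image
#'
#' Phase-contrast mode produces a dark body on a brighter background with a
#' bright halo hugging the outline (blurred outer boundary ring, the positive
#' part of a difference-of-Gaussians edge); fluorescence mode produces a
#' bright body. Both modes then apply Gaussian blur, an optional linear
#' background ramp, and additive Gaussian noise. Deterministic for a fixed
#' seed; the global RNG state is left untouched.
#'
#' @param mask a [binary_mask()]; must be non-empty.
#' @param render a [render_spec()].
#' @param seed integer noise seed.
#' @return A [gray_image()] in the requested channel.
#' @export
render_image <- function(mask, render = render_spec(), seed = 1L) {
  m <- as_pixels(mask) * 1
  if (sum(m) == 0) stop("mask is empty; nothing to render")
  H <- nrow(m); W <- ncol(m)
  if (render$mode == "phase_contrast") {
    img <- 0.7 - 0.4 * m
    if (render$halo_amplitude != 0) {
      ring <- (binary_dilate1(m > 0.5) & !(m > 0.5)) * 1
      halo <- gauss_blur(ring, max(render$blur_sigma, 0.8))
      if (max(halo) > 0) halo <- halo / max(halo)
      img <- img + render$halo_amplitude * halo
    }
  } else {
    img <- 0.05 + 0.95 * m
  }
  if (render$blur_sigma > 0) img <- gauss_blur(img, render$blur_sigma)
  if (render$background_gradient != 0) {
    xs <- matrix(rep(0:(W - 1), each = H), H, W)
    ys <- matrix(rep(0:(H - 1), W), H, W)
    img <- img + render$background_gradient * (xs + ys) / 2
  }
  if (render$noise_sd > 0) {
    noise <- with_local_seed(seed, matrix(rnorm(H * W, 0, render$noise_sd), H, W))
    img <- img + noise
  }
  img <- pmax(img, 0)
  gray_image(img, mask$pixel_size, channel = if (render$mode == "fluorescence")
    "fluorescence" else "phase_contrast")
}

#' Synthetic two-phase spreading sequence
#'
#' Emulates the canonical platelet spreading time course: a constant-area
#' idle phase, a fast area-growth phase, then a slow growth phase. Masks are
#' digitized disks whose designed areas follow the piecewise-linear
#' trajectory exactly.
#'
#' @param initial_area starting area in px^2.
#' @param idle_frames number of initial constant-area frames.
#' @param fast_rate,slow_rate area growth in px^2 per frame,
#'   `fast_rate > slow_rate >= 0`.
#' @param switch_frame last frame index (0-based) of the fast phase.
#' @param n_frames total frames.
#' @param pixel_size micrometres per pixel.
#' @return List with `masks` (list of [binary_mask()]) and `truth`
#'   (data frame: `frame`, `designed_area` in px^2).
#' @export
make_spreading_sequence <- function(initial_area = 200, idle_frames = 3,
                                    fast_rate = 60, slow_rate = 10,
                                    switch_frame = 16, n_frames = 24,
                                    pixel_size = 1) {
  if (!(fast_rate > slow_rate && slow_rate >= 0))
    stop("parameter error: need fast_rate > slow_rate >= 0")
  if (!(idle_frames < switch_frame && switch_frame < n_frames))
    stop("parameter error: need idle_frames < switch_frame < n_frames")
  f <- 0:(n_frames - 1)
  last_idle <- idle_frames - 1
  area <- ifelse(f <= last_idle, initial_area,
          ifelse(f <= switch_frame,
                 initial_area + fast_rate * (f - last_idle),
                 initial_area + fast_rate * (switch_frame - last_idle) +
                   slow_rate * (f - switch_frame)))
  rmax <- sqrt(max(area) / pi)
  side <- ceiling(2 * (rmax + 10)) + 1
  cx <- (side - 1) / 2
  xs <- matrix(rep(0:(side - 1), each = side), side, side)
  ys <- matrix(rep(0:(side - 1), side), side, side)
  d2 <- (xs - cx)^2 + (ys - cx)^2
  masks <- lapply(area, function(A)
    binary_mask(d2 <= A / pi, pixel_size))
  list(masks = masks, truth = data.frame(frame = f, designed_area = area))
}

#' Synthetic migration sequence with a known centroid path
#'
#' Moves an elliptical phantom along a designed path and rasterizes one mask
#' per frame. Path kinds: `straight` (fixed seeded heading),
#' `isotropic_random` (fresh uniform heading each step), `persistent_random`
#' (wrapped-normal heading increments; see [motion_spec()]), `stationary`.
#'
#' @param motion a [motion_spec()].
#' @param shape a [phantom_spec()] for the moving body (filopodia allowed but
#'   a plain ellipse gives the cleanest centroids); its `centroid` is ignored.
#' @param canvas optional `c(nrow, ncol)`; auto-sized to contain the whole
#'   path when `NULL`.
#' @param pixel_size micrometres per pixel.
#' @return List with `masks` (one [binary_mask()] per frame) and `truth`
#'   (data frame: `frame`, `x`, `y` designed centroids in px).
#' @export
make_migration_sequence <- function(motion, shape = phantom_spec(8, 6),
                                    canvas = NULL, pixel_size = 1) {
  n <- motion$n_frames
  path <- make_motion_path(motion)
  reach <- phantom_reach(shape)
  margin <- reach + 10
  xr <- range(path[, 1]); yr <- range(path[, 2])
  if (is.null(canvas)) {
    canvas <- c(ceiling(diff(yr) + 2 * margin) + 1,
                ceiling(diff(xr) + 2 * margin) + 1)
  }
  offset <- c(margin - xr[1], margin - yr[1])
  path[, 1] <- path[, 1] + offset[1]
  path[, 2] <- path[, 2] + offset[2]
  if (min(path[, 1]) < reach || min(path[, 2]) < reach ||
      max(path[, 1]) > canvas[2] - 1 - reach ||
      max(path[, 2]) > canvas[1] - 1 - reach)
    stop("sizing error: designed path leaves the canvas")
  masks <- lapply(seq_len(n), function(f) {
    sp <- shape
    sp$centroid <- c(path[f, 1], path[f, 2])
    make_platelet_mask(sp, canvas = canvas, pixel_size = pixel_size)$mask
  })
  list(masks = masks,
       truth = data.frame(frame = 0:(n - 1), x = path[, 1], y = path[, 2]))
}

#' Designed centroid path for a motion specification
#'
#' The pure path generator behind [make_migration_sequence()]: straight
#' paths use one seeded heading, isotropic random walks draw a fresh uniform
#' heading every step, persistent random walks accumulate wrapped-normal
#' heading increments, stationary paths do not move. Deterministic for a
#' fixed spec.
#'
#' @param motion a [motion_spec()].
#' @return `n_frames` x 2 matrix of `(x, y)` positions starting at (0, 0).
#' @export
make_motion_path <- function(motion) {
  n <- motion$n_frames
  steps <- with_local_seed(motion$seed, {
    headings <- switch(motion$path_kind,
      straight = rep(runif(1, 0, 2 * pi), n - 1),
      isotropic_random = runif(n - 1, 0, 2 * pi),
      persistent_random = {
        sdv <- pi * (1 - motion$persistence)
        cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 2, 0, sdv)))
      },
      stationary = rep(0, n - 1))
    sp <- if (motion$path_kind == "stationary") 0 else motion$speed
    cbind(sp * cos(headings), sp * sin(headings))
  })
  if (n == 2) return(rbind(c(0, 0), steps))
  rbind(c(0, 0), apply(steps, 2, cumsum))
}

#' Generate a phantom segmentation training/evaluation set
#'
#' Draws random platelet phantoms (body size, elongation, orientation,
#' filopodia count and geometry, position) on a square canvas and renders
#' each one in phase contrast with the default imaging model (bright halo,
#' optical blur sigma = 0.8 px, 5% additive noise). The designed masks are
#' the ground truth. One platelet per image, as in high-magnification
#' single-platelet fields.
#'
#' @param n number of image/mask pairs.
#' @param side canvas side in pixels (64-128 at desk scale).
#' @param seed integer master seed; pair `i` is derived deterministically.
#' @param render a [render_spec()] for the phase-contrast channel.
#' @param empty_every every `empty_every`-th pair is a platelet-free field
#'   (background plus noise, empty truth mask), emulating the empty fields
#'   of a real recording; set to `Inf` to disable.
#' @return List of `n` pairs `list(phase = gray_image, truth = binary_mask,
#'   spec = phantom_spec or NULL for empty fields)`.
#' @export
make_segmentation_set <- function(n, side = 64, seed = 1L,
                                  render = render_spec(halo_amplitude = 0.3,
                                                       blur_sigma = 0.8,
                                                       noise_sd = 0.05),
                                  empty_every = 10L) {
  scale <- side / 64
  lapply(seq_len(n), function(i) {
    pair_seed <- seed * 100000L + i
    if (is.finite(empty_every) && i %% empty_every == 0) {
      img <- with_local_seed(pair_seed, {
        px <- 0.7 + matrix(rnorm(side * side, 0, render$noise_sd), side, side)
        gray_image(pmax(px, 0), channel = "phase_contrast")
      })
      return(list(phase = img,
                  truth = binary_mask(matrix(FALSE, side, side)),
                  spec = NULL))
    }
    with_local_seed(pair_seed, {
      a <- runif(1, 8, 15) * scale
      b <- max(runif(1, 0.5, 1) * a, 6 * scale)
      nf <- sample(0:4, 1)
      ctr <- (side - 1) / 2 + runif(2, -5 * scale, 5 * scale)
      sp <- phantom_spec(a, b, orientation = runif(1, 0, 2 * pi),
                         n_filopodia = nf,
                         filopodium_length = runif(1, 6, 10) * scale,
                         filopodium_width = 3 * scale,
                         centroid = ctr, seed = pair_seed)
      ph <- make_platelet_mask(sp, canvas = c(side, side))
      img <- render_image(ph$mask, render, seed = pair_seed + 1L)
      list(phase = img, truth = ph$mask, spec = sp)
    })
  })
}
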