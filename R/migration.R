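#' Link platelet centroids across frames into tracks
#'
#' Per-frame area centroids (of the filled components) are linked between
#' consecutive frames by mutual nearest neighbours within a gating distance.
#' Equidistant ambiguous links are broken deterministically towards the
#' smaller platelet id. Tracks that do not span the whole sequence are kept
#' but marked `complete = FALSE`; metric summaries exclude them.
#'
#' @param masks list of [binary_mask()] frames (>= 2).
#' @param gate maximum per-frame displacement in pixels.
#' @param min_area minimum component area (um^2) to consider.
#' @return List of tracks; each is a list with `platelet_id`, `positions`
#'   (n x 2 matrix, um), `frames`, `complete`.
#' @export
link_tracks <- function(masks, gate = 20, min_area = 0) {
  if (length(masks) < 2) stop("need at least 2 frames to link tracks")
  ps <- masks[[1]]$pixel_size
  cents <- lapply(masks, function(m) {
    comps <- label_platelets(m, min_area = min_area, exclude_border = FALSE)
    if (length(comps) == 0) return(matrix(numeric(0), 0, 2))
    do.call(rbind, lapply(comps, function(cp) cp$centroid))
  })
  n_frames <- length(masks)
  # active tracks: list of list(id, rows = matrix of px positions, frames)
  tracks <- list()
  active <- integer(0)  # indices into tracks, position = centroid row in prev frame
  next_id <- 1L
  prev <- cents[[1]]
  for (r in seq_len(nrow(prev))) {
    tracks[[next_id]] <- list(platelet_id = next_id,
                              pos = prev[r, , drop = FALSE], frames = 0L)
    active[r] <- next_id
    next_id <- next_id + 1L
  }
  for (f in 2:n_frames) {
    cur <- cents[[f]]
    na <- nrow(prev); nb <- nrow(cur)
    match_ab <- rep(NA_integer_, na)
    if (na > 0 && nb > 0) {
      d <- outer(seq_len(na), seq_len(nb), function(i, j)
        sqrt((prev[i, 1] - cur[j, 1])^2 + (prev[i, 2] - cur[j, 2])^2))
      # mutual nearest neighbour within the gate; ties to the smaller id
      for (i in seq_len(na)) {
        j <- which(d[i, ] == min(d[i, ]))[1]
        if (d[i, j] > gate) next
        i_back <- which(d[, j] == min(d[, j]))[1]
        if (i_back == i) match_ab[i] <- j
      }
    }
    new_active <- rep(NA_integer_, nb)
    for (i in seq_len(na)) {
      j <- match_ab[i]
      if (!is.na(j) && is.na(new_active[j])) {
        tid <- active[i]
        tracks[[tid]]$pos <- rbind(tracks[[tid]]$pos, cur[j, ])
        tracks[[tid]]$frames <- c(tracks[[tid]]$frames, f - 1L)
        new_active[j] <- tid
      }
    }
    for (j in seq_len(nb)) {
      if (is.na(new_active[j])) {
        tracks[[next_id]] <- list(platelet_id = next_id,
                                  pos = cur[j, , drop = FALSE],
                                  frames = f - 1L)
        new_active[j] <- next_id
        next_id <- next_id + 1L
      }
    }
    active <- new_active
    prev <- cur
  }
  lapply(tracks, function(tr) {
    list(platelet_id = tr$platelet_id,
         positions = tr$pos * ps,
         frames = tr$frames,
         complete = length(tr$frames) == n_frames)
  })
}

#' Construct a track from positions
#'
#' @param positions n x 2 matrix of `(x, y)` in micrometres, time-ordered.
#' @param frame_interval seconds between frames (default 30 s, the standard
#'   migration acquisition rate).
#' @param platelet_id identifier.
#' @param complete whether the track spans the full sequence.
#' @return A `track` object.
#' @export
track <- function(positions, frame_interval = 30, platelet_id = 1L,
                  complete = TRUE) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("input error: a track needs >= 2 positions")
  if (any(!is.finite(positions))) stop("positions must be finite")
  structure(list(platelet_id = platelet_id, positions = positions,
                 frame_interval = frame_interval, complete = complete),
            class = "track")
}

as_track <- function(x, frame_interval = 30) {
  if (inherits(x, "track")) return(x)
  track(x$positions, frame_interval, x$platelet_id,
        isTRUE(x$complete))
}

track_steps <- function(tr) {
  p <- tr$positions
  p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
}

#' Migration velocity: accumulated distance over time
#'
#' @param tr a [track()].
#' @return Velocity in um/min.
#' @export
migration_velocity <- function(tr) {
  tr <- as_track(tr)
  steps <- track_steps(tr)
  total_um <- sum(sqrt(rowSums(steps^2)))
  total_min <- (nrow(tr$positions) - 1) * tr$frame_interval / 60
  total_um / total_min
}

#' Path straightness: Euclidean distance over accumulated distance
#'
#' 1 for a perfectly straight path, 0 for a closed loop.
#'
#' @param tr a [track()].
#' @return Straightness in `[0, 1]`, `NA` (with a warning) for a track that
#'   never moves.
#' @export
straightness <- function(tr) {
  tr <- as_track(tr)
  steps <- track_steps(tr)
  acc <- sum(sqrt(rowSums(steps^2)))
  if (acc == 0) {
    warning("zero accumulated distance: straightness undefined")
    return(NA_real_)
  }
  p <- tr$positions
  sqrt(sum((p[nrow(p), ] - p[1, ])^2)) / acc
}

#' Mean directional change cos(theta)
#'
#' For every available time interval of the given length, the cosine of the
#' angle between the movement direction at the interval start and at the
#' interval end, averaged over all intervals. 1 indicates persistent
#' (straight) movement, 0 random movement.
#'
#' @param tr a [track()].
#' @param interval interval length in seconds (a multiple of the frame
#'   interval).
#' @param mode `"step"` compares the single-frame displacement directions at
#'   the interval's first and last frame (default); `"net"` compares net
#'   displacements over consecutive windows of the interval length.
#' @return Mean cos(theta); intervals with a zero-length displacement at a
#'   boundary are skipped.
#' @export
directional_change <- function(tr, interval = NULL, mode = c("step", "net")) {
  tr <- as_track(tr)
  mode <- match.arg(mode)
  if (is.null(interval)) interval <- tr$frame_interval
  k <- interval / tr$frame_interval
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("`interval` must be a positive multiple of the frame interval")
  k <- as.integer(round(k))
  steps <- track_steps(tr)
  n <- nrow(steps)
  cosines <- numeric(0)
  if (mode == "step") {
    if (n < k + 1) stop("track too short for this interval")
    for (i in seq_len(n - k)) {
      u <- steps[i, ]; v <- steps[i + k, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) next
      cosines <- c(cosines, sum(u * v) / (nu * nv))
    }
  } else {
    p <- tr$positions
    if (nrow(p) < 2 * k + 1) stop("track too short for this interval")
    for (i in seq_len(nrow(p) - 2 * k)) {
      u <- p[i + k, ] - p[i, ]
      v <- p[i + 2 * k, ] - p[i + k, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) next
      cosines <- c(cosines, sum(u * v) / (nu * nv))
    }
  }
  if (length(cosines) == 0) return(NA_real_)
  mean(cosines)
}

#' Curve of mean cos(theta) against interval length
#'
#' @param tr a [track()].
#' @param intervals interval lengths in seconds; defaults to all multiples
#'   of the frame interval up to half the track duration.
#' @param mode see [directional_change()].
#' @return Data frame `interval_s`, `mean_cos_theta`.
#' @export
directional_change_curve <- function(tr, intervals = NULL,
                                     mode = c("step", "net")) {
  tr <- as_track(tr)
  mode <- match.arg(mode)
  if (is.null(intervals)) {
    kmax <- max(1, floor((nrow(tr$positions) - 1) / 2))
    intervals <- tr$frame_interval * seq_len(kmax)
  }
  data.frame(interval_s = intervals,
             mean_cos_theta = vapply(intervals, function(iv)
               directional_change(tr, iv, mode), numeric(1)))
}

#' Align tracks to a common initial direction
#'
#' Rotates each track rigidly about its start point so that the first
#' displacement points along the positive y axis; step lengths (and thus
#' velocity, straightness and directional change) are preserved exactly.
#' Tracks with a zero initial displacement are flagged and left unrotated.
#'
#' @param tracks a [track()] or list of tracks.
#' @return List of tracks with an added `aligned` flag.
#' @export
align_initial_direction <- function(tracks) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  lapply(tracks, function(tr) {
    tr <- as_track(tr)
    p <- tr$positions
    d0 <- p[2, ] - p[1, ]
    if (sum(d0^2) == 0) {
      tr$aligned <- FALSE
      return(tr)
    }
    # rotation taking d0 to +y
    ang <- atan2(d0[2], d0[1])
    rot <- pi / 2 - ang
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
    centred <- sweep(p, 2, p[1, ])
    tr$positions <- sweep(centred %*% t(R), 2, p[1, ], `+`)
    tr$aligned <- TRUE
    tr
  })
}

#' Summary metrics for a list of linked tracks
#'
#' Incomplete tracks (not spanning the whole sequence) are excluded, per the
#' tracking rule.
#'
#' @param tracks output of [link_tracks()].
#' @param frame_interval seconds per frame.
#' @return Data frame: `platelet_id`, `velocity_um_min`, `straightness`,
#'   `mean_cos_theta` (one frame-interval spacing).
#' @export
migration_metrics <- function(tracks, frame_interval = 30) {
  keep <- Filter(function(tr) isTRUE(tr$complete) &&
                   nrow(tr$positions) >= 3, tracks)
  if (length(keep) == 0)
    return(data.frame(platelet_id = integer(), velocity_um_min = numeric(),
                      straightness = numeric(), mean_cos_theta = numeric()))
  do.call(rbind, lapply(keep, function(x) {
    tr <- as_track(x, frame_interval)
    data.frame(platelet_id = tr$platelet_id,
               velocity_um_min = migration_velocity(tr),
               straightness = straightness(tr),
               mean_cos_theta = directional_change(tr))
  }))
}

#' Plot aligned migration paths
#'
#' Draws all complete tracks aligned to a common +y initial direction
#' (rose-plot style overview of directional persistence), optionally to a
#' PNG or SVG file.
#'
#' @param tracks list of tracks (aligned internally via
#'   [align_initial_direction()]).
#' @param file optional output path ending in `.png` or `.svg`.
#' @param ... passed to [graphics::plot()].
#' @return The input tracks, invisibly.
#' @export
plot_aligned_tracks <- function(tracks, file = NULL, ...) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  keep <- Filter(function(tr) !identical(tr$complete, FALSE), tracks)
  al <- align_initial_direction(keep)
  if (!is.null(file)) {
    if (grepl("\\.png$", file)) grDevices::png(file, 600, 600)
    else if (grepl("\\.svg$", file)) grDevices::svg(file)
    else stop("`file` must end in .png or .svg")
    on.exit(grDevices::dev.off())
  }
  rel <- lapply(al, function(tr) sweep(tr$positions, 2, tr$positions[1, ]))
  lim <- max(1e-6, vapply(rel, function(p) max(abs(p)), numeric(1)))
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = "aligned migration paths", ...)
  for (p in rel) graphics::lines(p[, 1], p[, 2],
                                 col = grDevices::rgb(0, 0, 0, 0.5))
  invisible(tracks)
}
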