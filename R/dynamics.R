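#' Spreading trace of a single platelet
#'
#' Time-ordered per-frame shape records for one platelet plus the acquisition
#' frame interval. Adhesion (first presence) anchors all spreading metrics at
#' `t = 0`.
#'
#' @param records data frame with at least `frame` and `area` columns (one
#'   row per frame where the platelet is present; areas in um^2).
#' @param frame_interval seconds between frames (default 10 s, the standard
#'   spreading acquisition rate).
#' @param platelet_id identifier carried through outputs.
#' @return A `spreading_trace` object.
#' @export
spreading_trace <- function(records, frame_interval = 10, platelet_id = 1L) {
  if (!all(c("frame", "area") %in% names(records)))
    stop("records need `frame` and `area` columns")
  if (frame_interval <= 0) stop("`frame_interval` must be > 0")
  records <- records[order(records$frame), , drop = FALSE]
  if (any(duplicated(records$frame)))
    stop("records contain duplicated frames")
  structure(list(records = records, frame_interval = frame_interval,
                 platelet_id = platelet_id),
            class = "spreading_trace")
}

#' Adhesion frame of a spreading trace
#'
#' The first frame at which the platelet is present as a tracked component;
#' all spreading metrics are measured from this frame.
#'
#' @param trace a [spreading_trace()].
#' @return Integer frame index.
#' @export
detect_adhesion <- function(trace) {
  if (nrow(trace$records) == 0)
    stop("detection error: platelet never present in the trace")
  as.integer(min(trace$records$frame))
}

#' Idle time: adhesion to 15% area increase
#'
#' Time from adhesion to the first frame whose area reaches at least
#' `(1 + threshold)` times the adhesion-frame area (inclusive crossing).
#' Traces that never cross are censored, not dropped.
#'
#' @param trace a [spreading_trace()].
#' @param threshold relative area increase defining spreading onset
#'   (default 0.15).
#' @return List with `idle_s` (seconds, `NA` when censored), `idle_frames`,
#'   and `status` (`"ok"` or `"censored"`).
#' @export
idle_time <- function(trace, threshold = 0.15) {
  ad <- detect_adhesion(trace)
  rec <- trace$records
  a0 <- rec$area[rec$frame == ad]
  cross <- rec$frame[rec$area >= (1 + threshold) * a0 & rec$frame >= ad]
  if (length(cross) == 0)
    return(list(idle_s = NA_real_, idle_frames = NA_integer_,
                status = "censored"))
  f <- min(cross)
  list(idle_s = (f - ad) * trace$frame_interval,
       idle_frames = as.integer(f - ad), status = "ok")
}

#' Initial spreading rate
#'
#' Least-squares slope of area versus time over the 2-minute window starting
#' at the end of idle time (window closed on both ends), in um^2/min.
#' Censored traces (idle time undefined) return `NA`; windows truncated by
#' the end of the trace are computed on the available frames and flagged.
#'
#' @param trace a [spreading_trace()].
#' @param window_s window length in seconds (default 120).
#' @param threshold idle-time threshold passed through.
#' @return List with `rate_um2_min`, `status` (`"ok"`, `"truncated"` or
#'   `"censored"`).
#' @export
initial_spreading_rate <- function(trace, window_s = 120, threshold = 0.15) {
  it <- idle_time(trace, threshold)
  if (it$status == "censored")
    return(list(rate_um2_min = NA_real_, status = "censored"))
  ad <- detect_adhesion(trace)
  t_start <- ad * trace$frame_interval + it$idle_s
  t_end <- t_start + window_s
  rec <- trace$records
  tt <- rec$frame * trace$frame_interval
  sel <- tt >= t_start & tt <= t_end
  status <- "ok"
  if (max(tt) < t_end) status <- "truncated"
  if (sum(sel) < 2)
    return(list(rate_um2_min = NA_real_, status = "censored"))
  fit <- lm(rec$area[sel] ~ tt[sel])
  list(rate_um2_min = unname(coef(fit)[2]) * 60, status = status)
}

#' Normalized area trace
#'
#' Per-frame area divided by the area at a reference frame (e.g. the frame
#' of agonist addition); the value at the reference frame is exactly 1.
#'
#' @param trace a [spreading_trace()].
#' @param t_ref reference frame index; must be present in the trace.
#' @return Data frame `frame`, `norm_area`.
#' @export
normalized_area_trace <- function(trace, t_ref) {
  rec <- trace$records
  if (!t_ref %in% rec$frame)
    stop("parameter error: reference frame not in the trace")
  a0 <- rec$area[rec$frame == t_ref]
  if (a0 <= 0) stop("parameter error: reference area must be positive")
  data.frame(frame = rec$frame, norm_area = rec$area / a0)
}

#' Spreading metrics for every platelet in a morphometry table
#'
#' @param records data frame from [measure_masks()] (needs `frame`,
#'   `platelet_id`, `area`).
#' @param frame_interval seconds per frame.
#' @return Data frame: one row per platelet with `platelet_id`,
#'   `adhesion_frame`, `idle_time_s`, `rate_um2_per_min`, `status`.
#' @export
spreading_metrics <- function(records, frame_interval = 10) {
  ids <- sort(unique(records$platelet_id))
  out <- lapply(ids, function(id) {
    tr <- spreading_trace(records[records$platelet_id == id, , drop = FALSE],
                          frame_interval, id)
    it <- idle_time(tr)
    rr <- initial_spreading_rate(tr)
    data.frame(platelet_id = id, adhesion_frame = detect_adhesion(tr),
               idle_time_s = it$idle_s, rate_um2_per_min = rr$rate_um2_min,
               status = if (it$status == "censored") "censored" else rr$status)
  })
  do.call(rbind, out)
}
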