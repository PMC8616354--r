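mk_track <- function(xy, interval = 30) track(as.matrix(xy), interval)

test_that("velocity is accumulated distance over time", {
  # straight 5 px/frame, 0.1 um/px, 30 s/frame -> 1 um/min
  p <- cbind(seq(0, 45, by = 5) * 0.1, 0)
  expect_equal(migration_velocity(mk_track(p)), 1.0)
  # stationary
  expect_equal(migration_velocity(mk_track(cbind(rep(1, 5), rep(2, 5)))), 0)
  # random walk with the same step length has the same accumulated velocity
  path <- make_motion_path(motion_spec("isotropic_random", speed = 5,
                                       n_frames = 10, seed = 3)) * 0.1
  expect_equal(migration_velocity(mk_track(path)), 1.0)
  expect_error(track(matrix(1:2, 1, 2)), ">= 2 positions")
})

test_that("straightness matches its analytic values", {
  expect_equal(straightness(mk_track(cbind(0:9, 0))), 1.0)
  expect_equal(straightness(mk_track(rbind(c(0, 0), c(3, 0), c(3, 4)))), 5 / 7)
  # closed loop
  loop <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(straightness(mk_track(loop)), 0)
  expect_warning(st <- straightness(mk_track(cbind(rep(0, 4), rep(0, 4)))),
                 "undefined")
  expect_true(is.na(st))
})

test_that("directional change follows the cosine definition", {
  straight <- mk_track(cbind(0:19, 0))
  for (iv in c(30, 90, 240))
    expect_equal(directional_change(straight, iv), 1.0)
  # single 90-degree turn
  turn <- mk_track(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(directional_change(turn, 30), 0)
  # interval must be a multiple of the frame interval
  expect_error(directional_change(straight, 45), "multiple")
  # net mode agrees on straight tracks
  expect_equal(directional_change(straight, 90, mode = "net"), 1.0)
})

test_that("persistent paths decorrelate with interval; straight stays 1", {
  path <- make_motion_path(motion_spec("persistent_random", speed = 5,
                                       persistence = 0.9, n_frames = 2000,
                                       seed = 8))
  tr <- mk_track(path)
  curve <- directional_change_curve(tr, intervals = 30 * c(1, 4, 16, 64))
  expect_true(all(diff(curve$mean_cos_theta) < 0))
  straight <- mk_track(cbind(0:40, 2 * (0:40)))
  cs <- directional_change_curve(straight, intervals = 30 * c(1, 5, 10))
  expect_equal(cs$mean_cos_theta, rep(1, 3))
})

test_that("metrics are invariant under rotation/translation; alignment is rigid", {
  path <- make_motion_path(motion_spec("persistent_random", speed = 4,
                                       persistence = 0.7, n_frames = 30,
                                       seed = 5))
  tr <- mk_track(path)
  ang <- 1.1
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  tr2 <- mk_track(sweep(path %*% t(R), 2, c(13, -7), `+`))
  expect_equal(migration_velocity(tr2), migration_velocity(tr))
  expect_equal(straightness(tr2), straightness(tr))
  expect_equal(directional_change(tr2, 60), directional_change(tr, 60))
  al <- align_initial_direction(list(tr, tr2))
  for (a in al) {
    d0 <- a$positions[2, ] - a$positions[1, ]
    expect_equal(d0[1], 0, tolerance = 1e-12)
    expect_gt(d0[2], 0)
  }
  expect_equal(straightness(al[[1]]), straightness(tr))
  expect_equal(migration_velocity(al[[1]]), migration_velocity(tr))
  # already-aligned track unchanged; (1,0) first step rotates to (0,1)
  t10 <- mk_track(rbind(c(0, 0), c(1, 0), c(2, 0)))
  a10 <- align_initial_direction(t10)[[1]]
  expect_equal(a10$positions[2, ], c(0, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  ty <- mk_track(rbind(c(0, 0), c(0, 1), c(0, 2)))
  ay <- align_initial_direction(ty)[[1]]
  expect_equal(ay$positions, ty$positions, tolerance = 1e-12)
})

test_that("single-platelet phantom scenes are tracked exactly", {
  seq <- make_migration_sequence(motion_spec("persistent_random", speed = 5,
                                             persistence = 0.8,
                                             n_frames = 8, seed = 4))
  tracks <- link_tracks(seq$masks, gate = 15)
  expect_length(tracks, 1)
  expect_true(tracks[[1]]$complete)
  err <- max(abs(tracks[[1]]$positions -
                   as.matrix(seq$truth[, c("x", "y")])))
  expect_lt(err, 0.5)
})

test_that("disappearing platelets yield incomplete tracks, excluded from metrics", {
  seq <- make_migration_sequence(motion_spec("straight", speed = 4,
                                             n_frames = 6, seed = 2))
  masks <- seq$masks
  masks[[4]] <- binary_mask(matrix(FALSE, nrow(masks[[4]]$pixels),
                                   ncol(masks[[4]]$pixels)))
  tracks <- link_tracks(masks, gate = 15)
  expect_true(all(!vapply(tracks, `[[`, logical(1), "complete")))
  expect_equal(nrow(migration_metrics(tracks)), 0)
})

test_that("multi-platelet linking matches the brute-force assignment oracle", {
  set.seed(9)
  for (trial in 1:4) {
    n_p <- sample(2:5, 1)
    n_frames <- 6
    # well-separated anchors, steps below half the gate
    anchors <- cbind(runif(n_p, 30, 170), runif(n_p, 30, 170))
    while (min(dist(anchors)) < 45)
      anchors <- cbind(runif(n_p, 30, 170), runif(n_p, 30, 170))
    paths <- lapply(seq_len(n_p), function(k)
      sweep(make_motion_path(motion_spec("isotropic_random", speed = 4,
                                         n_frames = n_frames,
                                         seed = trial * 10 + k)),
            2, anchors[k, ], `+`))
    masks <- lapply(seq_len(n_frames), function(f) {
      m <- matrix(FALSE, 200, 200)
      for (k in seq_len(n_p)) {
        sp <- phantom_spec(6, 5, centroid = paths[[k]][f, ], seed = 1)
        m <- m | make_platelet_mask(sp, canvas = c(200, 200))$mask$pixels
      }
      binary_mask(m)
    })
    tracks <- link_tracks(masks, gate = 20)
    complete <- Filter(function(tr) tr$complete, tracks)
    expect_length(complete, n_p)
    # frame-by-frame, the linking must equal the optimal assignment
    cents <- lapply(seq_len(n_frames), function(f)
      do.call(rbind, lapply(label_platelets(masks[[f]],
                                            exclude_border = FALSE),
                            function(cp) cp$centroid)))
    for (f in seq_len(n_frames - 1)) {
      perm <- oracle_assignment(cents[[f]], cents[[f + 1]])
      for (tr in complete) {
        i <- which.min(rowSums(sweep(cents[[f]], 2,
                                     tr$positions[f, ])^2))
        j <- which.min(rowSums(sweep(cents[[f + 1]], 2,
                                     tr$positions[f + 1, ])^2))
        expect_equal(perm[i], j)
      }
    }
  }
})

test_that("aligned-path plot export writes an image file", {
  tracks <- list(track(cbind(0:5, 0)), track(cbind(0, 0:5)))
  f <- withr::local_tempfile(fileext = ".png")
  plot_aligned_tracks(tracks, file = f)
  expect_true(file.exists(f) && file.info(f)$size > 0)
  expect_error(plot_aligned_tracks(tracks, file = "x.bmp"), "png or .svg")
})
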