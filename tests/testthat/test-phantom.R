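test_that("phantom masks carry their designed truth", {
  # disk: aspect ratio 1 by symmetry
  disk <- make_platelet_mask(phantom_spec(20, 20))
  expect_equal(disk$truth$aspect_ratio, 1.0)
  expect_equal(disk$truth$n_filopodia, 0L)
  # designed ratio a/b
  ell <- make_platelet_mask(phantom_spec(30, 15))
  expect_equal(ell$truth$aspect_ratio, 2.0)
  # designed filopodia count
  fil <- make_platelet_mask(phantom_spec(20, 20, n_filopodia = 5,
                                         filopodium_length = 15))
  expect_equal(fil$truth$n_filopodia, 5L)
  # analytic area matches rasterization within discretization tolerance
  for (ph in list(disk, ell, fil)) {
    realized <- sum(ph$mask$pixels)
    expect_lt(abs(realized - ph$truth$area) / ph$truth$area, 0.06)
  }
})

test_that("phantom masks are single 8-connected hole-free components", {
  for (seed in 1:8) {
    nf <- seed %% 6
    ph <- make_platelet_mask(phantom_spec(18, 12, orientation = seed,
                                          n_filopodia = nf,
                                          filopodium_length = 12, seed = seed))
    lab <- platemorph:::cpp_label(ph$mask$pixels, 8L)
    expect_equal(max(lab), 1)
    filled <- platemorph:::cpp_fill_holes(ph$mask$pixels)
    expect_identical(filled, ph$mask$pixels)
  }
})

test_that("phantom generators are deterministic and validate invariants", {
  a <- make_platelet_mask(phantom_spec(15, 10, n_filopodia = 3, seed = 7))
  b <- make_platelet_mask(phantom_spec(15, 10, n_filopodia = 3, seed = 7))
  expect_identical(a$mask$pixels, b$mask$pixels)
  expect_error(phantom_spec(10, 15), "a >= b")
  expect_error(phantom_spec(10, 5, n_filopodia = 2, filopodium_width = 6),
               "filopodium_width")
  expect_error(make_platelet_mask(phantom_spec(20, 20), canvas = c(30, 30)),
               "canvas too small")
  # crowding violates the angular-separation invariant
  expect_error(make_platelet_mask(
    phantom_spec(8, 6, n_filopodia = 8, filopodium_width = 5)),
    "separated")
})

test_that("degenerate phase render is an affine transform of the mask", {
  ph <- make_platelet_mask(phantom_spec(12, 9))
  img <- render_image(ph$mask, render_spec(halo_amplitude = 0, blur_sigma = 0,
                                           noise_sd = 0), seed = 1)
  vals <- sort(unique(as.vector(img$pixels)))
  expect_length(vals, 2)
  # body darker than background
  expect_lt(mean(img$pixels[ph$mask$pixels]),
            mean(img$pixels[!ph$mask$pixels]))
  # affine: foreground/background each constant
  expect_equal(sd(img$pixels[ph$mask$pixels]), 0)
})

test_that("phase render shows a bright halo around the outline", {
  ph <- make_platelet_mask(phantom_spec(12, 9))
  img <- render_image(ph$mask, render_spec(halo_amplitude = 0.3,
                                           blur_sigma = 0, noise_sd = 0),
                      seed = 1)
  ring <- platemorph:::binary_dilate1(ph$mask$pixels) & !ph$mask$pixels
  bg_far <- img$pixels[1:5, 1:5]
  expect_gt(mean(img$pixels[ring]), mean(bg_far))
  expect_lt(mean(img$pixels[ph$mask$pixels]), mean(bg_far))
})

test_that("fluorescence render recovers the mask within a blur band", {
  ph <- make_platelet_mask(phantom_spec(15, 10, seed = 3))
  img <- render_image(ph$mask, render_spec(mode = "fluorescence",
                                           blur_sigma = 1, noise_sd = 0,
                                           background_gradient = 0), seed = 1)
  rec <- img$pixels > (max(img$pixels) + min(img$pixels)) / 2
  expect_true(within_band(rec, ph$mask$pixels, k = 2))
})

test_that("renders are deterministic for a fixed seed and leave the RNG alone", {
  ph <- make_platelet_mask(phantom_spec(12, 9))
  set.seed(123); before <- runif(1)
  set.seed(123)
  a <- render_image(ph$mask, render_spec(noise_sd = 0.1), seed = 5)
  after <- runif(1)
  b <- render_image(ph$mask, render_spec(noise_sd = 0.1), seed = 5)
  expect_identical(a$pixels, b$pixels)
  expect_identical(before, after)
  d <- render_image(ph$mask, render_spec(noise_sd = 0.1), seed = 6)
  expect_false(identical(a$pixels, d$pixels))
})

test_that("spreading sequences follow the designed two-phase trajectory", {
  ss <- make_spreading_sequence(initial_area = 100, idle_frames = 3,
                                fast_rate = 50, slow_rate = 5,
                                switch_frame = 6, n_frames = 10)
  expect_equal(ss$truth$designed_area[1:3], rep(100, 3))
  # 4 fast frames gain 200
  expect_equal(ss$truth$designed_area[7] - ss$truth$designed_area[3], 200)
  # slow phase
  expect_equal(diff(ss$truth$designed_area[8:10]), rep(5, 2))
  # realized areas within discretization tolerance per frame
  realized <- vapply(ss$masks, function(m) sum(m$pixels), numeric(1))
  expect_true(all(abs(realized - ss$truth$designed_area) /
                    ss$truth$designed_area < 0.08))
  expect_error(make_spreading_sequence(idle_frames = 5, switch_frame = 4),
               "parameter error")
  expect_error(make_spreading_sequence(fast_rate = 5, slow_rate = 10),
               "parameter error")
})

test_that("migration sequences realize the designed paths", {
  # straight: accumulated distance 9 steps x 5 px
  sq <- make_migration_sequence(motion_spec("straight", speed = 5,
                                            n_frames = 10, seed = 2))
  d <- diff(as.matrix(sq$truth[, c("x", "y")]))
  expect_equal(sum(sqrt(rowSums(d^2))), 45)
  # collinear, equally spaced
  expect_true(all(abs(sqrt(rowSums(d^2)) - 5) < 1e-9))
  expect_lt(max(abs(d[, 1] / sqrt(rowSums(d^2)) -
                    d[1, 1] / sqrt(sum(d[1, ]^2)))), 1e-9)
  # stationary: zero displacement
  st <- make_migration_sequence(motion_spec("stationary", n_frames = 5))
  expect_equal(max(dist(as.matrix(st$truth[, c("x", "y")]))), 0)
  # isotropic: fixed step length
  iso <- make_motion_path(motion_spec("isotropic_random", speed = 5,
                                      n_frames = 50, seed = 4))
  steps <- sqrt(rowSums(diff(iso)^2))
  expect_true(all(abs(steps - 5) < 1e-9))
  # masks exist for each frame, one component each
  expect_length(sq$masks, 10)
  expect_true(all(vapply(sq$masks, function(m)
    max(platemorph:::cpp_label(m$pixels, 8L)) == 1, logical(1))))
})

test_that("segmentation set generator is deterministic with designed truth", {
  s1 <- make_segmentation_set(3, seed = 9)
  s2 <- make_segmentation_set(3, seed = 9)
  expect_identical(s1[[2]]$phase$pixels, s2[[2]]$phase$pixels)
  expect_identical(s1[[2]]$truth$pixels, s2[[2]]$truth$pixels)
  expect_true(all(vapply(s1, function(p)
    sum(p$truth$pixels) > 0 && all(dim(p$phase$pixels) == c(64, 64)),
    logical(1))))
  # every 10th pair is an empty platelet-free field
  s10 <- make_segmentation_set(10, seed = 9)
  expect_equal(sum(s10[[10]]$truth$pixels), 0)
  expect_null(s10[[10]]$spec)
})
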