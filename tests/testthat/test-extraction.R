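test_that("background of a constant-depth video is that constant", {
  rec <- depth_recording(array(600, c(5, 8, 8)), floor_depth_mm = 600)
  expect_true(all(estimate_background(rec, 5) == 600))
})

test_that("background estimation ignores a moving animal", {
  arena <- test_arena(120, 120)
  track <- simulate_track(150, arena, seed = 2, speed_mm = 6)
  rec <- render_depth_video(track, arena, noise_sd_mm = 0, seed = 2)
  bg <- estimate_background(rec, 50)
  expect_lt(max(abs(bg - arena$floor_depth_mm)), 1)
})

test_that("asking for more background frames than exist is an error", {
  rec <- depth_recording(array(600, c(3, 4, 4)), floor_depth_mm = 600)
  expect_error(estimate_background(rec, 10), "exceeds")
  empty <- depth_recording(array(600, c(0, 4, 4)), floor_depth_mm = 600)
  expect_error(estimate_background(empty, 1), "empty")
})

test_that("a frame equal to background yields an empty mask", {
  bg <- matrix(650, 20, 20)
  expect_false(any(segment_animal(bg, bg)))
})

test_that("segmentation keeps only the largest component", {
  bg <- matrix(650, 40, 60)
  fr <- bg
  fr[5:28, 5:28] <- 600        # 576 px blob
  fr[35:39, 50:55] <- 600      # 30 px blob
  mask <- segment_animal(fr, bg, min_height_mm = 10, min_area_px = 20)
  expect_equal(sum(mask), 24 * 24)
  expect_true(all(which(mask, arr.ind = TRUE)[, 1] <= 28))
  # below the area floor: empty
  mask2 <- segment_animal(fr, bg, min_height_mm = 10, min_area_px = 1000)
  expect_false(any(mask2))
})

test_that("segmented area matches the analytic level set of the ellipsoid", {
  arena <- test_arena(160, 160)
  rec <- render_one(0.7, arena, body_length = 60, body_height = 40)
  mask <- segment_animal(rec$frames[1, , ], flat_background(arena),
                         min_height_mm = 10)
  # the 10 mm level set: elliptical cross-section scaled by the anterior
  # half; integrate the exact footprint area numerically at fine resolution
  a <- 30; c_ <- 30 * 0.45; h <- 40
  xs <- seq(-a, a, length.out = 2001)
  half_width <- function(u) {
    taper <- 1 - 0.2 * pmax(-u, 0) / a
    core <- 1 - (u / a)^2 - (10 / (h * taper))^2 * (1 - (u / a)^2)
    # solve h*taper*sqrt(1-(u/a)^2-(v/c)^2) = 10 for v
    inner <- 1 - (u / a)^2 - (10 / (h * taper))^2
    ifelse(inner > 0, c_ * sqrt(inner), 0)
  }
  area <- sum(2 * half_width(xs)) * diff(xs[1:2])
  expect_lt(abs(sum(mask) - area) / area, 0.10)
})

test_that("heading is recovered within 3 degrees given a near prior heading", {
  arena <- test_arena(160, 160)
  rec <- render_one(30 * pi / 180, arena)
  mask <- segment_animal(rec$frames[1, , ], flat_background(arena))
  hgt <- pmax(flat_background(arena) - rec$frames[1, , ], 0)
  al <- align_egocentric(hgt, mask, prev_heading = 25 * pi / 180)
  expect_lt(abs(al$heading - 30 * pi / 180), 3 * pi / 180)
})

test_that("empty masks give an invalid frame with an all-zero crop", {
  al <- align_egocentric(matrix(0, 30, 30), matrix(FALSE, 30, 30))
  expect_false(al$valid)
  expect_true(all(al$crop == 0))
})

test_that("a circularly symmetric blob falls back to the documented heading convention", {
  hgt <- matrix(0, 41, 41)
  for (i in 1:41) for (j in 1:41)
    hgt[i, j] <- max(0, 20 - ((i - 21)^2 + (j - 21)^2) / 10)
  al <- align_egocentric(hgt, hgt > 0)
  expect_true(al$valid)
  expect_true(is.finite(al$heading))
})

test_that("alignment is equivariant: translating the input translates the centroid only", {
  arena <- test_arena(160, 160)
  rec1 <- render_one(1.1, arena, x = 70, y = 75)
  rec2 <- render_one(1.1, arena, x = 90, y = 95)
  bg <- flat_background(arena)
  do_align <- function(rec) {
    mask <- segment_animal(rec$frames[1, , ], bg)
    align_egocentric(pmax(bg - rec$frames[1, , ], 0), mask,
                     prev_heading = 1.1)
  }
  a1 <- do_align(rec1); a2 <- do_align(rec2)
  expect_equal(a2$centroid_xy - a1$centroid_xy, c(20, 20), tolerance = 0.2)
  expect_lt(mean(abs(a2$crop - a1$crop)), 0.1)
})

test_that("crops are invariant to rotating the scene about the centroid", {
  arena <- test_arena(160, 160)
  bg <- flat_background(arena)
  r0 <- render_one(0.4, arena, x = 80, y = 80)$frames[1, , ]
  r90 <- render_one(0.4 + pi / 2, arena, x = 80, y = 80)$frames[1, , ]
  a0 <- align_egocentric(pmax(bg - r0, 0), segment_animal(r0, bg),
                         prev_heading = 0.4)
  a90 <- align_egocentric(pmax(bg - r90, 0), segment_animal(r90, bg),
                          prev_heading = 0.4 + pi / 2)
  expect_lt(mean(abs(a0$crop - a90$crop)), 1)
})

test_that("centroid and heading tracks recover ground truth on a smooth synthetic video", {
  arena <- test_arena(192, 192)
  track <- simulate_track(150, arena, seed = 12)
  rec <- render_depth_video(track, arena, noise_sd_mm = 1, seed = 12)
  video <- extract_poses(rec, crop_size = c(64, 64))
  expect_true(all(video$valid))
  rms <- sqrt(mean((video$centroid_xy[, 1] - track$x_mm)^2 +
                     (video$centroid_xy[, 2] - track$y_mm)^2))
  expect_lt(rms, 1)
  cd <- ((video$heading - track$heading_rad + pi) %% (2 * pi)) - pi
  expect_lt(sqrt(mean(cd^2)) * 180 / pi, 5)
})

test_that("spine profile of a constant-height rectangular blob is constant", {
  crop <- matrix(0, 30, 40)
  crop[10:20, 5:35] <- 30
  expect_equal(spine_height_profile(crop, 8), rep(30, 8))
  expect_length(spine_height_profile(crop, 2), 2)
})

test_that("spine profile of the rendered animal peaks near the middle at its body height", {
  arena <- test_arena(160, 160)
  rec <- render_one(0, arena, body_height = 40)
  bg <- flat_background(arena)
  mask <- segment_animal(rec$frames[1, , ], bg)
  al <- align_egocentric(pmax(bg - rec$frames[1, , ], 0), mask,
                         crop_size = c(80, 80), prev_heading = 0)
  pr <- spine_height_profile(al$crop, 21)
  expect_lt(abs(max(pr) - 40) / 40, 0.05)
  expect_gt(which.max(pr), 7)
  expect_lt(which.max(pr), 15)
})

test_that("spine profile of an empty crop is all zero", {
  expect_equal(spine_height_profile(matrix(0, 10, 10), 5), rep(0, 5))
})
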