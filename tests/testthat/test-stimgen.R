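test_that("rendered sequences keep shape, bounds and determinism", {
  sp <- stimulus_spec(width = 120, height = 60, duration = 20,
                      target_size = c(10, 30), target_grey = 255,
                      target_velocity = 27,
                      background_kind = "procedural_clutter",
                      background_velocity = -20, texture_seed = 7)
  f1 <- render_stimulus(sp)
  f2 <- render_stimulus(sp)
  expect_equal(dim(f1), c(60, 120, 20))
  expect_true(all(f1 >= 0 & f1 <= 255))
  expect_identical(unclass(f1), unclass(f2))
  sp2 <- sp; sp2$texture_seed <- 8L
  expect_false(identical(unclass(f1), unclass(render_stimulus(sp2))))
})

test_that("zero velocity gives identical frames", {
  sp <- stimulus_spec(width = 80, height = 60, duration = 8,
                      target_size = c(10, 20), target_grey = 0,
                      target_velocity = 0)
  fr <- render_stimulus(sp)
  for (t in 2:8) expect_identical(fr[, , t], fr[, , 1])
  spc <- stimulus_spec(width = 80, height = 60, duration = 8,
                       target_kind = "none",
                       background_kind = "procedural_clutter",
                       background_velocity = 0)
  frc <- render_stimulus(spc)
  for (t in 2:8) expect_identical(frc[, , t], frc[, , 1])
})

test_that("target centroid tracks the analytic trajectory", {
  # 9 deg/s at 0.25 deg/px and 30 fps is exactly 1.2 px/frame
  sp <- stimulus_spec(width = 200, height = 60, duration = 40,
                      target_size = c(11, 21), target_grey = 255,
                      target_velocity = 9, background_grey = 0,
                      target_start = c(30, 30))
  expect_equal(px_per_frame(9, sp), 1.2)
  fr <- render_stimulus(sp)
  centroids <- sapply(seq_len(40), function(t) {
    cols <- which(colSums(fr[, , t]) > 0)
    mean(cols)
  })
  analytic <- 30 + 1.2 * (0:39)
  expect_true(all(abs(centroids - analytic) <= 0.5 + 1e-9))
  # whole-sequence displacement within one pixel of the analytic value
  expect_lt(abs((centroids[40] - centroids[1]) - 1.2 * 39), 1)
})

test_that("leftward render mirrors rightward render on uniform ground", {
  C <- 121
  right <- stimulus_spec(width = C, height = 41, duration = 15,
                         target_size = c(9, 15), target_grey = 200,
                         target_velocity = 18, background_grey = 40,
                         target_start = c(30.2, 21))
  left <- right
  left$target_velocity <- -18
  left$target_start <- c(C + 1 - 30.2, 21)
  fr <- render_stimulus(right)
  fl <- render_stimulus(left)
  expect_equal(unclass(mirror_frames(fr)), unclass(fl),
               ignore_attr = TRUE)
})

test_that("centred discs are mirror symmetric and clamp at the field edge", {
  sp <- stimulus_spec(width = 100, height = 70, duration = 30,
                      target_kind = "disc", target_axis = "depth",
                      target_grey = 0, radius_start = 5,
                      target_velocity = 7.5,  # 1 px/frame growth
                      background_grey = 128)
  fr <- render_stimulus(sp)
  for (t in c(1, 10, 20, 30)) {
    expect_identical(fr[, , t], fr[, 100:1, t])
    expect_identical(fr[, , t], fr[70:1, , t])
  }
  big <- sp; big$radius_start <- 40
  expect_warning(render_stimulus(big), "clamped")
})

test_that("clutter background scrolls at the commanded sub-pixel rate", {
  sp_args <- list(width = 240, height = 60, texture_seed = 3,
                  background_velocity = -20, degrees_per_pixel = 0.25,
                  fps = 30, duration = 31)
  fr <- do.call(render_clutter_background, sp_args)
  # phase-correlation oracle: best integer lag between consecutive frames
  best_lag <- function(a, b, max_lag = 6) {
    pa <- colMeans(a); pb <- colMeans(b)
    lags <- -max_lag:max_lag
    sc <- sapply(lags, function(l) {
      ib <- ((seq_along(pa) - 1 + l) %% length(pa)) + 1
      stats::cor(pa, pb[ib])
    })
    lags[which.max(sc)]
  }
  lags <- sapply(1:30, function(t) best_lag(fr[, , t], fr[, , t + 1]))
  expect_equal(mean(lags), -20 / (0.25 * 30), tolerance = 0.15)
})

test_that("oversized targets and empty sequences are rejected", {
  expect_error(stimulus_spec(width = 50, height = 50,
                             target_size = c(60, 10)), "larger")
  expect_error(stimulus_spec(duration = 0), "duration")
  expect_error(stimulus_spec(fps = 0), "fps")
})
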