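test_that("wide-field pooling and opponency match direct sums", {
  z <- matrix(0, 5, 5)
  T4 <- list(r = z, l = z, d = z, u = z)
  T5 <- T4
  expect_equal(pool_lptc(T4, T5), c(r = 0, l = 0, d = 0, u = 0))
  T4$r[2, 3] <- 2; T5$r[4, 4] <- 3
  expect_equal(pool_lptc(T4, T5), c(r = 5, l = 0, d = 0, u = 0))
  set.seed(3)
  T4 <- lapply(T4, function(m) matrix(rnorm(25), 5, 5))
  T5 <- lapply(T5, function(m) matrix(rnorm(25), 5, 5))
  LP <- pool_lptc(T4, T5)
  for (d in names(LP))
    expect_equal(unname(LP[d]), sum(T4[[d]]) + sum(T5[[d]]), tolerance = 1e-12)
  expect_equal(opponency(c(r = 5, l = 2, d = 4, u = 1)),
               c(HS_raw = 3, VS_raw = 3))
  expect_equal(opponency(c(r = 2, l = 2, d = 0, u = 0)),
               c(HS_raw = 0, VS_raw = 0))
})

test_that("sigmoid activation is odd, bounded, increasing and exact", {
  p <- model_params()  # k = 0.01
  C <- 320; R <- 180   # C * R * k = 576
  expect_equal(activate(0, p, C, R), 0)
  expect_equal(activate(576, p, C, R),
               2 * (1 / (1 + exp(-1)) - 0.5), tolerance = 1e-12)
  expect_equal(activate(576, p, C, R), 0.46212, tolerance = 1e-5)
  x <- c(-1e12, -1e6, -1e3, -1, 0, 1, 1e3, 1e6, 1e12)
  f <- activate(x, p, C, R)
  expect_equal(f, -rev(f), tolerance = 1e-12)       # odd
  # bounded by one; the extreme arguments saturate to exactly 1 in doubles
  expect_true(all(abs(f) <= 1))
  expect_true(all(diff(f) >= 0))
  # strictly inside (-1, 1) and strictly increasing below saturation
  xm <- seq(-2000, 2000, by = 250)
  fm <- activate(xm, p, C, R)
  expect_true(all(abs(fm) < 1))
  expect_true(all(diff(fm) > 0))
  expect_error(activate(1, p, 0, 10), "non-zero")
})

test_that("the full model is silent on static input and on frame one", {
  p <- model_params()
  frames <- array(137, c(30, 40, 10))
  resp <- run_model(frames, p)
  expect_equal(resp$HS, rep(0, 10))
  expect_equal(resp$VS, rep(0, 10))
  set.seed(2)
  noisy <- array(runif(30 * 40 * 4, 0, 255), c(30, 40, 4))
  r2 <- run_model(noisy, p)
  expect_equal(r2$HS[1], 0)
  expect_equal(r2$VS[1], 0)
})

test_that("a rightward bar on clean ground drives HS positive, VS silent", {
  p <- model_params()
  sp <- stimulus_spec(width = 120, height = 80, duration = 30,
                      target_size = c(12, 50), target_grey = 0,
                      target_velocity = 27, background_grey = 200)
  resp <- run_model(render_stimulus(sp), p)
  w <- crossing_window(sp)
  expect_gt(median(resp$HS[w]), 0)
  expect_lt(abs(median(resp$VS[w])), 0.1 * median(resp$HS[w]) + 1e-15)
})

test_that("mirroring the input negates the matching opponent output exactly", {
  p <- model_params()
  set.seed(9)
  frames <- array(runif(40 * 60 * 8, 0, 255), c(40, 60, 8))
  base <- run_model(frames, p)
  hm <- run_model(mirror_frames(frames, "horizontal"), p)
  expect_equal(hm$HS, -base$HS, tolerance = 1e-9)
  expect_equal(hm$VS, base$VS, tolerance = 1e-9)
  vm <- run_model(mirror_frames(frames, "vertical"), p)
  expect_equal(vm$VS, -base$VS, tolerance = 1e-9)
  expect_equal(vm$HS, base$HS, tolerance = 1e-9)
})

test_that("response statistics summarise the requested window", {
  p <- model_params()
  sp <- stimulus_spec(width = 100, height = 60, duration = 20,
                      target_size = c(10, 30), target_grey = 0,
                      target_velocity = 27, background_grey = 200)
  resp <- run_model(render_stimulus(sp), p)
  st <- response_stats(resp, 5:15)
  expect_equal(st$median_HS, median(resp$HS[5:15]))
  expect_equal(st$var_VS, var(resp$VS[5:15]))
})
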