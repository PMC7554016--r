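test_that("delay maps hit their limits and fixed points", {
  p <- model_params()
  M <- matrix(runif(20, 0, 4), 4, 5)
  prev <- matrix(runif(20, 0, 4), 4, 5)
  # alpha3 at the slowest pair
  a3 <- p$tau_i / (p$tau_i + 200)
  expect_equal(a3, 0.14286, tolerance = 1e-4)
  expect_equal(delay_map(M, prev, 200, p), a3 * M + (1 - a3) * prev)
  # tau_s -> 0 removes the delay entirely
  expect_equal(delay_map(M, prev, 0, p), M)
  # constant signal is a fixed point
  expect_equal(delay_map(M, M, 137, p), M)
})

test_that("a rightward-stepping ON pulse drives T4_r and not T4_l", {
  p <- model_params(n_c = 1)  # single correlator at distance sd = 4
  z <- matrix(0, 3, 20)
  m1 <- z; m1[2, 5] <- 1    # pulse at column 5
  m2 <- z; m2[2, 9] <- 1    # pulse moved right by sd
  st <- delay_state(z, p)
  s1 <- delay_step(m1, st, p)
  s2 <- delay_step(m2, s1$state, p)
  T4 <- t4_responses(m2, s2$Mhat, p)
  expect_gt(T4$r[2, 5], 0)   # delayed trace at 5 times current at 9
  expect_equal(sum(T4$l), 0) # no leftward pairing exists for this step
  expect_gt(sum(T4$r), sum(T4$l))
  expect_equal(T4$d, z)
  expect_equal(T4$u, z)
})

test_that("correlator maps stay non-negative for non-negative inputs and
           swap direction under mirroring", {
  p <- model_params()
  set.seed(11)
  M <- matrix(runif(25 * 30), 25, 30)
  Mhat <- lapply(1:4, function(i) matrix(runif(25 * 30), 25, 30))
  T4 <- t4_responses(M, Mhat, p)
  for (d in c("r", "l", "d", "u")) expect_true(all(T4[[d]] >= 0))
  # horizontal flip of all inputs exchanges the rightward and leftward
  # responses; per pixel the exchanged map is shifted by the pair distance,
  # so the exact identity holds for the wide-field sums
  flip <- function(m) m[, ncol(m):1]
  T4f <- t4_responses(flip(M), lapply(Mhat, flip), p)
  expect_equal(sum(T4f$r), sum(T4$l), tolerance = 1e-12)
  expect_equal(sum(T4f$l), sum(T4$r), tolerance = 1e-12)
  expect_equal(sum(T4f$d), sum(T4$d), tolerance = 1e-12)
  # vertical flip exchanges down and up
  vflip <- function(m) m[nrow(m):1, ]
  T4v <- t4_responses(vflip(M), lapply(Mhat, vflip), p)
  expect_equal(sum(T4v$d), sum(T4$u), tolerance = 1e-12)
  expect_equal(sum(T4v$u), sum(T4$d), tolerance = 1e-12)
  # T5 shares the identical contract
  expect_equal(t5_responses(M, Mhat, p), T4)
})

test_that("zero medulla input yields zero DS maps", {
  p <- model_params()
  z <- matrix(0, 8, 8)
  T4 <- t4_responses(z, rep(list(z), 4), p)
  for (d in c("r", "l", "d", "u")) expect_equal(T4[[d]], z)
})

test_that("C++ correlator matches the per-pixel loop oracle", {
  p <- model_params(sd = 4, n_c = 2)
  set.seed(5)
  for (i in 1:3) {
    M <- matrix(rnorm(20 * 20), 20, 20)
    Mhat <- lapply(1:2, function(j) matrix(rnorm(20 * 20), 20, 20))
    fast <- t4_responses(M, Mhat, p)
    slow <- naive_ds_maps(M, Mhat, c(4L, 8L))
    for (d in c("r", "l", "d", "u"))
      expect_equal(fast[[d]], slow[[d]], tolerance = 1e-10)
  }
})
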