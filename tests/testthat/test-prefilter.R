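test_that("retina output is zero for constant input and decays a step", {
  p <- model_params()  # n_p = 2
  z <- matrix(100, 6, 6)
  st <- retina_state(z, p)
  for (i in 1:4) {
    out <- retina_step(z, st, p)
    st <- out$state
    expect_equal(out$P, matrix(0, 6, 6))
  }
  # single-pixel step of +10, then constant: P decays by a_i recursion
  a <- decay_coefficients(2)
  f2 <- z; f2[3, 3] <- 110
  out <- retina_step(f2, st, p); st <- out$state
  expect_equal(out$P[3, 3], 10)
  out <- retina_step(f2, st, p); st <- out$state
  expect_equal(out$P[3, 3], a[1] * 10, tolerance = 1e-12)
  expect_equal(out$P[3, 3], 2.6894, tolerance = 1e-4)
  out <- retina_step(f2, st, p)
  expect_equal(out$P[3, 3], a[1]^2 * 10 + a[2] * 10, tolerance = 1e-12)
  expect_error(retina_step(matrix(0, 3, 3), st, p), "shape")
})

test_that("vDoG kernels and responses match their closed forms", {
  p <- model_params()
  kk <- flyvis:::vdog_kernels(p)
  expect_equal(dim(kk$e), c(5, 5))
  expect_equal(dim(kk$i), c(9, 9))
  expect_equal(kk$e[3, 3], 1 / (8 * pi), tolerance = 1e-12)
  expect_equal(kk$e[3, 3], 0.039789, tolerance = 1e-5)
  expect_equal(kk$i[5, 5], 1 / (32 * pi), tolerance = 1e-12)
  expect_equal(vdog(matrix(0, 10, 10), p), matrix(0, 10, 10))
  # uniform positive input: interior response is c * (S_e - S_i), positive sign
  S_e <- sum(kk$e); S_i <- sum(kk$i)
  LA <- vdog(matrix(3, 15, 15), p)
  expect_equal(LA[8, 8], 3 * abs(S_e - S_i), tolerance = 1e-12)
  expect_equal(vdog(matrix(-3, 15, 15), p)[8, 8], -3 * abs(S_e - S_i),
               tolerance = 1e-12)
})

test_that("vDoG agrees with the brute-force oracle on random input", {
  p <- model_params()
  set.seed(42)
  for (i in 1:3) {
    P <- matrix(rnorm(20 * 20, sd = 10), 20, 20)
    expect_equal(vdog(P, p), naive_vdog(P, p), tolerance = 1e-10)
  }
})

test_that("half-wave rectification splits ON and OFF exclusively", {
  expect_equal(rectify(matrix(5, 1, 1)), list(L1 = matrix(5, 1, 1),
                                              L2 = matrix(0, 1, 1)))
  expect_equal(rectify(matrix(-3, 1, 1)), list(L1 = matrix(0, 1, 1),
                                               L2 = matrix(3, 1, 1)))
  set.seed(1)
  LA <- matrix(rnorm(300), 15, 20)
  rl <- rectify(LA)
  expect_true(all(rl$L1 >= 0))
  expect_true(all(rl$L2 >= 0))
  expect_equal(rl$L1 * rl$L2, matrix(0, 15, 20))
  expect_equal(rl$L1 - rl$L2, LA)
})

test_that("contrast-polarity inversion swaps the ON and OFF maps exactly", {
  p <- model_params()
  set.seed(7)
  frames <- array(runif(12 * 12 * 5, 0, 255), c(12, 12, 5))
  run_maps <- function(fr) {
    st <- retina_state(fr[, , 1], p)
    out <- NULL
    for (t in 2:5) {
      s <- retina_step(fr[, , t], st, p); st <- s$state
      out <- rectify(vdog(s$P, p))
    }
    out
  }
  a <- run_maps(frames)
  b <- run_maps(255 - frames)
  expect_equal(a$L1, b$L2, tolerance = 1e-12)
  expect_equal(a$L2, b$L1, tolerance = 1e-12)
})

test_that("FDSR suppresses sustained input and is exact on the step response", {
  p <- model_params(fdsr_recursive = TRUE)
  z <- matrix(0, 4, 4)
  st <- adapt_state(z, z)
  L <- matrix(8, 4, 4)
  # first presentation: trace jumps to alpha1 * L, M = (1 - alpha1) * L
  out <- fdsr_step(L, z, st, p)
  expect_equal(out$M1[1, 1], (1 - p$alpha1) * 8, tolerance = 1e-12)
  expect_equal(out$M2, z)
  # sustained input: M shrinks geometrically with factor (1 - alpha1)
  prev <- out$M1[1, 1]
  st <- out$state
  for (i in 1:4) {
    out <- fdsr_step(L, z, st, p); st <- out$state
    expect_equal(out$M1[1, 1] / prev, 1 - p$alpha1, tolerance = 1e-8)
    prev <- out$M1[1, 1]
  }
  # literal (FIR) variant passes a fixed share of each increment
  pl <- model_params(fdsr_recursive = FALSE)
  st <- adapt_state(z, z)
  out <- fdsr_step(L, z, st, pl)
  expect_equal(out$M1, (1 - pl$alpha1) * L, tolerance = 1e-12)
  out <- fdsr_step(L, z, out$state, pl)   # no further change: M = 0
  expect_equal(out$M1, z, tolerance = 1e-12)
  # falling input engages the slow branch
  out <- fdsr_step(z, z, out$state, pl)
  expect_equal(out$M1, -(1 - pl$alpha2) * L, tolerance = 1e-12)
})
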