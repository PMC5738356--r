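test_that("sinusoid and sawtooth have the declared shape and period", {
  s <- sup_sinusoid(5)
  # zeros at multiples of the half period, peak at the quarter period
  expect_equal(drop(s$eval(c(0, 0.1, 0.2))), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(drop(s$eval(0.05)), 1)
  expect_equal(s$T, 0.2)

  sw <- sup_sawtooth(5)
  x <- drop(sw$eval(seq(0, 0.199, by = 0.001)))
  expect_equal(min(x), -1, tolerance = 0.02)
  expect_equal(max(x), 1, tolerance = 0.02)
  expect_true(all(diff(x[1:199]) > 0)) # rising ramp within a period
  expect_equal(drop(sw$eval(0.2)), drop(sw$eval(0)))
})

test_that("product of sinusoids has period 0.5 s and the stated noise level", {
  s <- sup_product_of_sines()
  tt <- seq(0, 1, by = 0.002)
  expect_equal(drop(s$eval(tt)), sin(2 * pi * 4 * tt) * sin(2 * pi * 6 * tt))
  expect_equal(s$T, 0.5)

  sn <- sup_product_of_sines(noise_sd = 0.05)
  set.seed(1)
  d <- drop(sn$eval(tt)) - drop(s$eval(tt))
  expect_equal(var(d), 0.0025, tolerance = 0.3)
})

test_that("Van der Pol supervisor is rescaled into the unit square", {
  v <- sup_van_der_pol(0.3)
  tt <- seq(0, 2, by = 0.001)
  x <- v$eval(tt)
  expect_equal(nrow(x), 2)
  expect_lte(max(abs(x)), 1 + 1e-6)
  # classical small-mu limit-cycle amplitude ~ 2 before rescaling
  expect_equal(attr(v, "amplitude_unscaled"), 2, tolerance = 0.1)
  # periodicity
  expect_equal(v$eval(0.05), v$eval(0.05 + v$T), tolerance = 1e-3)
  # relaxation regime integrates and stays bounded too
  v5 <- sup_van_der_pol(5)
  expect_lte(max(abs(v5$eval(tt))), 1 + 1e-6)
})

test_that("Lorenz supervisor: bounded attractor, positive z, sensitivity", {
  lz_raw <- sup_lorenz(duration_s = 20, normalize = FALSE)
  tt <- seq(0, 20, by = 0.01)
  X <- lz_raw$eval(tt)
  expect_true(all(is.finite(X)))
  expect_true(all(X[3, ] > 0)) # z stays positive on the attractor
  expect_lt(max(abs(X[1:2, ])), 30)
  # both wings are visited
  expect_gt(sum(diff(sign(X[1, ])) != 0), 4)

  lz <- sup_lorenz(duration_s = 20)
  expect_lte(max(abs(lz$eval(tt))), 1 + 1e-9)

  # nearby initial conditions diverge (chaotic sensitivity)
  lz2 <- sup_lorenz(duration_s = 20, normalize = FALSE, y0 = c(1 + 1e-12, 1, 25))
  d <- sqrt(colSums((lz_raw$eval(tt) - lz2$eval(tt))^2))
  expect_lt(d[1], 1)
  expect_gt(max(d), 10)
})

test_that("note-song supervisor encodes pulses monophonically", {
  one <- sup_note_song(data.frame(note = "E", dur = "q"))
  tt <- seq(0.001, 0.249, by = 0.001)
  x <- one$eval(tt)
  expect_equal(dim(x), c(5, length(tt)))
  expect_true(all(x[3, ] > 0))          # E lives in component 3
  expect_true(all(x[-3, ] == 0))
  expect_equal(x[3, ], sin(2 * pi * 2 * tt)[seq_along(tt)], tolerance = 1e-9)

  song <- sup_note_song(ode_to_joy_score())
  expect_equal(song$T, 4)
  xs <- song$eval(seq(0, 3.999, by = 0.004))
  expect_true(all(colSums(xs > 1e-12) <= 1)) # monophonic
  expect_equal(sup_note_song(ode_to_joy_score(1))$T, 1)
  expect_error(sup_note_song(data.frame(note = "H", dur = "q")), "unknown note")
})

test_that("sine HDTS tiles time with single-component pulses", {
  h <- sup_hdts(2, 8, shape = "sine")
  centers <- 2 * (2 * (1:8) - 1) / 16
  xc <- h$eval(centers)
  expect_equal(diag(xc), rep(1, 8), tolerance = 1e-9)
  expect_equal(sum(xc) - sum(diag(xc)), 0)
  # one active component at generic interior times
  tt <- seq(0.01, 1.99, by = 0.013)
  act <- colSums(h$eval(tt) > 1e-12)
  expect_true(all(act == 1))
})

test_that("gaussian HDTS peaks at 1 in every subinterval centre", {
  h <- sup_hdts(1, 5, shape = "gaussian", sigma = 0.05)
  centers <- (2 * (1:5) - 1) / 10
  expect_equal(diag(h$eval(centers)), rep(1, 5))
})

test_that("pulse chains are contiguous, non-overlapping and equal-area", {
  pc <- sup_pulse_chain(K = 10, period_ms = 20)
  expect_equal(pc$T, 0.1)
  tt <- seq(5e-4, 0.0995, by = 1e-4)
  x <- pc$eval(tt)
  expect_true(all(colSums(x > 1e-9) <= 1))
  areas <- rowSums(x) * 1e-4
  expect_lt(diff(range(areas)) / mean(areas), 0.02)
  # 500 pulses of a 20 ms-period half wave span 5 s
  expect_equal(sup_pulse_chain(500, 20)$T, 5)
})

test_that("moving-blob movie supervisor emits unit-interval pixels", {
  mv <- sup_moving_blob(T_s = 2, side = 8)
  expect_equal(mv$m, 64)
  x <- mv$eval(seq(0, 1.9, by = 0.1))
  expect_true(all(x >= 0 & x <= 1))
  expect_gt(max(x), 0.9)
  expect_equal(mv$eval(0.3), mv$eval(2.3), tolerance = 1e-12)
  # the blob moves: frames differ
  expect_gt(max(abs(mv$eval(0.2) - mv$eval(0.7))), 0.5)
})

test_that("supervisor evaluation is pure apart from declared noise", {
  for (s in list(sup_sinusoid(3), sup_hdts(1, 4), sup_van_der_pol(0.3),
                 sup_moving_blob(1, 4))) {
    tt <- seq(0, 0.9, by = 0.05)
    expect_identical(s$eval(tt), s$eval(tt))
  }
})
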