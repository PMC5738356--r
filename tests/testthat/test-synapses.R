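test_that("single-exponential filter decays exactly", {
  fs <- filter_state(1)
  fs$r <- 1
  p <- synapse_params("single_exp", tau_s = 20)
  for (k in 1:100) fs <- update_filter(fs, logical(1), 0.5, p)
  expect_equal(fs$r, exp(-50 / 20), tolerance = 1e-12)
})

test_that("double-exponential impulse response: unit area and peak time", {
  dt <- 0.01
  p <- synapse_params("double_exp", tau_r = 2, tau_d = 20)
  fs <- update_filter(filter_state(1), 1L, dt, p)
  trace <- numeric(round(250 / dt))
  for (k in seq_along(trace)) {
    trace[k] <- fs$r
    fs <- update_filter(fs, logical(1), dt, p)
  }
  expect_equal(sum(trace) * dt, 1, tolerance = dt / 20)
  t_peak <- which.max(trace) * dt
  expect_equal(t_peak, log(10) * 40 / 18, tolerance = 0.1)
})

test_that("alpha filter is the tau_r = tau_d limit", {
  dt <- 0.01
  tau <- 5
  p <- synapse_params("alpha", tau_r = tau)
  fs <- update_filter(filter_state(1), 1L, dt, p)
  tt <- seq(dt, 40, by = dt)
  trace <- numeric(length(tt))
  for (k in seq_along(tt)) {
    fs <- update_filter(fs, logical(1), dt, p)
    trace[k] <- fs$r
  }
  expect_lt(max(abs(trace - tt / tau^2 * exp(-tt / tau))), 1e-6)
})

test_that("static weights honour sparsity and variance contracts", {
  N <- 1000; p <- 0.1
  om <- build_static_weights(N, p, "izhikevich", seed = 1)
  nz <- om@x
  frac <- length(nz) / N^2
  se <- sqrt(p * (1 - p) / N^2)
  expect_lt(abs(frac - p), 3 * se)
  # spiking contract: nonzero entries ~ N(0, 1/(N p^2))
  expect_lt(abs(var(nz) - 1 / (N * p^2)) / (1 / (N * p^2)), 0.1)

  om_r <- build_static_weights(N, p, "rate", seed = 1)
  expect_lt(abs(var(om_r@x) - 1 / (N * p)^2) / (1 / (N * p)^2), 0.1)

  # LIF/theta are globally mean-centred to machine precision
  om_l <- build_static_weights(400, p, "lif", seed = 2)
  expect_lt(abs(sum(om_l@x)), 1e-9)
  om_t <- build_static_weights(400, p, "theta", seed = 2)
  expect_lt(abs(sum(om_t@x)), 1e-9)
  # Izhikevich is not centred
  om_i <- build_static_weights(400, p, "izhikevich", seed = 2)
  expect_gt(abs(sum(om_i@x)), 1e-6)

  expect_error(build_static_weights(100, 0, "lif"), "sparsity")
  expect_error(build_static_weights(100, 1.5, "lif"), "sparsity")
})

test_that("per-row centring zeroes every row sum", {
  om <- build_static_weights(200, 0.2, "izhikevich", seed = 3, mean_zero = "row")
  expect_lt(max(abs(Matrix::rowSums(om))), 1e-10)
})

test_that("effective weights compose the rank-m decomposition", {
  N <- 30; m <- 2
  set.seed(1)
  om0 <- build_static_weights(N, 0.3, "lif")
  eta <- matrix(runif(N * m, -1, 1), N, m)
  phi <- matrix(rnorm(N * m), N, m)

  expect_equal(effective_weights(om0, 2, 5, eta, matrix(0, N, m)),
               as.matrix(2 * om0))
  # G = 0, single nonzero outer product entry
  e1 <- matrix(0, N, 1); e1[1] <- 1
  e2 <- matrix(0, N, 1); e2[2] <- 1
  om <- effective_weights(Matrix::Matrix(0, N, N, sparse = TRUE), 0, 7, e1, e2)
  expect_equal(om[1, 2], 7)
  expect_equal(sum(om != 0), 1)
  # learned component has rank <= m
  om <- effective_weights(om0, 1.5, 3, eta, phi)
  expect_lte(qr(om - as.matrix(1.5 * om0))$rank, m)
  # linear in phi
  om2 <- effective_weights(om0, 1.5, 3, eta, 2 * phi)
  expect_equal(om2 - as.matrix(1.5 * om0), 2 * (om - as.matrix(1.5 * om0)))
  expect_error(effective_weights(om0, 1, 1, eta, phi[-1, ]), "shape")
})

test_that("suggested feedback gain is linear and vanishes without activity", {
  expect_equal(suggested_Q(2, 0.5, 10), 2 * suggested_Q(1, 0.5, 10))
  expect_equal(suggested_Q(3, 1, 0), 0)
  expect_error(suggested_Q(-1, 1, 1))
})

test_that("static matrix spectral radius scales with G", {
  set.seed(4)
  om <- build_static_weights(300, 0.1, "izhikevich")
  r1 <- max(Mod(eigenspectrum(as.matrix(om))))
  r3 <- max(Mod(eigenspectrum(as.matrix(3 * om))))
  expect_equal(r3 / r1, 3, tolerance = 1e-8)
})

test_that("the Q heuristic lands within an order of magnitude of the
           working theta feedback gain", {
  # measure the rms filtered rate from a short trained theta run, then
  # compare the suggested gain with the preset's Q = 1e4
  fit <- force_train(sup_sinusoid(5), model = "theta", N = 500, G = 10,
                     Q = 1e4, rls_lambda = 0.01,
                     neuron = neuron_params("theta", t_scale = 1e-3),
                     schedule = train_schedule(1, 1, 0.5, 0.01, 0.5),
                     seed = 13)
  rate_rms_hz <- 1000 * sqrt(mean(drop(fit$state_final$r)^2))
  sigma_scaled <- sqrt(500) * fit$weights$sigma_omega # root-N-scaled spread
  Qs <- suggested_Q(10, sigma_scaled, rate_rms_hz)
  expect_gt(Qs, 1e3)
  expect_lt(Qs, 1e5)
})
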