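test_that("mean firing rate is spikes over N times time", {
  raster <- data.frame(time_ms = seq(1, 5000, length.out = 229000 / 100),
                       neuron = rep(1:20, length.out = 2290))
  expect_equal(mean_firing_rate(raster, c(0, 5000), N = 20), 22.9)
  expect_equal(mean_firing_rate(data.frame(time_ms = numeric(0),
                                           neuron = integer(0)),
                                c(0, 1000), N = 10), 0)
  expect_error(mean_firing_rate(raster, c(100, 100), N = 20), "empty window")
})

test_that("ISI statistics: periodic, Poisson and bimodal trains", {
  per <- data.frame(time_ms = seq(10, 1000, by = 10), neuron = 1L)
  s <- isi_stats(per)
  expect_equal(unname(s$cv["1"]), 0)

  set.seed(1)
  pois <- data.frame(time_ms = cumsum(rexp(10000, rate = 20 / 1000)),
                     neuron = 1L)
  s <- isi_stats(pois)
  expect_lt(abs(unname(s$cv["1"]) - 1), 0.05)

  bimodal <- data.frame(time_ms = cumsum(rep(c(5, 100), 200)), neuron = 1L)
  s <- isi_stats(bimodal, breaks = 20)
  dens <- s$hist$counts
  # two well-separated modes
  expect_equal(sum(dens > 0), 2)
  # neurons with a single spike are excluded and counted
  s2 <- isi_stats(data.frame(time_ms = c(1, 2, 3, 5), neuron = c(1, 1, 1, 2)))
  expect_equal(s2$n_excluded, 1)
})

test_that("L2 error identities: zero, offset, homogeneity", {
  x <- matrix(sin(seq(0, 10, by = 0.01)), nrow = 1)
  expect_equal(l2_error(x, x), 0)
  expect_equal(l2_error(x + 0.3, x), 0.3)
  expect_equal(l2_error(2 * x, x), 2 * l2_error(1.5 * x, x))
  expect_error(l2_error(x, x[, -1, drop = FALSE]), "misaligned")
  expect_equal(l2_error(x + 1, x, type = "integral", dt_ms = 2),
               sqrt(ncol(x) * 2))
})

test_that("time-averaged correlation handles sign, noise and constants", {
  set.seed(2)
  x <- matrix(rnorm(4 * 500), 4, 500)
  expect_equal(as.numeric(time_avg_correlation(x, x)), 1)
  expect_equal(as.numeric(time_avg_correlation(-x, x)), -1)
  xh <- x
  xh[2, ] <- rnorm(500) # one of four components replaced by noise
  expect_equal(as.numeric(time_avg_correlation(xh, x)), 0.75, tolerance = 0.05)
  # constant target components are excluded
  x2 <- x; x2[3, ] <- 1
  r <- time_avg_correlation(x2, x2)
  expect_equal(attr(r, "n_excluded"), 1)
  expect_error(time_avg_correlation(matrix(1, 1, 5), matrix(1, 1, 5)),
               "constant")
})

test_that("replay classifier: perfect tiling, shifts and noise", {
  tt <- seq(0.004, 1, by = 0.004)
  xp <- rbind(sin(2 * pi * tt), cos(2 * pi * 3 * tt))
  tiled <- cbind(xp, xp, xp, xp)
  rep <- replay_classifier(tiled, xp, dt_ms = 4)
  expect_equal(rep$fraction_correct_duration, 1)
  expect_equal(min(rep$E_trace$E), 0, tolerance = 1e-12)
  # replay times at multiples of the period
  expect_equal(rep$replay_times_ms %% 1000, rep(0, rep$n_correct))

  # half-period shift: single best minimum at T/2
  shifted <- cbind(xp[, 126:250], xp, xp)[, 1:500]
  rep2 <- replay_classifier(shifted[, 1:375, drop = FALSE], xp, dt_ms = 4)
  expect_true(any(abs(rep2$replay_times_ms - 500) < 10))

  set.seed(3)
  noise <- matrix(rnorm(2 * 1000, sd = 10), 2, 1000)
  rep3 <- replay_classifier(noise, xp, dt_ms = 4)
  expect_equal(rep3$n_correct, 0)
  expect_error(replay_classifier(tiled, xp, 4, threshold = -1), "threshold")
})

test_that("eigenspectrum: circular-law radius, rank bound, symmetry", {
  set.seed(4)
  N <- 400; p <- 0.2
  om <- build_static_weights(N, p, "izhikevich")
  ev <- eigenspectrum(as.matrix(om))
  sigma_all <- sqrt(p) * attr(om, "sigma_omega")
  expect_equal(max(Mod(ev)), sigma_all * sqrt(N), tolerance = 0.15)

  eta <- matrix(runif(N * 3, -1, 1), N, 3)
  phi <- matrix(rnorm(N * 3), N, 3)
  ev2 <- eigenspectrum(tcrossprod(eta, phi))
  expect_lte(sum(Mod(ev2) > 1e-8 * max(Mod(ev2))), 3)

  S <- crossprod(matrix(rnorm(100), 10, 10))
  expect_true(all(abs(Im(eigenspectrum(S))) < 1e-9))
  expect_error(eigenspectrum(matrix(1, 2, 3)), "square")
})

test_that("trained weight matrices differ from static by a rank-m update", {
  fit <- small_lif_fit()
  sp <- eigenspectrum(fit)
  expect_length(sp$before, 600)
  w <- fit$weights
  D <- effective_weights(w$omega0, w$G, w$Q, w$eta, fit$phi) -
    as.matrix(w$G * w$omega0)
  expect_lte(qr(D)$rank, 1)
})

test_that("population activity binning and dominant frequency", {
  # 4 Hz modulated Poisson raster
  set.seed(5)
  tt <- seq(0.5, 5000, by = 0.5)
  lam <- 0.02 * (1 + sin(2 * pi * 4 * tt / 1000))
  spikes <- tt[runif(length(tt)) < lam * 25]
  raster <- data.frame(time_ms = spikes,
                       neuron = sample(1:50, length(spikes), TRUE))
  mp <- mean_population_activity(raster, bin_ms = 10, N = 50)
  expect_equal(mp$dominant_hz, 4, tolerance = 0.3)
  # doubling the bin width halves the bin count
  mp2 <- mean_population_activity(raster, bin_ms = 20, N = 50)
  expect_equal(length(mp2$rate_hz), floor(length(mp$rate_hz) / 2))
  # flat Poisson raster: no dominant structure
  flat <- data.frame(time_ms = sort(runif(5000, 0, 5000)),
                     neuron = sample(1:50, 5000, TRUE))
  mpf <- mean_population_activity(flat, bin_ms = 10, N = 50)
  peak_share <- max(mpf$power) / sum(mpf$power)
  expect_lt(peak_share, 0.05)
})

test_that("log-log slope fitting is exact on clean power laws", {
  N <- rep(c(100, 200, 400, 800), each = 3)
  err <- 5 * N^(-0.5)
  sl <- fit_loglog_slope(N, err)
  expect_equal(sl$slope, -0.5, tolerance = 1e-10)
  err2 <- 2 * N^(-1)
  expect_equal(fit_loglog_slope(N, err2)$slope, -1, tolerance = 1e-10)
  expect_error(fit_loglog_slope(c(1, 2), c(1, 2)), "3 distinct")
})
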