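# frozen manifest of the headline preset parameters
.preset_manifest <- list(
  fig1_rate = list(model = "rate", N = 1000, G = 1, Q = 1.5, p = 0.1,
                   dt = 0.5, dt_rls = 2, lambda = 0.5,
                   t_init = 1, t_train = 4, t_test = 5),
  fig2_theta_sine = list(model = "theta", N = 2000, G = 10, Q = 1e4, p = 0.1,
                         dt = 0.01, dt_rls = 0.5, lambda = 0.01,
                         t_init = 5, t_train = 5, t_test = 5),
  fig2_theta_sawtooth = list(model = "theta", N = 2000, G = 10, Q = 1e4,
                             p = 0.1, dt = 0.01, dt_rls = 0.5, lambda = 0.01,
                             t_init = 5, t_train = 5, t_test = 5),
  fig2_theta_vdp_harmonic = list(model = "theta", N = 2000, G = 15, Q = 1e4,
                                 p = 0.1, dt = 0.01, dt_rls = 0.5,
                                 lambda = 0.01, t_init = 5, t_train = 5,
                                 t_test = 5),
  fig2_theta_product = list(model = "theta", N = 2000, G = 25, Q = 1e4,
                            p = 0.1, dt = 0.01, dt_rls = 0.5, lambda = 0.01,
                            t_init = 5, t_train = 50, t_test = 10),
  fig2_lif_sine = list(model = "lif", N = 2000, G = 0.04, Q = 10, p = 0.1,
                       dt = 0.5, dt_rls = 2.5, lambda = 0.0025,
                       t_init = 0, t_train = 4, t_test = 5),
  fig2_izh_sine = list(model = "izhikevich", N = 2000, G = 5e3, Q = 5e3,
                       p = 0.1, dt = 0.04, dt_rls = 0.8, lambda = 1,
                       t_init = 0, t_train = 4, t_test = 5),
  fig2_lorenz = list(model = "theta", N = 5000, G = 14, Q = 1e4, p = 0.1,
                     dt = 0.01, dt_rls = 0.5, lambda = 0.01,
                     t_init = 5, t_train = 45, t_test = 50),
  fig3_ode_to_joy = list(model = "izhikevich", N = 5000, G = 1e4, Q = 4e3,
                         p = 0.1, dt = 0.04, dt_rls = 4, lambda = 2,
                         t_init = 0, t_train = 900, t_test = 1000))

test_that("preset defaults match the frozen parameter manifest", {
  for (nm in names(.preset_manifest)) {
    cfg <- force_preset(nm)
    ref <- .preset_manifest[[nm]]
    expect_equal(cfg$model, ref$model, info = nm)
    expect_equal(cfg$N, ref$N, info = nm)
    expect_equal(cfg$G, ref$G, info = nm)
    expect_equal(cfg$Q, ref$Q, info = nm)
    expect_equal(cfg$p, ref$p, info = nm)
    expect_equal(cfg$schedule$dt_ms, ref$dt, info = nm)
    expect_equal(cfg$schedule$dt_rls_ms, ref$dt_rls, info = nm)
    expect_equal(cfg$rls_lambda, ref$lambda, info = nm)
    expect_equal(cfg$schedule$t_init_s, ref$t_init, info = nm)
    expect_equal(cfg$schedule$t_train_s, ref$t_train, info = nm)
    expect_equal(cfg$schedule$t_test_s, ref$t_test, info = nm)
  }
  # theta presets run the dimensionless equations on a seconds clock
  expect_equal(force_preset("fig2_theta_sine")$neuron$t_scale, 1e-3)
})

test_that("scaled variants divide N and durations by four", {
  full <- force_preset("fig2_lif_sine")
  sc <- force_preset("fig2_lif_sine_scaled")
  expect_equal(sc$N, full$N / 4)
  expect_equal(sc$schedule$t_train_s, full$schedule$t_train_s / 4)
  expect_equal(sc$schedule$dt_ms, full$schedule$dt_ms)
  expect_error(force_preset("nonexistent_preset"), "unknown preset")
  expect_error(run_preset("fig2_lif_sine", overrides = list(bogus = 1)),
               "invalid override")
  expect_true(all(c("fig1_rate", "fig2_lif_sine_scaled", "chaos_sweep_izh")
                  %in% preset_names()))
})

test_that("run_preset executes end to end and writes run artefacts", {
  out <- file.path(tempdir(), "run_lif_scaled")
  fit <- run_preset("fig2_lif_sine_scaled", seed = 3, out = out,
                    overrides = list(schedule = train_schedule(0, 1, 1, 0.5, 2.5)))
  expect_s3_class(fit, "force_fit")
  expect_true(all(file.exists(file.path(out, c("manifest.txt", "metrics.txt",
                                               "raster.tsv", "xhat.tsv")))))
  # rerunning with the same seed reproduces the metrics file exactly
  out2 <- file.path(tempdir(), "run_lif_scaled2")
  run_preset("fig2_lif_sine_scaled", seed = 3, out = out2,
             overrides = list(schedule = train_schedule(0, 1, 1, 0.5, 2.5)))
  expect_identical(readLines(file.path(out, "metrics.txt")),
                   readLines(file.path(out2, "metrics.txt")))

  rep <- report(out)
  expect_true(file.exists(file.path(out, "report.txt")))
  expect_equal(rep$manifest$preset, "fig2_lif_sine_scaled")
  expect_error(report(file.path(tempdir(), "no_such_run")), "missing manifest")
})

test_that("fixtures are deterministic given a seed", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  f1 <- make_fixture("supervisor_trace", seed = 2, dir = d1)
  f2 <- make_fixture("supervisor_trace", seed = 2, dir = d2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  tr <- make_fixture("toy_raster", list(rate_hz = 10, t_max_s = 1),
                     seed = 1, dir = d1)
  expect_equal(nrow(read_raster(tr)), 10)

  mv <- make_fixture("synthetic_movie", list(side = 16, frames = 64),
                     seed = 1, dir = d1)
  tab <- read.table(mv, header = TRUE)
  expect_equal(nrow(tab), 64)
  expect_equal(ncol(tab), 257) # t + 256 pixels
  expect_true(all(tab[, -1] >= 0 & tab[, -1] <= 1))

  ws <- make_fixture("weight_set", list(N = 20), seed = 6, dir = d1)
  w <- load_weights(dirname(ws[1]))
  expect_s3_class(w, "weight_config")
  expect_equal(w$N, 20)
})
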