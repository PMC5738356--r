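# Config-driven experiment presets: each reproduces one of the standard
# desk-scale experiments end to end.  Every `_scaled` variant divides the
# network size and phase durations by four so a full run finishes in
# minutes on one core.

.preset_registry <- function() {
  list(
    fig1_rate = function() list(
      kind = "train", model = "rate",
      supervisor = sup_sinusoid(5),
      N = 1000, G = 1, Q = 1.5, p = 0.1,
      neuron = neuron_params("rate", F = 10, tau_s = 10),
      schedule = train_schedule(1, 4, 5, dt_ms = 0.5, dt_rls_ms = 2),
      rls_lambda = 0.5),
    fig2_theta_sine = function() list(
      kind = "train", model = "theta",
      supervisor = sup_sinusoid(5),
      N = 2000, G = 10, Q = 1e4, p = 0.1,
      neuron = neuron_params("theta", t_scale = 1e-3),
      schedule = train_schedule(5, 5, 5, dt_ms = 0.01, dt_rls_ms = 0.5),
      rls_lambda = 0.01),
    fig2_theta_sawtooth = function() list(
      kind = "train", model = "theta",
      supervisor = sup_sawtooth(5),
      N = 2000, G = 10, Q = 1e4, p = 0.1,
      neuron = neuron_params("theta", t_scale = 1e-3),
      schedule = train_schedule(5, 5, 5, dt_ms = 0.01, dt_rls_ms = 0.5),
      rls_lambda = 0.01),
    fig2_theta_vdp_harmonic = function() list(
      kind = "train", model = "theta",
      supervisor = sup_van_der_pol(0.3),
      N = 2000, G = 15, Q = 1e4, p = 0.1,
      neuron = neuron_params("theta", t_scale = 1e-3),
      schedule = train_schedule(5, 5, 5, dt_ms = 0.01, dt_rls_ms = 0.5),
      rls_lambda = 0.01),
    fig2_theta_vdp_relaxation = function() list(
      kind = "train", model = "theta",
      supervisor = sup_van_der_pol(5),
      N = 2000, G = 15, Q = 1e4, p = 0.1,
      neuron = neuron_params("theta", t_scale = 1e-3),
      schedule = train_schedule(5, 5, 5, dt_ms = 0.01, dt_rls_ms = 0.5),
      rls_lambda = 0.01),
    fig2_theta_product = function() list(
      kind = "train", model = "theta",
      supervisor = sup_product_of_sines(4, 6),
      N = 2000, G = 25, Q = 1e4, p = 0.1,
      neuron = neuron_params("theta", t_scale = 1e-3),
      schedule = train_schedule(5, 50, 10, dt_ms = 0.01, dt_rls_ms = 0.5),
      rls_lambda = 0.01),
    fig2_theta_product_noise = function() list(
      kind = "train", model = "theta",
      supervisor = sup_product_of_sines(4, 6, noise_sd = 0.05),
      N = 2000, G = 15, Q = 1e4, p = 0.1,
      neuron = neuron_params("theta", t_scale = 1e-3),
      schedule = train_schedule(5, 50, 10, dt_ms = 0.01, dt_rls_ms = 0.5),
      rls_lambda = 0.01),
    fig2_lif_sine = function() list(
      kind = "train", model = "lif",
      supervisor = sup_sinusoid(5),
      N = 2000, G = 0.04, Q = 10, p = 0.1,
      neuron = neuron_params("lif"),
      schedule = train_schedule(0, 4, 5, dt_ms = 0.5, dt_rls_ms = 2.5),
      rls_lambda = 0.0025),
    fig2_izh_sine = function() list(
      kind = "train", model = "izhikevich",
      supervisor = sup_sinusoid(5),
      N = 2000, G = 5e3, Q = 5e3, p = 0.1,
      neuron = neuron_params("izhikevich"),
      schedule = train_schedule(0, 4, 5, dt_ms = 0.04, dt_rls_ms = 0.8),
      rls_lambda = 1),
    fig2_lorenz = function() list(
      kind = "train", model = "theta",
      supervisor = sup_lorenz(duration_s = 100),
      N = 5000, G = 14, Q = 1e4, p = 0.1,
      neuron = neuron_params("theta", t_scale = 1e-3),
      schedule = train_schedule(5, 45, 50, dt_ms = 0.01, dt_rls_ms = 0.5),
      rls_lambda = 0.01),
    fig2_lorenz_lif = function() list(
      # LIF variant of the Lorenz task at reduced scale; bias at -39 pA
      kind = "train", model = "lif",
      supervisor = sup_lorenz(duration_s = 60),
      N = 1000, G = 0.04, Q = 10, p = 0.1,
      neuron = neuron_params("lif", I_bias = -39),
      schedule = train_schedule(1, 30, 20, dt_ms = 0.5, dt_rls_ms = 2.5),
      rls_lambda = 0.0025),
    fig3_ode_to_joy = function() list(
      kind = "train", model = "izhikevich",
      supervisor = sup_note_song(ode_to_joy_score(4)),
      N = 5000, G = 1e4, Q = 4e3, p = 0.1,
      neuron = neuron_params("izhikevich"),
      synapse = synapse_params("double_exp", tau_r = 2, tau_d = 20),
      schedule = train_schedule(0, 900, 1000, dt_ms = 0.04, dt_rls_ms = 4),
      rls_lambda = 2),
    fig3_ode_to_joy_scaled = function() list(
      # single-bar song, smaller reservoir, slower synapses
      kind = "train", model = "izhikevich",
      supervisor = sup_note_song(ode_to_joy_score(1)),
      N = 1000, G = 1e4, Q = 4e3, p = 0.1,
      neuron = neuron_params("izhikevich"),
      synapse = synapse_params("double_exp", tau_r = 2, tau_d = 50),
      schedule = train_schedule(0, 60, 16, dt_ms = 0.04, dt_rls_ms = 4),
      rls_lambda = 2),
    hdts_replay_synthetic = function() list(
      kind = "train", model = "izhikevich",
      supervisor = sup_moving_blob(T_s = 4, side = 8),
      N = 1000, G = 5e3, Q = 4e2, p = 0.1,
      neuron = neuron_params("izhikevich"),
      schedule = train_schedule(0, 40, 8, dt_ms = 0.04, dt_rls_ms = 4),
      rls_lambda = 2,
      # 16 pulses of 250 ms: a 4 Hz assembly clock, as in the external case
      input = feedforward_input(sup_hdts(4, 16), scale = 4e3, sample_ms = 1)),
    chaos_sweep_izh = function() list(
      kind = "chaos", model = "izhikevich",
      G_grid = c(125, 250, 500, 1000, 2000, 4000),
      N = 1000, trials = 3),
    chaos_sweep_theta = function() list(
      kind = "chaos", model = "theta",
      G_grid = c(0.0025, 0.005, 0.01, 0.02, 0.04, 0.08),
      N = 1000, trials = 3),
    convergence_lif = function() list(
      kind = "convergence", model = "lif",
      N_list = c(250, 500, 1000, 2000, 4000), reps = 3,
      supervisor = sup_sinusoid(5),
      G = 0.04, Q = 10, p = 0.1,
      schedule = train_schedule(0, 10, 1, dt_ms = 0.5, dt_rls_ms = 2.5),
      rls_lambda = 0.0025),
    convergence_rate = function() list(
      kind = "convergence", model = "rate",
      N_list = c(250, 500, 1000, 2000, 4000), reps = 3,
      supervisor = sup_sinusoid(5),
      neuron = neuron_params("rate", F = 10, tau_s = 10),
      G = 1, Q = 1.5, p = 0.1, metric = "test",
      schedule = train_schedule(1, 8, 1, dt_ms = 0.5, dt_rls_ms = 2),
      rls_lambda = 0.5)
  )
}

#' Names of the shipped experiment presets
#'
#' Each training preset also has a `<name>_scaled` variant with N and the
#' phase durations divided by four.
#'
#' @return character vector.
#' @export
preset_names <- function() {
  base <- names(.preset_registry())
  train <- base[vapply(.preset_registry(), function(f) f()$kind == "train",
                       logical(1))]
  sort(unique(c(base, paste0(setdiff(train, "fig3_ode_to_joy_scaled"), "_scaled"))))
}

#' Retrieve an experiment preset configuration
#'
#' @param name preset name, see [preset_names()].
#' @return a named config list (class `experiment_config`) consumable by
#'   [run_preset()].
#' @export
force_preset <- function(name) {
  reg <- .preset_registry()
  scaled <- FALSE
  base <- name
  if (!name %in% names(reg) && grepl("_scaled$", name)) {
    base <- sub("_scaled$", "", name)
    scaled <- TRUE
  }
  if (!base %in% names(reg)) stop("unknown preset: ", name)
  cfg <- reg[[base]]()
  if (scaled) {
    if (cfg$kind != "train") stop("only training presets have scaled variants")
    cfg$N <- max(100, round(cfg$N / 4))
    sch <- cfg$schedule
    cfg$schedule <- train_schedule(sch$t_init_s / 4, sch$t_train_s / 4,
                                   sch$t_test_s / 4, sch$dt_ms, sch$dt_rls_ms)
  }
  cfg$preset <- name
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config: %s (%s)>\n", x$preset, x$kind))
  if (x$kind == "train")
    cat(sprintf("  %s, N = %d, G = %g, Q = %g, p = %g, rls_lambda = %g\n",
                x$model, x$N, x$G, x$Q, x$p, x$rls_lambda))
  invisible(x)
}

#' Run an experiment preset end to end
#'
#' Executes the preset's full schedule and, when an output directory is
#' given, writes the spike raster, decoded/target traces, metrics and a
#' manifest (config hash, seed, package version) into it.
#'
#' @param name preset name.
#' @param overrides named list of config fields to override (must name
#'   existing fields).
#' @param seed integer seed.
#' @param out optional output directory.
#' @return for training presets, the `force_fit`; for analysis presets,
#'   the analysis result list.  The output directory (if any) is attached
#'   as attribute `out`.
#' @export
run_preset <- function(name, overrides = list(), seed = 1L, out = NULL) {
  cfg <- force_preset(name)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("invalid override(s): ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  res <- switch(cfg$kind,
    train = {
      args <- cfg[intersect(names(cfg),
                            c("supervisor", "model", "N", "G", "Q", "p",
                              "neuron", "synapse", "schedule", "rls_lambda",
                              "input"))]
      args$seed <- seed
      do.call(force_train, args)
    },
    chaos = chaos_onset_sweep(cfg$model, cfg$G_grid, trials = cfg$trials,
                              N = cfg$N),
    convergence = {
      args <- cfg[intersect(names(cfg),
                            c("model", "N_list", "reps", "supervisor", "G",
                              "Q", "p", "schedule", "rls_lambda", "neuron",
                              "metric"))]
      do.call(convergence_experiment, args)
    },
    stop("unknown preset kind"))
  if (!is.null(out)) .write_run(res, cfg, seed, out)
  attr(res, "preset") <- name
  attr(res, "out") <- out
  res
}
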