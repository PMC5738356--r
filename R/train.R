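.MODEL_CODE <- c(theta = 0L, lif = 1L, izhikevich = 2L, rate = 3L)
.SYN_CODE <- c(single_exp = 0L, double_exp = 1L, alpha = 1L)

#' Training schedule
#'
#' Phase durations in seconds and clock settings in ms.  The run is an
#' initialisation phase (learning off; the reservoir settles onto its
#' chaotic attractor), a training phase (an RLS update every `dt_rls_ms`
#' of simulated time), and a test phase (decoders frozen).
#'
#' @param t_init_s,t_train_s,t_test_s phase durations (s), each >= 0.
#' @param dt_ms integration step (ms).
#' @param dt_rls_ms RLS application interval (ms); must be an integer
#'   multiple of `dt_ms`.
#' @return object of class `train_schedule`.
#' @export
train_schedule <- function(t_init_s = 1, t_train_s = 4, t_test_s = 5,
                           dt_ms = 0.04, dt_rls_ms = 2) {
  stopifnot(t_init_s >= 0, t_train_s >= 0, t_test_s >= 0, dt_ms > 0)
  k <- dt_rls_ms / dt_ms
  if (abs(k - round(k)) > 1e-8 || round(k) < 1)
    stop("dt_rls_ms must be a positive integer multiple of dt_ms")
  structure(list(t_init_s = t_init_s, t_train_s = t_train_s,
                 t_test_s = t_test_s, dt_ms = dt_ms, dt_rls_ms = dt_rls_ms),
            class = "train_schedule")
}

.default_schedule <- function(model) {
  switch(model,
    theta = train_schedule(5, 5, 5, dt_ms = 0.01, dt_rls_ms = 0.5),
    lif = train_schedule(0, 4, 5, dt_ms = 0.5, dt_rls_ms = 2.5),
    izhikevich = train_schedule(0, 4, 5, dt_ms = 0.04, dt_rls_ms = 0.8),
    rate = train_schedule(1, 4, 5, dt_ms = 0.5, dt_rls_ms = 2))
}

#' Feedforward input specification
#'
#' Wraps an input signal (typically an HDTS or pulse chain) and the static
#' feedforward weights through which it is injected as per-neuron current
#' `W_in u(t)` at every integration step.
#'
#' @param supervisor a [supervisor()] providing the K-dimensional signal.
#' @param W_in N x K feedforward matrix, or `NULL` to draw entries
#'   uniformly from `[-scale, scale]` when the network is built.
#' @param scale half-width of the uniform draw when `W_in` is `NULL`.
#' @param sample_ms hold interval for the input (the signal is sampled and
#'   held constant over this many ms).
#' @return object of class `ff_input`.
#' @export
feedforward_input <- function(supervisor, W_in = NULL, scale = 4e3, sample_ms = 1) {
  stopifnot(inherits(supervisor, "supervisor"), sample_ms > 0)
  structure(list(supervisor = supervisor, W_in = W_in, scale = scale,
                 sample_ms = sample_ms),
            class = "ff_input")
}

.sample_grid_X <- function(sup, nX, dt_rls_ms) {
  sample_supervisor(sup, (seq_len(nX)) * dt_rls_ms / 1000)
}

#' FORCE-train a recurrent network on a teaching signal
#'
#' Runs the full init/train/test schedule: the reservoir (a chaotic
#' recurrent network of the chosen neuron model) is simulated with a fixed
#' Euler step; during the training phase, recursive least squares updates
#' the linear decoders `phi` every `dt_rls_ms` so that the decoded output
#' `xhat = phi' r` tracks the supervisor; the feedback current
#' `Q eta xhat` uses the current approximant at every integration step.
#' During the test phase the decoders are frozen and the network runs
#' autonomously.
#'
#' @param supervisor a [supervisor()] teaching signal.
#' @param model neuron model.
#' @param N network size.
#' @param G static (chaos) gain.
#' @param Q feedback gain.
#' @param p static-matrix sparsity.
#' @param neuron a [neuron_params()] (defaults to the model's standard
#'   set).
#' @param synapse a [synapse_params()] (spiking models only).
#' @param schedule a [train_schedule()] (defaults per model).
#' @param rls_lambda RLS regulariser/learning-rate parameter (the
#'   per-experiment quoted value, ms-based units): `P(0) = I / rls_lambda`.
#'   Smaller values mean weaker ridge regularisation and faster error
#'   clamping.
#' @param variant RLS decoder-update variant, see [decoder_state()].
#' @param input optional [feedforward_input()].
#' @param weights optional [weight_config()] to reuse (overrides N, G, Q,
#'   p).
#' @param seed integer seed governing all random draws.
#' @param runaway_rate abort if the mean rate exceeds this bound (Hz); 0
#'   disables.
#' @param phi_record_dt_ms decoder snapshot cadence (default ~200
#'   snapshots per run).
#' @param return_P keep the final inverse-correlation estimate (N x N).
#' @return an object of class `force_fit`; see [predict.force_fit()],
#'   [summary.force_fit()].
#' @examples
#' \donttest{
#' fit <- force_train(sup_sinusoid(5), model = "lif", N = 400,
#'                    G = 0.04, Q = 10, rls_lambda = 0.0025,
#'                    schedule = train_schedule(0, 2, 2, 0.5, 2.5),
#'                    seed = 1)
#' summary(fit)
#' }
#' @export
force_train <- function(supervisor,
                        model = c("izhikevich", "theta", "lif", "rate"),
                        N = 2000, G = 5e3, Q = 5e3, p = 0.1,
                        neuron = NULL,
                        synapse = synapse_params(),
                        schedule = NULL,
                        rls_lambda = 1,
                        variant = c("denominator", "plain"),
                        input = NULL,
                        weights = NULL,
                        seed = 1L,
                        runaway_rate = 400,
                        phi_record_dt_ms = NULL,
                        return_P = FALSE) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  stopifnot(inherits(supervisor, "supervisor"))
  if (is.null(neuron)) neuron <- neuron_params(model)
  if (neuron$model != model) stop("neuron params are for model ", neuron$model)
  if (is.null(schedule)) schedule <- .default_schedule(model)
  set.seed(seed)

  if (is.null(weights)) {
    weights <- weight_config(N, p, G, Q, m = supervisor$m, model = model)
  } else {
    if (weights$m != supervisor$m) stop("weight_config encoder dimension != supervisor dimension")
    N <- weights$N; G <- weights$G; Q <- weights$Q; p <- weights$p
  }
  st0 <- network_state(neuron, N)

  dt <- schedule$dt_ms
  n_init <- round(schedule$t_init_s * 1000 / dt)
  n_train <- round(schedule$t_train_s * 1000 / dt)
  n_test <- round(schedule$t_test_s * 1000 / dt)
  nt <- n_init + n_train + n_test
  rls_every <- round(schedule$dt_rls_ms / dt)
  nX <- nt %/% rls_every
  if (supervisor$periodic == FALSE &&
      supervisor$T < (nt * dt / 1000) - 1e-9)
    warning("non-periodic supervisor shorter than the run; evaluation clamps at its end")
  X <- .sample_grid_X(supervisor, nX, schedule$dt_rls_ms)

  # feedforward input plumbing
  Win <- matrix(0, 0, 0); U <- matrix(0, 0, 0); u_every <- 1L
  if (!is.null(input)) {
    stopifnot(inherits(input, "ff_input"))
    K <- input$supervisor$m
    Win <- input$W_in
    if (is.null(Win)) Win <- matrix(runif(N * K, -input$scale, input$scale), N, K)
    if (!all(dim(Win) == c(N, K))) stop("W_in must be N x K")
    u_every <- max(1L, as.integer(round(input$sample_ms / dt)))
    nU <- max(1L, ceiling(nt / u_every))
    U <- sample_supervisor(input$supervisor, (seq_len(nU) - 1) * u_every * dt / 1000)
    input$W_in <- Win
  }

  if (is.null(phi_record_dt_ms)) {
    phi_record_dt_ms <- max(schedule$dt_rls_ms, (nt * dt) / 200)
  }
  phi_record_every <- max(1L, round(phi_record_dt_ms / dt))

  omega_static <- methods::as(weights$G * weights$omega0, "dgCMatrix")
  res <- .cpp_force_run(
    .MODEL_CODE[[model]], unclass(neuron), omega_static, weights$Q,
    weights$eta, .SYN_CODE[[synapse$kind]],
    synapse$tau_s, synapse$tau_r, synapse$tau_d,
    X, dt, as.integer(nt),
    as.integer(n_init + 1), as.integer(n_init + n_train), as.integer(rls_every),
    1 / rls_lambda, variant == "denominator", n_train > 0,
    matrix(0, N, supervisor$m), matrix(0, 0, 0),
    Win, U, as.integer(u_every),
    as.integer(rls_every), as.integer(phi_record_every),
    list(v = st0$v, u = st0$u, refr = st0$refr),
    -1L, -1, -1, FALSE, runaway_rate, return_P,
    as.integer(n_init))

  t_rec <- drop(res$t_rec)
  xhat <- res$xhat
  raster <- data.frame(time_ms = res$spike_t, neuron = res$spike_id)
  bounds_ms <- cumsum(c(n_init, n_train, n_test)) * dt
  phase_of <- function(t) findInterval(t, c(0, bounds_ms[1], bounds_ms[2]),
                                       left.open = TRUE)
  kX <- seq_len(min(ncol(X), ncol(xhat)))
  err2 <- colSums((xhat[, kX, drop = FALSE] - X[, kX, drop = FALSE])^2)
  ph <- phase_of(t_rec[kX])
  l2 <- sqrt(tapply(err2, factor(ph, levels = 1:3), mean))
  names(l2) <- c("init", "train", "test")

  mean_rate <- function(t0, t1) {
    if (t1 <= t0) return(NA_real_)
    if (model == "rate") return(NA_real_)
    1000 * sum(raster$time_ms > t0 & raster$time_ms <= t1) / (N * (t1 - t0))
  }
  rates <- c(init = mean_rate(0, bounds_ms[1]),
             train = mean_rate(bounds_ms[1], bounds_ms[2]),
             test = mean_rate(bounds_ms[2], bounds_ms[3]))
  unit_rate <- NULL
  if (model == "rate" && res$stat_n > 0) {
    unit_rate <- list(mean = drop(res$sum_r) / res$stat_n, max = drop(res$max_r))
  }

  fit <- structure(list(
    call = match.call(),
    model = model, supervisor = supervisor,
    neuron = neuron, synapse = synapse, schedule = schedule,
    weights = weights, rls_lambda = rls_lambda, variant = variant,
    input = input, seed = seed,
    phi = res$phi,
    phi_history = list(t_ms = drop(res$t_phi), norm = res$phi_norm,
                       track = res$phi_track),
    raster = raster,
    xhat = xhat, t_rec_ms = t_rec, x = X,
    phase_bounds_ms = bounds_ms,
    metrics = list(l2 = l2, mean_rate_hz = rates, unit_rate = unit_rate),
    state_final = res$state,
    P = if (return_P) res$P else NULL),
    class = "force_fit")
  fit
}

# internal: run a frozen-decoder (test-only) simulation from a fit
.run_frozen <- function(fit, t_s, phi = fit$phi, omega_static = NULL,
                        Q = fit$weights$Q, eta = fit$weights$eta,
                        input = fit$input, state = fit$state_final,
                        record_every = NULL, X = NULL,
                        delete = NULL, runaway = 0) {
  sch <- fit$schedule
  dt <- sch$dt_ms
  nt <- round(t_s * 1000 / dt)
  rls_every <- round(sch$dt_rls_ms / dt)
  if (is.null(record_every)) record_every <- rls_every
  if (is.null(omega_static))
    omega_static <- methods::as(fit$weights$G * fit$weights$omega0, "dgCMatrix")
  Win <- matrix(0, 0, 0); U <- matrix(0, 0, 0); u_every <- 1L
  if (!is.null(input)) {
    u_every <- max(1L, as.integer(round(input$sample_ms / dt)))
    nU <- max(1L, ceiling(nt / u_every))
    U <- sample_supervisor(input$supervisor, (seq_len(nU) - 1) * u_every * dt / 1000)
    Win <- input$W_in
  }
  if (is.null(X)) X <- matrix(0, ncol(phi), 1)
  del <- if (is.null(delete)) list(n = -1L, t0 = -1, t1 = -1, trans = FALSE) else delete
  .cpp_force_run(
    .MODEL_CODE[[fit$model]], unclass(fit$neuron), omega_static, Q,
    eta, .SYN_CODE[[fit$synapse$kind]],
    fit$synapse$tau_s, fit$synapse$tau_r, fit$synapse$tau_d,
    X, dt, as.integer(nt), 1L, 0L, as.integer(rls_every),
    1 / fit$rls_lambda, TRUE, FALSE,
    phi, matrix(0, 0, 0), Win, U, as.integer(u_every),
    as.integer(record_every), 0L,
    state, as.integer(del$n), del$t0, del$t1, isTRUE(del$trans),
    runaway, FALSE, 0L)
}
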