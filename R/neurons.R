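#' Neuron model parameters
#'
#' Parameter container for the four unit models.  Defaults are the standard
#' parameter sets used throughout: Izhikevich units with spike-frequency
#' adaptation biased at rheobase (1000 pA), theta (quadratic
#' integrate-and-fire phase) units biased at threshold, LIF units with a
#' 2 ms refractory period biased at threshold (-40 pA against a -40 mV
#' threshold, unit resistance absorbed into the current), and type-I
#' square-root rate units.
#'
#' Units: time in ms, potentials in mV, currents in pA (dimensionless for
#' the theta model).  The theta model additionally carries `t_scale`, the
#' factor applied to its dimensionless phase velocity per ms of simulated
#' time: `t_scale = 1` makes a constant current I fire at sqrt(I) spikes
#' per ms; `t_scale = 1e-3` runs the dimensionless clock in seconds so
#' that rates are sqrt(I) Hz, which is the convention the large-Q network
#' presets require.
#'
#' @param model one of `"izhikevich"`, `"theta"`, `"lif"`, `"rate"`.
#' @param ... named overrides of individual parameters.
#' @return an object of class `neuron_params` (a named list).
#' @examples
#' neuron_params("lif")
#' neuron_params("izhikevich", v_t = -40, a = 0.002, d = 100) # songbird variant
#' @export
neuron_params <- function(model = c("izhikevich", "theta", "lif", "rate"), ...) {
  model <- match.arg(model)
  def <- switch(model,
    izhikevich = list(C = 250, v_r = -60, v_t = -20, b = 0, v_peak = 30,
                      v_reset = -65, a = 0.01, d = 200, I_bias = 1000, k = 2.5),
    theta = list(I_bias = 0, t_scale = 1),
    lif = list(tau_m = 10, tau_ref = 2, v_reset = -65, v_t = -40, I_bias = -40),
    rate = list(F = 10, tau_s = 10, I_bias = 0))
  ov <- list(...)
  bad <- setdiff(names(ov), names(def))
  if (length(bad)) stop("unknown parameter(s) for ", model, " model: ",
                        paste(bad, collapse = ", "))
  p <- modifyList(def, ov)
  p$model <- model
  # invariants
  if (model == "izhikevich") {
    stopifnot(p$v_reset < p$v_t, p$v_t < p$v_peak, p$C > 0)
  } else if (model == "lif") {
    stopifnot(p$v_reset < p$v_t, p$tau_m > 0, p$tau_ref >= 0)
  } else if (model == "rate") {
    stopifnot(p$tau_s > 0, p$F >= 0)
  }
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params:", x$model, "model>\n")
  flds <- setdiff(names(x), "model")
  cat(paste0("  ", flds, " = ", unlist(x[flds]), collapse = "\n"), "\n")
  invisible(x)
}

#' Initialise the dynamical state of a network
#'
#' Membrane potentials start uniformly between the reset potential and a
#' suprathreshold ceiling (the spike peak for Izhikevich units, a nominal
#' 30 mV for LIF units; phases uniformly on (-pi, pi\] for theta units;
#' filtered drives uniformly on \[0, 1\] for rate units).  Part of the
#' population therefore fires within the first few steps, which seeds
#' recurrent activity: with bias currents at threshold a population
#' started strictly below threshold would otherwise stay silent forever.
#' Adaptation currents and refractory clocks start at zero.
#'
#' @param params a [neuron_params()] object.
#' @param N number of neurons.
#' @param seed optional integer seed for reproducible draws.
#' @return an object of class `network_state`: fields `v` (potential,
#'   phase, or filtered drive), `u` (adaptation), `refr` (remaining
#'   refractory time, ms), `t` (current time, ms).
#' @export
network_state <- function(params, N, seed = NULL) {
  stopifnot(inherits(params, "neuron_params"), N >= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- switch(params$model,
    theta = runif(N, -pi, pi),
    lif = runif(N, params$v_reset, 30),
    izhikevich = runif(N, params$v_reset, params$v_peak),
    rate = runif(N, 0, 1))
  structure(list(v = v, u = numeric(N), refr = numeric(N), t = 0,
                 model = params$model),
            class = "network_state")
}

.check_finite_state <- function(v, t) {
  if (!all(is.finite(v))) {
    bad <- which(!is.finite(v))[1]
    stop(sprintf("integration instability: non-finite state for neuron %d at t = %g ms",
                 bad, t))
  }
}

#' Advance theta neurons one Euler step
#'
#' Phase dynamics `theta' = (1 - cos theta) + pi^2 (1 + cos theta) I`
#' (times `t_scale`).  A spike is flagged when the phase crosses pi from
#' below during the step, after which the phase is wrapped by subtracting
#' 2 pi.  There is no refractory period.
#'
#' @param state a `network_state`.
#' @param I per-neuron input current (dimensionless), recycled if scalar.
#' @param dt time step (ms).
#' @param params a theta [neuron_params()] object.
#' @return list with elements `state` (advanced) and `spikes` (logical).
#' @export
step_theta <- function(state, I, dt, params = neuron_params("theta")) {
  stopifnot(dt > 0, all(is.finite(I)))
  th <- state$v
  th <- th + dt * params$t_scale *
    ((1 - cos(th)) + pi^2 * (1 + cos(th)) * I)
  spikes <- th >= pi
  th[spikes] <- th[spikes] - 2 * pi
  state$t <- state$t + dt
  .check_finite_state(th, state$t)
  state$v <- th
  list(state = state, spikes = spikes)
}

#' Advance LIF neurons one Euler step
#'
#' Non-refractory neurons follow `tau_m v' = -v + I`; a neuron reaching
#' threshold emits a spike, is reset, and holds at the reset potential for
#' `tau_ref` ms while its refractory clock runs down.
#'
#' @inheritParams step_theta
#' @param params a LIF [neuron_params()] object.
#' @return list with elements `state` and `spikes`.
#' @export
step_lif <- function(state, I, dt, params = neuron_params("lif")) {
  stopifnot(dt > 0)
  v <- state$v
  refr <- state$refr
  I <- rep_len(I, length(v))
  inref <- refr > 0
  refr[inref] <- refr[inref] - dt
  v[inref] <- params$v_reset
  act <- !inref
  v[act] <- v[act] + dt * (-v[act] + I[act]) / params$tau_m
  spikes <- act & (v >= params$v_t)
  v[spikes] <- params$v_reset
  refr[spikes] <- params$tau_ref
  state$t <- state$t + dt
  .check_finite_state(v, state$t)
  state$v <- v
  state$refr <- refr
  list(state = state, spikes = spikes)
}

#' Advance Izhikevich neurons one Euler step
#'
#' `C v' = k (v - v_r)(v - v_t) - u + I`, `u' = a (b (v - v_r) - u)`.
#' When `v` reaches `v_peak` the neuron spikes, `v` is reset and the
#' adaptation current jumps by `d`.
#'
#' @inheritParams step_theta
#' @param params an Izhikevich [neuron_params()] object.
#' @return list with elements `state` and `spikes`.
#' @export
step_izhikevich <- function(state, I, dt, params = neuron_params("izhikevich")) {
  stopifnot(dt > 0)
  v <- state$v
  u <- state$u
  I <- rep_len(I, length(v))
  vnew <- v + dt * (params$k * (v - params$v_r) * (v - params$v_t) - u + I) / params$C
  u <- u + dt * params$a * (params$b * (v - params$v_r) - u)
  spikes <- vnew >= params$v_peak
  vnew[spikes] <- params$v_reset
  u[spikes] <- u[spikes] + params$d
  state$t <- state$t + dt
  .check_finite_state(vnew, state$t)
  state$v <- vnew
  state$u <- u
  list(state = state, spikes = spikes)
}

#' Type-I rate transfer function
#'
#' Firing rate `F * sqrt(s)` for non-negative drive, 0 otherwise
#' (element-wise).
#'
#' @param s filtered drive.
#' @param F rate scale.
#' @return firing rates, same shape as `s`.
#' @export
rate_transfer <- function(s, F) {
  F * sqrt(pmax(s, 0))
}

#' Advance rate units one Euler step
#'
#' `tau_s s' = -s + drive`, where `drive` is the total recurrent plus
#' feedback input already assembled by the caller.
#'
#' @param s per-unit filtered drive.
#' @param drive per-unit input.
#' @param dt time step (ms).
#' @param tau_s unit time constant (ms).
#' @return the advanced drive vector.
#' @export
step_rate_network <- function(s, drive, dt, tau_s) {
  stopifnot(dt > 0, tau_s > 0)
  out <- s + dt * (-s + drive) / tau_s
  .check_finite_state(out, NA_real_)
  out
}

#' Default integration step for a neuron model
#'
#' The fixed forward-Euler steps used throughout: 0.01 ms (theta), 0.5 ms
#' (LIF), 0.04 ms (Izhikevich), 0.5 ms (rate units).
#'
#' @param model model name.
#' @return step size in ms.
#' @export
default_dt <- function(model) {
  switch(model, theta = 0.01, lif = 0.5, izhikevich = 0.04, rate = 0.5,
         stop("unknown model: ", model))
}
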