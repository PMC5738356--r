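# Independent pure-R reference implementations used as oracles.

# single-neuron constant-current rate, forward Euler, arithmetic written
# out independently of the package's step functions
ref_theta_rate <- function(I, dt, t_max_ms, th0 = -pi / 2, t_scale = 1) {
  th <- th0
  n <- 0
  for (k in seq_len(round(t_max_ms / dt))) {
    th <- th + dt * t_scale * ((1 - cos(th)) + pi^2 * (1 + cos(th)) * I)
    if (th >= pi) {
      th <- th - 2 * pi
      n <- n + 1
    }
  }
  n / t_max_ms
}

ref_izh_rate <- function(I, dt, t_max_ms, discard_ms = 500) {
  C <- 250; k <- 2.5; vr <- -60; vt <- -20; vpeak <- 30; vreset <- -65
  a <- 0.01; b <- 0; d <- 200
  v <- vr; u <- 0; n <- 0; t <- 0
  nsteps <- round(t_max_ms / dt)
  for (s in seq_len(nsteps)) {
    vold <- v
    v <- v + dt * (k * (vold - vr) * (vold - vt) - u + I) / C
    u <- u + dt * a * (b * (vold - vr) - u)
    t <- t + dt
    if (v >= vpeak) {
      v <- vreset
      u <- u + d
      if (t > discard_ms) n <- n + 1
    }
  }
  1000 * n / (t_max_ms - discard_ms) # Hz
}

# slow but straightforward network simulator mirroring the engine's
# update order for small spiking networks (double-exp synapses)
ref_network_sim <- function(model, neuron, omega_static, Q, eta, phi,
                            dt, nt, state, tau_r = 2, tau_d = 20,
                            I_extra = 0) {
  N <- nrow(omega_static)
  m <- ncol(eta)
  v <- state$v; u <- state$u; refr <- state$refr
  r <- numeric(N); hr <- numeric(N)
  Ipsc <- numeric(N); hI <- numeric(N)
  e_d <- exp(-dt / tau_d); e_r <- exp(-dt / tau_r)
  c_de <- (e_d - e_r) / (1 / tau_r - 1 / tau_d)
  spikes_t <- c(); spikes_id <- c()
  om <- as.matrix(omega_static)
  for (s in seq_len(nt)) {
    xhat <- drop(crossprod(phi, r))
    I <- neuron$I_bias + Ipsc + Q * drop(eta %*% xhat) + I_extra
    if (model == "theta") {
      cth <- cos(v)
      v <- v + dt * neuron$t_scale * ((1 - cth) + pi^2 * (1 + cth) * I)
      sp <- v >= pi
      v[sp] <- v[sp] - 2 * pi
    } else if (model == "lif") {
      inref <- refr > 0
      refr[inref] <- refr[inref] - dt
      v[inref] <- neuron$v_reset
      act <- !inref
      v[act] <- v[act] + dt * (-v[act] + I[act]) / neuron$tau_m
      sp <- act & v >= neuron$v_t
      v[sp] <- neuron$v_reset
      refr[sp] <- neuron$tau_ref
    } else {
      vold <- v
      v <- v + dt * (neuron$k * (vold - neuron$v_r) * (vold - neuron$v_t) -
                       u + I) / neuron$C
      u <- u + dt * neuron$a * (neuron$b * (vold - neuron$v_r) - u)
      sp <- v >= neuron$v_peak
      v[sp] <- neuron$v_reset
      u[sp] <- u[sp] + neuron$d
    }
    r <- r * e_d + hr * c_de
    hr <- hr * e_r
    Ipsc <- Ipsc * e_d + hI * c_de
    hI <- hI * e_r
    idx <- which(sp)
    for (j in idx) {
      hr[j] <- hr[j] + 1 / (tau_r * tau_d)
      hI <- hI + om[, j] / (tau_r * tau_d)
      spikes_t <- c(spikes_t, s * dt)
      spikes_id <- c(spikes_id, j)
    }
  }
  list(spike_t = spikes_t, spike_id = spikes_id, v = v, r = r)
}

# quick scaled-down training run used by several tests
small_lif_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- force_train(sup_sinusoid(5), model = "lif", N = 600,
                            G = 0.04, Q = 10, rls_lambda = 0.0025,
                            schedule = train_schedule(0, 3, 2, 0.5, 2.5),
                            seed = 11)
    }
    cache
  }
})

# correlation of consecutive one-period windows against a reference
# period, maximising over a common circular lag (tolerates phase and
# amplitude error, per-period)
per_period_correlation <- function(xh, dt_ms, period_ms, ref = NULL) {
  per <- round(period_ms / dt_ms)
  if (is.null(ref)) ref <- sin(2 * pi * (0:(per - 1)) / per)
  nw <- floor(length(xh) / per)
  lags <- seq(0, per - 1, by = max(1, floor(per / 64)))
  best_lag <- lags[which.max(vapply(lags, function(l)
    cor(xh[1:per], ref[((0:(per - 1)) + l) %% per + 1]), numeric(1)))]
  shifted <- ref[((0:(per - 1)) + best_lag) %% per + 1]
  vapply(seq_len(nw), function(k) {
    seg <- xh[((k - 1) * per + 1):(k * per)]
    if (sd(seg) == 0) return(0)
    max(vapply(lags, function(l)
      cor(seg, ref[((0:(per - 1)) + l) %% per + 1]), numeric(1)))
  }, numeric(1))
}
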