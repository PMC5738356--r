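# Chaos diagnostics and the network-size convergence experiment.

# minimal engine wrapper for untrained (or externally configured) runs
.raw_sim <- function(model, neuron, synapse, omega_static, Q = 0,
                     eta = NULL, phi = NULL, dt, t_s, state,
                     delete = NULL, input = NULL, record_every = 0L) {
  N <- nrow(omega_static)
  if (is.null(eta)) eta <- matrix(0, N, 1)
  if (is.null(phi)) phi <- matrix(0, N, ncol(eta))
  nt <- round(t_s * 1000 / dt)
  Win <- matrix(0, 0, 0); U <- matrix(0, 0, 0); u_every <- 1L
  if (!is.null(input)) {
    u_every <- max(1L, as.integer(round(input$sample_ms / dt)))
    nU <- max(1L, ceiling(nt / u_every))
    U <- sample_supervisor(input$supervisor, (seq_len(nU) - 1) * u_every * dt / 1000)
    Win <- input$W_in
  }
  del <- if (is.null(delete)) list(n = -1L, t0 = -1, t1 = -1, trans = FALSE) else delete
  .cpp_force_run(.MODEL_CODE[[model]], unclass(neuron),
                 methods::as(omega_static, "dgCMatrix"), Q, eta,
                 .SYN_CODE[[synapse$kind]],
                 synapse$tau_s, synapse$tau_r, synapse$tau_d,
                 matrix(0, ncol(eta), 1), dt, as.integer(nt),
                 1L, 0L, 1L, 1, TRUE, FALSE,
                 phi, matrix(0, 0, 0), Win, U, as.integer(u_every),
                 as.integer(record_every), 0L,
                 state, as.integer(del$n), del$t0, del$t1, isTRUE(del$trans),
                 0, FALSE, 0L)
}

.binned_hamming <- function(r1, r2, N, window_ms, bin_ms = 1) {
  edges <- seq(window_ms[1], window_ms[2], by = bin_ms)
  nb <- length(edges) - 1
  key <- function(r) {
    keep <- r$spike_t > window_ms[1] & r$spike_t <= window_ms[2]
    b <- findInterval(r$spike_t[keep], edges, left.open = TRUE,
                      rightmost.closed = TRUE)
    b <- pmin(pmax(b, 1), nb)
    unique((r$spike_id[keep] - 1) * nb + b)
  }
  k1 <- key(r1); k2 <- key(r2)
  diffs <- c(setdiff(k1, k2), setdiff(k2, k1))
  bins_of <- ((diffs - 1) %% nb) + 1
  h <- tabulate(bins_of, nbins = nb)
  data.frame(t_ms = edges[-1] - bin_ms / 2, hamming = h)
}

#' Single-spike deletion chaos diagnostic
#'
#' Runs two simulations of the same (untrained, feedback-free) network
#' from identical initial conditions, suppressing exactly one spike in
#' the second run, and reports the Hamming distance between the two
#' 1 ms-binned rasters over time.  In a chaotic network the deletion's
#' effect spreads to a finite fraction of all neuron-bins; with no
#' coupling (G = 0) it stays confined to the deleted neuron.
#'
#' @param model neuron model.
#' @param N network size.
#' @param G static gain.
#' @param p sparsity.
#' @param neuron,synapse parameter objects (model defaults if `NULL`).
#' @param dt_ms integration step (model default if `NULL`).
#' @param t_delete_s earliest time (s) at which a spike may be deleted.
#' @param horizon_s how long to track divergence after `t_delete_s`.
#' @param bin_ms raster bin width for the distance.
#' @param seed seed for weights and initial conditions.
#' @return list: `trace` (data.frame `t_ms`, `hamming`, `frac` of
#'   neuron-bins differing), `deleted_neuron`, `deleted_t_ms`,
#'   `n_spikes_baseline`.
#' @export
spike_deletion_test <- function(model = c("theta", "lif", "izhikevich"),
                                N = 1000, G, p = 0.1,
                                neuron = NULL, synapse = NULL, dt_ms = NULL,
                                t_delete_s = 0.1, horizon_s = 0.5,
                                bin_ms = 1, seed = 1L) {
  model <- match.arg(model)
  if (is.null(neuron)) neuron <- neuron_params(model)
  if (is.null(synapse)) synapse <- synapse_params()
  if (is.null(dt_ms)) dt_ms <- default_dt(model)
  set.seed(seed)
  om <- G * build_static_weights(N, p, model)
  st0 <- network_state(neuron, N)
  state <- list(v = st0$v, u = st0$u, refr = st0$refr)
  t_total <- t_delete_s + horizon_s
  base <- .raw_sim(model, neuron, synapse, om, dt = dt_ms, t_s = t_total,
                   state = state)
  cand <- which(base$spike_t > t_delete_s * 1000)
  if (!length(cand)) stop("no spike to delete in the requested window")
  j <- base$spike_id[cand[1]]
  tdel <- base$spike_t[cand[1]]
  pert <- .raw_sim(model, neuron, synapse, om, dt = dt_ms, t_s = t_total,
                   state = state,
                   delete = list(n = j - 1L, t0 = tdel - dt_ms / 2,
                                 t1 = tdel + dt_ms / 2, trans = FALSE))
  win <- c(tdel, t_total * 1000)
  tr <- .binned_hamming(base, pert, N, win, bin_ms)
  tr$frac <- tr$hamming / N
  list(trace = tr, deleted_neuron = j, deleted_t_ms = tdel,
       n_spikes_baseline = length(base$spike_t))
}

#' Locate the onset of chaotic spiking as a function of G
#'
#' For each static gain in `G_grid`, runs [spike_deletion_test()] over
#' several trials and flags divergence when the fraction of differing
#' neuron-bins in the final quarter of the horizon exceeds
#' `criterion_frac`.  The onset estimate is the smallest G whose
#' divergence criterion holds in a majority of trials; runs with no
#' spikes to delete count as non-divergent (quiescence).
#'
#' @param model neuron model.
#' @param G_grid increasing static gains to probe.
#' @param trials trials (seeds) per G.
#' @param N network size.
#' @param horizon_s divergence horizon (s).
#' @param criterion_frac divergence criterion on the mean differing
#'   fraction per bin.
#' @param ... forwarded to [spike_deletion_test()].
#' @return list: `onset_G` (NA with a message when no onset is detected),
#'   `curve` (data.frame G, trial, divergence, detected).
#' @export
chaos_onset_sweep <- function(model, G_grid, trials = 3, N = 1000,
                              horizon_s = 0.5, criterion_frac = 0.005, ...) {
  stopifnot(!is.unsorted(G_grid))
  rows <- list()
  for (G in G_grid) {
    for (tr in seq_len(trials)) {
      div <- tryCatch({
        sdt <- spike_deletion_test(model, N = N, G = G, horizon_s = horizon_s,
                                   seed = tr, ...)
        tail_q <- sdt$trace[sdt$trace$t_ms >
                              quantile(sdt$trace$t_ms, 0.75), "frac"]
        mean(tail_q)
      }, error = function(e) 0) # quiescent: nothing to delete
      rows[[length(rows) + 1]] <- data.frame(G = G, trial = tr,
                                             divergence = div,
                                             detected = div > criterion_frac)
    }
  }
  curve <- do.call(rbind, rows)
  byG <- tapply(curve$detected, curve$G, mean)
  hit <- names(byG)[byG > 0.5]
  onset <- if (length(hit)) as.numeric(hit[1]) else NA_real_
  if (is.na(onset)) message("no onset detected within the probed G range")
  list(onset_G = onset, curve = curve)
}

#' Network-size convergence of the decoding error
#'
#' Trains networks of increasing size on the same supervisor (several
#' seeds per size), measures a time-averaged L2 decoding error, and fits
#' the log-log slope of error against N.  Spiking reservoirs converge
#' like ~N^(-1/2); smooth rate reservoirs converge faster, ~N^(-1).
#'
#' Two error read-outs are available.  `"test"` is the autonomous
#' test-phase error against the absolute-time supervisor; it is the
#' right read-out when the trained network phase-locks (the rate
#' baseline does).  Spiking oscillators hold the waveform but slowly
#' drift in phase once free-running, which saturates the test error
#' regardless of N; for them `"closed_loop"` measures the residual over
#' the final quarter of the training phase, while the error feedback
#' still holds the network on the target trajectory — this is the
#' quantity whose shot-noise scaling reflects the basis size.
#'
#' @param model neuron model.
#' @param N_list at least 3 distinct network sizes.
#' @param reps seeds per size.
#' @param supervisor teaching signal.
#' @param metric `"closed_loop"` (default) or `"test"`.
#' @param scale_sigma keep the effective coupling `G sigma sqrt(N p)`
#'   fixed at its value for the N = 1000 reference network, so that every
#'   size runs in the same dynamical regime and only the basis size
#'   varies.  This matters for the rate model, whose default sigma does
#'   not follow reservoir-invariant scaling; the spiking defaults already
#'   do.
#' @param G,Q,p gains and sparsity (as in [force_train()]).
#' @param base_seed offset added to the per-run seeds, so a whole sweep
#'   can be re-randomised from one integer.
#' @param ... forwarded to [force_train()] (schedule, rls_lambda, ...).
#' @return list: `slope`, `ci`, `table` (N, rep, error), plus the
#'   underlying `lm` fit.
#' @export
convergence_experiment <- function(model, N_list, reps = 3,
                                   supervisor = sup_sinusoid(5),
                                   metric = c("closed_loop", "test"),
                                   scale_sigma = TRUE,
                                   G = 1, Q = 1.5, p = 0.1,
                                   base_seed = 0L, ...) {
  metric <- match.arg(metric)
  stopifnot(length(unique(N_list)) >= 3, reps >= 1)
  sigma_ref <- attr(build_static_weights(1000, p, model, seed = 1),
                    "sigma_omega")
  tab <- expand.grid(N = N_list, rep = seq_len(reps))
  tab$error <- NA_real_
  for (i in seq_len(nrow(tab))) {
    seed_i <- base_seed + 1000 * tab$rep[i] + i
    sig <- if (scale_sigma) sigma_ref * sqrt(1000 / tab$N[i]) else NULL
    fit <- tryCatch({
      set.seed(seed_i)
      w <- weight_config(tab$N[i], p, G, Q, m = supervisor$m, model = model,
                         sigma = sig)
      force_train(supervisor, model = model, weights = w,
                  seed = seed_i, ...)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    tab$error[i] <- if (metric == "test") {
      fit$metrics$l2["test"]
    } else {
      b <- fit$phase_bounds_ms
      keep <- which(fit$t_rec_ms > b[1] + 0.75 * (b[2] - b[1]) &
                      fit$t_rec_ms <= b[2])
      keep <- keep[keep <= ncol(fit$x)]
      sqrt(mean(colSums((fit$xhat[, keep, drop = FALSE] -
                           fit$x[, keep, drop = FALSE])^2)))
    }
  }
  sl <- fit_loglog_slope(tab$N, tab$error)
  list(slope = sl$slope, ci = sl$ci, table = tab, fit = sl$fit, metric = metric)
}
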