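#' @export
print.force_fit <- function(x, ...) {
  w <- x$weights
  cat(sprintf("FORCE-trained %s network\n", x$model))
  cat(sprintf("  N = %d, p = %g, G = %g, Q = %g, supervisor: %s (m = %d)\n",
              w$N, w$p, w$G, w$Q, x$supervisor$label, x$supervisor$m))
  sch <- x$schedule
  cat(sprintf("  schedule: %g s init / %g s train / %g s test (dt = %g ms, RLS every %g ms)\n",
              sch$t_init_s, sch$t_train_s, sch$t_test_s, sch$dt_ms, sch$dt_rls_ms))
  if (!is.na(x$metrics$l2["test"]))
    cat(sprintf("  test-phase L2 error: %.4g (log: %.3g)\n",
                x$metrics$l2["test"], log(x$metrics$l2["test"])))
  mr <- x$metrics$mean_rate_hz["test"]
  if (!is.na(mr)) cat(sprintf("  test-phase mean firing rate: %.1f Hz\n", mr))
  invisible(x)
}

#' Summarise a FORCE fit
#'
#' @param object a `force_fit`.
#' @param ... unused.
#' @return object of class `summary.force_fit` with per-phase L2 errors,
#'   firing rates, the test-phase correlation between decoded output and
#'   teaching signal, and decoder norms.
#' @export
summary.force_fit <- function(object, ...) {
  test_cols <- which(object$t_rec_ms > object$phase_bounds_ms[2])
  test_cols <- test_cols[test_cols <= ncol(object$x)]
  corr <- if (length(test_cols) > 2) {
    time_avg_correlation(object$xhat[, test_cols, drop = FALSE],
                         object$x[, test_cols, drop = FALSE])
  } else NA_real_
  out <- list(fit = object,
              l2 = object$metrics$l2,
              mean_rate_hz = object$metrics$mean_rate_hz,
              unit_rate = object$metrics$unit_rate,
              test_correlation = corr,
              phi_norm = sqrt(colSums(object$phi^2)),
              n_spikes = nrow(object$raster))
  class(out) <- "summary.force_fit"
  out
}

#' @export
print.summary.force_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  L2 error by phase: init %.4g / train %.4g / test %.4g\n",
              x$l2["init"], x$l2["train"], x$l2["test"]))
  if (!is.na(x$test_correlation))
    cat(sprintf("  test-phase output/target correlation: %.3f\n", x$test_correlation))
  if (!is.null(x$unit_rate))
    cat(sprintf("  unit rates (time-averaged): mean %.2f Hz, max %.2f Hz\n",
                mean(x$unit_rate$mean), max(x$unit_rate$mean)))
  cat(sprintf("  decoder column norms: %s\n",
              paste(signif(x$phi_norm, 3), collapse = ", ")))
  invisible(x)
}

#' @export
coef.force_fit <- function(object, ...) object$phi

#' @export
fitted.force_fit <- function(object, ...) {
  keep <- object$t_rec_ms > object$phase_bounds_ms[2]
  object$xhat[, keep, drop = FALSE]
}

#' @export
residuals.force_fit <- function(object, ...) {
  keep <- which(object$t_rec_ms > object$phase_bounds_ms[2])
  keep <- keep[keep <= ncol(object$x)]
  object$xhat[, keep, drop = FALSE] - object$x[, keep, drop = FALSE]
}

#' Run a trained network forward with frozen decoders
#'
#' Continues the simulation from the fitted network's final state with
#' learning off, optionally under a [perturbation_spec()]: rescaled
#' excitation (applied to the composed effective weight matrix),
#' compressed/reversed/attenuated feedforward HDTS, and/or neuron
#' lesioning.  Returns the decoded output together with replay metrics
#' against the (time-compressed, if applicable) teaching signal.
#'
#' @param object a `force_fit`.
#' @param t_s duration to simulate (default: the fit's test duration).
#' @param perturbation optional [perturbation_spec()].
#' @param target optional [supervisor()] to score against (default: the
#'   fit's supervisor, with its timeline compressed by the perturbation's
#'   compression factor).
#' @param state optional starting `state` list (default: the fit's final
#'   state).
#' @param ... unused.
#' @return object of class `force_pred`: recorded times (ms), decoded
#'   trace, target samples, spike raster, mean rate, correlation and L2
#'   error.
#' @export
predict.force_fit <- function(object, t_s = NULL, perturbation = NULL,
                              target = NULL, state = NULL, ...) {
  if (is.null(t_s)) t_s <- object$schedule$t_test_s
  ps <- perturbation
  phi <- object$phi
  eta <- object$weights$eta
  Q <- object$weights$Q
  omega_static <- NULL
  input <- object$input
  compression <- 1

  if (!is.null(ps)) {
    stopifnot(inherits(ps, "perturbation_spec"))
    compression <- ps$compression
    if (ps$alpha != 1) {
      # excitation/inhibition rescaling acts on the composed matrix; the
      # learned feedback is folded in, so the engine runs with Q = 0
      om <- effective_weights(object$weights$omega0, object$weights$G, Q,
                              eta, phi)
      om <- scale_excitatory(om, ps$alpha)
      omega_static <- methods::as(om, "dgCMatrix")
      Q <- 0
    }
    if (!is.null(input) &&
        (ps$compression != 1 || ps$reverse || ps$hdts_amplitude != 1)) {
      input$supervisor <- transform_hdts(input$supervisor, ps$compression,
                                         ps$reverse, ps$hdts_amplitude)
    }
    if (ps$lesion_fraction > 0) {
      les <- .lesion_indices(object$weights$N, ps$lesion_fraction, ps$seed)
      if (is.null(omega_static))
        omega_static <- methods::as(object$weights$G * object$weights$omega0,
                                    "dgCMatrix")
      omega_static <- .zero_rows_cols(omega_static, les,
                                      mode = ps$lesion_mode)
      phi[les, ] <- 0
      eta[les, ] <- 0
      if (!is.null(input)) input$W_in[les, ] <- 0
    }
  }

  if (is.null(state)) state <- object$state_final
  dt <- object$schedule$dt_ms
  rls_every <- round(object$schedule$dt_rls_ms / dt)
  res <- .run_frozen(object, t_s, phi = phi, omega_static = omega_static,
                     Q = Q, eta = eta, input = input, state = state)
  if (is.null(target)) {
    sup <- object$supervisor
    target <- if (compression != 1) {
      supervisor(sup$m, sup$T / compression,
                 function(t) sup$eval(t * compression),
                 label = paste0(sup$label, sprintf(" (%gx compressed)", compression)),
                 periodic = sup$periodic)
    } else sup
  }
  t_rec <- drop(res$t_rec)
  x <- sample_supervisor(target, t_rec / 1000)
  corr <- tryCatch(time_avg_correlation(res$xhat, x), error = function(e) NA_real_)
  raster <- data.frame(time_ms = res$spike_t, neuron = res$spike_id)
  if (!is.null(ps) && ps$lesion_fraction > 0) {
    les <- .lesion_indices(object$weights$N, ps$lesion_fraction, ps$seed)
    raster <- raster[!(raster$neuron %in% les), , drop = FALSE]
  }
  if (!is.null(object$lesioned))
    raster <- raster[!(raster$neuron %in% object$lesioned), , drop = FALSE]
  out <- list(t_ms = t_rec, xhat = res$xhat, x = x,
              raster = raster,
              mean_rate_hz = if (object$model == "rate") NA_real_ else
                1000 * nrow(raster) / (object$weights$N * t_s * 1000),
              correlation = corr,
              l2 = sqrt(mean(colSums((res$xhat - x)^2))),
              perturbation = ps, target = target,
              state_final = res$state)
  class(out) <- "force_pred"
  out
}

#' @export
print.force_pred <- function(x, ...) {
  cat(sprintf("<force_pred: %.3g s replay | correlation %.3f, L2 %.4g%s>\n",
              max(x$t_ms) / 1000, x$correlation, x$l2,
              if (!is.na(x$mean_rate_hz)) sprintf(", mean rate %.1f Hz", x$mean_rate_hz) else ""))
  invisible(x)
}

#' Re-simulate the test phase under state perturbations
#'
#' Draws `nsim` replicate test runs, each starting from the fitted
#' network's final state with a small random kick to the membrane
#' variables (relative size `state_jitter`); used to probe the stability
#' of the learned dynamics (chaotic fits diverge between replicates).
#'
#' @param object a `force_fit`.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param t_s duration of each replicate (s).
#' @param state_jitter kick size relative to the membrane scale.
#' @param ... unused.
#' @return list of `force_pred` objects.
#' @export
simulate.force_fit <- function(object, nsim = 1, seed = NULL, t_s = NULL,
                               state_jitter = 0.01, ...) {
  if (!is.null(seed)) set.seed(seed)
  vscale <- switch(object$model,
    theta = pi, rate = 1,
    lif = object$neuron$v_t - object$neuron$v_reset,
    izhikevich = object$neuron$v_t - object$neuron$v_reset)
  lapply(seq_len(nsim), function(i) {
    st <- object$state_final
    st$v <- st$v + rnorm(length(st$v), 0, state_jitter * vscale)
    predict(object, t_s = t_s, state = st)
  })
}

#' Plot a FORCE fit
#'
#' Decoded output against the teaching signal around the train/test
#' boundary, plus (for spiking fits) a raster of the lowest-index neurons
#' and the decoder-norm history.
#'
#' @param x a `force_fit`.
#' @param components which supervisor components to draw.
#' @param n_neurons raster size.
#' @param ... unused.
#' @export
plot.force_fit <- function(x, components = 1:min(3, x$supervisor$m),
                           n_neurons = 30, ...) {
  op <- par(mfrow = c(if (nrow(x$raster)) 3 else 2, 1),
            mar = c(3.5, 3.5, 1.5, 1), mgp = c(2.2, 0.7, 0))
  on.exit(par(op))
  tt <- x$t_rec_ms / 1000
  kX <- seq_len(min(ncol(x$x), ncol(x$xhat)))
  matplot(tt[kX], t(x$x[components, kX, drop = FALSE]), type = "l", lty = 2,
          col = "black", xlab = "time (s)", ylab = "x(t)", main = x$supervisor$label)
  matlines_cols <- seq_along(components) + 1
  for (i in seq_along(components))
    lines(tt[kX], x$xhat[components[i], kX], col = matlines_cols[i])
  abline(v = x$phase_bounds_ms[1:2] / 1000, col = "grey", lty = 3)
  legend("topright", c("target", "decoded"), lty = c(2, 1),
         col = c("black", 2), bty = "n", cex = 0.8)
  if (nrow(x$raster)) {
    sub <- x$raster[x$raster$neuron <= n_neurons, ]
    plot(sub$time_ms / 1000, sub$neuron, pch = ".", cex = 2,
         xlab = "time (s)", ylab = "neuron", main = "spike raster")
    abline(v = x$phase_bounds_ms[1:2] / 1000, col = "grey", lty = 3)
  }
  matplot(x$phi_history$t_ms / 1000, t(x$phi_history$norm), type = "l",
          xlab = "time (s)", ylab = "|phi| per output", main = "decoder norms")
  abline(v = x$phase_bounds_ms[1:2] / 1000, col = "grey", lty = 3)
  invisible(x)
}
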