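#' Post-training perturbation settings
#'
#' Describes manipulations applied to a frozen trained network:
#' excitation/inhibition rescaling (`alpha` multiplies the positive
#' entries of the composed effective weight matrix), temporal compression
#' and component-order reversal of a feedforward HDTS, HDTS amplitude
#' attenuation, and random neuron lesioning.
#'
#' @param alpha excitatory scale factor (>= 0); 1 is the identity.
#' @param compression time-compression factor (> 0) for the HDTS.
#' @param reverse reverse the HDTS component order (pulse-internal
#'   dynamics are not reversed).
#' @param hdts_amplitude multiplies all HDTS components.
#' @param lesion_fraction fraction of neurons to remove, in \[0, 1\].
#' @param lesion_target which subnetwork the lesion applies to (the
#'   replay reservoir, or an upstream HDTS-generating network when one is
#'   simulated separately).
#' @param lesion_mode `"remove"` zeroes incoming and outgoing weights and
#'   decoder rows; `"silence"` zeroes only outgoing weights and decoder
#'   rows.
#' @param seed seed for the lesion draw.
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(alpha = 1, compression = 1, reverse = FALSE,
                              hdts_amplitude = 1, lesion_fraction = 0,
                              lesion_target = c("replay", "hdts"),
                              lesion_mode = c("remove", "silence"),
                              seed = 1L) {
  lesion_target <- match.arg(lesion_target)
  lesion_mode <- match.arg(lesion_mode)
  stopifnot(alpha >= 0, compression > 0, hdts_amplitude >= 0,
            lesion_fraction >= 0, lesion_fraction <= 1)
  structure(list(alpha = alpha, compression = compression, reverse = reverse,
                 hdts_amplitude = hdts_amplitude,
                 lesion_fraction = lesion_fraction,
                 lesion_target = lesion_target, lesion_mode = lesion_mode,
                 seed = seed),
            class = "perturbation_spec")
}

#' Rescale the excitatory entries of a weight matrix
#'
#' Positive entries of the (effective) matrix are multiplied by `alpha`;
#' non-positive entries are untouched.  `alpha > 1` tips the network
#' towards excess excitation, `alpha < 1` towards excess inhibition.
#'
#' @param omega square weight matrix (dense or sparse).
#' @param alpha scale factor >= 0.
#' @return matrix of the same storage class.
#' @export
scale_excitatory <- function(omega, alpha) {
  stopifnot(alpha >= 0)
  if (inherits(omega, "sparseMatrix")) {
    omega <- methods::as(omega, "dgCMatrix")
    pos <- omega@x > 0
    omega@x[pos] <- alpha * omega@x[pos]
    omega
  } else {
    pos <- omega > 0
    omega[pos] <- alpha * omega[pos]
    omega
  }
}

#' Compress, reverse or attenuate an HDTS supervisor
#'
#' Compression rescales the time axis (`x'(t) = x(compression * t)`, so
#' the duration shrinks by the factor); reversal flips the component
#' order (the pulse sequence runs backwards while each pulse's internal
#' time course still runs forwards); amplitude multiplies all components.
#' The transform is invertible: applying the inverse compression and
#' reversing again recovers the original samples.
#'
#' @param sup a [supervisor()] (typically from [sup_hdts()] or
#'   [sup_pulse_chain()]).
#' @param compression time-scale factor > 0.
#' @param reverse flip component order.
#' @param amplitude output scale >= 0.
#' @return a transformed [supervisor()].
#' @export
transform_hdts <- function(sup, compression = 1, reverse = FALSE, amplitude = 1) {
  stopifnot(inherits(sup, "supervisor"), compression > 0, amplitude >= 0)
  if (compression == 1 && !reverse && amplitude == 1) return(sup)
  base_eval <- sup$eval
  m <- sup$m
  ev <- function(t) {
    out <- base_eval(t * compression)
    if (reverse) out <- out[m:1, , drop = FALSE]
    amplitude * out
  }
  out <- supervisor(m, sup$T / compression, ev,
                    label = sprintf("%s [x%g%s%s]", sup$label, compression,
                                    if (reverse) ", reversed" else "",
                                    if (amplitude != 1) sprintf(", amp %g", amplitude) else ""),
                    periodic = sup$periodic)
  attr(out, "hdts_spec") <- attr(sup, "hdts_spec")
  out
}

.lesion_indices <- function(N, fraction, seed) {
  n <- ceiling(fraction * N)
  if (n == 0) return(integer(0))
  if (!is.null(seed)) set.seed(seed)
  sort(sample.int(N, min(n, N)))
}

.zero_rows_cols <- function(sp, idx, mode = "remove") {
  if (!length(idx)) return(sp)
  sp <- methods::as(sp, "dgCMatrix")
  sp[, idx] <- 0
  if (mode == "remove") sp[idx, ] <- 0
  Matrix::drop0(sp)
}

#' Lesion a fraction of neurons in a trained network
#'
#' Removes `ceiling(fraction * N)` randomly selected neurons: their
#' incoming and outgoing static weights, encoder rows, decoder rows and
#' feedforward input rows are zeroed (mode `"remove"`); mode `"silence"`
#' zeroes only the outgoing pathways (static columns and decoder rows),
#' leaving the neurons driven but mute.  Lesioning with a fixed seed and
#' fraction is idempotent.
#'
#' @param fit a `force_fit`.
#' @param fraction fraction of neurons to lesion, in \[0, 1\].
#' @param seed seed for the selection.
#' @param mode `"remove"` or `"silence"`.
#' @return a modified `force_fit`.
#' @export
lesion_neurons <- function(fit, fraction, seed = 1L,
                           mode = c("remove", "silence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "force_fit"), fraction >= 0, fraction <= 1)
  idx <- .lesion_indices(fit$weights$N, fraction, seed)
  if (!length(idx)) return(fit)
  fit$weights$omega0 <- .zero_rows_cols(fit$weights$omega0, idx, mode)
  fit$phi[idx, ] <- 0
  if (mode == "remove") {
    fit$weights$eta[idx, ] <- 0
    if (!is.null(fit$input)) fit$input$W_in[idx, ] <- 0
    fit$state_final$v[idx] <- switch(fit$model,
      theta = 0, rate = 0, fit$neuron$v_reset)
    for (f in c("r", "hr", "Ipsc", "hI", "u", "refr"))
      fit$state_final[[f]][idx] <- 0
  }
  fit$lesioned <- idx
  fit
}
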