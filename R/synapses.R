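#' Synaptic filter parameters
#'
#' Spikes are filtered into continuous, unit-area synaptic variables.
#' `single_exp` decays with one time constant `tau_s`; `double_exp` has a
#' rise time `tau_r` and decay time `tau_d` (defaults 2 ms and 20 ms); the
#' `alpha` filter is the double-exponential limit `tau_r = tau_d`.
#'
#' @param kind filter type.
#' @param tau_s single-exponential time constant (ms).
#' @param tau_r double-exponential rise time (ms).
#' @param tau_d double-exponential decay time (ms).
#' @return object of class `synapse_params`.
#' @export
synapse_params <- function(kind = c("double_exp", "single_exp", "alpha"),
                           tau_s = 20, tau_r = 2, tau_d = 20) {
  kind <- match.arg(kind)
  if (kind == "alpha") {
    if (!missing(tau_r) && !missing(tau_d) && tau_r != tau_d)
      stop("alpha filter requires tau_r == tau_d")
    if (missing(tau_r)) tau_r <- tau_d
    tau_d <- tau_r
  }
  stopifnot(tau_s > 0, tau_r > 0, tau_d > 0)
  structure(list(kind = kind, tau_s = tau_s, tau_r = tau_r, tau_d = tau_d),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("<synapse_params:", x$kind,
      if (x$kind == "single_exp") sprintf("tau_s = %g ms", x$tau_s)
      else sprintf("tau_r = %g ms, tau_d = %g ms", x$tau_r, x$tau_d), ">\n")
  invisible(x)
}

#' Create an empty synaptic filter state
#'
#' @param N number of neurons.
#' @return list with `r` (filtered output) and `h` (auxiliary rise
#'   variable, double-exponential only), both zero.
#' @export
filter_state <- function(N) {
  list(r = numeric(N), h = numeric(N))
}

#' Advance a synaptic filter one step
#'
#' The decay is integrated exactly over each step (multiplication by
#' `exp(-dt/tau)`, with the rise-to-decay coupling of the
#' double-exponential cascade also treated in closed form), and each
#' spike applies an impulse: the rise variable `h` jumps by
#' `1/(tau_r tau_d)` for the double-exponential (and alpha) filter, the
#' trace itself by `1/tau_s` for the single-exponential filter.  A single
#' spike therefore injects unit area into `r` up to the O(dt/tau_d)
#' sampling error of the discrete trace.
#'
#' @param fs a [filter_state()].
#' @param spikes logical vector (or integer indices) of spiking neurons.
#' @param dt time step (ms).
#' @param params a [synapse_params()].
#' @return the advanced filter state.
#' @export
update_filter <- function(fs, spikes, dt, params = synapse_params()) {
  stopifnot(dt > 0)
  if (is.logical(spikes)) spikes <- which(spikes)
  if (params$kind == "single_exp") {
    fs$r <- fs$r * exp(-dt / params$tau_s)
    fs$r[spikes] <- fs$r[spikes] + 1 / params$tau_s
  } else {
    e_d <- exp(-dt / params$tau_d)
    e_r <- exp(-dt / params$tau_r)
    c_de <- if (abs(params$tau_r - params$tau_d) < 1e-12) dt * e_d
      else (e_d - e_r) / (1 / params$tau_r - 1 / params$tau_d)
    fs$r <- fs$r * e_d + fs$h * c_de
    fs$h <- fs$h * e_r
    fs$h[spikes] <- fs$h[spikes] + 1 / (params$tau_r * params$tau_d)
  }
  fs
}

#' Build the sparse static (chaos-inducing) weight matrix
#'
#' Entries are nonzero independently with probability `p`.  For the
#' spiking models the nonzero entries are Normal(0, 1/(N p^2)) — i.e. the
#' matrix as a whole (zeros included) has the 1/(N p) variance of the
#' classic chaotic-reservoir scaling — which places the printed working
#' gains (G = 0.04 LIF, 10 theta, 5e3 Izhikevich) in the chaotic regime.
#' For the rate model the nonzero entries are Normal(0, 1/(N p)^2), the
#' weak-coupling convention under which the G = 1, Q = 1.5 rate reservoir
#' runs below 30 Hz and the feedback and static fluctuations balance.
#' Pass `sigma` to override either convention explicitly.
#'
#' For the LIF and theta models the sample mean of the nonzero entries is
#' explicitly subtracted so the matrix sums to zero, counterbalancing
#' firing-rate heterogeneity; Izhikevich and rate matrices are left
#' uncorrected.
#'
#' @param N number of neurons (>= 2).
#' @param p connection probability in (0, 1].
#' @param model model family the matrix is for.
#' @param seed optional integer seed.
#' @param mean_zero `"auto"` (model-dependent, see above), `TRUE`, `FALSE`,
#'   or `"row"` for per-row centring.
#' @param sigma optional standard deviation of the nonzero entries,
#'   overriding the model default.
#' @return a sparse `dgCMatrix` with attribute `sigma_omega`, the standard
#'   deviation of the nonzero-entry distribution.
#' @export
build_static_weights <- function(N, p, model = c("izhikevich", "theta", "lif", "rate"),
                                 seed = NULL, mean_zero = "auto", sigma = NULL) {
  model <- match.arg(model)
  if (!(p > 0 && p <= 1)) stop("sparsity p must lie in (0, 1]")
  stopifnot(N >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma))
    sigma <- if (model == "rate") 1 / (N * p) else 1 / (p * sqrt(N))
  mask <- matrix(runif(N * N) < p, N, N)
  vals <- rnorm(sum(mask), 0, sigma)
  if (identical(mean_zero, "auto")) mean_zero <- model %in% c("lif", "theta")
  M <- matrix(0, N, N)
  M[mask] <- vals
  if (identical(mean_zero, "row")) {
    for (i in seq_len(N)) {
      nz <- which(mask[i, ])
      if (length(nz)) M[i, nz] <- M[i, nz] - mean(M[i, nz])
    }
  } else if (isTRUE(mean_zero)) {
    M[mask] <- M[mask] - mean(M[mask])
  }
  out <- as(as(M, "CsparseMatrix"), "generalMatrix")
  attr(out, "sigma_omega") <- sigma
  out
}

#' Bundle the static weights, encoders and gain structure of a reservoir
#'
#' @param N network size; `p` sparsity; `G` static gain; `Q` feedback gain.
#' @param p,G,Q see above.
#' @param m supervisor dimension (encoder columns).
#' @param model model family.
#' @param seed optional integer seed (draws the static matrix, then the
#'   encoders, in that order).
#' @param sigma optional nonzero-entry standard deviation forwarded to
#'   [build_static_weights()].
#' @return object of class `weight_config`: `omega0` (sparse static
#'   matrix), `eta` (N x m encoders, uniform on \[-1, 1\]), `sigma_omega`,
#'   and the scalar settings.
#' @export
weight_config <- function(N, p, G, Q, m, model = c("izhikevich", "theta", "lif", "rate"),
                          seed = NULL, sigma = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  omega0 <- build_static_weights(N, p, model, sigma = sigma)
  eta <- matrix(runif(N * m, -1, 1), N, m)
  structure(list(N = N, p = p, G = G, Q = Q, m = m, model = model,
                 omega0 = omega0, eta = eta,
                 sigma_omega = attr(omega0, "sigma_omega"), seed = seed),
            class = "weight_config")
}

#' Compose the effective (dense) weight matrix
#'
#' `omega = G omega0 + Q eta phi^T`: the static chaotic backbone plus the
#' rank-m learned feedback.
#'
#' @param omega0 N x N static matrix (sparse or dense).
#' @param G,Q gains.
#' @param eta N x m encoder matrix.
#' @param phi N x m decoder matrix.
#' @return dense N x N matrix.
#' @export
effective_weights <- function(omega0, G, Q, eta, phi) {
  eta <- as.matrix(eta)
  phi <- as.matrix(phi)
  if (nrow(omega0) != ncol(omega0)) stop("omega0 must be square")
  if (!all(dim(eta) == dim(phi)) || nrow(eta) != nrow(omega0))
    stop("shape mismatch: eta and phi must both be N x m")
  as.matrix(G * omega0) + Q * tcrossprod(eta, phi)
}

#' Order-of-magnitude feedback gain heuristic
#'
#' Balancing the fluctuations of the static input (which scale like
#' `G sigma_omega sqrt(<r^2>)` in a large sparse balanced network) against
#' the O(1) learned feedback suggests `Q = c G sigma_omega sqrt(<r^2>)`
#' with c of order one (default 1).  Here `sigma_omega` is the standard
#' deviation of the root-N-scaled static weight distribution and
#' `rate_rms` the root-mean-square filtered rate measured from an
#' untrained run.
#'
#' @param G static gain.
#' @param sigma_omega std. dev. of the scaled static weight distribution.
#' @param rate_rms sqrt of the mean squared filtered rate.
#' @param c proportionality constant.
#' @return suggested feedback gain Q.
#' @export
suggested_Q <- function(G, sigma_omega, rate_rms, c = 1) {
  stopifnot(G >= 0, sigma_omega >= 0, rate_rms >= 0, c > 0)
  c * G * sigma_omega * rate_rms
}
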