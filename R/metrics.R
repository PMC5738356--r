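#' Mean network firing rate
#'
#' Total spikes divided by (N x window length), in Hz.
#'
#' @param raster data.frame with columns `time_ms` and `neuron`.
#' @param window `c(t0, t1)` in ms; spikes with `t0 < t <= t1` count.
#' @param N number of neurons in the network.
#' @return rate in Hz.
#' @export
mean_firing_rate <- function(raster, window, N) {
  stopifnot(N >= 1, length(window) == 2)
  if (diff(window) <= 0) stop("empty window")
  n <- sum(raster$time_ms > window[1] & raster$time_ms <= window[2])
  1000 * n / (N * diff(window))
}

#' Interspike-interval statistics
#'
#' Per-neuron ISI lists, coefficients of variation (sd/mean of the ISIs;
#' neurons with fewer than two spikes are excluded and counted), and a
#' pooled histogram (optionally log-spaced bins).
#'
#' @param raster data.frame with `time_ms`, `neuron`.
#' @param breaks number of histogram bins.
#' @param log_bins use log-spaced bin edges.
#' @return list with `isi` (per-neuron list), `cv` (named vector),
#'   `n_excluded`, and `hist`.
#' @export
isi_stats <- function(raster, breaks = 30, log_bins = FALSE) {
  by_n <- split(raster$time_ms, raster$neuron)
  isi <- lapply(by_n, function(t) diff(sort(t)))
  isi <- isi[lengths(isi) >= 1]
  cv <- vapply(isi, function(d) if (length(d) >= 2) sd(d) / mean(d) else NA_real_,
               numeric(1))
  n_excluded <- length(by_n) - sum(!is.na(cv))
  pooled <- unlist(isi, use.names = FALSE)
  h <- if (length(pooled)) {
    if (log_bins) {
      edges <- exp(seq(log(max(min(pooled), 1e-3)), log(max(pooled) + 1e-9),
                       length.out = breaks + 1))
      hist(pooled, breaks = unique(edges), plot = FALSE)
    } else hist(pooled, breaks = breaks, plot = FALSE)
  } else NULL
  list(isi = isi, cv = cv[!is.na(cv)], n_excluded = n_excluded, hist = h)
}

#' Time-averaged L2 error between decoded output and target
#'
#' `sqrt(mean_t |xhat(t) - x(t)|^2)` over aligned sample columns
#' (`type = "time_avg"`, the default), or the raw integral
#' `sqrt(sum_t |xhat - x|^2 dt)` when `type = "integral"`.
#'
#' @param xhat,x `m x K` matrices (or vectors) on the same time grid.
#' @param type normalisation.
#' @param dt_ms sample spacing, required for `type = "integral"`.
#' @return scalar error; take `log()` for the log-L2 read-out.
#' @export
l2_error <- function(xhat, x, type = c("time_avg", "integral"), dt_ms = NULL) {
  type <- match.arg(type)
  if (is.null(dim(xhat))) xhat <- matrix(xhat, nrow = 1)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(dim(xhat) == dim(x))) stop("misaligned traces")
  e2 <- colSums((xhat - x)^2)
  if (type == "time_avg") sqrt(mean(e2))
  else {
    if (is.null(dt_ms)) stop("dt_ms required for integral normalisation")
    sqrt(sum(e2) * dt_ms)
  }
}

#' Time-averaged correlation between output and target
#'
#' Pearson correlation per component over time, averaged over components.
#' Components whose target is constant are excluded (their count is
#' reported in attribute `n_excluded`); components whose output is
#' constant against a varying target contribute 0.
#'
#' @param xhat,x `m x K` matrices (or vectors) on the same grid, K >= 2.
#' @return mean correlation in \[-1, 1\].
#' @export
time_avg_correlation <- function(xhat, x) {
  if (is.null(dim(xhat))) xhat <- matrix(xhat, nrow = 1)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(dim(xhat) == dim(x))) stop("misaligned traces")
  if (ncol(x) < 2) stop("need at least 2 samples")
  sx <- apply(x, 1, sd)
  keep <- sx > 0
  if (!any(keep)) stop("all target components constant")
  rs <- vapply(which(keep), function(i) {
    if (sd(xhat[i, ]) == 0) 0 else cor(xhat[i, ], x[i, ])
  }, numeric(1))
  out <- mean(rs)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Classify correct replays with a moving-average error function
#'
#' Slides one period of the teaching signal along the decoded output and
#' accumulates the squared error `E(t) = sum_i int_t^{t+T} (xhat_i(t') -
#' x_i(t' - t))^2 dt'`.  Local minima of `E` below `threshold` are counted
#' as correct replays (enforcing at least half a period of separation);
#' the fraction of the output duration covered by correct replays is
#' `n_correct * T / duration`.
#'
#' @param xhat `m x K` decoded trace sampled every `dt_ms`.
#' @param x_period `m x nT` one period of the teaching signal on the same
#'   grid.
#' @param dt_ms sample spacing (ms).
#' @param threshold acceptance level for `E(t*)`; default 25% of the
#'   time-integrated power of the teaching signal over one period.
#' @return list (`ReplayReport`): `E_trace` (data.frame `t_ms`, `E`),
#'   `replay_times_ms`, `n_correct`, `fraction_correct_duration`,
#'   `threshold`.
#' @export
replay_classifier <- function(xhat, x_period, dt_ms, threshold = NULL) {
  if (is.null(dim(xhat))) xhat <- matrix(xhat, nrow = 1)
  if (is.null(dim(x_period))) x_period <- matrix(x_period, nrow = 1)
  stopifnot(nrow(xhat) == nrow(x_period), dt_ms > 0)
  nT <- ncol(x_period)
  K <- ncol(xhat)
  if (K < nT) stop("decoded trace shorter than one supervisor period")
  dt_s <- dt_ms / 1000
  if (is.null(threshold)) threshold <- 0.25 * sum(x_period^2) * dt_s
  if (threshold <= 0) stop("threshold must be positive")
  nE <- K - nT + 1
  E <- numeric(nE)
  for (j in seq_len(nT)) {
    d <- xhat[, j:(j + nE - 1), drop = FALSE] - x_period[, j]
    E <- E + colSums(d * d)
  }
  E <- E * dt_s
  # local minima (strictly lower than the left neighbour, no higher than the right)
  cand <- which(diff(c(Inf, E)) < 0 & diff(c(E, Inf)) >= 0)
  cand <- cand[E[cand] < threshold]
  # enforce separation of at least half a period
  sep <- floor(nT / 2)
  times <- integer(0)
  last <- -Inf
  for (k in cand) {
    if (k - last >= sep) {
      times <- c(times, k)
      last <- k
    }
  }
  t_ms <- (seq_len(nE) - 1) * dt_ms
  Tdur <- nT * dt_ms
  list(E_trace = data.frame(t_ms = t_ms, E = E),
       replay_times_ms = t_ms[times],
       n_correct = length(times),
       fraction_correct_duration = min(1, length(times) * Tdur / (K * dt_ms)),
       threshold = threshold)
}

#' Eigenvalue spectrum of a weight matrix
#'
#' For a `force_fit`, returns the spectra of the static matrix `G omega0`
#' (before training) and of the effective matrix
#' `G omega0 + Q eta phi'` (after training).
#'
#' @param x square matrix or `force_fit`.
#' @param ... unused.
#' @return complex eigenvalue vector, or for fits a list with `before`
#'   and `after`.
#' @export
eigenspectrum <- function(x, ...) UseMethod("eigenspectrum")

#' @export
eigenspectrum.default <- function(x, ...) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("matrix must be square")
  eigen(x, only.values = TRUE)$values
}

#' @export
eigenspectrum.force_fit <- function(x, ...) {
  w <- x$weights
  before <- eigenspectrum(as.matrix(w$G * w$omega0))
  after <- eigenspectrum(effective_weights(w$omega0, w$G, w$Q, w$eta, x$phi))
  list(before = before, after = after)
}

#' Binned mean population activity and its dominant frequency
#'
#' Spike counts per time bin normalised to a population rate (Hz), plus
#' the dominant frequency of the rate's periodogram (DC excluded).
#'
#' @param raster data.frame with `time_ms`, `neuron`.
#' @param bin_ms bin width (ms).
#' @param N network size.
#' @param window `c(t0, t1)` ms (default: raster extent from 0).
#' @return list: `t_ms` (bin centres), `rate_hz`, `freq_hz`, `power`,
#'   `dominant_hz`.
#' @export
mean_population_activity <- function(raster, bin_ms, N, window = NULL) {
  stopifnot(bin_ms > 0, N >= 1)
  if (is.null(window)) window <- c(0, max(raster$time_ms, bin_ms))
  nb <- floor(diff(window) / bin_ms)
  if (nb < 2) stop("window too short for the requested bin width")
  edges <- window[1] + (0:nb) * bin_ms
  cnt <- hist(raster$time_ms[raster$time_ms > window[1] &
                               raster$time_ms <= edges[nb + 1]],
              breaks = edges, plot = FALSE)$counts
  rate <- 1000 * cnt / (N * bin_ms)
  z <- rate - mean(rate)
  sp <- Mod(fft(z))^2
  nb <- length(z)
  freqs <- (seq_len(nb) - 1) / (nb * bin_ms / 1000)
  half <- 2:floor(nb / 2)
  dom <- if (length(half) && any(sp[half] > 0)) freqs[half][which.max(sp[half])]
  else NA_real_
  list(t_ms = edges[-1] - bin_ms / 2, rate_hz = rate,
       freq_hz = freqs[half], power = sp[half], dominant_hz = dom)
}

#' Least-squares slope of log(error) against log(N)
#'
#' @param N network sizes (replicated per repetition).
#' @param err corresponding errors.
#' @param n_boot bootstrap resamples (within each N) for a confidence
#'   interval.
#' @return list: `slope`, `intercept`, `ci` (2.5/97.5%), `fit` (the `lm`).
#' @export
fit_loglog_slope <- function(N, err, n_boot = 200) {
  ok <- is.finite(err) & err > 0
  N <- N[ok]; err <- err[ok]
  if (length(unique(N)) < 3) stop("need at least 3 distinct N with finite errors")
  fit <- lm(log(err) ~ log(N))
  slope <- unname(coef(fit)[2])
  boots <- replicate(n_boot, {
    idx <- unlist(lapply(split(seq_along(N), N), function(ii)
      sample(ii, length(ii), replace = TRUE)))
    unname(coef(lm(log(err[idx]) ~ log(N[idx])))[2])
  })
  list(slope = slope, intercept = unname(coef(fit)[1]),
       ci = quantile(boots, c(0.025, 0.975), names = FALSE), fit = fit)
}
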