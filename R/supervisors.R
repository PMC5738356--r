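#' Construct a teaching-signal (supervisor) object
#'
#' A supervisor is a deterministic (up to declared noise) function of time
#' with a declared output dimension `m` and period/duration `T` in
#' seconds.  `eval(t)` takes a vector of times in seconds and returns an
#' `m x length(t)` matrix.
#'
#' @param m output dimension.
#' @param T period (periodic supervisors) or duration (trajectories), s.
#' @param eval vectorised evaluation function.
#' @param label human-readable description.
#' @param periodic whether `eval(t + T) == eval(t)`.
#' @return object of class `supervisor`.
#' @export
supervisor <- function(m, T, eval, label = "supervisor", periodic = TRUE) {
  stopifnot(m >= 1, T > 0, is.function(eval))
  structure(list(m = m, T = T, eval = eval, label = label, periodic = periodic),
            class = "supervisor")
}

#' @export
print.supervisor <- function(x, ...) {
  cat(sprintf("<supervisor: %s | m = %d, T = %g s%s>\n", x$label, x$m, x$T,
              if (x$periodic) ", periodic" else ""))
  invisible(x)
}

#' Sample a supervisor on a time grid
#'
#' @param sup a [supervisor()].
#' @param times_s times in seconds.
#' @return `m x length(times_s)` matrix.
#' @export
sample_supervisor <- function(sup, times_s) {
  out <- sup$eval(times_s)
  if (is.null(dim(out))) out <- matrix(out, nrow = sup$m)
  out
}

.wrap_time <- function(t, T) t - floor(t / T) * T

#' Sinusoidal supervisor
#'
#' @param freq_hz frequency in Hz.
#' @param amplitude peak amplitude.
#' @return a 1-dimensional [supervisor()].
#' @export
sup_sinusoid <- function(freq_hz = 5, amplitude = 1) {
  stopifnot(freq_hz > 0)
  supervisor(1, 1 / freq_hz,
             function(t) matrix(amplitude * sin(2 * pi * freq_hz * t), nrow = 1),
             label = sprintf("%g Hz sinusoid", freq_hz))
}

#' Sawtooth supervisor
#'
#' Rising ramp from -1 to 1 with a discontinuity at the end of each
#' period.
#'
#' @param freq_hz frequency in Hz.
#' @return a 1-dimensional [supervisor()].
#' @export
sup_sawtooth <- function(freq_hz = 5) {
  stopifnot(freq_hz > 0)
  supervisor(1, 1 / freq_hz,
             function(t) matrix(2 * (t * freq_hz - floor(t * freq_hz)) - 1, nrow = 1),
             label = sprintf("%g Hz sawtooth", freq_hz))
}

#' Product-of-sinusoids supervisor
#'
#' `sin(2 pi f1 t) * sin(2 pi f2 t)` (period 0.5 s at the default 4 and
#' 6 Hz), optionally distorted by fresh additive Gaussian white noise at
#' each evaluation.
#'
#' @param f1,f2 component frequencies in Hz.
#' @param noise_sd standard deviation of the additive noise (0 = clean).
#' @return a 1-dimensional [supervisor()].
#' @export
sup_product_of_sines <- function(f1 = 4, f2 = 6, noise_sd = 0) {
  stopifnot(f1 > 0, f2 > 0, noise_sd >= 0)
  # period = 1 / gcd(f1, f2) for commensurate integer-ish frequencies
  g <- function(a, b) if (b < 1e-9) a else g(b, a %% b)
  Tp <- 1 / g(f1, f2)
  supervisor(1, Tp, function(t) {
    x <- sin(2 * pi * f1 * t) * sin(2 * pi * f2 * t)
    if (noise_sd > 0) x <- x + rnorm(length(t), 0, noise_sd)
    matrix(x, nrow = 1)
  }, label = sprintf("product of %g and %g Hz sinusoids%s", f1, f2,
                     if (noise_sd > 0) sprintf(" + noise sd %g", noise_sd) else ""))
}

#' Van der Pol oscillator supervisor
#'
#' The limit cycle of `x'' = mu (1 - x^2) x' - x`, integrated with a
#' fixed-step 4th-order scheme, rescaled so the attractor lies within
#' \[-1, 1\]^2 and sped up in time (20x by default).  `mu = 0.3` gives a
#' near-harmonic cycle, `mu = 5` a relaxation oscillation.
#'
#' @param mu damping parameter (> 0).
#' @param speed temporal speed-up factor.
#' @return a 2-dimensional [supervisor()] with attributes
#'   `amplitude_unscaled` (the classical ~2 limit-cycle amplitude) and
#'   `period_unscaled`.
#' @export
sup_van_der_pol <- function(mu = 0.3, speed = 20) {
  stopifnot(mu > 0, speed > 0)
  deriv <- function(t, y, parms) list(c(y[2], mu * (1 - y[1]^2) * y[2] - y[1]))
  dt <- 0.001
  tt <- seq(0, 40 + 8 * pi * (1 + mu), by = dt)
  tr <- deSolve::ode(c(x = 2, y = 0), tt, deriv, NULL, method = "rk4")
  if (!all(is.finite(tr[, 2:3]))) stop("Van der Pol integration failure")
  # keep the final cycles, then isolate one period between upward zero crossings
  tail_i <- tr[, 1] >= max(tt) / 2
  x <- tr[tail_i, 2]; y <- tr[tail_i, 3]; tcyc <- tr[tail_i, 1]
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  if (length(up) < 2) stop("Van der Pol integration failure: no complete cycle found")
  i0 <- up[length(up) - 1]; i1 <- up[length(up)]
  seg <- i0:i1
  Tun <- tcyc[i1] - tcyc[i0]
  ax <- max(abs(x[seg])); ay <- max(abs(y[seg]))
  fx <- approxfun(tcyc[seg] - tcyc[i0], x[seg] / ax, rule = 2)
  fy <- approxfun(tcyc[seg] - tcyc[i0], y[seg] / ay, rule = 2)
  Ts <- Tun / speed
  out <- supervisor(2, Ts, function(t) {
    tau <- .wrap_time(t * speed, Tun)
    rbind(fx(tau), fy(tau))
  }, label = sprintf("Van der Pol (mu = %g, %gx speed)", mu, speed))
  attr(out, "amplitude_unscaled") <- ax
  attr(out, "period_unscaled") <- Tun
  out
}

#' Lorenz system supervisor
#'
#' A chaotic trajectory of the Lorenz system (`x' = sigma (y - x)`,
#' `y' = x (rho - z) - y`, `z' = x y - B z`), integrated from a burned-in
#' initial condition.  By default each component is centred and scaled to
#' maximum absolute value 1 over the stored trajectory, so the feedback
#' sees O(1) signals; `normalize = FALSE` keeps raw coordinates.
#'
#' @param rho,sigma,B system parameters.
#' @param duration_s length of usable trajectory (seconds of supervisor
#'   time).
#' @param normalize centre/scale components to \[-1, 1\].
#' @param y0 initial condition (before burn-in).
#' @return a 3-dimensional, non-periodic [supervisor()]; times beyond
#'   `duration_s` evaluate at the final point.  Attributes `center` and
#'   `scale` store the normalisation.
#' @export
sup_lorenz <- function(rho = 28, sigma = 10, B = 8 / 3, duration_s = 60,
                       normalize = TRUE, y0 = c(1, 1, 25)) {
  stopifnot(rho > 0, sigma > 0, B > 0, duration_s > 0)
  deriv <- function(t, y, parms) {
    list(c(sigma * (y[2] - y[1]),
           y[1] * (rho - y[3]) - y[2],
           y[1] * y[2] - B * y[3]))
  }
  dt <- 0.005
  burn <- 25
  # supervisor seconds map 1:1 onto Lorenz time units
  tt <- seq(0, burn + duration_s, by = dt)
  tr <- deSolve::ode(y0, tt, deriv, NULL, method = "rk4")
  if (!all(is.finite(tr[, 2:4]))) stop("Lorenz integration failure")
  keep <- tr[, 1] >= burn
  tg <- tr[keep, 1] - burn
  XYZ <- tr[keep, 2:4, drop = FALSE]
  ctr <- if (normalize) colMeans(XYZ) else c(0, 0, 0)
  scl <- if (normalize) apply(abs(sweep(XYZ, 2, ctr)), 2, max) else c(1, 1, 1)
  fs <- lapply(1:3, function(j) approxfun(tg, (XYZ[, j] - ctr[j]) / scl[j], rule = 2))
  out <- supervisor(3, duration_s, function(t) {
    rbind(fs[[1]](t), fs[[2]](t), fs[[3]](t))
  }, label = sprintf("Lorenz trajectory (rho = %g)", rho), periodic = FALSE)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Score of the Ode-to-Joy teaching phrase
#'
#' The four-bar phrase over the five notes C-G: quarter notes are 0.25 s,
#' the closing half note 0.5 s, total 4 s.  `bars` selects a prefix (e.g.
#' `bars = 1` gives the 1 s first bar used for scaled-down training).
#'
#' @param bars how many leading bars to keep (1-4).
#' @return data.frame with columns `note` and `dur` (`"q"` or `"h"`).
#' @export
ode_to_joy_score <- function(bars = 4) {
  stopifnot(bars >= 1, bars <= 4)
  notes <- c("E", "E", "F", "G", "G", "F", "E", "D",
             "C", "C", "D", "E", "E", "D", "D")
  durs <- c(rep("q", 14), "h")
  bar_of <- c(rep(1, 4), rep(2, 4), rep(3, 4), rep(4, 3))
  keep <- bar_of <= bars
  data.frame(note = notes[keep], dur = durs[keep], stringsAsFactors = FALSE)
}

#' Note-pulse song supervisor
#'
#' Converts a monophonic score over the notes C, D, E, F, G into a
#' 5-dimensional pulse signal: a quarter note contributes the positive
#' half of a 2 Hz sinusoid (0.25 s) in its note's component, a half note
#' the positive half of a 1 Hz sinusoid (0.5 s).  At any time at most one
#' component is nonzero.
#'
#' @param score data.frame with columns `note` (C/D/E/F/G) and `dur`
#'   (`"q"` quarter or `"h"` half), e.g. [ode_to_joy_score()].
#' @return a 5-dimensional periodic [supervisor()] whose period is the
#'   total score duration.
#' @export
sup_note_song <- function(score = ode_to_joy_score()) {
  stopifnot(nrow(score) >= 1)
  notes <- c("C", "D", "E", "F", "G")
  comp <- match(score$note, notes)
  if (anyNA(comp)) stop("unknown note symbol: ",
                        paste(unique(score$note[is.na(comp)]), collapse = ", "))
  durs <- c(q = 0.25, h = 0.5)[score$dur]
  if (anyNA(durs)) stop("unknown duration symbol (use 'q' or 'h')")
  starts <- cumsum(c(0, durs[-length(durs)]))
  Tt <- sum(durs)
  supervisor(5, Tt, function(t) {
    tau <- .wrap_time(t, Tt)
    out <- matrix(0, 5, length(t))
    for (i in seq_along(comp)) {
      inn <- tau >= starts[i] & tau < starts[i] + durs[i]
      if (any(inn)) {
        # positive half of a sinusoid with period 2*dur
        out[comp[i], inn] <- sin(pi * (tau[inn] - starts[i]) / durs[i])
      }
    }
    out
  }, label = sprintf("note song (%d notes, %g s)", nrow(score), Tt))
}

#' High-dimensional temporal signal (HDTS)
#'
#' Partitions \[0, T\] into `m` subintervals `I_n` and emits one pulse
#' component per subinterval, centred at `T (2n - 1) / (2m)`.  The
#' `"sine"` shape is `|sin(m pi t / T)|` restricted to `I_n` (exactly one
#' component nonzero at any interior time); the `"gaussian"` shape is a
#' Gaussian bump of width `sigma` centred in each subinterval (all
#' components peak at 1).
#'
#' @param T_s total duration in seconds.
#' @param m number of subintervals/components.
#' @param shape `"sine"` or `"gaussian"`.
#' @param sigma Gaussian width in seconds (default half the subinterval).
#' @return an m-dimensional periodic [supervisor()] with attribute
#'   `hdts_spec`.
#' @export
sup_hdts <- function(T_s, m, shape = c("sine", "gaussian"), sigma = T_s / (2 * m)) {
  shape <- match.arg(shape)
  stopifnot(T_s > 0, m >= 1, sigma > 0)
  centers <- T_s * (2 * seq_len(m) - 1) / (2 * m)
  ev <- if (shape == "sine") {
    function(t) {
      tau <- .wrap_time(t, T_s)
      idx <- pmin(floor(tau * m / T_s) + 1, m)
      out <- matrix(0, m, length(t))
      out[cbind(idx, seq_along(t))] <- abs(sin(m * pi * tau / T_s))
      out
    }
  } else {
    function(t) {
      tau <- .wrap_time(t, T_s)
      out <- matrix(0, m, length(t))
      for (n in seq_len(m)) out[n, ] <- exp(-((tau - centers[n])^2) / sigma^2)
      out
    }
  }
  out <- supervisor(m, T_s, ev, label = sprintf("%s HDTS (%d pulses over %g s)",
                                                shape, m, T_s))
  attr(out, "hdts_spec") <- list(T = T_s, m = m, shape = shape, sigma = sigma)
  out
}

#' Chain of successive half-wave pulses
#'
#' `K` contiguous, non-overlapping pulses; pulse `n` is the positive half
#' of a sinusoid with the stated period (width `period_ms / 2`), active in
#' component `n` only.  Models a clock-like feedforward chain (e.g. 500
#' pulses of a 20 ms-period sinusoid spanning 5 s).
#'
#' @param K number of pulses/components.
#' @param period_ms full sinusoid period in ms (pulse width is half).
#' @return a K-dimensional periodic [supervisor()] of duration
#'   `K * period_ms / 2000` seconds.
#' @export
sup_pulse_chain <- function(K = 500, period_ms = 20) {
  stopifnot(K >= 1, period_ms > 0)
  w <- period_ms / 2000 # pulse width, s
  Tt <- K * w
  out <- supervisor(K, Tt, function(t) {
    tau <- .wrap_time(t, Tt)
    idx <- pmin(floor(tau / w) + 1, K)
    res <- matrix(0, K, length(t))
    res[cbind(idx, seq_along(t))] <- sin(pi * (tau - (idx - 1) * w) / w)
    res
  }, label = sprintf("pulse chain (%d pulses, %g ms period)", K, period_ms))
  attr(out, "hdts_spec") <- list(T = Tt, m = K, shape = "sine", sigma = w / 2)
  out
}

#' Synthetic moving-blob pixel supervisor
#'
#' A Gaussian intensity blob orbiting the centre of a `side x side` pixel
#' frame, one full revolution per period; each supervisor component is one
#' pixel's intensity in \[0, 1\].  A stand-in for naturalistic
#' high-dimensional (movie-like) teaching signals.
#'
#' @param T_s period of one revolution, seconds.
#' @param side frame edge length in pixels (m = side^2).
#' @param blob_sd blob width in pixels.
#' @return a `side^2`-dimensional periodic [supervisor()].
#' @export
sup_moving_blob <- function(T_s = 2, side = 8, blob_sd = side / 5) {
  stopifnot(T_s > 0, side >= 2)
  gx <- rep(seq_len(side), side)
  gy <- rep(seq_len(side), each = side)
  c0 <- (side + 1) / 2
  rad <- side / 3
  supervisor(side^2, T_s, function(t) {
    tau <- .wrap_time(t, T_s)
    ang <- 2 * pi * tau / T_s
    cx <- c0 + rad * cos(ang)
    cy <- c0 + rad * sin(ang)
    d2 <- outer(gx, cx, function(a, b) (a - b)^2) +
      outer(gy, cy, function(a, b) (a - b)^2)
    exp(-d2 / (2 * blob_sd^2))
  }, label = sprintf("moving blob movie (%dx%d px, %g s)", side, side, T_s))
}
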