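#' Decoder state for recursive least squares
#'
#' Holds the linear decoders `phi` (N x m, initialised to zero), the
#' running inverse-correlation estimate `P` (initialised to
#' `lambda_inv * I`), and the update variant.  The default
#' `"denominator"` variant divides the decoder update by `1 + r' P r`,
#' which is the same as updating the decoders with the already-updated
#' `P(t)`; the recursion is then exactly equivalent to batch ridge
#' regression with ridge `1 / lambda_inv` (the Sherman-Morrison form,
#' used as a correctness oracle).  The `"plain"` variant omits that
#' denominator from the decoder update only.
#'
#' @param N number of basis functions (neurons).
#' @param m output dimension.
#' @param lambda_inv reciprocal of the ridge regulariser lambda; `P`
#'   starts at `lambda_inv * I`.  Quoted in ms-based units to match the
#'   integration clock.
#' @param variant `"denominator"` (default) or `"plain"`.
#' @return object of class `decoder_state`.
#' @export
decoder_state <- function(N, m, lambda_inv, variant = c("denominator", "plain")) {
  variant <- match.arg(variant)
  stopifnot(N >= 1, m >= 1, lambda_inv > 0)
  structure(list(phi = matrix(0, N, m),
                 P = diag(lambda_inv, N),
                 lambda_inv = lambda_inv,
                 variant = variant),
            class = "decoder_state")
}

#' Network approximant
#'
#' The decoded output `xhat = phi' r`, an m-vector.
#'
#' @param phi N x m decoder matrix.
#' @param r length-N vector of filtered rates.
#' @return numeric m-vector.
#' @export
approximant <- function(phi, r) {
  phi <- as.matrix(phi)
  if (nrow(phi) != length(r)) stop("shape mismatch: phi has ", nrow(phi),
                                   " rows but r has length ", length(r))
  drop(crossprod(phi, r))
}

#' One recursive least squares update
#'
#' Rank-one update of the inverse-correlation estimate
#' `P <- P - (P r r' P) / (1 + r' P r)` followed by the decoder update
#' `phi <- phi - P r e'` using the updated `P` (each output dimension
#' updates its own decoder column against the shared `P`).  `e = xhat - x`
#' is the error of the *prior* decoders.
#'
#' @param ds a [decoder_state()].
#' @param r length-N filtered-rate vector sampled at the update time.
#' @param e length-m error vector `xhat - x`.
#' @return the updated `decoder_state`.
#' @export
rls_step <- function(ds, r, e) {
  stopifnot(inherits(ds, "decoder_state"))
  if (length(r) != nrow(ds$phi)) stop("r has wrong length")
  if (length(e) != ncol(ds$phi)) stop("e has wrong dimension")
  Pr <- drop(ds$P %*% r)
  denom <- 1 + sum(r * Pr)
  if (!is.finite(denom)) stop("training divergence: non-finite RLS denominator")
  ds$P <- ds$P - tcrossprod(Pr) / denom
  ds$P <- (ds$P + t(ds$P)) / 2
  scale <- if (ds$variant == "denominator") denom else 1
  ds$phi <- ds$phi - tcrossprod(Pr, e) / scale
  if (!all(is.finite(ds$P))) stop("training divergence: non-finite P (conditioning collapse)")
  ds
}
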