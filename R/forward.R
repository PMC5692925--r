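#' Frequency grid for spectral prediction and fitting
#'
#' @param from,to Range in Hz; the model is fitted over 1-100 Hz.
#' @param by Spacing in Hz (default 0.5).
#' @return Numeric vector of strictly increasing frequencies.
#' @export
frequency_grid <- function(from = 1, to = 100, by = 0.5) {
  stopifnot(from >= 1, to <= 100, from < to, by > 0)
  seq(from, to, by = by)
}

#' Linearised transfer function of the microcircuit
#'
#' Frequency response from exogenous drive to the observed mixture,
#' obtained from the Laplace transform of the linearised, conduction-
#' delayed dynamics at the fixed point. Eliminating the current states
#' gives, per angular frequency \code{w} (rad/ms),
#' \deqn{M(w) x_v = B, \quad
#'   M(w) = (iw)^2 I + 2 K iw + K^2 - K (A S'(x^*) E(w)),}
#' with \code{E(w) = exp(-iwD)} applied to between-population couplings,
#' \code{K = diag(1/T)}, \code{B = C kappa_SS e_1}, and
#' \code{H(w) = L x_v}. Stability is gated on the eigenvalues of the
#' first-order delay-adjusted Jacobian (see \code{\link{delay_jacobian}}).
#'
#' @param params A \code{cmc_parameters} object.
#' @param grid Frequencies in Hz (default \code{\link{frequency_grid}()}).
#' @return Complex vector of \code{H} evaluated at each grid frequency.
#' @export
transfer_function <- function(params, grid = frequency_grid()) {
  JD <- delay_jacobian(params, cmc_jacobian(params, fixed_point(params)))
  ev <- eigen(JD, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop(sprintf("unstable Jacobian: eigenvalue %s has non-negative real part",
                 format(ev[which.max(Re(ev))], digits = 4)))
  omega <- 2 * pi * grid / 1000
  as.complex(cmc_transfer_cpp(rate_constants(params),
                              coupling_matrix(params),
                              params$r / 4, params$C, params$L, params$D,
                              omega))
}

#' Innovations (drive) spectrum
#'
#' White + pink mixture \code{g_u(f) = white + pink / f}; the prior
#' expectation is dominated by the white term because the data handed to
#' the inversion are pre-whitened.
#'
#' @param params A \code{cmc_parameters} object.
#' @param grid Frequencies in Hz.
#' @return Non-negative numeric vector.
#' @export
input_spectrum <- function(params, grid = frequency_grid()) {
  params$input[["white"]] + params$input[["pink"]] / grid
}

#' Channel-noise spectrum: white floor plus alpha Gaussian
#'
#' \code{g_n(f) = a_n + a_alpha exp(-(f - mu_alpha)^2 / (2 sigma_alpha^2))}.
#' The alpha centre is hard-constrained to [8, 13] Hz.
#'
#' @param params A \code{cmc_parameters} object.
#' @param grid Frequencies in Hz.
#' @return Non-negative numeric vector.
#' @export
noise_spectrum <- function(params, grid = frequency_grid()) {
  no <- params$noise
  if (no[["alpha_mu"]] < 8 || no[["alpha_mu"]] > 13)
    stop("alpha centre frequency must lie in [8, 13] Hz")
  no[["white"]] + no[["alpha_amp"]] *
    exp(-(grid - no[["alpha_mu"]])^2 / (2 * no[["alpha_sigma"]]^2))
}

#' Predicted observed power spectrum
#'
#' The generative prediction on the (whitened) data scale: a neural
#' component \code{|H|^2 g_u} shaped by the linearised circuit, plus the
#' channel-noise component. Deterministic in the parameters.
#'
#' @param params A \code{cmc_parameters} object.
#' @param grid Frequencies in Hz.
#' @return A list of class \code{predicted_spectrum} with elements
#'   \code{grid}, \code{neural}, \code{noise} and \code{total}
#'   (bin-wise sum, amplitude^2 units).
#' @export
predicted_spectrum <- function(params, grid = frequency_grid()) {
  H <- transfer_function(params, grid)
  neural <- Mod(H)^2 * input_spectrum(params, grid)
  noise <- noise_spectrum(params, grid)
  structure(list(grid = grid, neural = neural, noise = noise,
                 total = neural + noise),
            class = "predicted_spectrum")
}

#' @export
print.predicted_spectrum <- function(x, ...) {
  cat(sprintf("Predicted spectrum: %d bins, %.3g-%.3g Hz\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  total power %.4g (neural %.3g, noise %.3g)\n",
              sum(x$total), sum(x$neural), sum(x$noise)))
  invisible(x)
}
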