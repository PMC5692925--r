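#' Centred sigmoid firing function
#'
#' Presynaptic firing-rate deviation as a function of membrane potential:
#' a logistic centred on zero, \code{S(v) = 1/(1+exp(-r v)) - 1/2}. Odd,
#' bounded in (-1/2, 1/2), with slope \code{r/4} at the origin.
#'
#' @param v Membrane potential (mV), any numeric array.
#' @param r Sigmoid slope (1/mV), positive scalar.
#' @param deriv If \code{TRUE}, return dS/dv instead of S.
#' @return Firing-rate deviation (or its derivative), same shape as \code{v}.
#' @export
sigmoid_firing <- function(v, r, deriv = FALSE) {
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  stopifnot(is.numeric(r), length(r) == 1, r > 0)
  s <- stats::plogis(r * v)
  if (deriv) r * s * (1 - s) else s - 0.5
}

#' Time derivative of the microcircuit state
#'
#' Second-order synaptic dynamics per population p (kappa = 1/T):
#' \deqn{\dot x_v = x_i, \quad
#'       \dot x_i = \kappa U - 2 \kappa x_i - \kappa^2 x_v}
#' where \code{U} collects the signed, gain-weighted presynaptic firing of
#' afferent populations plus the exogenous drive \code{C u} onto the spiny
#' stellate cells.
#'
#' @param state Numeric length-8 vector \code{c(x_v, x_i)} ordered
#'   (SS, SP, II, DP).
#' @param params A \code{cmc_parameters} object.
#' @param u Exogenous input (scalar).
#' @return Length-8 derivative vector.
#' @export
state_derivative <- function(state, params, u = 0) {
  stopifnot(length(state) == 8, is.numeric(state))
  if (any(!is.finite(state))) stop("non-finite state")
  xv <- state[1:4]; xi <- state[5:8]
  kappa <- rate_constants(params)
  A <- coupling_matrix(params)
  U <- drop(A %*% sigmoid_firing(xv, params$r))
  U[1] <- U[1] + params$C * u
  c(xi, kappa * U - 2 * kappa * xi - kappa^2 * xv)
}

#' Fixed point of the microcircuit under steady input
#'
#' Damped Newton iteration from the zero state; the returned state has
#' residual derivative below \code{tol} in the sup norm. With the centred
#' sigmoid and zero input the fixed point is exactly the origin.
#'
#' @param params A \code{cmc_parameters} object.
#' @param u Steady exogenous input.
#' @param tol Residual tolerance (default 1e-9).
#' @param max_iter Maximum Newton iterations.
#' @return Length-8 state vector.
#' @export
fixed_point <- function(params, u = 0, tol = 1e-9, max_iter = 100) {
  x <- numeric(8)
  for (iter in seq_len(max_iter)) {
    f <- state_derivative(x, params, u)
    if (max(abs(f)) < tol) return(x)
    J <- cmc_jacobian(params, x)
    step <- -solve(J, f)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- state_derivative(xn, params, u)
      if (max(abs(fn)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- xn
  }
  f <- state_derivative(x, params, u)
  if (max(abs(f)) >= tol)
    stop(sprintf("fixed point not found: residual %.3e after %d iterations",
                 max(abs(f)), max_iter))
  x
}

#' Analytic Jacobian of the microcircuit dynamics
#'
#' @param params A \code{cmc_parameters} object.
#' @param state Length-8 state at which to linearise (default: origin).
#' @return 8 x 8 matrix in 1/ms units; the upper-right block is the
#'   identity (\code{d xv_dot / d xi}).
#' @export
cmc_jacobian <- function(params, state = numeric(8)) {
  stopifnot(length(state) == 8)
  if (any(!is.finite(state))) stop("non-finite state")
  xv <- state[1:4]
  kappa <- rate_constants(params)
  A <- coupling_matrix(params)
  Sp <- sigmoid_firing(xv, params$r, deriv = TRUE)
  K <- diag(kappa)
  J <- matrix(0, 8, 8)
  J[1:4, 5:8] <- diag(4)
  J[5:8, 1:4] <- K %*% sweep(A, 2, Sp, `*`) - diag(kappa^2)
  J[5:8, 5:8] <- -2 * K
  J
}

#' Delay-adjusted Jacobian
#'
#' Conduction delays are treated at the linearised level through the
#' first-order delay operator: expanding \code{x(t - D)} to first order
#' turns \code{xdot = J x(t - D)} into \code{xdot = (I + D o J)^{-1} J x},
#' where \code{D o J} applies the delay \code{D} (ms) elementwise to
#' between-population coupling entries (current rows, voltage columns of
#' other populations).
#'
#' @param params A \code{cmc_parameters} object.
#' @param J Plain Jacobian from \code{\link{cmc_jacobian}}.
#' @return 8 x 8 delay-adjusted Jacobian.
#' @export
delay_jacobian <- function(params, J = cmc_jacobian(params)) {
  if (params$D == 0) return(J)
  Dmat <- matrix(0, 8, 8)
  cross <- matrix(params$D, 4, 4); diag(cross) <- 0
  Dmat[5:8, 1:4] <- cross
  solve(diag(8) + Dmat * J, J)
}

#' Simulate the full nonlinear microcircuit
#'
#' Fixed-step 4th-order Runge-Kutta integration of the state equations
#' under a sampled exogenous drive (zero-order hold within a step).
#' Between-population coupling uses the conduction-delayed voltages,
#' linearly interpolated from the integration history; delays below the
#' step size are ignored with a warning. Intended as the brute-force
#' check on the linearised spectral predictions.
#'
#' @param params A \code{cmc_parameters} object.
#' @param input Numeric vector of exogenous drive samples, one per step
#'   (recycled scalar allowed).
#' @param dt Step size in ms (default 0.1).
#' @param x0 Initial state (default: origin).
#' @param bound Divergence guard: any \code{|x_v|} above this (mV) aborts
#'   with an instability error.
#' @return A list with \code{time} (ms), \code{xv} (steps x 4 voltage
#'   matrix), and \code{observed = xv \%*\% L}.
#' @export
simulate_timecourse <- function(params, input, dt = 0.1, x0 = numeric(8),
                                bound = 1e4) {
  stopifnot(inherits(params, "cmc_parameters"), dt > 0)
  delay <- params$D
  if (delay > 0 && delay < dt) {
    warning("conduction delay D below the step size is ignored")
    delay <- 0
  }
  n <- length(input)
  stopifnot(n >= 1, length(x0) == 8)
  kappa <- rate_constants(params)
  A <- coupling_matrix(params)
  xv <- cmc_rk4(A, kappa, params$r, params$C, as.numeric(input), dt,
                as.numeric(x0), bound, delay)
  if (any(!is.finite(xv)))
    stop("simulation diverged: |x_v| exceeded bound ", bound)
  colnames(xv) <- cmc_populations()
  list(time = seq_len(nrow(xv)) * dt, xv = xv,
       observed = drop(xv %*% params$L))
}
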