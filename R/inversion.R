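#' Default prior specification for model inversion
#'
#' Prior expectations are the default parameter set, with time-constant
#' priors of 2, 2, 10 and 20 ms for the SP, SS, II and DP populations.
#' Free parameters are log-scale deviations from these expectations.
#' G1, G3, G10, G13 and the spiny-stellate time constant are fixed (their
#' posterior equals the prior): the gain parameters because they have
#' little effect on the fitted spectrum, the SS time constant because
#' small changes can push the circuit through a phase transition. The
#' alpha centre frequency is box-constrained to [8, 13] Hz and its
#' deviation acts on a scaled-logit scale.
#'
#' @param params Prior-mean \code{cmc_parameters} (default
#'   \code{cmc_parameters()}).
#' @return Object of class \code{cmc_priors}: the prior means, the free
#'   parameter names, per-parameter log-scale prior precisions, and the
#'   observation-noise hyperprior.
#' @export
default_priors <- function(params = cmc_parameters()) {
  free <- c("T.SP", "T.II", "T.DP",
            "G.2", "G.4", "G.5", "G.6", "G.7", "G.8", "G.9", "G.11", "G.12",
            "input.white", "input.pink",
            "noise.white", "noise.alpha_amp", "noise.alpha_mu",
            "noise.alpha_sigma")
  precision <- c(rep(16, 3), rep(16, 9), 4, 4, 4, 4, 1, 4)
  names(precision) <- free
  structure(list(params = params, free = free, precision = precision,
                 hyper = list(mean = NA_real_, precision = 1 / 16)),
            class = "cmc_priors")
}

validate_priors <- function(priors) {
  stopifnot(inherits(priors, "cmc_priors"),
            inherits(priors$params, "cmc_parameters"),
            length(priors$free) == length(priors$precision),
            all(names(priors$precision) == priors$free),
            all(priors$precision > 0))
  invisible(priors)
}

#' @export
print.cmc_priors <- function(x, ...) {
  cat(sprintf("Prior specification: %d free parameters\n", length(x$free)))
  cat("  free:", paste(x$free, collapse = " "), "\n")
  invisible(x)
}

#' Write / read a prior specification (YAML)
#'
#' @param priors A \code{cmc_priors} object.
#' @param path File path.
#' @export
write_priors <- function(priors, path) {
  validate_priors(priors)
  yaml::write_yaml(list(params = flatten_params(priors$params),
                        free = as.list(priors$free),
                        precision = as.list(priors$precision),
                        hyper = priors$hyper), path, precision = 15)
  invisible(path)
}

#' @rdname write_priors
#' @return \code{read_priors} returns the \code{cmc_priors} object.
#' @export
read_priors <- function(path) {
  raw <- yaml::read_yaml(path)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(raw$params, tmp, precision = 15)
  params <- read_cmc_parameters(tmp)
  pr <- structure(list(params = params, free = unlist(raw$free),
                       precision = unlist(raw$precision),
                       hyper = lapply(raw$hyper, as.numeric)),
                  class = "cmc_priors")
  validate_priors(pr)
  pr
}

# observation weights: spectral estimates have noise roughly proportional
# to their level (multiplicative periodogram variability), so the Gaussian
# likelihood uses fixed per-bin precision weights 1/y^2 and a single
# fitted relative log-precision lambda
obs_weights <- function(y) 1 / pmax(y, .Machine$double.eps)^2

# free-energy value given a precomputed prediction (or NULL = unstable)
fe_value <- function(mu, v, y, priors, lambda, w = obs_weights(y)) {
  n <- length(y)
  pi_h <- priors$hyper$precision
  h_mean <- if (is.finite(priors$hyper$mean)) priors$hyper$mean else lambda
  if (is.null(mu)) return(-1e10)
  e <- y - mu
  acc <- 0.5 * n * lambda + 0.5 * sum(log(w)) - 0.5 * n * log(2 * pi) -
    0.5 * exp(lambda) * sum(w * e^2)
  comp <- 0.5 * sum(priors$precision * v^2)
  hyp <- -0.5 * pi_h * (lambda - h_mean)^2
  acc - comp + hyp
}

#' Variational free energy of a candidate parameter setting
#'
#' The objective maximised during inversion: Gaussian log-likelihood of
#' the observed spectrum given the model prediction, minus the quadratic
#' prior complexity of the log-scale deviations (exactly zero at the
#' prior means), minus the quadratic hyperprior on \code{lambda}.
#' Spectral estimates carry noise roughly proportional to their level,
#' so the likelihood is heteroscedastic: bin precision is
#' \code{exp(lambda) / y^2}, i.e. a single fitted relative precision.
#' A parameter setting at which the circuit is unstable receives a large
#' finite penalty rather than NaN.
#'
#' @param free Named numeric vector of log-scale deviations over
#'   \code{priors$free}.
#' @param data A whitened, normalised \code{cmc_spectrum}.
#' @param priors A \code{cmc_priors}.
#' @param lambda Log observation precision.
#' @return Scalar free energy.
#' @export
free_energy <- function(free, data, priors, lambda) {
  validate_priors(priors)
  stopifnot(inherits(data, "cmc_spectrum"))
  v <- free[priors$free]
  fwd <- make_fast_forward(priors, data$grid)
  fe_value(fwd(v), v, data$values, priors, lambda)
}

# Finite-difference Jacobian of the prediction wrt free deviations.
prediction_jacobian <- function(fwd, v, mu, step = 1e-4) {
  J <- matrix(NA_real_, length(mu), length(v),
              dimnames = list(NULL, names(v)))
  for (k in seq_along(v)) {
    vp <- v; vp[k] <- vp[k] + step
    mup <- fwd(vp)
    if (is.null(mup)) {
      vp[k] <- v[k] - step
      mup2 <- fwd(vp)
      if (is.null(mup2)) return(NULL)
      J[, k] <- (mu - mup2) / step
    } else J[, k] <- (mup - mu) / step
  }
  J
}

#' Invert the spectral model by variational Laplace
#'
#' Regularised Gauss-Newton ascent on the free energy, alternating
#' parameter and noise-hyperparameter updates. A step is accepted only if
#' it increases the free energy, otherwise the Levenberg damping is
#' increased and the step retried; accepted free energies are therefore
#' monotone. Convergence is declared when the free-energy change stays
#' below \code{tol} for three successive iterations.
#'
#' @param data A whitened, normalised \code{cmc_spectrum} on the model grid.
#' @param priors A \code{cmc_priors}.
#' @param max_iter Maximum outer iterations (default 64).
#' @param tol Free-energy convergence tolerance (default 1e-2).
#' @param fd_step Finite-difference step on the log scale (default 1e-4).
#' @return Object of class \code{cmc_posterior}: posterior mean deviations,
#'   covariance (inverse Gauss-Newton curvature), free-energy trace, noise
#'   hyperparameter, fitted spectrum, and the posterior-mean parameter set.
#' @export
variational_laplace <- function(data, priors, max_iter = 64, tol = 1e-2,
                                fd_step = 1e-4) {
  validate_priors(priors)
  stopifnot(inherits(data, "cmc_spectrum"))
  y <- data$values
  n <- length(y)
  p <- length(priors$free)
  fwd <- make_fast_forward(priors, data$grid)
  v <- stats::setNames(numeric(p), priors$free)
  mu <- fwd(v)
  if (is.null(mu)) stop("model unstable at the prior means; cannot start")
  w <- obs_weights(y)
  e <- y - mu
  lambda <- log(n / sum(w * e^2))
  if (!is.finite(priors$hyper$mean)) priors$hyper$mean <- lambda
  Pi <- priors$precision
  Fcur <- fe_value(mu, v, y, priors, lambda, w)
  if (!is.finite(Fcur)) stop("non-finite free energy at start")
  trace <- Fcur
  damping <- 1
  small <- 0
  for (iter in seq_len(max_iter)) {
    J <- prediction_jacobian(fwd, v, mu, fd_step)
    if (is.null(J)) break
    tau <- exp(lambda)
    H <- tau * crossprod(J, w * J) + diag(Pi, p)
    gvec <- tau * crossprod(J, w * e) - Pi * v
    accepted <- FALSE
    for (try in 1:8) {
      dv <- tryCatch(solve(H + damping * diag(diag(H), p), gvec),
                     error = function(e) NULL)
      if (!is.null(dv)) {
        vn <- stats::setNames(v + as.numeric(dv), names(v))
        mun <- fwd(vn)
        Fn <- fe_value(mun, vn, y, priors, lambda, w)
        if (is.finite(Fn) && Fn > Fcur) {
          v <- vn; mu <- mun; Fcur <- Fn
          damping <- max(damping / 4, 1e-6)
          accepted <- TRUE
          break
        }
      }
      damping <- damping * 8
    }
    if (is.null(mu)) break
    e <- y - mu
    # hyperparameter update (Newton on lambda, accepted only if F rises)
    pi_h <- priors$hyper$precision
    dl1 <- n / 2 - exp(lambda) / 2 * sum(w * e^2) -
      pi_h * (lambda - priors$hyper$mean)
    dl2 <- -exp(lambda) / 2 * sum(w * e^2) - pi_h
    dl <- -dl1 / dl2
    dl <- max(min(dl, 4), -4)
    repeat {
      Fl <- fe_value(mu, v, y, priors, lambda + dl, w)
      if (is.finite(Fl) && Fl > Fcur) {
        lambda <- lambda + dl; Fcur <- Fl
        break
      }
      dl <- dl / 2
      if (abs(dl) < 1e-6) break
    }
    trace <- c(trace, Fcur)
    dF <- trace[length(trace)] - trace[length(trace) - 1]
    small <- if (dF < tol) small + 1 else 0
    if (!accepted || small >= 3) break
  }
  failed <- is.null(mu) || !is.finite(Fcur)
  if (is.null(mu)) mu <- rep(NA_real_, n)
  J <- if (!failed) prediction_jacobian(fwd, v, mu, fd_step) else NULL
  if (is.null(J)) {
    cov <- diag(1 / Pi, p)
    failed <- TRUE
  } else {
    H <- exp(lambda) * crossprod(J, w * J) + diag(Pi, p)
    ev <- eigen(H, symmetric = TRUE)
    if (any(ev$values <= 0)) {
      warning("non-positive-definite curvature; eigenvalues floored")
      ev$values <- pmax(ev$values, 1e-8 * max(ev$values))
    }
    cov <- ev$vectors %*% diag(1 / ev$values, p) %*% t(ev$vectors)
  }
  dimnames(cov) <- list(priors$free, priors$free)
  post_params <- tryCatch(apply_log_deviations(priors$params, v),
                          error = function(e) priors$params)
  structure(list(
    mean = stats::setNames(as.numeric(v), priors$free),
    cov = cov,
    free_energy = Fcur,
    F_trace = trace,
    lambda = lambda,
    priors = priors,
    params = post_params,
    fit = list(grid = data$grid, observed = y, predicted = mu),
    iterations = length(trace) - 1,
    converged = small >= 3,
    failed = failed), class = "cmc_posterior")
}

#' @export
print.cmc_posterior <- function(x, ...) {
  cat(sprintf("Posterior: F = %.3f after %d iterations (%s)\n",
              x$free_energy, x$iterations,
              if (x$failed) "FAILED" else if (x$converged) "converged" else "max iterations"))
  dev <- x$mean[order(-abs(x$mean))][1:min(6, length(x$mean))]
  cat("  largest deviations:",
      paste(sprintf("%s=%+.2f", names(dev), dev), collapse = "  "), "\n")
  invisible(x)
}

#' Empirical priors from the grand-mean spectrum
#'
#' Fits the model to the cohort-mean spectrum starting from the default
#' priors, and returns a prior specification whose expectations are the
#' grand-mean posterior means (precisions unchanged). These empirical
#' priors seed the individual fits.
#'
#' The grand-mean inversion itself uses prior precisions on the gains
#' and time constants scaled by the number of spectra: the mean of n
#' subjects deviates from the population expectation by roughly
#' spread/sqrt(n), and the broadening that averaging inflicts on the
#' mean spectrum (peaks at different frequencies smear out) should be
#' absorbed by the amplitude and noise parameters, not read as synaptic
#' differences.
#'
#' @param cohort_spectra List of whitened, normalised \code{cmc_spectrum}
#'   objects on one grid.
#' @param priors Starting priors (default \code{\link{default_priors}()}).
#' @param precision_scale Factor applied to gain/time-constant prior
#'   precisions for the grand-mean fit only; defaults to the number of
#'   spectra.
#' @param ... Passed to \code{\link{variational_laplace}}.
#' @return A list with \code{priors} (the empirical \code{cmc_priors}) and
#'   \code{posterior} (the grand-mean fit).
#' @export
fit_grand_mean <- function(cohort_spectra, priors = default_priors(),
                           precision_scale = length(cohort_spectra), ...) {
  stopifnot(is.list(cohort_spectra), length(cohort_spectra) >= 1,
            precision_scale >= 1)
  g0 <- cohort_spectra[[1]]$grid
  vals <- vapply(cohort_spectra, function(s) {
    if (any(s$grid != g0)) stop("all spectra must share one frequency grid")
    s$values
  }, numeric(length(g0)))
  m <- new_spectrum(g0, rowMeans(as.matrix(vals)), whitened = TRUE,
                    normalised = TRUE,
                    provenance = list(n = length(cohort_spectra),
                                      kind = "grand mean"))
  gm_priors <- priors
  gt <- grep("^(G|T)\\.", priors$free, value = TRUE)
  gm_priors$precision[gt] <- gm_priors$precision[gt] * precision_scale
  post <- variational_laplace(m, gm_priors, ...)
  emp <- priors
  emp$params <- post$params
  emp$hyper$mean <- NA_real_
  list(priors = emp, posterior = post)
}

#' Fit every subject of a cohort
#'
#' Independent inversions of each spectrum under a common prior
#' specification. Individual failures are recorded, not fatal.
#'
#' @param cohort_spectra List of whitened, normalised \code{cmc_spectrum}.
#' @param priors A \code{cmc_priors} (typically empirical, from
#'   \code{\link{fit_grand_mean}}).
#' @param ... Passed to \code{\link{variational_laplace}}.
#' @return List of class \code{cmc_cohort_fit}: \code{posteriors} (one per
#'   input, order preserved), \code{failed} (logical vector).
#' @export
fit_cohort <- function(cohort_spectra, priors, ...) {
  validate_priors(priors)
  posteriors <- lapply(cohort_spectra, function(s) {
    tryCatch(variational_laplace(s, priors, ...),
             error = function(e) structure(list(error = conditionMessage(e),
                                                failed = TRUE),
                                           class = "cmc_posterior"))
  })
  structure(list(posteriors = posteriors,
                 failed = vapply(posteriors, function(p) isTRUE(p$failed),
                                 logical(1))),
            class = "cmc_cohort_fit")
}

#' @export
print.cmc_cohort_fit <- function(x, ...) {
  cat(sprintf("Cohort fit: %d subjects, %d failed\n",
              length(x$posteriors), sum(x$failed)))
  invisible(x)
}

#' Matrix of posterior mean deviations across a cohort
#'
#' @param fit A \code{cmc_cohort_fit}.
#' @return Numeric matrix subjects x free parameters (NA rows for failures).
#' @export
posterior_means <- function(fit) {
  stopifnot(inherits(fit, "cmc_cohort_fit"))
  ok <- which(!fit$failed)
  if (!length(ok)) stop("no successful fits")
  free <- names(fit$posteriors[[ok[1]]]$mean)
  t(vapply(fit$posteriors, function(p) {
    if (isTRUE(p$failed) && is.null(p$mean)) rep(NA_real_, length(free))
    else p$mean[free]
  }, numeric(length(free))))
}
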