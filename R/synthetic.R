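#' Specification of a synthetic cohort
#'
#' Describes a cohort of subjects whose spectra are generated from the
#' microcircuit model with known ground truth: between-subject log-scale
#' spreads around the prior expectations, multiplicative trial noise
#' emulating periodogram variability, an optional shared alpha-beta
#' amplitude factor, and (for the time-series path) a 1/f channel-noise
#' power law.
#'
#' @param n_subjects Number of subjects (default 97).
#' @param n_trials Trials per subject (default 100).
#' @param spread Named log-scale SDs of the between-subject deviations;
#'   defaults to 0.25 for gains/time constants, 0.3 for amplitudes, 1 for
#'   the alpha-centre logit.
#' @param trial_shape Gamma shape of the per-bin, per-trial multiplicative
#'   noise (larger = less noisy; default 3, roughly the behaviour of a
#'   smoothed single-trial periodogram).
#' @param alpha_beta_coupling Log-SD of a per-trial multiplicative factor
#'   shared by the alpha and beta bands (default 0 = off).
#' @param powerlaw_intercept,powerlaw_slope Mean and SD (length-2
#'   vectors) of the subject-level 1/f channel-noise law used by the
#'   time-series path.
#' @param seed Mandatory RNG seed.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 97, n_trials = 100,
                        spread = NULL, trial_shape = 3,
                        alpha_beta_coupling = 0,
                        powerlaw_intercept = c(0, 0.3),
                        powerlaw_slope = c(-1.5, 0.2),
                        seed) {
  if (missing(seed)) stop("a seed is mandatory")
  def <- c("T.SP" = 0.25, "T.II" = 0.25, "T.DP" = 0.25,
           "G.2" = 0.25, "G.4" = 0.25, "G.5" = 0.25, "G.6" = 0.25,
           "G.7" = 0.25, "G.8" = 0.25, "G.9" = 0.25, "G.11" = 0.25,
           "G.12" = 0.25,
           "input.white" = 0.3, "input.pink" = 0.3, "noise.white" = 0.3,
           "noise.alpha_amp" = 0.3, "noise.alpha_mu" = 1,
           "noise.alpha_sigma" = 0.2)
  if (!is.null(spread)) def[names(spread)] <- spread
  if (any(def < 0)) stop("spreads must be non-negative")
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 spread = def, trial_shape = trial_shape,
                 alpha_beta_coupling = alpha_beta_coupling,
                 powerlaw_intercept = powerlaw_intercept,
                 powerlaw_slope = powerlaw_slope,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample ground-truth parameters for every subject of a cohort
#'
#' Log-normal deviations around the prior expectations, with masked
#' (fixed) parameters held at their prior means. Draws for which the
#' linearised circuit is unstable are rejected and redrawn (the
#' between-subject distribution is therefore truncated to the stable
#' region), so every generated subject has a finite predicted spectrum.
#' The returned ledger of true deviations is sufficient to score
#' recovery of every free parameter.
#'
#' @param spec A \code{cohort_spec}.
#' @param priors A \code{cmc_priors} supplying the prior means and free
#'   parameter set.
#' @return List with \code{params} (per-subject \code{cmc_parameters}),
#'   \code{deviations} (subjects x free matrix of true log deviations) and
#'   \code{priors}.
#' @export
sample_cohort_parameters <- function(spec, priors = default_priors()) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_priors(priors)
  set.seed(spec$seed)
  free <- priors$free
  sds <- spec$spread[free]
  sds[is.na(sds)] <- 0.25
  dev <- matrix(NA_real_, spec$n_subjects, length(free),
                dimnames = list(NULL, free))
  params <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    for (attempt in 1:100) {
      d <- stats::setNames(stats::rnorm(length(free), 0, sds), free)
      p <- tryCatch(apply_log_deviations(priors$params, d),
                    error = function(e) NULL)
      if (is.null(p)) next
      J <- delay_jacobian(p, cmc_jacobian(p))
      if (max(Re(eigen(J, only.values = TRUE)$values)) < 0) {
        dev[s, ] <- d
        params[[s]] <- p
        break
      }
    }
    if (is.null(params[[s]]))
      stop("could not sample a stable parameter set for subject ", s)
  }
  list(params = params, deviations = dev, priors = priors)
}

# cosine-tapered band indicator over the grid (1 inside, 0 outside,
# 2 Hz cosine ramps)
band_weight <- function(grid, lo, hi, ramp = 2) {
  w <- numeric(length(grid))
  w[grid >= lo & grid <= hi] <- 1
  up <- grid > lo - ramp & grid < lo
  w[up] <- 0.5 + 0.5 * cos(pi * (lo - grid[up]) / ramp)
  dn <- grid > hi & grid < hi + ramp
  w[dn] <- 0.5 + 0.5 * cos(pi * (grid[dn] - hi) / ramp)
  w
}

#' Generate per-trial spectra for one subject (fast path)
#'
#' Multiplies the model-predicted total spectrum by per-trial, per-bin
#' gamma-distributed noise of mean 1 (emulating smoothed-periodogram
#' variability) and, optionally, by a per-trial lognormal factor shared
#' across the alpha and beta bands.
#'
#' @param params Subject's true \code{cmc_parameters}.
#' @param spec A \code{cohort_spec} (trial count and noise settings).
#' @param grid Frequency grid.
#' @return Matrix frequencies x trials.
#' @export
generate_subject_spectra <- function(params, spec, grid = frequency_grid()) {
  mu <- predicted_spectrum(params, grid)$total
  sh <- spec$trial_shape
  tr <- matrix(stats::rgamma(length(grid) * spec$n_trials,
                             shape = sh, rate = sh),
               length(grid), spec$n_trials)
  out <- mu * tr
  if (spec$alpha_beta_coupling > 0) {
    w <- band_weight(grid, 8, 30)
    f <- exp(stats::rnorm(spec$n_trials, 0, spec$alpha_beta_coupling))
    out <- out * exp(outer(w, log(f)))
  }
  out
}

#' Generate a whole synthetic cohort of spectra
#'
#' Samples ground-truth parameters and per-trial spectra for every
#' subject; returns trial-averaged spectra (flagged whitened, since the
#' model lives on the whitened scale) plus the truth ledger. Reproducible
#' bit-for-bit from (spec, seed).
#'
#' @param spec A \code{cohort_spec}.
#' @param priors A \code{cmc_priors}.
#' @param grid Frequency grid.
#' @param keep_trials Keep per-trial matrices (needed for covariance
#'   maps; default FALSE).
#' @return List with \code{spectra} (list of \code{cmc_spectrum}),
#'   \code{trials} (optional), \code{truth} (deviations matrix),
#'   \code{params}, \code{priors}.
#' @export
generate_cohort_spectra <- function(spec, priors = default_priors(),
                                    grid = frequency_grid(),
                                    keep_trials = FALSE) {
  samp <- sample_cohort_parameters(spec, priors)
  trials <- lapply(seq_len(spec$n_subjects), function(s)
    generate_subject_spectra(samp$params[[s]], spec, grid))
  spectra <- lapply(seq_len(spec$n_subjects), function(s)
    new_spectrum(grid, rowMeans(trials[[s]]), whitened = TRUE,
                 provenance = list(subject = s, n_trials = spec$n_trials)))
  out <- list(spectra = spectra, truth = samp$deviations,
              params = samp$params, priors = samp$priors)
  if (keep_trials) out$trials <- trials
  out
}

# 1/f channel noise by spectral factorisation: white Gaussian noise
# shaped to amplitude sqrt(exp(intercept) * f^slope) in the frequency
# domain
pink_noise <- function(n, fs, intercept, slope) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1e-3, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f * 0) # one-sided mirror handled by symmetry of |H|
  fmirror <- pmin(f, fs * (1 - (seq_len(n) - 1) / n))
  shape <- sqrt(exp(intercept) * pmax(fmirror, 1e-3)^slope)
  Re(stats::fft(X * shape, inverse = TRUE)) / n
}

# narrowband stochastic alpha source: damped AR(2) oscillator
alpha_source <- function(n, fs, freq, bw = 1.5) {
  rho <- exp(-pi * bw / fs)
  phi1 <- 2 * rho * cos(2 * pi * freq / fs)
  phi2 <- -rho^2
  e <- stats::rnorm(n + 200)
  x <- numeric(n + 200)
  for (t in 3:(n + 200)) x[t] <- phi1 * x[t - 1] + phi2 * x[t - 2] + e[t]
  x <- x[-(1:200)]
  x / stats::sd(x)
}

#' Generate trial time series for one subject
#'
#' Full time-domain path: the nonlinear circuit is simulated per trial
#' under seeded white stochastic drive; 1/f channel noise (by spectral
#' factorisation) and an independent narrowband alpha source at the
#' subject's alpha frequency are added to the observed mixture.
#'
#' @param params Subject's true \code{cmc_parameters}.
#' @param n_trials Number of trials.
#' @param fs Sampling rate in Hz (>= 600).
#' @param duration_s Trial duration in seconds (>= 1.2).
#' @param drive_sd SD of the white drive.
#' @param channel_noise \code{c(intercept, slope)} of the additive 1/f
#'   noise, and \code{white_sd} its white floor; \code{alpha_sd} the
#'   alpha-source amplitude.
#' @param white_sd,alpha_sd Additive component amplitudes.
#' @param seed RNG seed.
#' @return Matrix samples x trials of the observed channel.
#' @export
generate_subject_recording <- function(params, n_trials = 100, fs = 1200,
                                       duration_s = 1.5, drive_sd = 0.05,
                                       channel_noise = c(-4, -1.5),
                                       white_sd = 0.002, alpha_sd = 0.01,
                                       seed = 1) {
  stopifnot(fs >= 600, duration_s >= 1.2)
  set.seed(seed)
  n <- round(duration_s * fs)
  dt <- 1000 / fs
  sapply(seq_len(n_trials), function(tr) {
    drive <- stats::rnorm(n, 0, drive_sd)
    sim <- simulate_timecourse(params, drive, dt = dt)
    obs <- sim$observed +
      pink_noise(n, fs, channel_noise[1], channel_noise[2]) +
      white_sd * stats::rnorm(n) +
      alpha_sd * alpha_source(n, fs, params$noise[["alpha_mu"]])
    obs
  })
}

#' Specification of a synthetic drug-crossover study
#'
#' A placebo-controlled crossover: each subject is measured in two arms
#' (placebo, drug) at four sessions (pre, 1 h, 3 h, 5 h). In the drug arm
#' the inhibitory-interneuron time constant rises and the SS-to-SP
#' excitatory gain falls, with the largest effect at the 3-h session;
#' placebo-arm effects are identically zero.
#'
#' @param n_subjects Number of subjects (default 15).
#' @param t3_profile Log-scale effect on \code{T.II} per session
#'   (pre, 1h, 3h, 5h).
#' @param g8_profile Log-scale effect on \code{G.8} per session.
#' @param n_trials,trial_shape,spread As in \code{\link{cohort_spec}}.
#' @param seed Mandatory RNG seed.
#' @return Object of class \code{drug_study_spec}.
#' @export
drug_study_spec <- function(n_subjects = 15,
                            t3_profile = c(0, 0.13, 0.20, 0.18),
                            g8_profile = c(0, -0.10, -0.15, -0.135),
                            n_trials = 100, trial_shape = 3,
                            spread = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(length(t3_profile) == 4, length(g8_profile) == 4,
            t3_profile[1] == 0, g8_profile[1] == 0)
  if (!(t3_profile[3] >= max(t3_profile)))
    stop("the T.II effect must peak at the 3-h session")
  structure(list(n_subjects = n_subjects, t3_profile = t3_profile,
                 g8_profile = g8_profile, n_trials = n_trials,
                 trial_shape = trial_shape, spread = spread,
                 seed = as.integer(seed)),
            class = "drug_study_spec")
}

# baseline sampling for the crossover design: a subject is accepted only
# if the baseline AND every drug-session-shifted parameter set is stable,
# so each of the 8 cells has a finite predicted spectrum
sample_drug_baselines <- function(cs, spec, priors) {
  validate_priors(priors)
  set.seed(cs$seed)
  free <- priors$free
  sds <- cs$spread[free]
  sds[is.na(sds)] <- 0.25
  stable <- function(p) {
    J <- delay_jacobian(p, cmc_jacobian(p))
    max(Re(eigen(J, only.values = TRUE)$values)) < 0
  }
  dev <- matrix(NA_real_, cs$n_subjects, length(free),
                dimnames = list(NULL, free))
  params <- vector("list", cs$n_subjects)
  for (s in seq_len(cs$n_subjects)) {
    for (attempt in 1:200) {
      d <- stats::setNames(stats::rnorm(length(free), 0, sds), free)
      p <- tryCatch(apply_log_deviations(priors$params, d),
                    error = function(e) NULL)
      if (is.null(p) || !stable(p)) next
      ok <- TRUE
      for (j in 2:4) {
        pj <- tryCatch(apply_log_deviations(
          p, c("T.II" = spec$t3_profile[j], "G.8" = spec$g8_profile[j])),
          error = function(e) NULL)
        if (is.null(pj) || !stable(pj)) { ok <- FALSE; break }
      }
      if (ok) {
        dev[s, ] <- d
        params[[s]] <- p
        break
      }
    }
    if (is.null(params[[s]]))
      stop("could not sample a stable baseline for subject ", s)
  }
  list(params = params, deviations = dev, priors = priors)
}

#' Generate a full synthetic drug-crossover dataset
#'
#' Subject baselines are sampled once (as in a cohort), then the
#' session-wise log effects are applied in the drug arm only, and trial
#' spectra generated for all subjects x 2 arms x 4 sessions.
#'
#' @param spec A \code{drug_study_spec}.
#' @param priors A \code{cmc_priors}.
#' @param grid Frequency grid.
#' @return List with \code{spectra} (subject x arm x session list-array of
#'   \code{cmc_spectrum}), \code{truth} (data.frame ledger with true
#'   \code{T.II} ms and \code{G.8} per cell) and \code{baseline}
#'   (deviations matrix).
#' @export
generate_drug_study <- function(spec, priors = default_priors(),
                                grid = frequency_grid()) {
  stopifnot(inherits(spec, "drug_study_spec"))
  cs <- cohort_spec(n_subjects = spec$n_subjects, n_trials = spec$n_trials,
                    trial_shape = spec$trial_shape, spread = spec$spread,
                    seed = spec$seed)
  samp <- sample_drug_baselines(cs, spec, priors)
  arms <- c("placebo", "drug")
  sessions <- c("pre", "1h", "3h", "5h")
  spectra <- array(list(), dim = c(spec$n_subjects, 2, 4),
                   dimnames = list(NULL, arms, sessions))
  truth <- NULL
  for (s in seq_len(spec$n_subjects)) {
    for (a in 1:2) for (j in 1:4) {
      eff <- if (a == 2) c("T.II" = spec$t3_profile[j],
                           "G.8" = spec$g8_profile[j])
             else c("T.II" = 0, "G.8" = 0)
      p <- apply_log_deviations(samp$params[[s]], eff)
      tr <- generate_subject_spectra(p, cs, grid)
      spectra[[s, a, j]] <- new_spectrum(grid, rowMeans(tr), whitened = TRUE,
                                         provenance = list(subject = s,
                                                           arm = arms[a],
                                                           session = sessions[j]))
      truth <- rbind(truth, data.frame(
        subject = s, arm = arms[a], session = sessions[j],
        T.II_ms = p$T[["II"]], G.8 = p$G[["G8"]],
        stringsAsFactors = FALSE))
    }
  }
  list(spectra = spectra, truth = truth, baseline = samp$deviations,
       priors = samp$priors)
}
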