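#' Construct a spectrum object
#'
#' Container for a power spectrum on a common frequency grid, with
#' provenance flags recording whether the 1/f background has been removed
#' (\code{whitened}) and whether the cohort unit-area scaling has been
#' applied (\code{normalised}). Flags are monotone: a spectrum is never
#' un-whitened or un-normalised.
#'
#' @param grid Frequencies in Hz, strictly increasing.
#' @param values Non-negative power values (amplitude^2), one per bin.
#' @param whitened,normalised Provenance flags.
#' @param provenance Free-form list (subject/session ids, trial count,
#'   removed power law, ...).
#' @return An object of class \code{cmc_spectrum}.
#' @export
new_spectrum <- function(grid, values, whitened = FALSE, normalised = FALSE,
                         provenance = list()) {
  stopifnot(is.numeric(grid), is.numeric(values),
            length(grid) == length(values), all(diff(grid) > 0))
  if (any(!is.finite(values)) || any(values < 0))
    stop("spectrum values must be finite and non-negative")
  structure(list(grid = grid, values = values, whitened = isTRUE(whitened),
                 normalised = isTRUE(normalised), provenance = provenance),
            class = "cmc_spectrum")
}

#' @export
print.cmc_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d bins %.3g-%.3g Hz [%s, %s]\n",
              length(x$grid), min(x$grid), max(x$grid),
              if (x$whitened) "whitened" else "raw",
              if (x$normalised) "cohort-normalised" else "unnormalised"))
  invisible(x)
}

#' @export
as.data.frame.cmc_spectrum <- function(x, ...) {
  data.frame(freq_hz = x$grid, value = x$values,
             whitened = x$whitened, normalised = x$normalised)
}

#' Trial-averaged smoothed periodogram
#'
#' Per-trial periodogram of the analysis window (mean removed, Hann taper),
#' averaged over trials, smoothed with a 3-bin moving average across
#' frequency, and linearly interpolated onto the model grid. Scaled as
#' one-sided power spectral density, so that the integral over frequency
#' approximates the windowed signal variance.
#'
#' @param trials Numeric matrix, samples x trials.
#' @param fs Sampling rate in Hz; must exceed twice the top grid frequency.
#' @param window Analysis window \code{c(t0, t1)} in seconds relative to
#'   trial start (default the 0.3-1.5 s stimulation period).
#' @param grid Output frequency grid (Hz).
#' @param smooth_bins Width of the frequency moving average (odd, default 3).
#' @return A raw \code{\link{new_spectrum}} object.
#' @export
estimate_periodogram <- function(trials, fs, window = c(0.3, 1.5),
                                 grid = frequency_grid(), smooth_bins = 3) {
  trials <- as.matrix(trials)
  stopifnot(is.numeric(trials), fs > 2 * max(grid), length(window) == 2,
            window[1] >= 0, window[2] > window[1])
  i0 <- floor(window[1] * fs) + 1
  i1 <- min(floor(window[2] * fs), nrow(trials))
  if (i1 > nrow(trials) || i1 - i0 + 1 < fs * (window[2] - window[1]) * 0.999)
    stop("analysis window extends beyond the trial")
  n <- i1 - i0 + 1
  if (n / fs < 1)
    stop("analysis window shorter than 1 s: insufficient resolution for a 1 Hz grid")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)) # Hann taper
  seg <- trials[i0:i1, , drop = FALSE]
  seg <- sweep(seg, 2, colMeans(seg))
  X <- stats::mvfft(seg * w)
  nf <- floor(n / 2)
  freqs <- (seq_len(nf)) * fs / n
  # one-sided PSD per trial, averaged
  P <- 2 * rowMeans(Mod(X[2:(nf + 1), , drop = FALSE])^2) / (fs * sum(w^2))
  if (smooth_bins > 1) {
    k <- rep(1 / smooth_bins, smooth_bins)
    P <- as.numeric(stats::filter(P, k, sides = 2))
    half <- (smooth_bins - 1) / 2
    P[seq_len(half)] <- P[half + 1]
    P[(length(P) - half + 1):length(P)] <- P[length(P) - half]
  }
  vals <- stats::approx(freqs, P, xout = grid, rule = 2)$y
  new_spectrum(grid, pmax(vals, 0),
               provenance = list(n_trials = ncol(trials), fs = fs,
                                 window = window))
}

#' Robust log-log power-law fit
#'
#' Straight line fitted to (log f, log power) by iteratively reweighted
#' least squares with Tukey bisquare weights (tuning constant 4.685), so
#' that narrow band-limited peaks do not bias the estimate of the 1/f
#' background.
#'
#' @param spectrum A \code{cmc_spectrum}.
#' @return List of class \code{powerlaw} with \code{intercept} (log-power
#'   at 1 Hz, natural log) and \code{slope} (d log-power / d log-frequency).
#' @export
fit_powerlaw_robust <- function(spectrum) {
  stopifnot(inherits(spectrum, "cmc_spectrum"))
  v <- spectrum$values
  if (any(v <= 0)) {
    warning("non-positive spectral values floored at machine epsilon")
    v <- pmax(v, .Machine$double.eps)
  }
  usable <- is.finite(v)
  if (sum(usable) < 10) stop("fewer than 10 usable bins for the power-law fit")
  lx <- log(spectrum$grid[usable]); ly <- log(v[usable])
  ols <- stats::lm.fit(cbind(1, lx), ly)
  if (max(abs(ols$residuals)) < 1e-10) {
    cf <- ols$coefficients
  } else {
    fit <- MASS::rlm(ly ~ lx, psi = MASS::psi.bisquare, c = 4.685,
                     maxit = 50, acc = 1e-8)
    cf <- stats::coef(fit)
  }
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2])),
            class = "powerlaw")
}

#' @export
print.powerlaw <- function(x, ...) {
  cat(sprintf("Power law: log-power at 1 Hz %.4g, slope %.4g\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Remove the fitted power law from a raw spectrum
#'
#' Divides the spectrum bin-wise by \code{exp(intercept + slope log f)}
#' (equivalently, subtracts the fitted line in log space), flattening the
#' 1/f background and disclosing band-limited peaks. Whitening twice is an
#' error.
#'
#' @param spectrum A raw \code{cmc_spectrum}.
#' @param law A \code{powerlaw}; defaults to a fresh robust fit.
#' @return The whitened spectrum; the removed law is kept in provenance.
#' @export
prewhiten <- function(spectrum, law = fit_powerlaw_robust(spectrum)) {
  stopifnot(inherits(spectrum, "cmc_spectrum"), inherits(law, "powerlaw"))
  if (spectrum$whitened) stop("spectrum is already whitened")
  bg <- exp(law$intercept + law$slope * log(spectrum$grid))
  out <- spectrum
  out$values <- spectrum$values / bg
  out$whitened <- TRUE
  out$provenance$powerlaw <- law
  out
}

#' Cohort unit-area normalisation
#'
#' Scales every spectrum by the single common factor that gives the mean
#' spectrum a sum (area under the curve) of 1. Between-subject amplitude
#' ratios are untouched.
#'
#' @param spectra List of whitened \code{cmc_spectrum} objects on one grid.
#' @return List with \code{spectra} (normalised) and \code{scale} (the
#'   common factor applied).
#' @export
normalize_cohort <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  lapply(spectra, function(s) stopifnot(inherits(s, "cmc_spectrum")))
  g0 <- spectra[[1]]$grid
  for (s in spectra) {
    if (length(s$grid) != length(g0) || any(s$grid != g0))
      stop("all spectra must share one frequency grid")
    if (!s$whitened) stop("normalisation expects whitened spectra")
    if (s$normalised) stop("cohort is already normalised")
  }
  m <- rowMeans(vapply(spectra, `[[`, numeric(length(g0)), "values"))
  s <- 1 / sum(m)
  out <- lapply(spectra, function(sp) {
    sp$values <- sp$values * s
    sp$normalised <- TRUE
    sp
  })
  list(spectra = out, scale = s)
}

#' Peak frequency and amplitude within a band
#'
#' Maximum bin inside \code{[lo, hi]}; ties break to the lower frequency.
#' A maximum on the band boundary is returned with \code{edge = TRUE}.
#'
#' @param spectrum A \code{cmc_spectrum} (or a plain list with \code{grid}
#'   and \code{values}).
#' @param band \code{c(lo, hi)} in Hz; the upper edge is exclusive when
#'   \code{right_open = TRUE}.
#' @param right_open Treat the band as \code{[lo, hi)}.
#' @return List with \code{freq}, \code{amp}, \code{edge}.
#' @export
extract_band_peak <- function(spectrum, band, right_open = FALSE) {
  stopifnot(length(band) == 2, band[1] < band[2])
  g <- spectrum$grid; v <- spectrum$values
  idx <- if (right_open) which(g >= band[1] & g < band[2])
         else which(g >= band[1] & g <= band[2])
  if (length(idx) == 0) stop("band contains no grid frequencies")
  i <- idx[which.max(v[idx])]
  list(freq = g[i], amp = v[i], edge = (i == idx[1] || i == idx[length(idx)]))
}

#' Alpha, beta and gamma spectral features
#'
#' Alpha parameters are copied from the fitted Gaussian of a completed
#' inversion (the circuit itself cannot generate alpha); beta and gamma are
#' read off the whitened spectrum as band argmax peaks, over [13, 30) and
#' [30, 80] Hz respectively. The power-law of the removed background is
#' carried along when present in provenance.
#'
#' @param whitened A whitened \code{cmc_spectrum}.
#' @param posterior_noise Named vector/list with \code{alpha_mu},
#'   \code{alpha_amp}, \code{alpha_sigma} from an inversion, or \code{NULL}
#'   (alpha fields returned as \code{NA}).
#' @return List of class \code{spectral_features}.
#' @export
extract_features <- function(whitened, posterior_noise = NULL) {
  stopifnot(inherits(whitened, "cmc_spectrum"))
  if (!whitened$whitened) stop("features are extracted from whitened spectra")
  beta <- extract_band_peak(whitened, c(13, 30), right_open = TRUE)
  gamma <- extract_band_peak(whitened, c(30, 80))
  alpha <- c(freq = NA_real_, amp = NA_real_, width = NA_real_)
  if (!is.null(posterior_noise)) {
    pn <- unlist(posterior_noise)
    alpha <- c(freq = unname(pn[["alpha_mu"]]), amp = unname(pn[["alpha_amp"]]),
               width = unname(pn[["alpha_sigma"]]))
  }
  structure(list(
    alpha_freq = alpha[["freq"]], alpha_amp = alpha[["amp"]],
    alpha_width = alpha[["width"]],
    beta_freq = beta$freq, beta_amp = beta$amp, beta_edge = beta$edge,
    gamma_freq = gamma$freq, gamma_amp = gamma$amp, gamma_edge = gamma$edge,
    powerlaw = whitened$provenance$powerlaw),
    class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf("alpha %.2f Hz (amp %.3g, width %.2f)\n",
              x$alpha_freq, x$alpha_amp, x$alpha_width))
  cat(sprintf("beta  %.1f Hz amp %.4g%s\n", x$beta_freq, x$beta_amp,
              if (x$beta_edge) " [edge]" else ""))
  cat(sprintf("gamma %.1f Hz amp %.4g%s\n", x$gamma_freq, x$gamma_amp,
              if (x$gamma_edge) " [edge]" else ""))
  invisible(x)
}

#' Write a spectrum to TSV
#'
#' Columns \code{freq_hz}, \code{value}, \code{whitened},
#' \code{normalised}.
#'
#' @param spectrum A \code{cmc_spectrum}.
#' @param path Output file path.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "cmc_spectrum"))
  utils::write.table(as.data.frame(spectrum), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum written by \code{\link{write_spectrum_tsv}}
#' @param path File path.
#' @return A \code{cmc_spectrum}.
#' @export
read_spectrum_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  new_spectrum(d$freq_hz, d$value, whitened = d$whitened[1],
               normalised = d$normalised[1])
}

#' @export
as.data.frame.spectral_features <- function(x, ...) {
  data.frame(alpha_freq = x$alpha_freq, alpha_amp = x$alpha_amp,
             alpha_width = x$alpha_width,
             beta_freq = x$beta_freq, beta_amp = x$beta_amp,
             beta_edge = x$beta_edge,
             gamma_freq = x$gamma_freq, gamma_amp = x$gamma_amp,
             gamma_edge = x$gamma_edge)
}

#' Read trial time series from delimited text
#'
#' Expects a numeric table, samples x trials, whitespace- or
#' comma-delimited, without row names.
#'
#' @param path File path.
#' @return Numeric matrix samples x trials.
#' @export
read_trials_text <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  storage.mode(m) <- "double"
  unname(m)
}
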