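test_that("periodogram finds a pure tone at its frequency", {
  fs <- 600; n <- round(1.5 * fs)
  t <- seq_len(n) / fs
  trials <- vapply(1:8, function(k) sin(2 * pi * 40 * t + k), numeric(n))
  sp <- estimate_periodogram(trials, fs, window = c(0.3, 1.5))
  expect_equal(sp$grid[which.max(sp$values)], 40, tolerance = 0.51)
  expect_false(sp$whitened)
})

test_that("white-noise trials give an approximately flat log-log spectrum", {
  set.seed(31)
  fs <- 600
  trials <- matrix(rnorm(round(1.5 * fs) * 200), ncol = 200)
  sp <- estimate_periodogram(trials, fs, window = c(0, 1.5))
  law <- fit_powerlaw_robust(sp)
  expect_lt(abs(law$slope), 0.05)
})

test_that("periodogram power matches time-domain variance (Parseval oracle)", {
  # band-limited multi-sine at exact DFT bins: total in-band power is known
  set.seed(32)
  fs <- 600; n <- 2 * fs # native resolution 0.5 Hz
  t <- (seq_len(n) - 1) / fs
  freqs <- seq(10, 90, by = 2.5)
  amps <- runif(length(freqs), 0.5, 1.5)
  x <- colSums(amps * t(sapply(seq_along(freqs), function(k)
    sin(2 * pi * freqs[k] * t + k))))
  trials <- matrix(rep(x, 4), ncol = 4)
  g <- seq(1, 100, by = 0.25)
  sp <- estimate_periodogram(trials, fs, window = c(0, 2), grid = g,
                             smooth_bins = 1)
  power <- sum(sp$values) * 0.25
  band_var <- sum(amps^2) / 2
  expect_equal(power, band_var, tolerance = 0.01 * band_var)
})

test_that("too-short analysis windows are rejected", {
  fs <- 600
  trials <- matrix(rnorm(fs * 2), ncol = 2)
  expect_error(estimate_periodogram(trials, fs, window = c(0, 0.5)),
               "shorter than 1 s")
})

test_that("robust fit recovers an exact power law and ignores a narrow bump", {
  sp <- powerlaw_spectrum(A = 3, b = 1.5)
  law <- fit_powerlaw_robust(sp)
  expect_equal(law$intercept, log(3), tolerance = 1e-8)
  expect_equal(law$slope, -1.5, tolerance = 1e-8)
  # narrow gaussian bump covering few bins must not move the slope
  g <- sp$grid
  bump <- 5 * exp(-(g - 50)^2 / (2 * 1^2))
  sp2 <- new_spectrum(g, sp$values * (1 + bump))
  law2 <- fit_powerlaw_robust(sp2)
  expect_lt(abs(law2$slope - law$slope), 0.05)
  # flat spectrum
  law3 <- fit_powerlaw_robust(new_spectrum(g, rep(2.5, length(g))))
  expect_equal(law3$slope, 0, tolerance = 1e-10)
  expect_equal(law3$intercept, log(2.5), tolerance = 1e-10)
})

test_that("pre-whitening flattens a power law and preserves narrow peaks", {
  sp <- powerlaw_spectrum(A = 2, b = 1.2)
  wh <- prewhiten(sp)
  cv <- sd(wh$values) / mean(wh$values)
  expect_lt(cv, 1e-8)
  expect_true(wh$whitened)
  expect_error(prewhiten(wh), "already whitened")
  # algebraic identity: law x (1 + bump) whitens to exactly (1 + bump)
  g <- sp$grid
  bump <- 3 * exp(-(g - 53)^2 / (2 * 2^2))
  law <- structure(list(intercept = log(2), slope = -0.5), class = "powerlaw")
  raw <- new_spectrum(g, 2 * g^(-0.5) * (1 + bump))
  wh2 <- prewhiten(raw, law)
  expect_equal(wh2$values, 1 + bump, tolerance = 1e-6)
  # peak location survives whitening within one bin
  rawpk <- extract_band_peak(raw, c(30, 80))
  whpk <- extract_band_peak(wh2, c(30, 80))
  expect_lte(abs(whpk$freq - rawpk$freq), 0.5)
})

test_that("cohort normalisation: unit mean-spectrum area, ratios untouched", {
  set.seed(33)
  g <- frequency_grid()
  spectra <- lapply(1:5, function(i)
    new_spectrum(g, rexp(length(g)) * i, whitened = TRUE))
  out <- normalize_cohort(spectra)
  m <- rowMeans(vapply(out$spectra, `[[`, numeric(length(g)), "values"))
  expect_equal(sum(m), 1, tolerance = 1e-12)
  r_before <- spectra[[2]]$values / spectra[[4]]$values
  r_after <- out$spectra[[2]]$values / out$spectra[[4]]$values
  expect_equal(r_before, r_after, tolerance = 1e-15)
  expect_error(normalize_cohort(out$spectra), "already normalised")
  # single-spectrum cohort sums to 1 itself
  one <- normalize_cohort(spectra[1])
  expect_equal(sum(one$spectra[[1]]$values), 1, tolerance = 1e-12)
  # mixed grids rejected
  other <- new_spectrum(frequency_grid(1, 50), rexp(99), whitened = TRUE)
  expect_error(normalize_cohort(list(spectra[[1]], other)), "grid")
})

test_that("band peak extraction: bump, boundary edge flag, tie-break", {
  sp <- bump_spectrum(centre = 53)
  pk <- extract_band_peak(sp, c(30, 80))
  expect_equal(pk$freq, 53)
  expect_false(pk$edge)
  dec <- new_spectrum(frequency_grid(), 100 - frequency_grid())
  pk2 <- extract_band_peak(dec, c(30, 80))
  expect_equal(pk2$freq, 30)
  expect_true(pk2$edge)
  g <- frequency_grid()
  v <- rep(1, length(g)); v[g == 40] <- 2; v[g == 60] <- 2
  pk3 <- extract_band_peak(new_spectrum(g, v), c(30, 80))
  expect_equal(pk3$freq, 40) # lower frequency wins ties
  expect_error(extract_band_peak(sp, c(200, 300)), "no grid frequencies")
})

test_that("feature extraction combines fitted alpha with band argmax peaks", {
  g <- frequency_grid()
  v <- 1 + 0.5 * exp(-(g - 53)^2 / 8) # gamma bump only, no beta bump
  wh <- new_spectrum(g, v, whitened = TRUE, normalised = TRUE)
  f <- extract_features(wh, posterior_noise = c(alpha_mu = 10.5,
                                                alpha_amp = 0.4,
                                                alpha_sigma = 1.5))
  expect_equal(f$alpha_freq, 10.5)
  expect_equal(f$gamma_freq, 53)
  expect_true(f$beta_edge) # monotone within beta -> boundary
  # alpha unavailable without a fit
  f2 <- extract_features(wh)
  expect_true(is.na(f2$alpha_freq))
  expect_equal(f2$gamma_freq, 53)
  expect_error(extract_features(new_spectrum(g, v)), "whitened")
})

test_that("normalising before or after feature extraction only rescales amplitudes", {
  coh <- small_cohort(n = 4, seed = 9)
  feats_before <- lapply(coh$spectra, extract_features)
  norm <- normalize_cohort(coh$spectra)
  feats_after <- lapply(norm$spectra, extract_features)
  for (i in seq_along(feats_before)) {
    expect_identical(feats_before[[i]]$gamma_freq, feats_after[[i]]$gamma_freq)
    expect_identical(feats_before[[i]]$beta_freq, feats_after[[i]]$beta_freq)
    expect_equal(feats_after[[i]]$gamma_amp,
                 feats_before[[i]]$gamma_amp * norm$scale)
  }
})
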