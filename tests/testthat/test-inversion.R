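test_that("default priors encode the documented expectations and masks", {
  pr <- default_priors()
  expect_equal(unname(pr$params$T[c("SP", "SS", "II", "DP")]), c(2, 2, 10, 20))
  expect_false(any(c("T.SS", "G.1", "G.3", "G.10", "G.13") %in% pr$free))
  expect_true(all(c("G.7", "T.II", "noise.alpha_mu") %in% pr$free))
  expect_true(all(pr$precision > 0))
})

test_that("prior specification round-trips through YAML", {
  pr <- default_priors()
  f <- tempfile(fileext = ".yaml")
  write_priors(pr, f)
  pr2 <- read_priors(f)
  expect_equal(pr2$free, pr$free)
  expect_equal(pr2$precision, pr$precision)
  expect_equal(unclass(pr2$params)[c("T", "C", "D", "r", "L", "input", "noise")],
               unclass(pr$params)[c("T", "C", "D", "r", "L", "input", "noise")],
               tolerance = 1e-12)
  expect_equal(unlist(pr2$params$G), unlist(pr$params$G), tolerance = 1e-12)
  unlink(f)
})

test_that("parameter sets round-trip through YAML", {
  p <- cmc_parameters()
  f <- tempfile(fileext = ".yaml")
  write_cmc_parameters(p, f)
  p2 <- read_cmc_parameters(f)
  expect_equal(unlist(p2$G), unlist(p$G), tolerance = 1e-12)
  expect_equal(p2$T, p$T, tolerance = 1e-12)
  unlink(f)
})

test_that("free energy matches an independent evaluation of the closed form", {
  set.seed(21)
  pr <- default_priors()
  pr$hyper$mean <- 0
  g <- frequency_grid()
  v <- stats::setNames(rnorm(length(pr$free), 0, 0.1), pr$free)
  y <- predicted_spectrum(cmc_parameters(), g)$total * exp(rnorm(length(g), 0, 0.05))
  data <- new_spectrum(g, y, whitened = TRUE, normalised = TRUE)
  lambda <- 1.3
  # independent implementation, straight from the formula
  # (heteroscedastic likelihood: bin precision exp(lambda) / y^2)
  mu <- predicted_spectrum(apply_log_deviations(pr$params, v), g)$total
  e <- y - mu
  n <- length(y)
  w <- 1 / y^2
  F_indep <- n / 2 * lambda + 0.5 * sum(log(w)) - n / 2 * log(2 * pi) -
    exp(lambda) / 2 * sum(w * e^2) -
    0.5 * sum(pr$precision * v^2) -
    0.5 * pr$hyper$precision * (lambda - 0)^2
  expect_equal(free_energy(v, data, pr, lambda), F_indep, tolerance = 1e-8)
})

test_that("free energy: zero deviation from prior leaves no complexity, mismatch lowers F", {
  pr <- default_priors()
  pr$hyper$mean <- 0
  g <- frequency_grid()
  mu <- predicted_spectrum(pr$params, g)$total
  data <- new_spectrum(g, mu, whitened = TRUE, normalised = TRUE)
  v0 <- stats::setNames(numeric(length(pr$free)), pr$free)
  F0 <- free_energy(v0, data, pr, lambda = 0)
  # no residual, no complexity: only the Gaussian normalisation remains
  expect_equal(F0, -length(g) / 2 * log(2 * pi) - sum(log(mu)),
               tolerance = 1e-10)
  # adding a fixed offset to the data strictly decreases F
  Fs <- vapply(c(0.001, 0.01, 0.05), function(off) {
    d <- new_spectrum(g, mu + off, whitened = TRUE, normalised = TRUE)
    free_energy(v0, d, pr, lambda = 0)
  }, numeric(1))
  expect_true(all(diff(c(F0, Fs)) < 0))
})

test_that("inversion of noiseless prior-generated data stays at the prior", {
  pr <- default_priors()
  g <- frequency_grid()
  y <- predicted_spectrum(pr$params, g)$total
  data <- new_spectrum(g, y, whitened = TRUE, normalised = TRUE)
  post <- variational_laplace(data, pr)
  expect_lt(max(abs(post$mean)), 0.05)
  expect_false(post$failed)
})

test_that("masked parameters stay at their prior means in the posterior parameter set", {
  coh <- small_cohort(n = 1, seed = 13)
  data <- normalize_cohort(coh$spectra)$spectra[[1]]
  pr <- default_priors()
  post <- variational_laplace(data, pr)
  expect_identical(post$params$T[["SS"]], pr$params$T[["SS"]])
  for (gl in c("G1", "G3", "G10", "G13"))
    expect_identical(post$params$G[[gl]], pr$params$G[[gl]])
  # free parameters did move
  expect_gt(max(abs(post$mean)), 0.01)
})

test_that("accepted free-energy trace is non-decreasing", {
  coh <- small_cohort(n = 3, seed = 14)
  for (s in normalize_cohort(coh$spectra)$spectra) {
    post <- variational_laplace(s, default_priors())
    expect_true(all(diff(post$F_trace) >= -1e-9))
  }
})

test_that("a +0.4 offset on G7 is recovered within the 90 percent credible interval", {
  pr <- default_priors()
  g <- frequency_grid()
  truth <- apply_log_deviations(pr$params, c("G.7" = 0.4))
  mu <- predicted_spectrum(truth, g)$total
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    y <- mu * exp(rnorm(length(g), 0, 0.03))
    post <- variational_laplace(new_spectrum(g, y, whitened = TRUE,
                                             normalised = TRUE), pr)
    ci <- post$mean["G.7"] + c(-1, 1) * 1.645 * sqrt(post$cov["G.7", "G.7"])
    if (ci[1] <= 0.4 && 0.4 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("grand-mean fit of a single-subject cohort equals that subject's fit", {
  coh <- small_cohort(n = 1, seed = 15)
  data <- normalize_cohort(coh$spectra)$spectra
  gm <- fit_grand_mean(data)
  single <- variational_laplace(data[[1]], default_priors())
  expect_equal(gm$posterior$mean, single$mean, tolerance = 1e-10)
  expect_equal(gm$posterior$free_energy, single$free_energy, tolerance = 1e-8)
  validate_priors(gm$priors) # returned empirical priors are a valid spec
  expect_equal(gm$priors$precision, default_priors()$precision)
})

test_that("empirical priors shrink from the default priors toward the population", {
  # cohort generated around a population whose G7 and interneuron time
  # constant sit 0.3 log-units above the default priors: the grand-mean
  # posterior must move in that direction without overshooting
  pr <- default_priors()
  shift <- c("G.7" = 0.3, "T.II" = 0.3)
  pop <- default_priors(apply_log_deviations(pr$params, shift))
  coh <- generate_cohort_spectra(cohort_spec(n_subjects = 40, seed = 71), pop)
  gm <- fit_grand_mean(normalize_cohort(coh$spectra)$spectra, pr)
  for (nm in names(shift)) {
    expect_gte(gm$posterior$mean[[nm]], -0.02)
    expect_lte(gm$posterior$mean[[nm]], shift[[nm]])
  }
})

test_that("cohort fitting preserves order and is deterministic", {
  coh <- small_cohort(n = 4, seed = 16)
  data <- normalize_cohort(coh$spectra)$spectra
  pr <- default_priors()
  fit1 <- fit_cohort(data, pr)
  fit2 <- fit_cohort(data[c(3, 1, 4, 2)], pr)
  expect_equal(fit1$posteriors[[3]]$mean, fit2$posteriors[[1]]$mean)
  expect_equal(fit1$posteriors[[2]]$mean, fit2$posteriors[[4]]$mean)
  fit3 <- fit_cohort(data, pr)
  expect_identical(posterior_means(fit1), posterior_means(fit3))
})

test_that("masking a parameter is the limit of infinite prior precision", {
  coh <- small_cohort(n = 1, seed = 17)
  data <- normalize_cohort(coh$spectra)$spectra[[1]]
  pr_mask <- default_priors()
  pr_mask$free <- setdiff(pr_mask$free, "G.7")
  pr_mask$precision <- pr_mask$precision[pr_mask$free]
  pr_pin <- default_priors()
  pr_pin$precision["G.7"] <- 1e12
  post_mask <- variational_laplace(data, pr_mask, tol = 1e-6, max_iter = 128)
  post_pin <- variational_laplace(data, pr_pin, tol = 1e-6, max_iter = 128)
  expect_lt(abs(post_pin$mean["G.7"]), 1e-5)
  expect_lt(max(abs(post_mask$mean - post_pin$mean[pr_mask$free])), 1e-3)
})
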