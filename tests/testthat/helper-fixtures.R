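# Shared fixtures, built in code.

# parameter set with all couplings removed and a single observed population
uncoupled_params <- function(pop = "SS", T = c(SS = 2, SP = 2, II = 10, DP = 20)) {
  G0 <- as.list(stats::setNames(rep(0, 13), paste0("G", 1:13)))
  L <- c(SS = 0, SP = 0, II = 0, DP = 0)
  L[pop] <- 1
  cmc_parameters(T = T, G = G0, D = 0, L = L)
}

# small synthetic cohort for pipeline tests
small_cohort <- function(n = 6, seed = 42, n_trials = 40, ...) {
  generate_cohort_spectra(cohort_spec(n_subjects = n, n_trials = n_trials,
                                      seed = seed, ...))
}

# exact power-law spectrum fixture
powerlaw_spectrum <- function(A = 3, b = 1.5, grid = frequency_grid()) {
  new_spectrum(grid, A * grid^(-b))
}

# gaussian bump on a flat background
bump_spectrum <- function(centre = 53, width = 2, amp = 1, base = 0.1,
                          grid = frequency_grid()) {
  new_spectrum(grid, base + amp * exp(-(grid - centre)^2 / (2 * width^2)))
}
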