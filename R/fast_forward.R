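# Internal fast path for repeated spectral predictions during inversion.
#
# Builds a closure that maps a free-deviation vector straight to the
# predicted total spectrum, skipping object validation and re-deriving
# only what changes. Exploits the fact that with a centred sigmoid and
# zero-mean drive the fixed point is exactly the origin, where the
# sigmoid slope is r/4.
make_fast_forward <- function(priors, grid) {
  p0 <- priors$params
  free <- priors$free
  graph <- cmc_connectivity()
  pops <- cmc_populations()
  tgt <- match(graph$target, pops)
  src <- match(graph$source, pops)
  glab <- graph$label
  sgn <- graph$sign
  T0 <- p0$T
  G0 <- unlist(p0$G)[glab]
  input0 <- p0$input
  noise0 <- p0$noise
  mu_u0 <- stats::qlogis((noise0[["alpha_mu"]] - 8) / 5)
  omega <- 2 * pi * grid / 1000
  iomega <- 1i * omega
  Dmat <- matrix(0, 8, 8)
  cross <- matrix(p0$D, 4, 4); diag(cross) <- 0
  Dmat[5:8, 1:4] <- cross
  Sp <- p0$r / 4
  kind <- sub("\\..*$", "", free)
  key <- sub("^[^.]*\\.", "", free)
  i8 <- diag(8)
  pinkbase <- 1 / grid

  function(v) {
    T <- T0; G <- G0; input <- input0; noise <- noise0
    for (k in seq_along(free)) {
      val <- v[k]
      switch(kind[k],
             T = { T[key[k]] <- T[key[k]] * exp(val) },
             G = { G[paste0("G", key[k])] <- G[paste0("G", key[k])] * exp(val) },
             input = { input[key[k]] <- input[key[k]] * exp(val) },
             noise = {
               if (key[k] == "alpha_mu")
                 noise[["alpha_mu"]] <- 8 + 5 * stats::plogis(mu_u0 + val)
               else noise[key[k]] <- noise[key[k]] * exp(val)
             })
    }
    kappa <- 1 / T
    A <- matrix(0, 4, 4)
    for (e in seq_along(glab))
      A[tgt[e], src[e]] <- A[tgt[e], src[e]] + sgn[e] * G[e]
    J <- matrix(0, 8, 8)
    J[1:4, 5:8] <- diag(4)
    J[5:8, 1:4] <- kappa * A * Sp - diag(kappa^2)
    J[5:8, 5:8] <- diag(-2 * kappa)
    JD <- tryCatch(solve(i8 + Dmat * J, J), error = function(e) NULL)
    if (is.null(JD)) return(NULL)
    ev <- eigen(JD, only.values = TRUE)$values
    if (any(Re(ev) >= 0)) return(NULL)
    H <- cmc_transfer_cpp(kappa, A, Sp, p0$C, p0$L, p0$D, omega)
    neural <- (Re(H)^2 + Im(H)^2) *
      (input[["white"]] + input[["pink"]] * pinkbase)
    neural + noise[["white"]] + noise[["alpha_amp"]] *
      exp(-(grid - noise[["alpha_mu"]])^2 / (2 * noise[["alpha_sigma"]]^2))
  }
}
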