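# shared fixtures, all generated in code

theta_default <- cri_params(0.55, 25, -0.010, 0.40, 30, 0.006)
theta_uncoupled <- cri_params(0.5, 10, 0, 0.4, 8, 0)
psi_default <- sad_params(0.9, 0.9, 1, 1.2, 0.5)

# closed-form logistic with init y0 at t0
logistic_closed <- function(t, alpha, K, y0, t0) {
  K * y0 * exp(alpha * (t - t0)) / (K + y0 * (exp(alpha * (t - t0)) - 1))
}

# forward-Euler oracle for the CRI system at a fine fixed step
euler_oracle <- function(params, init, times, h = 1e-5) {
  th <- as.numeric(params)
  H <- init[["H"]]; D <- init[["D"]]
  out <- matrix(NA_real_, length(times), 2)
  out[1, ] <- c(H, D)
  for (i in 2:length(times)) {
    nst <- round((times[i] - times[i - 1]) / h)
    for (k in seq_len(nst)) {
      dH <- th[1] * (1 - H / th[2]) * H + th[1] * th[3] * H * D
      dD <- th[4] * (1 - D / th[5]) * D + th[4] * th[6] * D * H
      H <- H + h * dH
      D <- D + h * dD
    }
    out[i, ] <- c(H, D)
  }
  out
}

# small simulated mapping dataset shared across tests (memoized)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n = 60, p = 12, H2 = 0.2, effect_size = 0.12,
                        seed = 11)
      g <- simulate_genotypes(cfg)
      ph <- simulate_phenotypes(g, cfg)
      cache <<- list(cfg = cfg, geno = g, pheno = ph)
    }
    cache
  }
})

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
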