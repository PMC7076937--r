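# Independent oracles used across the test suite.

# Fixed-step Heun (predictor-corrector) method-of-steps integrator for the
# delayed-elimination system, written without any package machinery.  The
# lag must be a multiple of dt so history lookups are exact grid reads.
heun_dde_oracle <- function(params, regimen, times, dt = 1e-4) {
  p <- as.list(params)
  stopifnot(p$t2 > 0, abs(p$t2 / dt - round(p$t2 / dt)) < 1e-8)
  t_end <- max(times)
  n <- round(t_end / dt)
  lag <- round(p$t2 / dt)
  Z1 <- numeric(n + 1)
  Z2 <- numeric(n + 1)
  Z1[1] <- p$V0
  A <- regimen$dose_amount; ke <- regimen$ke; td <- regimen$dose_time
  l0 <- p$lambda0; l1 <- p$lambda1; psi <- p$psi; k1 <- p$k1; k2 <- p$k2
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    z1 <- Z1[i]; z2 <- Z2[i]
    z2l <- if (i - lag >= 1) Z2[i - lag] else 0
    c1 <- if (t >= td) A * exp(-ke * (t - td)) else 0
    u <- (l0 / l1) * max(z1 + z2, 0)
    g1 <- l0 * z1 / (1 + u^psi)^(1 / psi)
    k1c <- k1 * c1 * z1
    d1a <- g1 - k1c
    d1b <- k1c - k2 * z2l
    # predictor at t + dt
    z1p <- z1 + dt * d1a
    z2p <- z2 + dt * d1b
    z2l2 <- if (i + 1 - lag >= 1) Z2[i + 1 - lag] else 0
    tn <- t + dt
    c2 <- if (tn >= td) A * exp(-ke * (tn - td)) else 0
    u2 <- (l0 / l1) * max(z1p + z2p, 0)
    g2 <- l0 * z1p / (1 + u2^psi)^(1 / psi)
    k2c <- k1 * c2 * z1p
    d2a <- g2 - k2c
    d2b <- k2c - k2 * z2l2
    Z1[i + 1] <- z1 + dt / 2 * (d1a + d2a)
    Z2[i + 1] <- z2 + dt / 2 * (d1b + d2b)
  }
  idx <- round(times / dt) + 1
  stopifnot(max(abs(times / dt - round(times / dt))) < 1e-8)
  (Z1 + Z2)[idx]
}

# deterministic random parameter sets for the perturbed models
random_tgi_params <- function(n, seed, delay = TRUE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    p <- c(lambda0 = runif(1, 0.1, 0.5), lambda1 = runif(1, 60, 250),
           V0 = runif(1, 80, 500), k1 = runif(1, 0.3, 1.5),
           k2 = runif(1, 0.2, 1))
    if (delay) p <- c(p, t2 = round(runif(1, 0.5, 3.5), 1))
    p
  })
}

# small deterministic cohort for estimation tests
small_cohort <- function(seed = 11, n_control = 4, n_treated = 3,
                         horizon = 21) {
  generate_cohort(default_population_spec(),
                  cohort_design(n_control = n_control,
                                n_treated = n_treated, horizon = horizon),
                  seed = seed)
}
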