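# Shared fixtures: small scenarios and configurations used across tests.

two_site_scenario <- function(p_e = 0.05, kex = 100, shift_g = 8.0,
                              shift_e = 8.9, tau_m = 8, j_hn = -93,
                              r_ex = 1, dr2 = 3) {
  exchange_scenario(c(1 - p_e, p_e, 0), kex = c(kex, 0),
                    shifts = c(shift_g, shift_e, 0), tau_m = tau_m,
                    j_hn = j_hn, r_ex = r_ex, dr2 = c(dr2, 0))
}

three_site_scenario <- function() {
  exchange_scenario(c(0.90, 0.06, 0.04), kex = c(150, 80),
                    shifts = c(8.0, 8.9, 7.2), tau_m = 8, j_hn = -93,
                    r_ex = 1, dr2 = c(3, -1))
}

small_config <- function(b1 = 30, n_offsets = 60, b0 = 18.8) {
  acquisition_config(b0 = b0, b1 = b1, offset_min = 6.6, offset_span = 3.4,
                     n_offsets = n_offsets, tex = 0.4)
}

# Full-propagator profile averaged over a Gaussian B1 distribution: the
# brute-force dephasing oracle against which the real-eigenvalue propagator
# is checked. Deliberately built from the full complex matrix exponential
# (via Matrix::expm), not from real_eig_propagator.
b1_averaged_profile <- function(scenario, config, width = 0.10,
                                n_quad = 21) {
  ns <- scenario$n_states
  p <- scenario$populations[seq_len(ns)]
  m0 <- numeric(6L * ns)
  for (s in seq_len(ns)) {
    m0[(s - 1L) * 6L + 3L] <- p[s]
    m0[(s - 1L) * 6L + 6L] <- -p[s]
  }
  detect <- function(m) m[3] - m[6]
  # Gauss-Legendre-free simple quadrature: equally spaced in +-3 sd with
  # Gaussian weights
  z <- seq(-3, 3, length.out = n_quad)
  w <- exp(-z^2 / 2)
  w <- w / sum(w)
  sig0 <- {
    L <- build_liouvillian(scenario, config, config$offsets[1],
                           phase = "ap", b1 = 0)
    U <- as.matrix(Matrix::expm(-config$tex * L$matrix))
    detect(U %*% m0)
  }
  vapply(config$offsets, function(off) {
    acc <- 0
    for (q in seq_along(z)) {
      b1q <- config$b1 * (1 + width * z[q])
      L <- build_liouvillian(scenario, config, off, phase = "ap", b1 = b1q)
      U <- as.matrix(Matrix::expm(-config$tex * L$matrix))
      acc <- acc + w[q] * detect(U %*% m0)
    }
    acc / sig0
  }, numeric(1))
}
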