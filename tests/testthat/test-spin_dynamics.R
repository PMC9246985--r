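# Liouvillian construction, rate matrices, relaxation rates and the
# real-eigenvalue dephasing propagator.

test_that("rate matrix obeys detailed balance, conservation and stationarity", {
  sc <- two_site_scenario(p_e = 0.05, kex = 100)
  K <- build_rate_matrix(sc)
  expect_equal(K["E1", "G"], 5)  # k_G->E = kex * p_E
  expect_equal(K["G", "E1"], 95) # k_E->G = kex * p_G
  expect_equal(colSums(K), c(G = 0, E1 = 0, E2 = 0))

  # unpopulated state: no exchange into or out of it
  sc1 <- exchange_scenario(c(1, 0, 0), kex = c(50, 0), shifts = c(8, 9, 0))
  expect_true(all(build_rate_matrix(sc1) == 0))

  # forked three-site: conservation and stationarity of the populations
  sc3 <- exchange_scenario(c(0.90, 0.06, 0.04), kex = c(150, 80),
                           shifts = c(8, 8.9, 7.2))
  K3 <- build_rate_matrix(sc3)
  expect_equal(colSums(K3), c(G = 0, E1 = 0, E2 = 0))
  expect_equal(as.numeric(K3 %*% sc3$populations), rep(0, 3),
               tolerance = 1e-10)
  # per-branch detailed balance
  expect_equal(K3["E1", "G"] * 0.90, K3["G", "E1"] * 0.06)
  expect_equal(K3["E2", "G"] * 0.90, K3["G", "E2"] * 0.04)
  expect_equal(K3["E1", "G"] + K3["G", "E1"], 150)
})

test_that("scenario validation rejects invalid inputs", {
  expect_error(exchange_scenario(c(0.9, 0.2, 0), kex = c(100, 0),
                                 shifts = c(8, 9, 0)), "sum to 1")
  expect_error(exchange_scenario(c(1.05, -0.05, 0), kex = c(100, 0),
                                 shifts = c(8, 9, 0)), "non-negative")
  expect_error(exchange_scenario(c(0.95, 0.05, 0), kex = c(-5, 0),
                                 shifts = c(8, 9, 0)), "non-negative")
  expect_error(exchange_scenario(c(0.95, 0.05, 0), kex = c(100, 0),
                                 shifts = c(8, 9, 0), tau_m = -1),
               "positive")
})

test_that("relaxation rates are positive, monotone in tau_m, and match an
           independent spectral-density calculation", {
  r10 <- relaxation_rates(10, 18.8)
  r5 <- relaxation_rates(5, 18.8)
  expect_gt(r10$r2_h, r5$r2_h)
  for (b0 in c(14.1, 16.4, 18.8, 21.1, 23.5)) {
    for (tau in c(3, 20)) {
      r <- relaxation_rates(tau, b0)
      expect_true(all(unlist(r) > 0) && all(is.finite(unlist(r))))
    }
  }
  expect_error(relaxation_rates(0, 18.8), "positive")

  # independent oracle: spectral-density sums written out by hand
  tau <- 10e-9
  gh <- 2.6752218744e8; gn <- 2.7126180e7
  wh <- gh * 18.8; wn <- gn * 18.8
  jj <- function(w) (2 / 5) * tau / (1 + (w * tau)^2)
  d <- 1e-7 * 1.054571817e-34 * gh * gn / (1.02e-10)^3
  r2_oracle <- d^2 / 8 * (4 * jj(0) + jj(wh - wn) + 3 * jj(wh) +
                            6 * jj(wn) + 6 * jj(wh + wn))
  r1n_oracle <- d^2 / 4 * (jj(wh - wn) + 3 * jj(wn) + 6 * jj(wh + wn)) +
    (wn * 164e-6)^2 / 3 * jj(wn)
  expect_equal(r10$r2_h, r2_oracle, tolerance = 1e-12)
  expect_equal(r10$r1_n, r1n_oracle, tolerance = 1e-12)
})

test_that("Liouvillian has the free-precession Bloch structure and the
           anti-phase doublet layout", {
  sc <- exchange_scenario(c(1, 0, 0), kex = c(0, 0), shifts = c(8.3, 0, 0),
                          tau_m = 8, j_hn = 0)
  cfg <- small_config(b1 = 0)
  L <- build_liouvillian(sc, cfg, offset = 8.0, phase = "ip")
  rr <- relaxation_rates(8, 18.8)
  ev <- eigen(L$matrix)$values
  omega <- 2 * pi * 0.3 * larmor_mhz(18.8)
  expect_equal(sort(Im(ev)), sort(c(-omega, 0, omega)), tolerance = 1e-8)
  expect_equal(sort(unique(round(Re(ev), 6))),
               sort(round(c(rr$r1_h, rr$r2_h + sc$r_ex), 6)))

  # J = 0: alpha and beta blocks identical
  sc0 <- two_site_scenario(j_hn = 0)
  Lap <- build_liouvillian(sc0, cfg, offset = 8.0, phase = "ap")$matrix
  expect_equal(Lap[1:3, 1:3], Lap[4:6, 4:6])
  # two-site anti-phase dimension: 6 operators x 2 states
  expect_equal(dim(Lap), c(12L, 12L))
  expect_error(build_liouvillian(sc0, cfg, 8, phase = "xy"))
})

test_that("real-eigenvalue propagator: full real spectrum, projection, and
           semigroup property", {
  # diagonal L (all eigenvalues real): propagator is the exact exponential
  L <- diag(c(11, 11, 0.02))
  expect_equal(real_eig_propagator(L, 0.3), diag(exp(-0.3 * c(11, 11, 0.02))),
               tolerance = 1e-12)

  # free spin with offset, B1 = 0: transverse components map to 0 and Hz
  # decays by exp(-R1 t) (only one real eigenvalue)
  sc <- exchange_scenario(c(1, 0, 0), kex = c(0, 0), shifts = c(8.3, 0, 0),
                          tau_m = 8, j_hn = 0)
  cfg <- small_config(b1 = 0)
  L1 <- build_liouvillian(sc, cfg, offset = 8.0, phase = "ip")
  P <- real_eig_propagator(L1, 0.4)
  rr <- relaxation_rates(8, 18.8)
  expect_equal(P %*% c(1, 1, 0), matrix(0, 3, 1), tolerance = 1e-10)
  expect_equal((P %*% c(0, 0, 1))[3], exp(-0.4 * rr$r1_h),
               tolerance = 1e-10)

  # semigroup on the real subspace
  sc2 <- two_site_scenario()
  L2 <- build_liouvillian(sc2, small_config(), offset = 8.85, phase = "ap")
  expect_equal(real_eig_propagator(L2, 0.1) %*% real_eig_propagator(L2, 0.3),
               real_eig_propagator(L2, 0.4), tolerance = 1e-8)
})

test_that("compiled and reference simulation engines agree to numerical
           precision", {
  cfg <- small_config(n_offsets = 40)
  for (sc in list(two_site_scenario(), three_site_scenario())) {
    ap_r <- simulate_ap_profile(sc, cfg, engine = "r")
    ap_c <- simulate_ap_profile(sc, cfg, engine = "cpp")
    expect_equal(ap_r$intensity, ap_c$intensity, tolerance = 1e-12)
    ip_r <- simulate_ip_profile(sc, cfg, engine = "r")
    ip_c <- simulate_ip_profile(sc, cfg, engine = "cpp")
    expect_equal(ip_r$intensity, ip_c$intensity, tolerance = 1e-12)
  }
})

test_that("simulated profiles satisfy the physical limit identities", {
  sc <- two_site_scenario()
  cfg <- small_config()

  # B1 -> 0 gives I/I0 = 1 at every offset
  cfg0 <- small_config(b1 = 0, n_offsets = 25)
  expect_equal(simulate_ap_profile(sc, cfg0)$intensity, rep(1, 25),
               tolerance = 1e-8)
  expect_equal(simulate_ip_profile(sc, cfg0)$intensity, rep(1, 25),
               tolerance = 1e-8)

  # far off resonance: no saturation
  sc1 <- exchange_scenario(c(1, 0, 0), kex = c(0, 0), shifts = c(9.9, 0, 0),
                           tau_m = 8, j_hn = -93)
  far <- acquisition_config(18.8, 30, offsets = seq(6.6, 7.0, length.out = 10),
                            tex = 0.4)
  expect_true(all(abs(simulate_ap_profile(sc1, far)$intensity - 1) < 1e-2))

  # J = 0 with ideal INEPT: anti-phase equals in-phase exactly
  sc0 <- two_site_scenario(j_hn = 0)
  expect_identical(simulate_ap_profile(sc0, cfg, inept = "ideal")$intensity,
                   simulate_ip_profile(sc0, cfg)$intensity)

  # in-phase intensities bounded in [0, 1]
  ip <- simulate_ip_profile(sc, cfg)
  expect_true(all(ip$intensity >= -1e-10 & ip$intensity <= 1 + 1e-10))

  # deeper minor-state dip for larger excited population
  off_e <- seq(8.7, 9.1, length.out = 21)
  cfg_e <- acquisition_config(18.8, 30, offsets = off_e, tex = 0.4)
  dip10 <- min(simulate_ip_profile(two_site_scenario(p_e = 0.10), cfg_e)$intensity)
  dip02 <- min(simulate_ip_profile(two_site_scenario(p_e = 0.02), cfg_e)$intensity)
  expect_lt(dip10, dip02)
})

test_that("anti-phase doublet components are split by the scalar coupling
           at weak B1", {
  sc <- exchange_scenario(c(1, 0, 0), kex = c(0, 0), shifts = c(8.3, 0, 0),
                          tau_m = 8, j_hn = -93)
  cfg <- acquisition_config(18.8, b1 = 5,
                            offsets = seq(7.8, 8.8, length.out = 401),
                            tex = 0.4)
  ap <- simulate_ap_profile(sc, cfg, inept = "ideal")
  # deepest point on either side of the chemical shift: the two doublet
  # components (the saturation profile has shallow satellite structure at
  # this resolution, so a plain local-minimum scan is not specific)
  lo <- ap$offset[ap$offset < 8.3][which.min(ap$intensity[ap$offset < 8.3])]
  hi <- ap$offset[ap$offset > 8.3][which.min(ap$intensity[ap$offset > 8.3])]
  sep_hz <- (hi - lo) * larmor_mhz(18.8)
  expect_equal(sep_hz, 93, tolerance = 0.10)
  # both components are saturation dips below the baseline
  expect_true(all(ap$intensity <= 1 + 1e-6))
})

test_that("explicit INEPT attenuates the anti-phase state but preserves the
           dip positions", {
  sc <- two_site_scenario()
  cfg <- small_config(n_offsets = 45)
  ap_id <- simulate_ap_profile(sc, cfg, inept = "ideal")
  ap_ex <- simulate_ap_profile(sc, cfg, inept = "explicit")
  # normalized profiles are close; the attenuation largely cancels in I/I0
  expect_equal(ap_ex$intensity, ap_id$intensity, tolerance = 0.05)
  a <- cestnet:::inept_amplitudes(sc, cfg)
  expect_true(all(a > 0 & a < 1)) # relaxation losses during 2 x 1/(4J)
})

test_that("real-eigenvalue dephasing reproduces brute-force B1-distribution
           averaging on a two-site system", {
  set.seed(401)
  sc <- two_site_scenario(p_e = 0.08, kex = 120)
  cfg <- small_config(b1 = 30, n_offsets = 30)
  prof <- simulate_ap_profile(sc, cfg, inept = "ideal")
  oracle <- b1_averaged_profile(sc, cfg)
  rms <- sqrt(mean((prof$intensity - oracle)^2))
  expect_lt(rms, 0.01)
})
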