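# Dip transform, real Fourier transform, zero-filling, packing and
# upsampling.

test_that("dip transform subtracts the maximum and is shift invariant", {
  expect_equal(dip_transform(c(1.0, 0.8, 1.0)), c(0, 0.2, 0))
  expect_equal(dip_transform(rep(0.7, 5)), rep(0, 5))
  x <- runif(40)
  expect_equal(dip_transform(x + 0.37), dip_transform(x))
  expect_equal(min(dip_transform(x)), 0)
  expect_error(dip_transform(numeric(0)), "empty")
})

test_that("real FT returns the non-redundant coefficients and round-trips", {
  expect_length(real_ft(rnorm(128)), 65)
  expect_length(real_ft(rnorm(86)), 44)  # floor(86/2) + 1; 42 redundant
  expect_length(real_ft(rnorm(87)), 44)  # odd N: (N-1)/2 redundant
  expect_error(real_ft(1), "two points")

  co <- real_ft(rep(2.5, 32))
  expect_equal(co[1], complex(real = 80, imaginary = 0))
  expect_true(all(abs(co[-1]) < 1e-10))

  for (n in c(50, 86, 87, 128)) {
    x <- rnorm(n)
    expect_equal(inverse_real_ft(real_ft(x), n, scale = n), x,
                 tolerance = 1e-10)
  }
})

test_that("zero-fill pads to exactly 65 complex points on the uniform time
           grid", {
  sw <- ppm_to_hz(3.4, 18.8)
  ptd <- zero_fill(complex(real = rnorm(48), imaginary = rnorm(48)), sw,
                   n_original = 94)
  expect_length(ptd$coef, 65)
  expect_true(all(ptd$coef[49:65] == 0))
  expect_equal(ptd$t0, (0:64) / sw)
  expect_true(all(diff(ptd$t0) > 0) && ptd$t0[1] == 0)

  full <- complex(real = rnorm(65), imaginary = rnorm(65))
  expect_equal(zero_fill(full, sw, 128)$coef, full)
  ptd44 <- zero_fill(complex(real = rnorm(44), imaginary = rnorm(44)), sw, 86)
  expect_true(all(ptd44$coef[45:65] == 0))
  expect_error(zero_fill(complex(70), sw), "capped")
})

test_that("packing lays out 130-vectors and round-trips", {
  sw <- ppm_to_hz(3.4, 18.8)
  ptd <- zero_fill(complex(real = rnorm(40), imaginary = rnorm(40)), sw,
                   n_original = 78)
  packed <- pack_input(ptd)
  expect_length(packed$coef, 130)
  expect_length(packed$time, 130)
  expect_true(all(packed$coef[c(41:65, 106:130)] == 0)) # zero-filled tail
  rt <- unpack_input(packed, n_original = 78)
  expect_equal(rt$coef, ptd$coef)
  expect_equal(rt$t0, ptd$t0, tolerance = 1e-12)
  expect_equal(rt$sw_hz, sw, tolerance = 1e-6)
})

test_that("upsampling is the band-limited interpolation of the original
           profile", {
  # 128-point profile: exact round trip
  x <- rnorm(128)
  ptd <- zero_fill(real_ft(x), sw_hz = 2720, n_original = 128)
  expect_equal(upsample_to_offsets(ptd), x, tolerance = 1e-10)

  # all-zero input stays zero
  expect_equal(upsample_to_offsets(zero_fill(complex(65), 2720, 128)),
               rep(0, 128))

  # band-limited input: values at the original sample points are recovered
  # exactly by the trigonometric interpolant (evaluated independently)
  n <- 86
  d <- dip_transform(simulate_ip_profile(two_site_scenario(),
                                         small_config(n_offsets = n)))
  co <- real_ft(d)
  trig_eval <- function(co, n, x) { # x in cycles: j/n recovers point j
    k <- seq_along(co) - 1
    nyq <- (n %% 2 == 0)
    w <- rep(2, length(co)); w[1] <- 1
    if (nyq) w[length(co)] <- 1
    Re(sum(w * co * exp(2i * pi * k * x))) / n
  }
  at_orig <- vapply((seq_len(n) - 1) / n, trig_eval, numeric(1), co = co,
                    n = n)
  expect_equal(at_orig, d, tolerance = 1e-10)
  # the 128-point upsampled profile equals that interpolant on its own grid
  up <- upsample_to_offsets(zero_fill(co, 2720, n_original = n))
  at_128 <- vapply((seq_len(128) - 1) / 128, trig_eval, numeric(1), co = co,
                   n = n)
  expect_equal(up, at_128, tolerance = 1e-10)
})

test_that("processing chain is linear and scale-equivariant after the dip
           transform", {
  d <- dip_transform(simulate_ip_profile(two_site_scenario(),
                                         small_config(n_offsets = 70)))
  up1 <- upsample_to_offsets(zero_fill(real_ft(d), 2720, 70))
  up3 <- upsample_to_offsets(zero_fill(real_ft(3 * d), 2720, 70))
  expect_equal(up3, 3 * up1, tolerance = 1e-10)
})

test_that("pack_profile carries metadata through the full chain", {
  sc <- two_site_scenario()
  cfg <- small_config(n_offsets = 94)
  ap <- simulate_ap_profile(sc, cfg)
  packed <- pack_profile(ap)
  expect_length(packed$coef, 130)
  expect_length(packed$time, 130)
  expect_equal(packed$n_original, 94)
  expect_equal(packed$sw_hz, ppm_to_hz(3.4, 18.8), tolerance = 1e-6)
  # time axis spacing is 1/SW
  expect_equal(packed$time[2] - packed$time[1], 1 / packed$sw_hz,
               tolerance = 1e-12)
})
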