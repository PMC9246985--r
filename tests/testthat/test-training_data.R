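# Training-data sampler: parameter ranges, reproducibility, noise model and
# example construction.

test_that("sampled scenarios stay within the training parameter ranges", {
  set.seed(101)
  draws <- replicate(2000, sample_scenario(), simplify = FALSE)
  sc <- lapply(draws, `[[`, "scenario")
  cfg <- lapply(draws, `[[`, "config")

  kex <- unlist(lapply(sc, function(s) s$kex[s$kex > 0]))
  expect_true(all(kex >= 10 & kex <= 300))
  pe <- unlist(lapply(sc, function(s) s$populations[-1]))
  expect_true(all(pe[pe > 0] >= 0.01 & pe[pe > 0] <= 0.15))
  expect_true(all(vapply(sc, function(s) s$j_hn, 1) >= -95))
  expect_true(all(vapply(sc, function(s) s$j_hn, 1) <= -91))
  expect_true(all(vapply(sc, function(s) s$tau_m, 1) >= 3))
  expect_true(all(vapply(sc, function(s) s$tau_m, 1) <= 20))
  expect_true(all(vapply(sc, function(s) s$r_ex, 1) >= 0))

  b0 <- vapply(cfg, function(c) c$b0, 1)
  expect_true(all(b0 %in% c(14.1, 16.4, 18.8, 21.1, 23.5)))
  b1 <- vapply(cfg, function(c) c$b1, 1)
  expect_true(all(b1 >= 15 & b1 <= 50))
  npts <- vapply(cfg, function(c) length(c$offsets), 1)
  expect_true(all(npts >= 50 & npts <= 128))
  spans <- vapply(cfg, function(c) diff(range(c$offsets)), 1)
  expect_equal(spans, rep(3.4, length(spans)), tolerance = 1e-10)
  expect_true(all(vapply(cfg, function(c) c$tex, 1) == 0.4))
  expect_true(all(vapply(cfg, function(c) c$d1, 1) == 0.5))

  # shifts inside the offset window
  ok <- vapply(seq_along(sc), function(i) {
    s <- sc[[i]]
    all(s$shifts[seq_len(s$n_states)] >= min(cfg[[i]]$offsets) &
          s$shifts[seq_len(s$n_states)] <= max(cfg[[i]]$offsets))
  }, logical(1))
  expect_true(all(ok))

  # excited-state slots ordered by population, descending
  p3 <- vapply(sc, function(s) {
    s$n_states < 3 || s$populations[2] >= s$populations[3]
  }, logical(1))
  expect_true(all(p3))
})

test_that("sampling is reproducible from the seed", {
  set.seed(7)
  a <- replicate(20, sample_scenario(), simplify = FALSE)
  set.seed(7)
  b <- replicate(20, sample_scenario(), simplify = FALSE)
  expect_identical(a, b)
})

test_that("noise injection matches the requested fraction of the profile
           maximum", {
  sc <- two_site_scenario()
  cfg <- small_config(n_offsets = 100)
  clean <- simulate_ap_profile(sc, cfg)
  expect_identical(add_noise(clean, 0), clean)

  set.seed(55)
  pooled <- unlist(lapply(1:200, function(i) {
    (add_noise(clean, 0.01)$intensity - clean$intensity) /
      max(clean$intensity)
  }))
  expect_equal(sd(pooled), 0.01, tolerance = 0.05)
})

test_that("transformation-network examples have the contracted shapes and
           noise-free targets", {
  set.seed(9)
  draw <- sample_scenario()
  ex <- make_tr_example(draw$scenario, draw$config)
  expect_length(ex$input$coef, 130)
  expect_length(ex$input$time, 130)
  expect_length(ex$target, 128)
  expect_equal(ex$indicator,
               as.numeric(seq_len(3) <= draw$scenario$n_states))
  expect_true(all(ex$f_true > 0 & ex$f_true < 1))

  # the target is deterministic (noise touches only the input)
  set.seed(10)
  ex1 <- make_tr_example(draw$scenario, draw$config)
  set.seed(11)
  ex2 <- make_tr_example(draw$scenario, draw$config)
  expect_identical(ex1$target, ex2$target)
  expect_false(identical(ex1$input$coef, ex2$input$coef))
  expect_true(all(ex1$target >= 0 & ex1$target <= 1 + 1e-8))
})

test_that("batch generation produces aligned arrays", {
  set.seed(12)
  dat <- generate_tr_examples(8)
  expect_equal(dim(dat$coef), c(8L, 130L))
  expect_equal(dim(dat$time), c(8L, 130L))
  expect_equal(dim(dat$target), c(8L, 128L))
  expect_equal(dim(dat$f_true), c(8L, 3L))
  expect_equal(dim(dat$indicator), c(8L, 3L))
  # same seed: identical batch
  set.seed(12)
  dat2 <- generate_tr_examples(8)
  expect_identical(dat$coef, dat2$coef)
})

test_that("shift-network examples normalize shifts into the offset window", {
  sc <- two_site_scenario(shift_g = 8.3, shift_e = 6.6 + 1.7)
  cfg <- small_config()
  ex <- make_cs_example(rep(0, 128), sc, cfg)
  expect_equal(ex$f_true[1], (8.3 - 6.6) / 3.4)
  expect_equal(ex$f_true[2], 0.5) # window center
  expect_equal(ex$indicator, c(1, 1, 0))
  # absent slot parked at 0.5
  expect_equal(ex$f_true[3], 0.5)

  sc_out <- two_site_scenario(shift_e = 11.2)
  expect_error(make_cs_example(rep(0, 128), sc_out, cfg), "outside")
})

test_that("a J = 0 scenario passes through the network-free chain to the
           in-phase target within interpolation error", {
  sc <- two_site_scenario(j_hn = 0, kex = 250, p_e = 0.1)
  cfg <- small_config(b1 = 45, n_offsets = 110)
  ex <- make_tr_example(sc, cfg, noise_frac = 0, inept = "ideal")
  up <- upsample_to_offsets(unpack_input(ex$input, n_original = 110))
  expect_lt(sqrt(mean((up - ex$target)^2)), 0.02)
})
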