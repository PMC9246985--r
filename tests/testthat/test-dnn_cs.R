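# Chemical-shift network: output contract, the two-part loss, the
# confidence/uncertainty mapping and its calibration.

test_that("the network emits three shift/confidence pairs in (0, 1)", {
  set.seed(41)
  cs <- build_dnn_cs(cs_model_config(init_filters = 4, growth = 4,
                                     depth = 2, n_blocks = 2, hidden = 16))
  x <- array(abs(rnorm(4 * 128)), c(4, 128, 1))
  out <- nn_predict(cs$net, x)
  expect_equal(dim(out), c(4, 6)) # 3 x 2 per profile
  expect_true(all(out > 0 & out < 1))
  expect_true(all(is.finite(out)))
  expect_gt(nn_n_params(cs$net), 0)

  pred <- predict_shifts(cs, matrix(abs(rnorm(2 * 128)), 2),
                         offset_min = 6.6, span = 3.4)
  expect_equal(nrow(pred), 6) # exactly three slots per profile
  expect_equal(pred$state_slot, rep(1:3, 2))
  expect_true(all(pred$delta_ppm >= 6.6 & pred$delta_ppm <= 10.0))
  expect_true(all(pred$sigma_ppm >= 0))
})

test_that("loss_freq matches its closed form and scaling properties", {
  f <- c(0.3, 0.5, 0.7)
  expect_equal(loss_freq(f, f, rep(0.1, 3)), 0)
  expect_equal(loss_freq(0.6, 0.5, 0.1), 1.0) # (0.1/0.1)^2
  sig <- c(0.05, 0.1, 0.2)
  ft <- c(0.25, 0.55, 0.75)
  expect_equal(loss_freq(f, ft, 2 * sig), loss_freq(f, ft, sig) / 4)
  expect_error(loss_freq(f, ft, c(0.1, 0, 0.1)))
})

test_that("loss_uncer penalizes only indicated states", {
  expect_equal(loss_uncer(c(0.01, 0.04, 1e6), c(1, 1, 0)), 3e-5)
  expect_equal(loss_uncer(rep(0, 3), c(1, 1, 1)), 0)
  sig <- c(0.2, 0.3, 0.4)
  expect_gte(loss_uncer(sig, c(1, 1, 1)), loss_uncer(sig, c(1, 1, 0)))
})

test_that("confidence/uncertainty mapping is a bijection with the stated
           limits", {
  cc <- seq(0.001, 0.999, length.out = 50)
  expect_equal(sigma_to_conf(conf_to_sigma(cc, 0.029), 0.029), cc,
               tolerance = 1e-12)
  expect_equal(conf_to_sigma(1, 2), 0)
  expect_gt(conf_to_sigma(1e-9, 1), 1e8)
  expect_true(all(diff(conf_to_sigma(cc, 1)) < 0)) # monotone decreasing
})

test_that("k calibration follows the rescaling rule", {
  expect_equal(signif(calibrate_k(3.4, 7.3e-5), 2), 0.029)
  expect_equal(calibrate_k(1, 1), 1)
  expect_equal(calibrate_k(6.8, 7.3e-5), 2 * calibrate_k(3.4, 7.3e-5))
  expect_error(calibrate_k(0, 1), "positive")
  expect_error(calibrate_k(3.4, -1), "positive")
})

test_that("map_shift is the affine window mapping", {
  expect_equal(map_shift(0, 6.6, 3.4), 6.6)
  expect_equal(map_shift(1, 6.6, 3.4), 10.0)
  expect_equal(map_shift(0.5, 6.6, 3.4), 8.3)
  expect_error(map_shift(1.2, 6.6, 3.4))
})

test_that("the training loss equals loss_freq + loss_uncer computed
           independently", {
  set.seed(42)
  b <- 5
  pred <- matrix(runif(b * 6, 0.05, 0.95), b)
  target <- list(f_true = matrix(runif(b * 3), b),
                 indicator = matrix(rbinom(b * 3, 1, 0.7), b))
  ls <- cestnet:::cs_loss()(pred, target)

  # independent scalar reimplementation, one example at a time
  ref <- 0
  for (i in seq_len(b)) {
    sig <- 1 / pred[i, 4:6] - 1
    ref <- ref + loss_freq(pred[i, 1:3], target$f_true[i, ], sig) +
      loss_uncer(sig, target$indicator[i, ])
  }
  expect_equal(ls$value, ref / b, tolerance = 1e-12)
  expect_equal(unname(ls$parts["l_freq"] + ls$parts["l_uncer"]), ls$value,
               tolerance = 1e-12)

  # analytic gradient against finite differences
  eps <- 1e-6
  g_fd <- matrix(0, b, 6)
  for (j in seq_len(6)) {
    for (i in seq_len(b)) {
      up <- pred; dn <- pred
      up[i, j] <- up[i, j] + eps
      dn[i, j] <- dn[i, j] - eps
      g_fd[i, j] <- (cestnet:::cs_loss()(up, target)$value -
                       cestnet:::cs_loss()(dn, target)$value) / (2 * eps)
    }
  }
  expect_equal(ls$grad, g_fd, tolerance = 1e-4)
})

test_that("training runs, records both loss components and calibrates k", {
  set.seed(43)
  dat <- generate_tr_examples(120, noise = c(0.001, 0.04))
  set.seed(44)
  cs <- build_dnn_cs(cs_model_config(init_filters = 4, growth = 4,
                                     depth = 2, n_blocks = 2, hidden = 16))
  cs <- train_dnn_cs(cs, dat, tr_model = NULL, epochs = 3, batch_size = 32)
  expect_named(cs$history, c("epoch", "loss", "l_freq", "l_uncer"))
  expect_true(cs$trained)
  expect_true(is.finite(cs$k) && cs$k > 0)
  expect_equal(cs$k, 3.4 * sqrt(cs$l_freq_final), tolerance = 1e-12)
})
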