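# Network engine: layer shapes, hand-derived gradients against finite
# differences, and optimizer behaviour.

nn_ns <- asNamespace("cestnet")

fd_check <- function(net, x, target, loss, n_probe = 2, eps = 1e-5) {
  fw <- nn_ns$net_forward(net, x, keep_cache = TRUE)
  ls <- loss(fw$out, target)
  bw <- nn_ns$net_backward(net, fw$caches, ls$grad)
  f0 <- function(net) loss(nn_ns$net_forward(net, x)$out, target)$value
  worst <- 0
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$params)) {
      p <- net$layers[[i]]$params[[nm]]
      g <- bw$grads[[i]][[nm]]
      ks <- if (is.list(p)) seq_along(p) else NA
      for (k in ks) {
        pv <- if (is.list(p)) p[[k]] else p
        gv <- if (is.list(g)) g[[k]] else g
        for (j in sample(length(pv), min(n_probe, length(pv)))) {
          up <- net; dn <- net
          if (is.list(p)) {
            up$layers[[i]]$params[[nm]][[k]][j] <- pv[j] + eps
            dn$layers[[i]]$params[[nm]][[k]][j] <- pv[j] - eps
          } else {
            up$layers[[i]]$params[[nm]][j] <- pv[j] + eps
            dn$layers[[i]]$params[[nm]][j] <- pv[j] - eps
          }
          fd <- (f0(up) - f0(dn)) / (2 * eps)
          worst <- max(worst,
                       abs(fd - gv[j]) / max(abs(fd), abs(gv[j]), 1e-8))
        }
      }
    }
  }
  worst
}

test_that("layer shapes follow the architecture contracts", {
  set.seed(21)
  x <- array(rnorm(4 * 65 * 3), c(4, 65, 3))
  conv <- nn_conv1d(3, 8, kernel = 3, dilation = 2)
  expect_equal(dim(nn_ns$layer_forward(conv, x)$out), c(4, 65, 8))
  gated <- nn_conv1d(3, 8, kernel = 3, act = "gated")
  expect_equal(dim(nn_ns$layer_forward(gated, x)$out), c(4, 65, 8))
  res <- nn_resblock(3, kernel = 3, dilation = 4)
  expect_equal(dim(nn_ns$layer_forward(res, x)$out), c(4, 65, 3))
  db <- nn_dense_block(3, growth = 4, depth = 2)
  expect_equal(dim(nn_ns$layer_forward(db, x)$out), c(4, 65, 11))
  pool <- nn_pool1d(2)
  x128 <- array(rnorm(4 * 128 * 2), c(4, 128, 2))
  expect_equal(dim(nn_ns$layer_forward(pool, x128)$out), c(4, 64, 2))
  # average pooling really averages
  expect_equal(nn_ns$layer_forward(pool, x128)$out[1, 1, 1],
               mean(x128[1, 1:2, 1]))

  net <- nn_network(nn_conv1d(3, 6), nn_flatten(), nn_dense(65 * 6, 10))
  expect_equal(dim(nn_predict(net, x)), c(4, 10))
  expect_equal(nn_n_params(net),
               3 * 3 * 6 + 6 + 65 * 6 * 10 + 10)
})

test_that("hand-derived gradients match finite differences for every layer
           type", {
  set.seed(22)
  net <- nn_network(
    nn_conv1d(3, 6, kernel = 1),
    nn_resblock(6, kernel = 3, dilation = 2),
    nn_conv1d(6, 8, kernel = 3, act = "gated"),
    nn_dense_block(8, growth = 4, depth = 2),
    nn_pool1d(2),
    nn_flatten(),
    nn_dense(32 * 16, 12, act = "relu"),
    nn_dense(12, 6, act = "sigmoid")
  )
  x <- array(rnorm(3 * 64 * 3), c(3, 64, 3))
  target <- matrix(runif(3 * 6), 3)
  expect_lt(fd_check(net, x, target, loss_mse()), 1e-5)

  # soft-argmax locator head
  set.seed(27)
  net2 <- nn_network(
    nn_conv1d(2, 6, kernel = 3, act = "relu"),
    nn_locator(6, n_slots = 3, hidden = 8)
  )
  x2 <- array(rnorm(3 * 32 * 2), c(3, 32, 2))
  t2 <- matrix(runif(3 * 6), 3)
  # looser tolerance: the locator's global max-pool context is piecewise
  # smooth, and a finite-difference probe can step across an argmax switch
  expect_lt(fd_check(net2, x2, t2, loss_mse(), n_probe = 4), 1e-3)
  out <- nn_predict(net2, x2)
  expect_equal(dim(out), c(3, 6))
  expect_true(all(out > 0 & out < 1))
})

test_that("Adam training reduces the loss and is reproducible", {
  make_data <- function() {
    x <- matrix(rnorm(400 * 8), 400)
    y <- cbind(sin(x[, 1] + x[, 2]), x[, 3] * x[, 4])
    list(x = x, y = y)
  }
  set.seed(23)
  d <- make_data()
  set.seed(24)
  net <- nn_network(nn_dense(8, 32, act = "tanh"), nn_dense(32, 2))
  set.seed(25)
  tr1 <- nn_train(net, d$x, d$y, loss_mse(), epochs = 25, batch_size = 64,
                  lr = 3e-3)
  expect_lt(tail(tr1$history$loss, 1), 0.5 * tr1$history$loss[1])
  # identical seeds give an identical loss curve
  set.seed(25)
  tr2 <- nn_train(net, d$x, d$y, loss_mse(), epochs = 25, batch_size = 64,
                  lr = 3e-3)
  expect_identical(tr1$history$loss, tr2$history$loss)
})

test_that("loss-coupled learning-rate schedule stays within its clip range
           and still trains", {
  set.seed(26)
  x <- matrix(rnorm(200 * 4), 200)
  y <- x[, 1:2, drop = FALSE] * 0.5
  net <- nn_network(nn_dense(4, 16, act = "relu"), nn_dense(16, 2))
  tr <- nn_train(net, x, y, loss_mse(), epochs = 8, batch_size = 50,
                 lr = 3e-3, schedule = "loss_coupled")
  expect_lt(tail(tr$history$loss, 1), tr$history$loss[1])
})
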