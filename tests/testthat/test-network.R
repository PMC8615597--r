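# Unit tests run on tiny inputs; the full training smoke test lives in
# test-acceptance.R.

small_config <- function(m = 3, blocks = 2, seed = 11) {
  ecg_net_config(n_categories = m, n_leads = 2, n_blocks = blocks,
                 filters = c(4, 6), kernel_size = 5, batch_size = 4,
                 epochs = 2, seed = seed)
}

test_that("forward pass yields probabilities with the right shape", {
  cfg <- small_config()
  net <- cicst:::init_ecg_net(cfg)
  x <- array(rnorm(4 * 64 * 2), c(4, 64, 2))
  p <- predict(net, x)
  expect_equal(dim(p), c(4, 3))
  expect_true(all(p > 0 & p < 1))
})

test_that("forward pass is deterministic and batch-equivariant", {
  cfg <- small_config()
  net <- cicst:::init_ecg_net(cfg)
  set.seed(30)
  x <- array(rnorm(6 * 64 * 2), c(6, 64, 2))
  p1 <- predict(net, x)
  p2 <- predict(net, x)
  expect_identical(p1, p2)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(predict(net, x[perm, , , drop = FALSE]), p1[perm, ],
               tolerance = 1e-12)
})

test_that("each residual block halves the time dimension", {
  cfg <- small_config(blocks = 1)
  net <- cicst:::init_ecg_net(cfg)
  x <- array(rnorm(2 * 8 * 2), c(2, 8, 2))
  fw <- cicst:::net_forward(net, x)
  expect_equal(dim(fw$cache$v)[2], 4)
  # two blocks: 8 -> 2
  net2 <- cicst:::init_ecg_net(small_config(blocks = 2))
  fw2 <- cicst:::net_forward(net2, x)
  expect_equal(dim(fw2$cache$v)[2], 2)
})

test_that("network parameter shapes are time-length independent", {
  cfg <- small_config()
  net <- cicst:::init_ecg_net(cfg)
  for (tt in c(32, 64)) {
    x <- array(rnorm(2 * tt * 2), c(2, tt, 2))
    expect_equal(dim(predict(net, x)), c(2, 3))
  }
})

test_that("attention weights are a convex combination over time", {
  cfg <- small_config()
  net <- cicst:::init_ecg_net(cfg)
  x <- array(rnorm(3 * 64 * 2), c(3, 64, 2))
  out <- predict(net, x, attention = TRUE)
  sums <- apply(out$attention, c(1, 3), sum)
  expect_equal(unname(sums), matrix(1, 3, 3), tolerance = 1e-12)
  expect_true(all(out$attention >= 0))
})

test_that("class-wise attention reduces to the time-mean for uniform keys", {
  set.seed(31)
  v <- array(rnorm(2 * 10 * 4), c(2, 10, 4))
  k_unif <- array(0.7, c(2, 10, 3))
  res <- class_wise_attention(k_unif, v)
  tmean <- apply(v, c(1, 3), mean)
  for (i in 1:3)
    expect_equal(res$fv[, i, ], tmean, tolerance = 1e-12)
})

test_that("a dominant key time step selects that time slice of V", {
  set.seed(32)
  v <- array(rnorm(1 * 8 * 5), c(1, 8, 5))
  k <- array(0, c(1, 8, 2))
  k[1, 3, 1] <- 60; k[1, 7, 2] <- 60     # softmax saturates
  res <- class_wise_attention(k, v)
  expect_equal(res$fv[1, 1, ], v[1, 3, ], tolerance = 1e-9)
  expect_equal(res$fv[1, 2, ], v[1, 7, ], tolerance = 1e-9)
})

test_that("class-wise attention matches an explicit loop oracle", {
  set.seed(33)
  b <- 3; tt <- 7; m <- 4; f <- 5
  k <- array(rnorm(b * tt * m), c(b, tt, m))
  v <- array(rnorm(b * tt * f), c(b, tt, f))
  res <- class_wise_attention(k, v)
  for (bb in 1:b) for (i in 1:m) {
    s <- k[bb, , i]
    w <- exp(s - max(s)); w <- w / sum(w)
    fv <- numeric(f)
    for (t in 1:tt) fv <- fv + w[t] * v[bb, t, ]
    expect_equal(res$weights[bb, , i], w, tolerance = 1e-12)
    expect_equal(res$fv[bb, i, ], fv, tolerance = 1e-12)
  }
  expect_error(class_wise_attention(array(0, c(1, 4, 0)), v), "positive")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(34)
  cfg <- small_config()
  net <- cicst:::init_ecg_net(cfg)
  x <- array(rnorm(4 * 32 * 2), c(4, 32, 2))
  y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  fw <- cicst:::net_forward(net, x, training = TRUE)
  gr <- cicst:::net_backward(net, fw, y)
  loss_at <- function(n2) cicst:::bce_loss(
    cicst:::net_forward(n2, x, training = TRUE)$prob, y)
  eps <- 1e-6
  for (nm in c("stem.W", "blk1.W1", "blk2.W2", "blk2.g1", "blk2.be2",
               "cwa.Wk", "head.W", "head.b")) {
    p <- net$params[[nm]]
    for (ii in sample(seq_along(p), min(3, length(p)))) {
      n2 <- net
      n2$params[[nm]][ii] <- p[ii] + eps
      lp <- loss_at(n2)
      n2$params[[nm]][ii] <- p[ii] - eps
      lm <- loss_at(n2)
      num <- (lp - lm) / (2 * eps)
      if (abs(num) < 1e-4) next      # null gradient (e.g. BN-absorbed shift)
      expect_lt(abs(num - gr[[nm]][ii]) / (abs(num) + abs(gr[[nm]][ii])),
                1e-4)
    }
  }
})

test_that("training reduces the loss on an easy separable task and is seeded", {
  set.seed(35)
  n <- 32; tt <- 64
  y <- cbind(a = rep(c(1, 0), n / 2), b = rep(c(0, 1), n / 2))
  x <- array(rnorm(n * tt * 2, sd = 0.1), c(n, tt, 2))
  bump <- sin(2 * pi * (1:tt) / 16)
  for (i in 1:n) {
    if (y[i, 1] == 1) x[i, , 1] <- x[i, , 1] + bump
    else x[i, , 2] <- x[i, , 2] + bump
  }
  cfg <- ecg_net_config(n_categories = 2, n_leads = 2, n_blocks = 2,
                        filters = c(4, 4), kernel_size = 5, batch_size = 8,
                        epochs = 5, seed = 21)
  net <- train_ecg_net(x, y, cfg)
  expect_lt(tail(net$history$loss, 1), net$history$loss[1])
  expect_equal(net$history$lr, 0.001 * 0.9^(0:4))
  net2 <- train_ecg_net(x, y, cfg)
  expect_identical(net$params, net2$params)
})

test_that("a single-category configuration trains and predicts one column", {
  set.seed(36)
  x <- array(rnorm(8 * 32 * 1), c(8, 32, 1))
  y <- matrix(rbinom(8, 1, 0.5), 8, 1)
  cfg <- ecg_net_config(n_categories = 1, n_leads = 1, n_blocks = 1,
                        filters = 4, kernel_size = 3, batch_size = 4,
                        epochs = 1, seed = 5)
  net <- train_ecg_net(x, y, cfg)
  expect_equal(dim(predict(net, x)), c(8, 1))
})
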