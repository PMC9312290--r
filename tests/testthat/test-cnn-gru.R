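test_that("convolution matches hand and brute-force oracles", {
  out <- conv_forward(matrix(1:5), array(c(1, 0, -1), c(3, 1, 1)), 0,
                      activation = "identity")
  expect_equal(as.vector(out), c(-2, -2, -2))

  expect_equal(
    as.vector(conv_forward(rep(0, 10), array(rnorm(3), c(3, 1, 1)), 0)),
    rep(0, 8)
  )

  set.seed(41)
  for (i in 1:20) {
    L <- sample(6:15, 1)
    k <- sample(2:5, 1)
    cin <- sample(1:3, 1)
    cout <- sample(1:3, 1)
    stride <- sample(1:2, 1)
    pad <- sample(c("valid", "same"), 1)
    act <- sample(c("relu", "identity"), 1)
    A <- matrix(rnorm(L * cin), L, cin)
    K <- array(rnorm(k * cin * cout), c(k, cin, cout))
    b <- rnorm(cout)
    expect_equal(conv_forward(A, K, b, stride, pad, act),
                 oracle_conv(A, K, b, stride, pad, act), tolerance = 1e-6)
  }
  expect_error(conv_forward(matrix(1:2), array(rnorm(5), c(5, 1, 1)), 0),
               "longer")
})

test_that("max pooling matches the windowed-max oracle", {
  expect_equal(as.vector(max_pool(c(1, 3, 2, 5))), c(3, 5))
  expect_equal(as.vector(max_pool(rep(2, 8))), rep(2, 4))
  set.seed(43)
  for (i in 1:20) {
    G <- matrix(rnorm(sample(4:12, 1) * 2), ncol = 2)
    expect_equal(max_pool(G), oracle_pool(G))
  }
})

test_that("the GRU cell honours its gate limits and scalar oracle", {
  q <- 4; p <- 3
  set.seed(47)
  w <- random_gru_weights(q, p)
  h0 <- rnorm(q); f0 <- rnorm(p)

  w_keep <- w
  w_keep$Wz[] <- 0; w_keep$Uz[] <- 0; w_keep$bz[] <- 100
  expect_equal(gru_cell(f0, h0, w_keep), h0)

  w_reset <- w
  w_reset$bz[] <- -100; w_reset$Wz[] <- 0; w_reset$Uz[] <- 0
  w_reset$br[] <- -100; w_reset$Wr[] <- 0; w_reset$Ur[] <- 0
  expect_equal(gru_cell(f0, h0, w_reset),
               as.vector(tanh(w_reset$Wc %*% f0 + w_reset$bc)))

  for (i in 1:30) {
    w2 <- random_gru_weights(q, p)
    f <- rnorm(p); h <- rnorm(q)
    expect_equal(gru_cell(f, h, w2), oracle_gru(f, h, w2),
                 tolerance = 1e-7)
    st <- .gru_step(f, h, w2)
    expect_true(all(st$z > 0 & st$z < 1))
    expect_true(all(st$r > 0 & st$r < 1))
    expect_true(all(abs(st$hc) < 1))
  }
  expect_error(gru_cell(rnorm(2), h0, w), "dimensions")
})

test_that("the forward pass is deterministic with probabilities in (0, 1)", {
  cfg <- network_config(n_labels = 3, input_channels = 10)
  params <- init_params(cfg, seed = 7)
  M0 <- matrix(0, 5, 10)
  expect_equal(nn_forward(M0, params, cfg), rep(0.5, 3))

  set.seed(53)
  M <- matrix(rnorm(50), 5, 10)
  expect_identical(nn_forward(M, params, cfg), nn_forward(M, params, cfg))
  expect_identical(init_params(cfg, seed = 7), params)

  for (i in 1:200) {
    Mi <- matrix(rnorm(30, sd = runif(1, 0.1, 5)), 3, 10)
    p <- nn_forward(Mi, params, cfg)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("the loss matches closed forms and a scalar oracle", {
  expect_lt(nn_loss(c(1, 0), c(1, 0)), 1e-10)
  expect_equal(nn_loss(1, 0.5), log(2))
  expect_true(is.finite(nn_loss(c(1, 0), c(0, 1)))) # clamped, not Inf

  set.seed(59)
  Y <- matrix(rbinom(40, 1, 0.5), 8, 5)
  P <- matrix(runif(40, 0.01, 0.99), 8, 5)
  oracle <- 0
  for (i in 1:8) {
    for (j in 1:5) {
      oracle <- oracle - (Y[i, j] * log(P[i, j]) +
                            (1 - Y[i, j]) * log(1 - P[i, j]))
    }
  }
  expect_equal(nn_loss(Y, P), oracle / 8, tolerance = 1e-9)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- network_config(n_labels = 2, input_channels = 8,
                        conv_blocks = list(list(kernel = 3, filters = 2,
                                                stride = 1)),
                        gru_hidden = 3, dense_sizes = c(4))
  params <- init_params(cfg, seed = 5)
  set.seed(61)
  M <- matrix(rnorm(32), 4, 8)
  y <- c(1, 0)
  fw <- .net_forward(M, params, cfg, keep = TRUE)
  gr <- .net_backward(fw, y, params, cfg)
  lossfn <- function(pp) nn_loss(y, .net_forward(M, pp, cfg)$prob)
  eps <- 1e-5

  check_block <- function(get, set, ganal) {
    v <- get(params)
    idx <- seq_len(min(8, length(v)))
    for (ii in idx) {
      vp <- v; vp[ii] <- vp[ii] + eps
      vm <- v; vm[ii] <- vm[ii] - eps
      fd <- (lossfn(set(params, vp)) - lossfn(set(params, vm))) / (2 * eps)
      expect_lt(abs(fd - ganal[ii]) / max(abs(fd), abs(ganal[ii]), 1e-8),
                1e-4)
    }
  }
  check_block(function(p) p$conv[[1]]$K,
              function(p, v) { p$conv[[1]]$K <- array(v, dim(p$conv[[1]]$K)); p },
              as.vector(gr$conv[[1]]$K))
  check_block(function(p) p$gru$Wz,
              function(p, v) { p$gru$Wz <- matrix(v, nrow(p$gru$Wz)); p },
              as.vector(gr$gru$Wz))
  check_block(function(p) p$gru$Uc,
              function(p, v) { p$gru$Uc <- matrix(v, nrow(p$gru$Uc)); p },
              as.vector(gr$gru$Uc))
  check_block(function(p) p$dense[[1]]$W,
              function(p, v) { p$dense[[1]]$W <- matrix(v, nrow(p$dense[[1]]$W)); p },
              as.vector(gr$dense[[1]]$W))
  check_block(function(p) p$dense[[2]]$b,
              function(p, v) { p$dense[[2]]$b <- v; p },
              gr$dense[[2]]$b)
})

test_that("training is deterministic, inert at zero learning rate, and learns", {
  set.seed(67)
  n <- 40
  mats <- list()
  Y <- matrix(0, n, 2)
  for (i in 1:n) {
    cls <- i %% 2
    mats[[i]] <- matrix(rnorm(5 * 8, mean = ifelse(cls, 1.2, -1.2),
                              sd = 0.5), 5, 8)
    Y[i, ] <- c(cls, 1 - cls)
  }
  cfg <- network_config(2, 8,
                        conv_blocks = list(list(kernel = 3, filters = 3,
                                                stride = 1)),
                        gru_hidden = 5, dense_sizes = c(5))

  tc0 <- train_config(learning_rate = 0, batch_size = 10, epochs = 3,
                      seed = 2)
  mod0 <- cnn_gru_train(mats, Y, cfg, tc0)
  expect_identical(mod0$params, init_params(cfg, seed = 2))
  expect_equal(diff(mod0$loss_trace), rep(0, 2), tolerance = 1e-12)

  tc <- train_config(learning_rate = 0.05, batch_size = 10, epochs = 40,
                     seed = 2)
  mod1 <- cnn_gru_train(mats, Y, cfg, tc)
  mod2 <- cnn_gru_train(mats, Y, cfg, tc)
  expect_identical(mod1$loss_trace, mod2$loss_trace)

  pred <- predict(mod1, mats)
  expect_gte(mean(pred == Y), 0.95)
  expect_lt(mod1$loss_trace[length(mod1$loss_trace)], mod1$loss_trace[1])
})

test_that("prediction thresholds follow the >= rule monotonically", {
  set.seed(71)
  cfg <- network_config(3, 6,
                        conv_blocks = list(list(kernel = 3, filters = 2,
                                                stride = 1)),
                        gru_hidden = 4, dense_sizes = c(4))
  params <- init_params(cfg, seed = 3)
  model <- structure(list(params = params, config = cfg,
                          loss_trace = 0, epochs_run = 0),
                     class = "cnn_gru_model")
  mats <- lapply(1:10, function(i) matrix(rnorm(24), 4, 6))
  P <- predict(model, mats, type = "prob")
  expect_equal(predict(model, mats, threshold = 0.5), (P >= 0.5) * 1L)
  expect_equal(predict(model, mats, threshold = 1 + 1e-9),
               matrix(0L, 10, 3), ignore_attr = TRUE)
  prev <- NULL
  for (th in c(0.9, 0.7, 0.5, 0.3, 0.1)) {
    cur <- predict(model, mats, threshold = th)
    if (!is.null(prev)) expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("model checkpoints round-trip through JSON", {
  cfg <- network_config(2, 6,
                        conv_blocks = list(list(kernel = 3, filters = 2,
                                                stride = 1)),
                        gru_hidden = 3, dense_sizes = c(4))
  params <- init_params(cfg, seed = 9)
  model <- structure(list(params = params, config = cfg,
                          loss_trace = c(1, 0.5), epochs_run = 2),
                     class = "cnn_gru_model")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  M <- matrix(rnorm(18), 3, 6)
  expect_equal(nn_forward(M, back$params, back$config),
               nn_forward(M, params, cfg), tolerance = 1e-12)
})
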