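# The backward passes are checked against central finite differences; this
# is the load-bearing correctness test for the whole training engine.

ns <- asNamespace("interpgaze")

test_that("conv1d backward matches finite differences (both paddings)", {
  set.seed(1)
  Cin <- 3; Cout <- 4; K <- 8; stride <- 4; pad <- 2; L <- 16; n <- 2
  W <- matrix(rnorm(Cout * Cin * K), Cout)
  b <- rnorm(Cout)
  x <- array(rnorm(Cin * L * n), c(Cin, L, n))
  eps <- 1e-6
  for (mode in c("zero", "reflect")) {
    loss <- function(W_, b_, x_)
      sum(sin(ns$conv1d_fwd(W_, b_, x_, stride, pad, mode)$y))
    f <- ns$conv1d_fwd(W, b, x, stride, pad, mode)
    bk <- ns$conv1d_bwd(W, f$cache, array(cos(f$y), dim(f$y)), need_dx = TRUE)
    for (probe in list(c(2, 5), c(1, 20), c(4, 1))) {
      W1 <- W; W1[probe[1], probe[2]] <- W1[probe[1], probe[2]] + eps
      W2 <- W; W2[probe[1], probe[2]] <- W2[probe[1], probe[2]] - eps
      fd <- (loss(W1, b, x) - loss(W2, b, x)) / (2 * eps)
      expect_equal(bk$dW[probe[1], probe[2]], fd, tolerance = 1e-5)
    }
    for (pos in list(c(1, 2, 1), c(2, 7, 2), c(3, 16, 1))) {
      x1 <- x; x1[pos[1], pos[2], pos[3]] <- x1[pos[1], pos[2], pos[3]] + eps
      x2 <- x; x2[pos[1], pos[2], pos[3]] <- x2[pos[1], pos[2], pos[3]] - eps
      fd <- (loss(W, b, x1) - loss(W, b, x2)) / (2 * eps)
      expect_equal(bk$dx[pos[1], pos[2], pos[3]], fd, tolerance = 1e-5)
    }
    b1 <- b; b1[3] <- b1[3] + eps
    b2 <- b; b2[3] <- b2[3] - eps
    fd <- (loss(W, b1, x) - loss(W, b2, x)) / (2 * eps)
    expect_equal(bk$db[3], fd, tolerance = 1e-5)
  }
})

test_that("tconv1d backward matches finite differences", {
  set.seed(2)
  Cin <- 4; Cout <- 3; K <- 8; stride <- 4; pad <- 2; L <- 4; n <- 2
  W <- matrix(rnorm(Cin * Cout * K), Cin)
  b <- rnorm(Cout)
  x <- array(rnorm(Cin * L * n), c(Cin, L, n))
  loss <- function(W_, b_, x_)
    sum(sin(ns$tconv1d_fwd(W_, b_, x_, stride, pad, Cout)$y))
  f <- ns$tconv1d_fwd(W, b, x, stride, pad, Cout)
  expect_equal(dim(f$y), c(Cout, L * stride, n))
  bk <- ns$tconv1d_bwd(W, f$cache, array(cos(f$y), dim(f$y)), need_dx = TRUE)
  eps <- 1e-6
  for (probe in list(c(1, 1), c(3, 10), c(4, 24))) {
    W1 <- W; W1[probe[1], probe[2]] <- W1[probe[1], probe[2]] + eps
    W2 <- W; W2[probe[1], probe[2]] <- W2[probe[1], probe[2]] - eps
    fd <- (loss(W1, b, x) - loss(W2, b, x)) / (2 * eps)
    expect_equal(bk$dW[probe[1], probe[2]], fd, tolerance = 1e-5)
  }
  x1 <- x; x1[2, 3, 1] <- x1[2, 3, 1] + eps
  x2 <- x; x2[2, 3, 1] <- x2[2, 3, 1] - eps
  fd <- (loss(W, b, x1) - loss(W, b, x2)) / (2 * eps)
  expect_equal(bk$dx[2, 3, 1], fd, tolerance = 1e-5)
})

test_that("batch norm forward/backward is exact in train mode", {
  set.seed(3)
  layer <- ns$bn_make(4)
  layer$gamma <- runif(4, 0.5, 2)
  layer$beta <- rnorm(4)
  x <- matrix(rnorm(4 * 30, 2, 3), 4)
  fw <- ns$bn_fwd(layer, x, train = TRUE)
  expect_lt(max(abs(rowMeans(fw$y) - layer$beta)), 1e-12)
  bk <- ns$bn_bwd(layer, fw$cache, cos(fw$y))
  loss <- function(x_) sum(sin(ns$bn_fwd(layer, x_, TRUE)$y))
  eps <- 1e-6
  for (pos in list(c(1, 5), c(4, 30))) {
    x1 <- x; x1[pos[1], pos[2]] <- x1[pos[1], pos[2]] + eps
    x2 <- x; x2[pos[1], pos[2]] <- x2[pos[1], pos[2]] - eps
    fd <- (loss(x1) - loss(x2)) / (2 * eps)
    expect_equal(bk$dx[pos[1], pos[2]], fd, tolerance = 1e-4)
  }
})

test_that("generator backward matches finite differences end to end", {
  arch <- tiny_arch()
  model <- init_model(arch, roster_size = 3, seed = 7)
  lat <- sample_latent(4, 3, seed = 9)
  X0 <- ns$latent_to_matrix(lat)
  loss <- function(m) sum(sin(ns$g_forward(m, X0, train = TRUE)$y))
  gf <- ns$g_forward(model, X0, train = TRUE)
  gg <- ns$g_backward(model, gf$cache, array(cos(gf$y), dim(gf$y)))
  eps <- 1e-5
  probes <- list(
    list(get = function(m) m$G$fc$W[3, 2],
         set = function(m, v) { m$G$fc$W[3, 2] <- v; m },
         grad = gg$fc$W[3, 2]),
    list(get = function(m) m$G$stages[[1]]$W[2, 9],
         set = function(m, v) { m$G$stages[[1]]$W[2, 9] <- v; m },
         grad = gg$stages[[1]]$W[2, 9]),
    list(get = function(m) m$G$stages[[2]]$bn$gamma[1],
         set = function(m, v) { m$G$stages[[2]]$bn$gamma[1] <- v; m },
         grad = gg$stages[[2]]$bn$gamma[1]),
    list(get = function(m) m$G$stages[[4]]$b[5],
         set = function(m, v) { m$G$stages[[4]]$b[5] <- v; m },
         grad = gg$stages[[4]]$b[5]))
  for (pr in probes) {
    v <- pr$get(model)
    fd <- (loss(pr$set(model, v + eps)) - loss(pr$set(model, v - eps))) /
      (2 * eps)
    expect_equal(pr$grad, fd, tolerance = 1e-3)
  }
})

test_that("discriminator backward matches finite differences", {
  arch <- tiny_arch()
  model <- init_model(arch, roster_size = 3, seed = 7)
  set.seed(5)
  # well-scaled input keeps activations away from LeakyReLU kinks
  X <- array(rnorm(9 * 512 * 3), c(9, 512, 3))
  loss <- function(m) {
    fw <- ns$d_forward(m, X, train = FALSE)
    sum(sin(fw$s)) + sum(cos(fw$c_bf)) + sum(sin(fw$c_p_logits)) +
      sum(cos(fw$c_t))
  }
  fw <- ns$d_forward(model, X, train = FALSE)
  dcode <- rbind(-sin(fw$c_bf), cos(fw$c_p_logits), -sin(fw$c_t))
  bk <- ns$d_backward(model, fw$cache, ds = cos(fw$s), dcode = dcode,
                      need_dx = TRUE)
  eps <- 1e-6
  # exact paths: biases, non-normalized output layers, dx
  v <- model$D$convs[[4]]$b[2]
  m1 <- model; m1$D$convs[[4]]$b[2] <- v + eps
  m2 <- model; m2$D$convs[[4]]$b[2] <- v - eps
  expect_equal(bk$grads$convs[[4]]$b[2], (loss(m1) - loss(m2)) / (2 * eps),
               tolerance = 1e-4)
  v <- model$D$head_real$W[1, 3]
  m1 <- model; m1$D$head_real$W[1, 3] <- v + eps
  m2 <- model; m2$D$head_real$W[1, 3] <- v - eps
  expect_equal(bk$grads$head_real$W[1, 3], (loss(m1) - loss(m2)) / (2 * eps),
               tolerance = 1e-4)
  v <- model$D$head_code$fc2$W[2, 3]
  m1 <- model; m1$D$head_code$fc2$W[2, 3] <- v + eps
  m2 <- model; m2$D$head_code$fc2$W[2, 3] <- v - eps
  expect_equal(bk$grads$head_code$fc2$W[2, 3],
               (loss(m1) - loss(m2)) / (2 * eps), tolerance = 1e-4)
  X1 <- X; X1[2, 100, 1] <- X1[2, 100, 1] + eps
  X2 <- X; X2[2, 100, 1] <- X2[2, 100, 1] - eps
  fd <- ({ Xs <- X1; fw1 <- ns$d_forward(model, Xs, FALSE)
           sum(sin(fw1$s)) + sum(cos(fw1$c_bf)) + sum(sin(fw1$c_p_logits)) +
             sum(cos(fw1$c_t)) } -
         { Xs <- X2; fw2 <- ns$d_forward(model, Xs, FALSE)
           sum(sin(fw2$s)) + sum(cos(fw2$c_bf)) + sum(sin(fw2$c_p_logits)) +
             sum(cos(fw2$c_t)) }) / (2 * eps)
  expect_equal(bk$dx[2, 100, 1], fd, tolerance = 1e-4)
  # spectrally normalized weights: frozen-sigma approximation, loose check
  v <- model$D$convs[[1]]$W[2, 5]
  m1 <- model; m1$D$convs[[1]]$W[2, 5] <- v + eps
  m2 <- model; m2$D$convs[[1]]$W[2, 5] <- v - eps
  fd <- (loss(m1) - loss(m2)) / (2 * eps)
  expect_equal(bk$grads$convs[[1]]$W[2, 5], fd, tolerance = 0.1)
})

test_that("adam_update descends a quadratic and tracks state", {
  p <- list(a = matrix(c(4, -2), 1), b = 3)
  st <- NULL
  for (i in 1:400) {
    g <- list(a = 2 * p$a, b = 2 * p$b)
    up <- ns$adam_update(p, g, st, lr = 0.05, beta1 = 0.5, beta2 = 0.9)
    p <- up$params; st <- up$state
  }
  expect_lt(max(abs(unlist(p))), 1e-2)
  expect_equal(st$a$t, 400)
})

test_that("spectral normalization bounds the largest singular value", {
  set.seed(8)
  W <- matrix(rnorm(20 * 30, 0, 1), 20)
  u <- rnorm(20); u <- u / sqrt(sum(u^2))
  # persist u across repeated steps as training does
  for (i in 1:50) {
    snr <- ns$sn_normalize(W, u)
    u <- snr$u
  }
  expect_lte(power_sigma(snr$W), 1.05)
  expect_gte(power_sigma(snr$W), 0.9)
})
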