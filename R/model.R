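# Generator / discriminator definition for the ss-InfoGAN.
#
# Generator: one fully connected layer to a (channels x 2) seed, then four
# transposed-convolution stages each upsampling x4 (2 -> 8 -> 32 -> 128 ->
# 512), ReLU activations and batch normalization everywhere except the linear
# output layer.  Discriminator: four convolution stages each downsampling x4
# with reflection padding and LeakyReLU(0.2), then a one-layer realness head
# (sigmoid) and a two-layer code head producing 5 continuous trait estimates,
# a categorical identity estimate on the simplex, and 1 continuous time
# estimate.  Spectral normalization on every discriminator layer except each
# head's terminal (output) layer.

#' Architecture configuration
#'
#' @param preset `"paper"` (full width: generator channels 256/128/64/32,
#'   discriminator 32/64/128/256, code-head hidden 128) or `"desk"` (quarter
#'   widths, for CPU-scale runs).
#' @param g_channels,d_channels,head_hidden optional overrides.
#' @return list of class `arch_config`.
#' @export
arch_config <- function(preset = c("desk", "paper"), g_channels = NULL,
                        d_channels = NULL, head_hidden = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper") {
    list(g_channels = c(256, 128, 64, 32), d_channels = c(32, 64, 128, 256),
         head_hidden = 128)
  } else {
    list(g_channels = c(64, 32, 16, 8), d_channels = c(8, 16, 32, 64),
         head_hidden = 32)
  }
  cfg$g_channels <- g_channels %||% cfg$g_channels
  cfg$d_channels <- d_channels %||% cfg$d_channels
  cfg$head_hidden <- head_hidden %||% cfg$head_hidden
  cfg$preset <- preset
  cfg$kernel <- 8L; cfg$stride <- 4L; cfg$seed_len <- 2L
  cfg$window <- 512L; cfg$n_channels <- 9L
  cfg$n_traits <- 5L; cfg$n_noise <- 10L
  class(cfg) <- "arch_config"
  cfg
}

latent_dim <- function(arch, roster_size) {
  arch$n_traits + roster_size + 1L + arch$n_noise
}

# Fan-in-scaled Gaussian init (He-style): keeps activation variance of order
# one through the stack, so the generator starts at a realistic output scale
# instead of spending early epochs growing its amplitude.
rand_mat <- function(nr, nc, fan_in = nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}
rand_u <- function(n) {
  u <- stats::rnorm(n)
  u / sqrt(sum(u^2))
}

#' Initialize generator and discriminator parameters
#'
#' Small-variance Gaussian weights, zero biases; deterministic given `seed`.
#' The constructor asserts the generator's shape contract (output exactly
#' `9 x 512` for any valid latent input).
#'
#' @param arch an [arch_config()].
#' @param roster_size number of identity codes (participants).
#' @param seed integer seed.
#' @return list of class `gan_model` with components `G`, `D`, `arch`,
#'   `roster_size`.
#' @export
init_model <- function(arch, roster_size = 14L, seed = 1L) {
  stop_if(arch$seed_len * arch$stride^4 != arch$window,
          "architecture cannot reach window length ", arch$window,
          " from seed length ", arch$seed_len, " with 4 x", arch$stride,
          " upsampling stages")
  K <- arch$kernel
  gch <- c(arch$g_channels, arch$n_channels)     # seed, s1, s2, s3, 9
  dch <- c(arch$n_channels, arch$d_channels)
  ld <- latent_dim(arch, roster_size)
  with_seed(seed, {
    G <- list(fc = list(W = rand_mat(gch[1] * arch$seed_len, ld),
                        b = rep(0, gch[1] * arch$seed_len)),
              bn0 = bn_make(gch[1]),
              stages = lapply(1:4, function(i) {
                # each transposed-conv output sample sums K/stride taps from
                # gch[i] channels
                st <- list(W = rand_mat(gch[i], gch[i + 1] * K,
                                        fan_in = gch[i] * K / arch$stride),
                           b = rep(0, gch[i + 1]))
                if (i < 4) st$bn <- bn_make(gch[i + 1])
                st
              }))
    flat_dim <- arch$d_channels[4] * arch$seed_len
    D <- list(convs = lapply(1:4, function(i) {
                list(W = rand_mat(dch[i + 1], dch[i] * K),
                     b = rep(0, dch[i + 1]), u = rand_u(dch[i + 1]))
              }),
              head_real = list(W = rand_mat(1, flat_dim),
                               b = 0),
              head_code = list(
                fc1 = list(W = rand_mat(arch$head_hidden, flat_dim),
                           b = rep(0, arch$head_hidden),
                           u = rand_u(arch$head_hidden)),
                fc2 = list(W = rand_mat(arch$n_traits + roster_size + 1,
                                        arch$head_hidden),
                           b = rep(0, arch$n_traits + roster_size + 1))))
    model <- structure(list(G = G, D = D, arch = arch,
                            roster_size = as.integer(roster_size)),
                       class = "gan_model")
    out <- generate(model, sample_latent(1L, roster_size), mode = "eval")
    stop_if(!identical(dim(out), c(9L, 512L, 1L)),
            "generator shape contract violated")
    model
  })
}

#' Sample a latent batch
#'
#' Trait codes from N(0, 1); identity codes one-hot with probability 1/R per
#' unit; time code and the 10 noise variables from U(-1, 1).  Uses the
#' current RNG state unless `seed` is given.
#'
#' @param n batch size (>= 0).
#' @param roster_size number of identity units.
#' @param seed optional integer seed.
#' @return list of class `latent_batch` with `c_bf` (5 x n), `c_p` (R x n
#'   one-hot), `c_t` (1 x n), `z` (10 x n).
#' @export
sample_latent <- function(n, roster_size = 14L, seed = NULL) {
  draw <- function() {
    c_p <- matrix(0, roster_size, n)
    if (n > 0) c_p[cbind(sample.int(roster_size, n, replace = TRUE),
                         seq_len(n))] <- 1
    structure(list(c_bf = matrix(stats::rnorm(5 * n), 5, n),
                   c_p = c_p,
                   c_t = matrix(stats::runif(n, -1, 1), 1, n),
                   z = matrix(stats::runif(10 * n, -1, 1), 10, n)),
              class = "latent_batch")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

latent_to_matrix <- function(latent) {
  rbind(latent$c_bf, latent$c_p, latent$c_t, latent$z)
}

# ---- generator forward/backward --------------------------------------------

g_forward <- function(model, X0, train) {
  G <- model$G
  arch <- model$arch
  n <- ncol(X0)
  cache <- list(X0 = X0)
  h <- G$fc$W %*% X0 + G$fc$b
  Cs <- nrow(G$fc$W) / arch$seed_len
  dim(h) <- c(Cs, arch$seed_len * n)
  b0 <- bn_fwd(G$bn0, h, train)
  model$G$bn0 <- b0$layer
  cache$bn0 <- b0$cache
  r0 <- relu_fwd(b0$y)
  cache$mask0 <- r0$mask
  h <- r0$y
  dim(h) <- c(Cs, arch$seed_len, n)
  for (i in 1:4) {
    st <- G$stages[[i]]
    Cout <- length(st$b)
    tc <- tconv1d_fwd(st$W, st$b, h, arch$stride, (arch$kernel - arch$stride) / 2,
                      Cout)
    cache[[paste0("tc", i)]] <- tc$cache
    h <- tc$y
    if (i < 4) {
      d <- dim(h)
      dim(h) <- c(d[1], d[2] * d[3])
      bi <- bn_fwd(st$bn, h, train)
      model$G$stages[[i]]$bn <- bi$layer
      cache[[paste0("bn", i)]] <- bi$cache
      ri <- relu_fwd(bi$y)
      cache[[paste0("mask", i)]] <- ri$mask
      h <- ri$y
      dim(h) <- d
    }
  }
  list(y = h, cache = cache, model = model)
}

g_backward <- function(model, cache, dy) {
  G <- model$G
  arch <- model$arch
  grads <- list(stages = vector("list", 4))
  h <- dy
  for (i in 4:1) {
    st <- G$stages[[i]]
    if (i < 4) {
      d <- dim(h)
      dim(h) <- c(d[1], d[2] * d[3])
      h <- h * cache[[paste0("mask", i)]]
      bb <- bn_bwd(st$bn, cache[[paste0("bn", i)]], h)
      grads$stages[[i]]$bn <- bb$grads
      h <- bb$dx
      dim(h) <- d
    }
    tb <- tconv1d_bwd(st$W, cache[[paste0("tc", i)]], h, need_dx = TRUE)
    grads$stages[[i]]$W <- tb$dW
    grads$stages[[i]]$b <- tb$db
    h <- tb$dx
  }
  d <- dim(h)
  dim(h) <- c(d[1], d[2] * d[3])
  h <- h * cache$mask0
  bb <- bn_bwd(G$bn0, cache$bn0, h)
  grads$bn0 <- bb$grads
  h <- bb$dx
  dim(h) <- c(d[1] * d[2], d[3])
  grads$fc <- list(W = h %*% t(cache$X0), b = rowSums(h))
  grads
}

# ---- discriminator forward/backward ----------------------------------------

d_forward <- function(model, X, train) {
  D <- model$D
  arch <- model$arch
  stop_if(!all(is.finite(X)), "non-finite values in discriminator input")
  n <- dim(X)[3]
  pad <- (arch$kernel - arch$stride) / 2
  cache <- list(sigmas = numeric(4))
  h <- X
  for (i in 1:4) {
    cv <- D$convs[[i]]
    sn <- sn_normalize(cv$W, cv$u)
    if (train) model$D$convs[[i]]$u <- sn$u
    cache[[paste0("Wn", i)]] <- sn$W
    cache$sigmas[i] <- sn$sigma
    cf <- conv1d_fwd(sn$W, cv$b, h, arch$stride, pad, "reflect")
    cache[[paste0("conv", i)]] <- cf$cache
    lr <- lrelu_fwd(cf$y)
    cache[[paste0("mask", i)]] <- lr$mask
    h <- lr$y
  }
  d <- dim(h)
  dim(h) <- c(d[1] * d[2], n)
  cache$flat <- h
  cache$conv_out_dim <- d
  s <- D$head_real$W %*% h + D$head_real$b
  snc <- sn_normalize(D$head_code$fc1$W, D$head_code$fc1$u)
  if (train) model$D$head_code$fc1$u <- snc$u
  cache$Wn_fc1 <- snc$W
  cache$sigma_fc1 <- snc$sigma
  h1p <- snc$W %*% h + D$head_code$fc1$b
  lr1 <- lrelu_fwd(h1p)
  cache$mask_fc1 <- lr1$mask
  cache$h1 <- lr1$y
  out <- D$head_code$fc2$W %*% lr1$y + D$head_code$fc2$b
  R <- model$roster_size
  if (R > 0 && nrow(out) == 5 + R + 1) {
    list(s = s, p = sigmoid(s),
         c_bf = out[1:5, , drop = FALSE],
         c_p_logits = out[5 + (1:R), , drop = FALSE],
         c_p = softmax_cols(out[5 + (1:R), , drop = FALSE]),
         c_t = out[5 + R + 1, , drop = FALSE],
         cache = cache, model = model)
  } else {
    # regression-only head (auxiliary estimator): all rows continuous
    list(s = s, p = sigmoid(s), c_bf = out,
         c_p_logits = NULL, c_p = NULL, c_t = NULL,
         cache = cache, model = model)
  }
}

# ds: grad wrt realness pre-sigmoid (1 x n) or NULL.
# dcode: grad wrt the raw code outputs ((5+R+1) x n) or NULL.
d_backward <- function(model, cache, ds = NULL, dcode = NULL,
                       need_dx = FALSE) {
  D <- model$D
  grads <- list()
  dflat <- matrix(0, nrow(cache$flat), ncol(cache$flat))
  if (!is.null(ds)) {
    grads$head_real <- list(W = ds %*% t(cache$flat), b = sum(ds))
    dflat <- dflat + crossprod(D$head_real$W, ds)
  }
  if (!is.null(dcode)) {
    dW2 <- dcode %*% t(cache$h1)
    dh1 <- crossprod(D$head_code$fc2$W, dcode) * cache$mask_fc1
    grads$head_code <- list(
      fc2 = list(W = dW2, b = rowSums(dcode)),
      fc1 = list(W = (dh1 %*% t(cache$flat)) / cache$sigma_fc1,
                 b = rowSums(dh1)))
    dflat <- dflat + crossprod(cache$Wn_fc1, dh1)
  }
  h <- dflat
  dim(h) <- cache$conv_out_dim
  grads$convs <- vector("list", 4)
  for (i in 4:1) {
    h <- h * cache[[paste0("mask", i)]]
    cb <- conv1d_bwd(cache[[paste0("Wn", i)]], cache[[paste0("conv", i)]], h,
                     need_dx = (i > 1 || need_dx))
    grads$convs[[i]] <- list(W = cb$dW / cache$sigmas[i], b = cb$db)
    h <- cb$dx
  }
  list(grads = grads, dx = h)
}

# ---- public wrappers --------------------------------------------------------

#' Generate sensor windows from latent codes
#'
#' @param model a `gan_model`.
#' @param latent a `latent_batch` (see [sample_latent()]).
#' @param mode `"eval"` (running batch-norm statistics; deterministic given
#'   parameters and latent) or `"train"` (batch statistics).
#' @return array `9 x 512 x n` of generated windows.
#' @export
generate <- function(model, latent, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  X0 <- latent_to_matrix(latent)
  stop_if(nrow(X0) != latent_dim(model$arch, model$roster_size),
          "latent dimension mismatch: got ", nrow(X0), ", expected ",
          latent_dim(model$arch, model$roster_size))
  if (ncol(X0) == 0)
    return(array(numeric(0), c(9, model$arch$window, 0)))
  g_forward(model, X0, train = (mode == "train"))$y
}

#' Run the discriminator on sensor windows
#'
#' @param model a `gan_model`.
#' @param windows array `9 x 512 x n` (a single `9 x 512` matrix is
#'   promoted).
#' @param mode `"eval"` or `"train"` (affects spectral-norm power-iteration
#'   persistence only; exported use should stay `"eval"`).
#' @return list of class `discriminator_output`: `realness` (n probabilities
#'   strictly inside (0,1)), `c_bf_hat` (n x 5), `c_p_hat` (n x R rows on the
#'   simplex), `c_t_hat` (length n).
#' @export
discriminate <- function(model, windows, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (length(dim(windows)) == 2) windows <- array(windows, c(dim(windows), 1))
  stop_if(dim(windows)[1] != 9 || dim(windows)[2] != model$arch$window,
          "windows must be 9 x ", model$arch$window, " x n")
  fw <- d_forward(model, windows, train = (mode == "train"))
  structure(list(realness = as.numeric(fw$p),
                 c_bf_hat = t(fw$c_bf),
                 c_p_hat = t(fw$c_p),
                 c_t_hat = as.numeric(fw$c_t)),
            class = "discriminator_output")
}

#' Save / load a model (bit-exact round trip)
#' @param model a `gan_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
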