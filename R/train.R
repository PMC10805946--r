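# Adversarial + code-estimation training.
#
# Each epoch optimizes the discriminator first and then the generator.
# Discriminator step: realness pushed to 1 on real and 0 on generated
# windows; code estimates fitted to the real labels (trait labels of masked
# participants excluded); a consistency penalty ties realness outputs on
# original and "translated" copies (cut at a random point, tail segment
# time-reversed).  Generator step: realness on generated windows pushed to 1
# and the input latent codes recovered through the code head, updating the
# generator plus the code head's two affine stages only.

#' Training configuration
#'
#' Defaults follow the full-scale regime: Adam with step size 0.005 for the
#' discriminator and 0.001 for the generator, momentum coefficients 0.5/0.9,
#' 200 epochs, mini-batches of 256, translation applied to 50% of samples.
#'
#' @param epochs number of epochs.
#' @param batch_size mini-batch size.
#' @param lr_d,lr_g Adam step sizes for discriminator and generator.
#' @param beta1,beta2 Adam momentum coefficients (shared).
#' @param translation_fraction fraction of samples translated for the
#'   consistency term.
#' @param consistency_weight weight of the consistency term.
#' @param supervision_mask participant ids whose trait labels are hidden
#'   during training (their windows, identity and time labels are retained).
#' @param seed integer seed controlling every stochastic element of a run.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 256L,
                         lr_d = 0.005, lr_g = 0.001,
                         beta1 = 0.5, beta2 = 0.9,
                         translation_fraction = 0.5,
                         consistency_weight = 1,
                         supervision_mask = character(0),
                         seed = 1L) {
  stop_if(translation_fraction < 0 || translation_fraction > 1,
          "translation_fraction must be in [0, 1]")
  stop_if(lr_d <= 0 || lr_g <= 0, "step sizes must be > 0")
  stop_if(epochs < 0 || batch_size < 1, "invalid epochs/batch_size")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_d = lr_d, lr_g = lr_g, beta1 = beta1, beta2 = beta2,
                 translation_fraction = translation_fraction,
                 consistency_weight = consistency_weight,
                 supervision_mask = supervision_mask,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Translate a batch of windows
#'
#' For each selected sample a cut point t is drawn uniformly from 1..L-1 and
#' the segment after t is reversed in time on all channels jointly;
#' unselected samples pass through.  Per-sample value multisets are
#' preserved, and translating again with the same cut restores the original.
#'
#' @param x array `9 x L x n`.
#' @param fraction fraction of samples to translate.
#' @param cuts optional integer vector of cut points (NA = not translated);
#'   when given, `fraction` is ignored.
#' @param seed optional integer seed (defaults to the current RNG state).
#' @return list with `x` (translated array), `selected` (logical), `cut`
#'   (integer, NA where unselected).
#' @export
translate_batch <- function(x, fraction = 0.5, cuts = NULL, seed = NULL) {
  run <- function() {
    L <- dim(x)[2]; n <- dim(x)[3]
    if (is.null(cuts)) {
      selected <- stats::runif(n) < fraction
      cut <- ifelse(selected, sample.int(L - 1, n, replace = TRUE), NA_integer_)
    } else {
      stopifnot(length(cuts) == n)
      cut <- cuts
      selected <- !is.na(cuts)
    }
    for (i in which(selected)) {
      t <- cut[i]
      x[, (t + 1):L, i] <- x[, L:(t + 1), i]
    }
    list(x = x, selected = selected, cut = cut)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Loss arithmetic for one discriminator output
#'
#' Pure bookkeeping used both for the training log and as the reference
#' definition of the loss terms: binary cross-entropy on the realness
#' probability, unit-variance Gaussian negative log-likelihood (constant
#' dropped, i.e. half squared error) on the continuous codes, cross-entropy
#' on the categorical code, and the mean squared difference of realness
#' between original and translated copies.
#'
#' @param d_out a `discriminator_output` (or any list with `realness`,
#'   `c_bf_hat`, `c_p_hat`, `c_t_hat`).
#' @param targets list with `real` (logical scalar: BCE target), and
#'   optionally `c_bf` (n x 5), `c_p` (n x R one-hot), `c_t` (length n).
#' @param supervision logical vector, TRUE where trait labels are observed;
#'   default all observed.  Trait terms average over supervised samples only.
#' @param translated_realness optional realness vector of the translated copy.
#' @return list of numeric terms: `realness`, `bf`, `person`, `time`,
#'   `consistency`, `total`.
#' @export
compute_losses <- function(d_out, targets, supervision = NULL,
                           translated_realness = NULL) {
  p <- pmin(pmax(d_out$realness, 1e-12), 1 - 1e-12)
  y <- as.numeric(isTRUE(targets$real))
  out <- list(realness = -mean(y * log(p) + (1 - y) * log(1 - p)))
  out$bf <- if (!is.null(targets$c_bf)) {
    w <- supervision %||% rep(TRUE, length(p))
    if (!any(w)) 0
    else mean(0.5 * rowSums((d_out$c_bf_hat[w, , drop = FALSE] -
                               targets$c_bf[w, , drop = FALSE])^2))
  } else NA_real_
  out$person <- if (!is.null(targets$c_p)) {
    pr <- pmax(rowSums(d_out$c_p_hat * targets$c_p), 1e-12)
    -mean(log(pr))
  } else NA_real_
  out$time <- if (!is.null(targets$c_t))
    mean(0.5 * (d_out$c_t_hat - targets$c_t)^2) else NA_real_
  out$consistency <- if (!is.null(translated_realness))
    mean((d_out$realness - translated_realness)^2) else NA_real_
  out$total <- sum(unlist(out), na.rm = TRUE)
  out
}

# gradient of BCE wrt pre-sigmoid score, target y in {0,1}; mean over n
bce_grad <- function(p, y) (p - y) / length(p)
bce_loss <- function(s, y) mean(softplus(s) - y * s)

#' Fit the ss-InfoGAN on a single-task windowed dataset
#'
#' @param dataset a `windowed_dataset` restricted to one task (see
#'   [dataset_subset()]).
#' @param params initial `gan_model` from [init_model()]; its roster size
#'   must equal the dataset roster.
#' @param config a [train_config()].
#' @return list with `model` (trained `gan_model`) and `log` (data.frame with
#'   one row per epoch: realness probabilities on real and generated data,
#'   discriminator code losses per label family, generator code-recovery
#'   losses per code family, consistency term).
#' @export
fit <- function(dataset, params, config) {
  stop_if(!inherits(dataset, "windowed_dataset"), "dataset must be a windowed_dataset")
  N <- dim(dataset$windows)[3]
  stop_if(N == 0, "empty dataset")
  stop_if(length(dataset$tasks) != 1,
          "fit consumes a single-task dataset; got tasks: ",
          paste(dataset$tasks, collapse = ", "),
          " (use dataset_subset())")
  model <- params
  R <- model$roster_size
  stop_if(R != length(dataset$roster), "model roster size != dataset roster")
  log_rows <- list()
  if (config$epochs == 0)
    return(list(model = model, log = empty_train_log()))

  tw <- t(dataset$c_bf)                      # 5 x N
  tp <- t(dataset$c_p)                       # R x N
  tt <- matrix(dataset$c_t, 1)               # 1 x N
  sup <- !(dataset$meta$participant_id %in% config$supervision_mask)
  lam <- config$consistency_weight

  st_d <- NULL; st_g <- NULL; st_q <- NULL
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    starts <- seq(1, N, by = config$batch_size)
    acc <- list()
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + config$batch_size - 1, N)]
      n <- length(idx)
      Xr <- dataset$windows[, , idx, drop = FALSE]

      ## ---- discriminator step ----
      lat <- sample_latent(n, R)
      gf <- g_forward(model, latent_to_matrix(lat), train = TRUE)
      model <- gf$model
      Xf <- gf$y
      tr <- translate_batch(Xr, config$translation_fraction)
      tf <- translate_batch(Xf, config$translation_fraction)
      # one batched pass over [real, fake, translated real, translated fake]
      Xcat <- c(Xr, Xf, tr$x, tf$x)
      dim(Xcat) <- c(9, dim(Xr)[2], 4 * n)
      fa <- d_forward(model, Xcat, train = TRUE)
      model <- fa$model
      i_r <- seq_len(n); i_f <- n + i_r; i_rt <- 2 * n + i_r
      i_ft <- 3 * n + i_r
      p_all <- as.numeric(fa$p)
      p_r <- p_all[i_r]; p_f <- p_all[i_f]
      p_rt <- p_all[i_rt]; p_ft <- p_all[i_ft]

      ds_r <- matrix(bce_grad(p_r, 1), 1)
      ds_f <- matrix(bce_grad(p_f, 0), 1)
      # consistency: d/dp chained through sigmoid (dp/ds = p(1-p))
      ds_r <- ds_r + matrix(lam * 2 * (p_r - p_rt) / n * p_r * (1 - p_r), 1)
      ds_rt <- matrix(-lam * 2 * (p_r - p_rt) / n * p_rt * (1 - p_rt), 1)
      ds_f <- ds_f + matrix(lam * 2 * (p_f - p_ft) / n * p_f * (1 - p_f), 1)
      ds_ft <- matrix(-lam * 2 * (p_f - p_ft) / n * p_ft * (1 - p_ft), 1)

      w <- sup[idx]
      nw <- max(1L, sum(w))
      d_bf <- (fa$c_bf[, i_r, drop = FALSE] - tw[, idx, drop = FALSE])
      d_bf[, !w] <- 0
      d_bf <- d_bf / nw
      d_pl <- (fa$c_p[, i_r, drop = FALSE] - tp[, idx, drop = FALSE]) / n
      d_t <- (fa$c_t[, i_r, drop = FALSE] - tt[, idx, drop = FALSE]) / n
      dcode_all <- matrix(0, 5 + R + 1, 4 * n)
      dcode_all[, i_r] <- rbind(d_bf, d_pl, d_t)

      ba <- d_backward(model, fa$cache,
                       ds = cbind(ds_r, ds_f, ds_rt, ds_ft),
                       dcode = dcode_all)
      up <- adam_update(model$D, ba$grads, st_d, config$lr_d, config$beta1,
                        config$beta2)
      model$D <- up$params; st_d <- up$state

      ## ---- generator step ----
      lat2 <- sample_latent(n, R)
      gf2 <- g_forward(model, latent_to_matrix(lat2), train = TRUE)
      model <- gf2$model
      df2 <- d_forward(model, gf2$y, train = TRUE); model <- df2$model
      p_g <- as.numeric(df2$p)
      ds_g <- matrix(bce_grad(p_g, 1), 1)
      g_bf <- (df2$c_bf - lat2$c_bf) / n
      g_pl <- (df2$c_p - lat2$c_p) / n
      g_t <- (df2$c_t - lat2$c_t) / n
      dcode_g <- rbind(g_bf, g_pl, g_t)
      db <- d_backward(model, df2$cache, ds = ds_g, dcode = dcode_g,
                       need_dx = TRUE)
      gg <- g_backward(model, gf2$cache, db$dx)
      upg <- adam_update(model$G, gg, st_g, config$lr_g, config$beta1, config$beta2)
      model$G <- upg$params; st_g <- upg$state
      upq <- adam_update(model$D$head_code, db$grads$head_code, st_q,
                         config$lr_g, config$beta1, config$beta2)
      model$D$head_code <- upq$params; st_q <- upq$state

      ## ---- diagnostics ----
      lr_real <- compute_losses(
        list(realness = p_r, c_bf_hat = t(fa$c_bf[, i_r, drop = FALSE]),
             c_p_hat = t(fa$c_p[, i_r, drop = FALSE]),
             c_t_hat = as.numeric(fa$c_t[, i_r])),
        targets = list(real = TRUE, c_bf = dataset$c_bf[idx, , drop = FALSE],
                       c_p = dataset$c_p[idx, , drop = FALSE],
                       c_t = dataset$c_t[idx]),
        supervision = w, translated_realness = p_rt)
      lr_gen <- compute_losses(
        list(realness = p_g, c_bf_hat = t(df2$c_bf), c_p_hat = t(df2$c_p),
             c_t_hat = as.numeric(df2$c_t)),
        targets = list(real = TRUE, c_bf = t(lat2$c_bf), c_p = t(lat2$c_p),
                       c_t = as.numeric(lat2$c_t)))
      acc[[length(acc) + 1]] <- c(
        p_real_real = mean(p_r), p_real_fake = mean(p_f),
        d_bce_real = lr_real$realness,
        d_bce_fake = bce_loss(fa$s[, i_f, drop = FALSE], 0),
        d_loss_bf = lr_real$bf, d_loss_person = lr_real$person,
        d_loss_time = lr_real$time,
        consistency = lr_real$consistency + mean((p_f - p_ft)^2),
        g_adv = lr_gen$realness, g_rec_bf = lr_gen$bf,
        g_rec_person = lr_gen$person, g_rec_time = lr_gen$time)
    }
    m <- colMeans(do.call(rbind, acc))
    log_rows[[ep]] <- data.frame(epoch = ep, t(m))
  }
  list(model = model, log = do.call(rbind, log_rows))
}

empty_train_log <- function() {
  data.frame(epoch = integer(0), p_real_real = numeric(0),
             p_real_fake = numeric(0), d_bce_real = numeric(0),
             d_bce_fake = numeric(0), d_loss_bf = numeric(0),
             d_loss_person = numeric(0), d_loss_time = numeric(0),
             consistency = numeric(0), g_adv = numeric(0),
             g_rec_bf = numeric(0), g_rec_person = numeric(0),
             g_rec_time = numeric(0))
}
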