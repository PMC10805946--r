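# The three disentanglement tests.
#
# Real data test: leave-one-out cross-validation over participants — train
# the whole model with one participant's trait labels masked, estimate that
# participant's traits from their real windows, pool (actual, estimated)
# pairs over folds and correlate per trait.  Generated data test: generate
# windows per identity with random trait codes and correlate the generating
# trait code with the code head's estimate within each identity.  Real and
# generated data test: train an independent estimator (same architecture as
# the discriminator, trait-regression output only) on real windows and real
# trait labels, then apply it to generated windows.

#' Pearson correlation with a two-sided significance test
#'
#' Standard product-moment r with p from the t transform on n - 2 degrees of
#' freedom.  A constant input yields an explicit undefined flag, never a
#' silent zero.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`, `undefined`.
#' @export
pearson_with_test <- function(x, y) {
  stop_if(length(x) != length(y), "x and y must have equal length")
  n <- length(x)
  stop_if(n < 3, "need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n, undefined = FALSE)
}

#' Real data test (leave-one-out cross-validation)
#'
#' One fold per participant: the full model is trained with that
#' participant's trait labels masked (sensor windows, identity and time
#' labels retained), the held-out participant's real windows are passed
#' through the discriminator, and (actual, estimated) trait pairs are
#' collected.  After all folds, per-trait pooled window-level correlations
#' with significance are reported, plus per-individual mean estimates.
#'
#' @param dataset single-task `windowed_dataset` (>= 3 participants).
#' @param arch an [arch_config()].
#' @param config a [train_config()]; its `supervision_mask` is overridden per
#'   fold and its `seed` seeds the fold-specific model and run seeds.
#' @return list of class `eval_report` with `test`, `task`, `per_trait`
#'   (data.frame trait/r/p/n), `scatter` (window-level pairs with
#'   participant tags), `per_individual` (mean actual/estimated per
#'   participant for openness), `epoch`.
#' @export
real_data_test <- function(dataset, arch, config) {
  roster <- dataset$roster
  present <- intersect(roster, unique(dataset$meta$participant_id))
  stop_if(length(present) < 3, "need at least 3 participants")
  stop_if(length(dataset$tasks) != 1, "dataset must be single-task")
  pairs <- list()
  for (fold in seq_along(present)) {
    pid <- present[fold]
    cfg <- config
    cfg$supervision_mask <- pid
    cfg$seed <- derive_seed(config$seed, fold)
    model0 <- init_model(arch, roster_size = length(roster),
                         seed = derive_seed(config$seed, 1000 + fold))
    res <- fit(dataset, model0, cfg)
    held <- which(dataset$meta$participant_id == pid)
    est <- discriminate(res$model, dataset$windows[, , held, drop = FALSE])
    pairs[[fold]] <- data.frame(participant_id = pid,
                                actual = dataset$c_bf[held, , drop = FALSE],
                                est = est$c_bf_hat)
  }
  sc <- do.call(rbind, pairs)
  per_trait <- do.call(rbind, lapply(seq_along(TRAITS), function(j) {
    pt <- pearson_with_test(sc[[paste0("actual.", TRAITS[j])]], sc[, 5 + j + 1])
    data.frame(trait = TRAITS[j], r = pt$r, p = pt$p, n = pt$n,
               undefined = pt$undefined)
  }))
  agg <- stats::aggregate(cbind(actual.openness, est.1) ~ participant_id,
                          data = sc, FUN = mean)
  names(agg) <- c("participant_id", "actual_openness", "estimated_openness")
  structure(list(test = "real_data_test", task = dataset$tasks,
                 per_trait = per_trait, scatter = sc, per_individual = agg,
                 epoch = config$epochs),
            class = "eval_report")
}

#' Permute trait labels across participants (null-destruction control)
#'
#' Reassigns each participant's five trait scores to another participant
#' (a derangement of the roster), leaving windows and all other labels
#' untouched.  Destroys any trait-to-signal relationship while preserving
#' marginals.
#'
#' @param dataset a `windowed_dataset`.
#' @param seed integer seed.
#' @return the dataset with permuted `c_bf`.
#' @export
permute_trait_labels <- function(dataset, seed = 1L) {
  with_seed(seed, {
    roster <- dataset$roster
    repeat {
      perm <- sample(seq_along(roster))
      if (!any(perm == seq_along(roster))) break
    }
    old <- dataset$c_bf
    for (i in seq_along(roster)) {
      src <- which(dataset$meta$participant_id == roster[i])
      dst <- which(dataset$meta$participant_id == roster[perm[i]])
      if (length(src) && length(dst))
        dataset$c_bf[src, ] <- matrix(old[dst[1], ], length(src), 5,
                                      byrow = TRUE)
    }
    dataset
  })
}

#' Generated data test
#'
#' For each identity code, `n_cases` windows are generated with random trait
#' codes (time and noise codes sampled as in training) and passed through
#' the discriminator; the within-individual correlation between the
#' generating openness code and its estimate is computed per identity.  No
#' p-values are reported (sample size is arbitrary).
#'
#' @param model trained `gan_model`.
#' @param n_cases generated cases per identity.
#' @param seed integer seed.
#' @return `eval_report` with `per_individual` (identity, r, undefined),
#'   `mean_r`, `sd_r`, `n_total`.
#' @export
generated_data_test <- function(model, n_cases = 100L, seed = 1L) {
  R <- model$roster_size
  rows <- list(); scatter <- list()
  for (j in seq_len(R)) {
    lat <- sample_latent(n_cases, R, seed = derive_seed(seed, j))
    lat$c_p[] <- 0
    lat$c_p[j, ] <- 1
    est <- discriminate(model, generate(model, lat))
    x <- lat$c_bf[1, ]
    y <- est$c_bf_hat[, 1]
    pt <- if (stats::sd(y) == 0)
      list(r = NA_real_, undefined = TRUE) else
        list(r = stats::cor(x, y), undefined = FALSE)
    rows[[j]] <- data.frame(identity = j, r = pt$r, undefined = pt$undefined)
    scatter[[j]] <- data.frame(identity = j, actual = x, estimated = y)
  }
  per <- do.call(rbind, rows)
  structure(list(test = "generated_data_test",
                 per_individual = per,
                 mean_r = mean(per$r[!per$undefined]),
                 sd_r = stats::sd(per$r[!per$undefined]),
                 n_total = n_cases * R,
                 scatter = do.call(rbind, scatter)),
            class = "eval_report")
}

# Supervised trait-regression estimator with the discriminator architecture
# (conv stack + two-layer head, single linear output).  Used by the real and
# generated data test; shares no parameter objects with the main model.
init_estimator <- function(arch, seed = 1L) {
  K <- arch$kernel
  dch <- c(arch$n_channels, arch$d_channels)
  with_seed(seed, {
    list(convs = lapply(1:4, function(i) {
           list(W = rand_mat(dch[i + 1], dch[i] * K),
                b = rep(0, dch[i + 1]), u = rand_u(dch[i + 1]))
         }),
         head_code = list(
           fc1 = list(W = rand_mat(arch$head_hidden,
                                   arch$d_channels[4] * arch$seed_len),
                      b = rep(0, arch$head_hidden),
                      u = rand_u(arch$head_hidden)),
           fc2 = list(W = rand_mat(1, arch$head_hidden), b = 0)),
         arch = arch)
  })
}

# Forward/backward for the estimator: reuse the discriminator machinery by
# wrapping it in a one-output pseudo-model.
estimator_wrap <- function(est) {
  structure(list(G = NULL,
                 D = list(convs = est$convs,
                          head_real = list(W = matrix(0, 1,
                                             est$arch$d_channels[4] * est$arch$seed_len),
                                           b = 0),
                          head_code = est$head_code),
                 arch = est$arch, roster_size = 0L),
            class = "gan_model")
}

estimator_predict <- function(est, windows) {
  m <- estimator_wrap(est)
  fw <- d_forward(m, windows, train = FALSE)
  as.numeric(fw$c_bf[1, ])  # single output row
}

# Train the estimator on windows (9 x 512 x N) against scalar targets with
# half-squared-error loss and the discriminator optimizer settings.
estimator_fit <- function(est, windows, targets, config) {
  m <- estimator_wrap(est)
  N <- dim(windows)[3]
  st <- NULL
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    for (s0 in seq(1, N, by = config$batch_size)) {
      idx <- ord[s0:min(s0 + config$batch_size - 1, N)]
      n <- length(idx)
      fw <- d_forward(m, windows[, , idx, drop = FALSE], train = TRUE)
      m <- fw$model
      dcode <- (fw$c_bf[1, , drop = FALSE] -
                  matrix(targets[idx], 1)) / n
      bk <- d_backward(m, fw$cache, dcode = dcode)
      bk$grads$head_real <- NULL
      up <- adam_update(m$D, bk$grads, st, config$lr_d, config$beta1,
                        config$beta2)
      m$D <- up$params; st <- up$state
    }
  }
  list(convs = m$D$convs, head_code = m$D$head_code, arch = est$arch)
}

#' Real and generated data test
#'
#' Trains a fresh estimator with the discriminator architecture (trait
#' regression head only) on the real windows and real openness labels, then
#' applies it to windows generated per identity with random openness codes.
#' Within-individual correlations between the generating code and the
#' independent estimate are reported.
#'
#' @param dataset single-task `windowed_dataset` (the real data).
#' @param model trained `gan_model` (the generator source).
#' @param arch the [arch_config()] used for the auxiliary estimator.
#' @param config a [train_config()] (optimizer settings and epochs for the
#'   auxiliary estimator).
#' @param n_cases generated cases per identity.
#' @param seed integer seed for the generation sweep.
#' @return `eval_report` with `per_individual`, `mean_r`, `sd_r`, and the
#'   trained `estimator`.
#' @export
real_and_generated_test <- function(dataset, model, arch, config,
                                    n_cases = 100L, seed = 1L) {
  est0 <- init_estimator(arch, seed = derive_seed(config$seed, 77))
  est <- estimator_fit(est0, dataset$windows, dataset$c_bf[, "openness"],
                       config)
  R <- model$roster_size
  rows <- list()
  for (j in seq_len(R)) {
    lat <- sample_latent(n_cases, R, seed = derive_seed(seed, 500 + j))
    lat$c_p[] <- 0
    lat$c_p[j, ] <- 1
    gen <- generate(model, lat)
    y <- estimator_predict(est, gen)
    x <- lat$c_bf[1, ]
    rows[[j]] <- if (stats::sd(y) == 0)
      data.frame(identity = j, r = NA_real_, undefined = TRUE) else
        data.frame(identity = j, r = stats::cor(x, y), undefined = FALSE)
  }
  per <- do.call(rbind, rows)
  structure(list(test = "real_and_generated_test",
                 per_individual = per,
                 mean_r = mean(per$r[!per$undefined]),
                 sd_r = stats::sd(per$r[!per$undefined]),
                 n_total = n_cases * R, estimator = est),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$test, "\n")
  if (!is.null(x$per_trait)) print(x$per_trait)
  if (!is.null(x$mean_r))
    cat(sprintf("mean within-individual r = %.3f (SD %.3f)\n",
                x$mean_r, x$sd_r))
  invisible(x)
}
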