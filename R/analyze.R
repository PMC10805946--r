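# Trait-interpolated sweep generation and movement-amplitude
# autocorrelation analysis.
#
# The overall movement amplitude of a window is built from six channels on
# the plane facing the gazed object: the accelerometer X/Y channels are
# first-differenced (orientation -> relative motion), then the absolute
# values of ACC X, ACC Y, GYRO X, GYRO Y, EOG H and EOG V are summed.  Mean
# autocorrelation profiles per virtual-trait level expose the
# saccade-fixation period as a peak lag (in 50 Hz samples), and a rank
# correlation of peak lag against level summarizes the trait-period trend.

#' Sweep configuration
#'
#' @param levels virtual openness values; default -2 to 2 in steps of 0.4
#'   (11 levels).
#' @param n_per_level generated cases per level and identity.
#' @param seed integer seed.
#' @return list of class `sweep_config`.
#' @export
sweep_config <- function(levels = seq(-2, 2, by = 0.4), n_per_level = 100L,
                         seed = 1L) {
  stop_if(any(diff(levels) <= 0), "levels must be strictly increasing")
  stop_if(n_per_level < 1, "n_per_level must be >= 1")
  structure(list(levels = levels, n_per_level = as.integer(n_per_level),
                 seed = as.integer(seed)),
            class = "sweep_config")
}

#' Generate the trait-interpolated sweep
#'
#' For each level x identity x repetition one window is generated with the
#' openness code fixed at the level, the other four trait codes fixed at 0,
#' the identity code fixed, and time/noise codes sampled as in training.
#'
#' @param model trained `gan_model`.
#' @param sweep a [sweep_config()].
#' @return list with `windows` (`9 x 512 x M`) and `tags` (data.frame
#'   `level`, `identity`, `rep`), `M = levels x identities x n_per_level`.
#' @export
sweep_generate <- function(model, sweep) {
  R <- model$roster_size
  nl <- length(sweep$levels)
  per <- sweep$n_per_level
  M <- nl * R * per
  win <- array(0, c(9, model$arch$window, M))
  tags <- data.frame(level = numeric(M), identity = integer(M),
                     rep = integer(M))
  i <- 0
  for (li in seq_len(nl)) for (j in seq_len(R)) {
    lat <- sample_latent(per, R, seed = derive_seed(sweep$seed, li * 1000 + j))
    lat$c_bf[] <- 0
    lat$c_bf[1, ] <- sweep$levels[li]
    lat$c_p[] <- 0
    lat$c_p[j, ] <- 1
    win[, , i + seq_len(per)] <- generate(model, lat)
    tags$level[i + seq_len(per)] <- sweep$levels[li]
    tags$identity[i + seq_len(per)] <- j
    tags$rep[i + seq_len(per)] <- seq_len(per)
    i <- i + per
  }
  list(windows = win, tags = tags)
}

#' Overall movement-amplitude series of one window
#'
#' Smooths all channels, first-differences ACC X and ACC Y (one leading zero
#' preserves length), takes absolute values of ACC X, ACC Y, GYRO X, GYRO Y,
#' EOG H, EOG V and sums them.  ACC Z, GYRO Z and EOG L are excluded.
#'
#' @param window `9 x L` matrix (channel order `acc_x ... eog_h`).
#' @param smooth_width odd moving-average width in samples.
#' @param channels channel names entering the sum (differenced ACC channels
#'   among them); configurable, default the six on the facing plane.
#' @return nonnegative numeric series of length L.
#' @export
amplitude_series <- function(window, smooth_width = 5L,
                             channels = c("acc_x", "acc_y", "gyro_x",
                                          "gyro_y", "eog_h", "eog_v")) {
  stop_if(nrow(window) != 9, "window must have 9 channels")
  rownames(window) <- CHANNELS
  sm <- t(apply(window, 1, moving_average, width = smooth_width))
  out <- numeric(ncol(window))
  for (ch in channels) {
    x <- sm[ch, ]
    if (startsWith(ch, "acc")) x <- c(0, diff(x))
    out <- out + abs(x)
  }
  out
}

#' Autocorrelation coefficients with biased normalization
#'
#' `r_k = sum (x_t - xbar)(x_{t+k} - xbar) / sum (x_t - xbar)^2` for
#' `k = 0..max_lag`.
#'
#' @param series numeric series, length > `max_lag`.
#' @param max_lag largest lag.
#' @return list with `acf` (coefficients at lags 0..max_lag) and `undefined`
#'   (TRUE for a constant series, in which case `acf` is all NA).
#' @export
autocorrelation <- function(series, max_lag = 150L) {
  stop_if(length(series) <= max_lag, "series length must exceed max_lag")
  if (stats::sd(series) == 0)
    return(list(acf = rep(NA_real_, max_lag + 1), undefined = TRUE))
  a <- stats::acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE)
  list(acf = as.numeric(a$acf), undefined = FALSE)
}

#' Mean autocorrelation profile per sweep level
#'
#' Per level, the mean over all identities and repetitions of each window's
#' amplitude-series autocorrelation; windows with constant amplitude are
#' skipped and counted.
#'
#' @param windows `9 x L x M` array of (generated or real) windows.
#' @param tags data.frame with a `level` column, one row per window.
#' @param max_lag largest lag (default 150, covering the 20-100 band of
#'   interest with margin).
#' @param smooth_width smoothing width passed to [amplitude_series()].
#' @param peak_range lag range searched for peaks.
#' @return object of class `autocorr_profile`: `levels`, `lags`, `mean_acf`
#'   (level x lag matrix), `n_windows`, `n_skipped`, `peak_lag` (per level,
#'   NA when no local maximum exists), `trend` (see [trend_test()]).
#' @export
profile_by_level <- function(windows, tags, max_lag = 150L, smooth_width = 5L,
                             peak_range = c(10L, max_lag)) {
  stop_if(dim(windows)[3] == 0, "empty sweep")
  levels <- sort(unique(tags$level))
  lags <- 0:max_lag
  macf <- matrix(NA_real_, length(levels), max_lag + 1,
                 dimnames = list(format(levels), NULL))
  nwin <- integer(length(levels)); nskip <- integer(length(levels))
  for (li in seq_along(levels)) {
    idx <- which(tags$level == levels[li])
    s <- numeric(max_lag + 1); cnt <- 0
    for (i in idx) {
      am <- amplitude_series(windows[, , i], smooth_width)
      ac <- autocorrelation(am, max_lag)
      if (ac$undefined) { nskip[li] <- nskip[li] + 1; next }
      s <- s + ac$acf; cnt <- cnt + 1
    }
    nwin[li] <- cnt
    if (cnt > 0) macf[li, ] <- s / cnt
  }
  pk <- vapply(seq_along(levels), function(li)
    peak_lag(macf[li, ], range = peak_range), numeric(1))
  prof <- structure(list(levels = levels, lags = lags, mean_acf = macf,
                         n_windows = nwin, n_skipped = nskip, peak_lag = pk),
                    class = "autocorr_profile")
  prof$trend <- trend_test(prof)
  prof
}

#' Lag of the dominant strict local maximum
#'
#' Among strict local maxima of the coefficients within `range`, returns the
#' lag of the one with the largest coefficient; plateaus resolve to their
#' smallest lag; returns `NA` when no local maximum exists.
#'
#' @param coefficients autocorrelation coefficients at lags `0..max_lag`.
#' @param range two-element lag search range.
#' @return integer lag or `NA`.
#' @export
peak_lag <- function(coefficients, range = c(10L, 150L)) {
  n <- length(coefficients)
  stop_if(range[2] > n - 1, "search range exceeds computed lags")
  if (anyNA(coefficients)) return(NA_real_)
  # strict local maxima with plateau handling: collapse equal runs first
  r <- rle(coefficients)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(vals)
  if (k < 3) return(NA_real_)
  cand_lag <- numeric(0); cand_val <- numeric(0)
  for (i in 2:(k - 1)) {
    if (vals[i] > vals[i - 1] && vals[i] > vals[i + 1]) {
      lag <- starts[i] - 1  # lags are 0-based
      if (lag >= range[1] && lag <= range[2]) {
        cand_lag <- c(cand_lag, lag)
        cand_val <- c(cand_val, vals[i])
      }
    }
  }
  if (!length(cand_lag)) return(NA_real_)
  cand_lag[which.max(cand_val)]
}

#' Monotone-association test of peak lag against trait level
#'
#' Spearman rank correlation of the per-level peak lags on the levels;
#' levels with no defined peak are excluded and reported, never imputed.
#'
#' @param profile an `autocorr_profile`.
#' @return list with `rho` (NA when inconclusive), `n_defined`,
#'   `n_absent`, `inconclusive`.
#' @export
trend_test <- function(profile) {
  ok <- !is.na(profile$peak_lag)
  nd <- sum(ok)
  if (nd < 3)
    return(list(rho = NA_real_, n_defined = nd, n_absent = sum(!ok),
                inconclusive = TRUE))
  rho <- suppressWarnings(stats::cor(profile$levels[ok],
                                     profile$peak_lag[ok],
                                     method = "spearman"))
  list(rho = rho, n_defined = nd, n_absent = sum(!ok),
       inconclusive = is.na(rho))
}

#' @export
print.autocorr_profile <- function(x, ...) {
  cat("<autocorr_profile>", length(x$levels), "levels, lags 0..",
      max(x$lags), "\n")
  print(data.frame(level = x$levels, n = x$n_windows, peak_lag = x$peak_lag))
  if (!is.null(x$trend))
    cat(sprintf("trend rho = %s (defined peaks: %d)\n",
                format(x$trend$rho, digits = 3), x$trend$n_defined))
  invisible(x)
}
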