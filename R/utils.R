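# Internal helpers shared across modules.

CHANNELS <- c("acc_x", "acc_y", "acc_z",
              "gyro_x", "gyro_y", "gyro_z",
              "eog_l", "eog_v", "eog_h")

TRAITS <- c("openness", "conscientiousness", "extraversion",
            "agreeableness", "neuroticism")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Derive a child seed from a parent seed
#'
#' Deterministic integer mixing used to give every stochastic stage its own
#' stream while remaining reproducible from a single integer.  Result stays
#' within the 32-bit signed range R requires of `set.seed()`.
#'
#' @param seed parent integer seed.
#' @param k stream index (any small integer).
#' @return a positive integer seed.
#' @keywords internal
derive_seed <- function(seed, k) {
  s <- (as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483629
  as.integer(s + 1)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Population standard deviation (divisor n) and the matching z-score; this
# definition makes two-point groups standardize exactly to {-1, +1}.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
pop_scale <- function(x) (x - mean(x)) / pop_sd(x)

# Centered moving average with edge-shrinking kernel; width must be odd.
moving_average <- function(x, width) {
  stop_if(width %% 2 == 0, "smoothing width must be odd, got ", width)
  if (width == 1L || length(x) == 0L) return(x)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
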