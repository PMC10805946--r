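make_rec <- function(values) {
  structure(list(participant_id = "P01", task = "t", sample_rate = 50,
                 values = values,
                 event_log = data.frame(onset_s = numeric(0),
                                        duration_s = numeric(0),
                                        amplitude = numeric(0))),
            class = "sensor_recording")
}

test_that("smooth_channels: identity at width 1, constants unchanged, plateau", {
  v <- matrix(rnorm(100 * 9), 100, 9, dimnames = list(NULL, CHANNELS))
  rec <- make_rec(v)
  expect_equal(smooth_channels(rec, 1)$values, v)
  const <- make_rec(matrix(3, 50, 9, dimnames = list(NULL, CHANNELS)))
  expect_equal(unname(smooth_channels(const, 5)$values),
               unname(const$values))
  # impulse of height 5 smoothed with width 5 -> plateau of height 1
  imp <- matrix(0, 50, 9); imp[25, 1] <- 5
  sm <- smooth_channels(make_rec(imp), 5)$values
  expect_equal(sm[23:27, 1], rep(1, 5))
  expect_equal(sm[22, 1], 0)
  expect_error(smooth_channels(rec, 4), "odd")
})

test_that("slice_windows obeys the count formula and discards tails", {
  rec <- make_rec(matrix(rnorm(512 * 9), 512, 9))
  expect_length(slice_windows(rec), 1)
  rec2 <- make_rec(matrix(rnorm(30000 * 9), 30000, 9))
  ws <- slice_windows(rec2)
  expect_length(ws, 231)  # floor((30000 - 512)/128) + 1
  expect_equal(ws[[1]]$start_index, 0)
  expect_equal(ws[[2]]$start_index, 128)
  short <- make_rec(matrix(0, 511, 9))
  expect_warning(out <- slice_windows(short), "shorter")
  expect_length(out, 0)
})

test_that("window count formula equals brute-force start enumeration", {
  set.seed(42)
  for (i in 1:100) {
    T_ <- sample(512:5000, 1)
    window <- 512L
    stride <- 128L
    rec <- make_rec(matrix(0, T_, 9))
    n_pkg <- length(suppressWarnings(slice_windows(rec, window, stride)))
    n_brute <- sum((seq(0, T_) + window) <= T_ &
                     seq(0, T_) %% stride == 0)
    expect_equal(n_pkg, n_brute)
  }
})

test_that("standardize_windows centers and scales each group", {
  set.seed(1)
  n_win <- 6
  arr <- array(rnorm(9 * 64 * n_win, mean = 3, sd = 2), c(9, 64, n_win))
  meta <- data.frame(participant_id = rep(c("A", "B"), each = 3),
                     task = "t", start_index = rep(0:2, 2) * 128)
  out <- standardize_windows(arr, meta)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  for (p in c("A", "B")) for (ch in c(1, 5, 9)) {
    v <- out[ch, , meta$participant_id == p]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(psd(as.numeric(v)) - 1), 1e-6)
  }
  # idempotent
  out2 <- standardize_windows(out, meta)
  expect_equal(out2, out, tolerance = 1e-6)
  # two-value group maps to {-1, +1}: single window, length-2 channels
  arr2 <- array(rnorm(9 * 2), c(9, 2, 1))
  meta2 <- data.frame(participant_id = "A", task = "t", start_index = 0)
  out3 <- standardize_windows(arr2, meta2)
  expect_equal(sort(out3[1, , 1]), c(-1, 1), tolerance = 1e-9)
  # zero-variance group errors and names the group
  arr2[3, , 1] <- 2
  expect_error(standardize_windows(arr2, meta2), "acc_z")
})

test_that("build_labels produces consistent label triples", {
  cfg <- tiny_sim_config(n_participants = 4)
  pop <- sample_population(cfg, seed = 3)
  meta <- data.frame(
    participant_id = rep(pop$participant_id[c(3, 1)], times = c(3, 4)),
    task = "data_entry",
    start_index = c(0, 128, 256, 0, 128, 256, 384))
  lab <- build_labels(pop, meta)
  expect_equal(lab$roster, sort(pop$participant_id))
  # one-hot correctness
  expect_true(all(rowSums(lab$c_p) == 1))
  expect_equal(unname(which(lab$c_p[1, ] == 1)),
               match(meta$participant_id[1], lab$roster))
  # time labels: K=3 -> {-1, 0, 1}; K=4 -> evenly spaced from -1 to 1
  expect_equal(lab$c_t[1:3], c(-1, 0, 1))
  expect_equal(lab$c_t[4:7], c(-1, -1/3, 1/3, 1))
  # trait labels copied from the population
  expect_equal(unname(lab$c_bf[1, "openness"]), pop$z_openness[3])
  # unknown participant errors
  meta$participant_id[1] <- "ZZ"
  expect_error(build_labels(pop, meta), "unknown participant")
})

test_that("single-window task gets time label 0", {
  cfg <- tiny_sim_config(n_participants = 2)
  pop <- sample_population(cfg, seed = 3)
  meta <- data.frame(participant_id = pop$participant_id[1], task = "x",
                     start_index = 0)
  expect_equal(build_labels(pop, meta)$c_t, 0)
})

test_that("make_windowed_dataset assembles a consistent dataset", {
  ds <- tiny_dataset()
  n <- dim(ds$windows)[3]
  expect_equal(nrow(ds$meta), n)
  expect_equal(nrow(ds$c_bf), n)
  expect_equal(nrow(ds$c_p), n)
  expect_length(ds$c_t, n)
  expect_true(all(ds$c_t >= -1 & ds$c_t <= 1))
  # labels consistent with meta, exhaustively
  pop_order <- ds$roster
  for (i in seq_len(n)) {
    expect_equal(which(ds$c_p[i, ] == 1),
                 match(ds$meta$participant_id[i], pop_order),
                 ignore_attr = TRUE)
  }
  # subsetting keeps alignment
  p1 <- ds$roster[1]
  sub <- dataset_subset(ds, participants = p1)
  expect_true(all(sub$meta$participant_id == p1))
  expect_true(all(sub$c_p[, match(p1, ds$roster)] == 1))
})
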