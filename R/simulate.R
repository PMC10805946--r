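# Ground-truthed synthetic sensor-data simulator.
#
# Real 50 Hz head/eye-movement recordings from a glasses-type wearable are not
# publicly deposited, so this module emulates them as a saccade-fixation
# renewal process: fixations with gamma-distributed durations alternate with
# short saccades; saccades render half-sine pulses on the gyrometer channels,
# step changes on the electrooculography channels, and first-order-lag steps
# on the accelerometer channels.  One designated personality trait modulates
# the log mean fixation duration with a task-dependent sign, so the
# trait-period relationship is a recoverable ground truth.  Individual
# attributes (per-channel gain and offset, noise level, an idiosyncratic
# low-frequency oscillation) are drawn independently of all traits.

#' Simulator configuration
#'
#' @param n_participants number of simulated participants (>= 2).
#' @param tasks task names; a task named `"baseline"` must have zero trait
#'   slope (it encodes "no trait modulation of these sensor data").
#' @param duration_s seconds per recording (>= 0; 0 gives empty recordings).
#' @param sample_rate sampling rate in Hz.
#' @param fixation_mean_base named numeric, mean fixation duration in seconds
#'   per task at trait value 0.
#' @param trait_slope named numeric, signed coefficient per task on the log
#'   mean fixation duration per standard-deviation of the target trait.
#' @param fixation_shape gamma shape of fixation durations.  The default 10
#'   (coefficient of variation ~0.32) keeps the first autocorrelation peak of
#'   the movement-amplitude series within ~15% of the mean period; more
#'   dispersed renewals (shape <= 4) bury the peak under spurious maxima.
#' @param saccade_dur_range min/max saccade duration in seconds.
#' @param individual_gain_sd SD of per-channel log gains.
#' @param individual_offset_sd SD of per-channel baseline offsets.
#' @param noise_sd_range min/max of the per-participant white-noise SD.
#' @param idiosyncrasy_strength amplitude of the per-individual fixed-frequency
#'   oscillatory confound.
#' @param idiosyncrasy_freq_range min/max of the per-individual oscillation
#'   frequency in Hz.
#' @param trait_target name of the trait that modulates fixation durations;
#'   the other four traits are simulated with zero slope.
#' @param seed default integer seed for stages that take no explicit seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 14,
                       tasks = c("data_entry", "conversation", "baseline"),
                       duration_s = 600,
                       sample_rate = 50,
                       fixation_mean_base = c(data_entry = 1.6,
                                              conversation = 1.0,
                                              baseline = 1.2),
                       trait_slope = c(data_entry = -0.2,
                                       conversation = 0.35,
                                       baseline = 0),
                       fixation_shape = 10,
                       saccade_dur_range = c(0.04, 0.12),
                       individual_gain_sd = 0.2,
                       individual_offset_sd = 0.5,
                       noise_sd_range = c(0.05, 0.3),
                       idiosyncrasy_strength = 0.5,
                       idiosyncrasy_freq_range = c(0.05, 0.4),
                       trait_target = "openness",
                       seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants), tasks = tasks,
              duration_s = duration_s, sample_rate = sample_rate,
              fixation_mean_base = fixation_mean_base,
              trait_slope = trait_slope, fixation_shape = fixation_shape,
              saccade_dur_range = saccade_dur_range,
              individual_gain_sd = individual_gain_sd,
              individual_offset_sd = individual_offset_sd,
              noise_sd_range = noise_sd_range,
              idiosyncrasy_strength = idiosyncrasy_strength,
              idiosyncrasy_freq_range = idiosyncrasy_freq_range,
              trait_target = trait_target, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if(cfg$n_participants < 2, "n_participants must be >= 2")
  stop_if(cfg$duration_s < 0, "duration_s must be >= 0")
  stop_if(cfg$sample_rate <= 0, "sample_rate must be > 0")
  stop_if(cfg$fixation_shape <= 0, "fixation_shape must be > 0")
  stop_if(!all(cfg$tasks %in% names(cfg$fixation_mean_base)),
          "fixation_mean_base must name every task")
  stop_if(!all(cfg$tasks %in% names(cfg$trait_slope)),
          "trait_slope must name every task")
  if ("baseline" %in% cfg$tasks)
    stop_if(cfg$trait_slope[["baseline"]] != 0,
            "baseline task must have trait_slope = 0")
  stop_if(!cfg$trait_target %in% TRAITS,
          "trait_target must be one of: ", paste(TRAITS, collapse = ", "))
  invisible(cfg)
}

#' Sample a ground-truthed participant population
#'
#' Raw trait scores mimic a 20-item questionnaire (four 7-point items per
#' trait, so sums range 4-28) and are standardized within trait across
#' participants.  Individual attributes (per-channel gains and offsets, noise
#' SD, idiosyncratic oscillation frequency) are drawn independently of every
#' trait, so attribute-trait orthogonality holds by construction.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a `data.frame` of class `population_table` with one row per
#'   participant: `participant_id`, `raw_<trait>`, `z_<trait>`,
#'   `gain_<channel>`, `offset_<channel>`, `noise_sd`, `idio_freq`.
#' @export
sample_population <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n <- config$n_participants
  with_seed(seed, {
    pop <- data.frame(participant_id = sprintf("P%02d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (tr in TRAITS) {
      raw <- as.numeric(rowSums(matrix(sample.int(7, n * 4, replace = TRUE),
                                       nrow = n)))
      # guard against a degenerate draw (all raw scores equal)
      while (stats::sd(raw) == 0)
        raw <- as.numeric(rowSums(matrix(sample.int(7, n * 4, replace = TRUE),
                                         nrow = n)))
      pop[[paste0("raw_", tr)]] <- raw
      pop[[paste0("z_", tr)]] <- pop_scale(raw)
    }
    for (ch in CHANNELS)
      pop[[paste0("gain_", ch)]] <- exp(stats::rnorm(n, 0, config$individual_gain_sd))
    for (ch in CHANNELS)
      pop[[paste0("offset_", ch)]] <- stats::rnorm(n, 0, config$individual_offset_sd)
    pop$noise_sd <- stats::runif(n, config$noise_sd_range[1], config$noise_sd_range[2])
    pop$idio_freq <- stats::runif(n, config$idiosyncrasy_freq_range[1],
                                  config$idiosyncrasy_freq_range[2])
    class(pop) <- c("population_table", "data.frame")
    pop
  })
}

# Mean fixation duration (s) for a participant on a task.
fixation_mean <- function(participant, task, config) {
  z <- participant[[paste0("z_", config$trait_target)]]
  config$fixation_mean_base[[task]] * exp(config$trait_slope[[task]] * z)
}

#' Closed-form mean saccade-to-saccade period
#'
#' Pure function returning the expected saccade-onset-to-onset period: the
#' mean fixation duration under the log-linear trait model plus the mean
#' saccade duration.  Serves as the independent oracle for autocorrelation
#' peak-lag recovery.
#'
#' @inheritParams simulate_recording
#' @return period in seconds.
#' @export
expected_mean_period <- function(participant, task, config) {
  stop_if(!task %in% config$tasks, "unknown task: ", task)
  fixation_mean(participant, task, config) + mean(config$saccade_dur_range)
}

#' Simulate one 9-channel sensor recording
#'
#' Renders the saccade-fixation renewal process of one participant on one
#' task: gaze jumps to uniform random targets in `[-1, 1]^2` at each saccade;
#' gyrometer channels receive half-sine velocity pulses, electrooculography
#' channels track the gaze position (step changes at saccades), and
#' accelerometer channels track head orientation as a first-order lag of gaze
#' (ACC X with inverted sign relative to ACC Y and ACC Z).  Per-individual
#' gain, offset, white noise and a fixed-frequency oscillation are then
#' applied per channel.
#'
#' @param participant one row of a [sample_population()] table.
#' @param task task name, must appear in `config$tasks`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return an object of class `sensor_recording`: list with `participant_id`,
#'   `task`, `sample_rate`, `values` (samples x 9 matrix, columns
#'   `acc_x ... eog_h`) and `event_log` (data.frame of ground-truth saccade
#'   `onset_s`, `duration_s`, `amplitude`).
#' @export
simulate_recording <- function(participant, task, config, seed = config$seed) {
  stop_if(!task %in% config$tasks, "unknown task: ", task)
  fs <- config$sample_rate
  dur <- config$duration_s
  n <- floor(dur * fs)
  empty <- function() {
    structure(list(participant_id = participant$participant_id, task = task,
                   sample_rate = fs,
                   values = matrix(numeric(0), 0, 9,
                                   dimnames = list(NULL, CHANNELS)),
                   event_log = data.frame(onset_s = numeric(0),
                                          duration_s = numeric(0),
                                          amplitude = numeric(0))),
              class = "sensor_recording")
  }
  if (n == 0) return(empty())

  mu <- fixation_mean(participant, task, config)
  shape <- config$fixation_shape
  sdr <- config$saccade_dur_range

  with_seed(seed, {
    # renewal event times: fixation ~ Gamma(shape, mean mu), saccade ~ U(sdr)
    n_expect <- ceiling(dur / (mu + mean(sdr))) + 10
    onsets <- numeric(0); sdur <- numeric(0)
    t <- 0
    repeat {
      fx <- stats::rgamma(n_expect, shape = shape, rate = shape / mu)
      sc <- stats::runif(n_expect, sdr[1], sdr[2])
      tt <- t + cumsum(fx + sc) - sc
      keep <- tt < dur
      onsets <- c(onsets, tt[keep]); sdur <- c(sdur, sc[keep])
      if (!all(keep)) break
      t <- t + sum(fx + sc)
    }
    k <- length(onsets)

    # gaze targets and amplitudes
    gx <- stats::runif(k, -1, 1); gy <- stats::runif(k, -1, 1)
    px <- c(stats::runif(1, -1, 1), gx)  # position before/after each saccade
    py <- c(stats::runif(1, -1, 1), gy)
    dh <- diff(px); dv <- diff(py)
    amp <- sqrt(dh^2 + dv^2)

    tgrid <- (seq_len(n) - 1) / fs
    # piecewise-linear gaze position: constant during fixation, ramp in saccade
    knots_t <- c(0, as.vector(rbind(onsets, pmin(onsets + sdur, dur))), dur + 1 / fs)
    knots_h <- c(px[1], as.vector(rbind(px[-length(px)], px[-1])), px[length(px)])
    knots_v <- c(py[1], as.vector(rbind(py[-length(py)], py[-1])), py[length(py)])
    ok <- !duplicated(knots_t)
    h <- stats::approx(knots_t[ok], knots_h[ok], xout = tgrid, rule = 2)$y
    v <- stats::approx(knots_t[ok], knots_v[ok], xout = tgrid, rule = 2)$y

    # saccade-locked transient pulses: half-sine on the gyrometer (head
    # rotation velocity) and on EOG V/H (AC-coupled electrodes see relative
    # eye motion, so only transients appear, not absolute position)
    gyro_x <- numeric(n); gyro_y <- numeric(n); gyro_z <- numeric(n)
    eog_v <- numeric(n); eog_h <- numeric(n)
    if (k > 0) for (i in seq_len(k)) {
      i0 <- floor(onsets[i] * fs) + 1
      w <- max(2L, round(sdur[i] * fs))
      idx <- i0:min(n, i0 + w - 1L)
      pulse <- sin(pi * seq_along(idx) / (w + 1))
      gyro_x[idx] <- gyro_x[idx] + 3 * dv[i] * pulse
      gyro_y[idx] <- gyro_y[idx] + 3 * dh[i] * pulse
      gyro_z[idx] <- gyro_z[idx] + 1.2 * (dh[i] - dv[i]) * pulse
      eog_v[idx] <- eog_v[idx] + 4 * dv[i] * pulse
      eog_h[idx] <- eog_h[idx] + 4 * dh[i] * pulse
    }

    # head orientation: first-order lag (tau = 0.4 s) of gaze position
    alpha <- min(1, (1 / fs) / 0.4)
    oh <- as.numeric(stats::filter(alpha * h, 1 - alpha, method = "recursive",
                                   init = h[1]))
    ov <- as.numeric(stats::filter(alpha * v, 1 - alpha, method = "recursive",
                                   init = v[1]))
    acc_x <- -(0.9 * ov + 0.3 * oh)      # inverted sign vs ACC Y / ACC Z
    acc_y <- 0.8 * ov + 0.2 * oh
    acc_z <- 0.7 * ov - 0.2 * oh

    # left-electrode absolute potential: transient mix plus slow drift
    eog_l <- 0.5 * eog_v - 0.3 * eog_h + 0.3 * sin(2 * pi * 0.01 * tgrid)

    raw <- cbind(acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z,
                 eog_l, eog_v, eog_h)
    colnames(raw) <- CHANNELS

    phases <- stats::runif(9, 0, 2 * pi)
    f0 <- participant$idio_freq
    osc <- outer(tgrid, phases, function(t, p) sin(2 * pi * f0 * t + p))
    gains <- as.numeric(participant[paste0("gain_", CHANNELS)])
    offs <- as.numeric(participant[paste0("offset_", CHANNELS)])
    vals <- sweep(raw, 2, gains, "*")
    vals <- sweep(vals, 2, offs, "+")
    vals <- vals + config$idiosyncrasy_strength * osc +
      matrix(stats::rnorm(n * 9, 0, participant$noise_sd), n, 9)
    colnames(vals) <- CHANNELS

    structure(list(participant_id = participant$participant_id, task = task,
                   sample_rate = fs, values = vals,
                   event_log = data.frame(onset_s = onsets, duration_s = sdur,
                                          amplitude = amp)),
              class = "sensor_recording")
  })
}

#' Simulate a whole study: population plus all recordings
#'
#' @param config a [sim_config()].
#' @param seed integer seed; per-recording seeds are derived from it.
#' @return list with `population` and `recordings` (list of
#'   `sensor_recording`, one per participant x task).
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  pop <- sample_population(config, seed = derive_seed(seed, 0))
  recs <- list()
  i <- 0
  for (p in seq_len(nrow(pop))) {
    for (task in config$tasks) {
      i <- i + 1
      recs[[i]] <- simulate_recording(pop[p, , drop = FALSE], task, config,
                                      seed = derive_seed(seed, i))
    }
  }
  list(population = pop, recordings = recs)
}

#' Write a population table to CSV
#' @param population a `population_table`.
#' @param path output file path.
#' @export
write_population_csv <- function(population, path) {
  utils::write.csv(as.data.frame(population), path, row.names = FALSE)
  invisible(path)
}

#' Write recordings (and their ground-truth event logs) to CSV
#'
#' One `<participant>_<task>.csv` per recording with columns
#' `participant_id, task, sample_index, acc_x, ..., eog_h`, plus a single
#' `events.csv` with the ground-truth saccade log.
#'
#' @param recordings list of `sensor_recording`.
#' @param dir output directory (created if absent).
#' @export
write_recordings_csv <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- list()
  for (rec in recordings) {
    df <- data.frame(participant_id = rec$participant_id, task = rec$task,
                     sample_index = seq_len(nrow(rec$values)) - 1L)
    df <- cbind(df, as.data.frame(rec$values))
    utils::write.csv(df, file.path(dir, paste0(rec$participant_id, "_",
                                               rec$task, ".csv")),
                     row.names = FALSE)
    if (nrow(rec$event_log))
      ev[[length(ev) + 1]] <- cbind(participant_id = rec$participant_id,
                                    task = rec$task, rec$event_log)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(participant_id = character(0), task = character(0),
               onset_s = numeric(0), duration_s = numeric(0),
               amplitude = numeric(0))
  utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read recordings written by [write_recordings_csv()]
#' @param dir directory containing the CSV files.
#' @param sample_rate sampling rate to attach.
#' @return list of `sensor_recording` (event logs reattached when present).
#' @export
read_recordings_csv <- function(dir, sample_rate = 50) {
  files <- setdiff(list.files(dir, pattern = "\\.csv$", full.names = TRUE),
                   file.path(dir, "events.csv"))
  evp <- file.path(dir, "events.csv")
  events <- if (file.exists(evp)) utils::read.csv(evp) else NULL
  files <- Filter(function(f) {
    hdr <- names(utils::read.csv(f, nrows = 1))
    all(CHANNELS %in% hdr)
  }, files)
  lapply(files, function(f) {
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    ev <- if (!is.null(events) && nrow(events))
      events[events$participant_id == df$participant_id[1] &
               events$task == df$task[1],
             c("onset_s", "duration_s", "amplitude")]
    else data.frame(onset_s = numeric(0), duration_s = numeric(0),
                    amplitude = numeric(0))
    structure(list(participant_id = df$participant_id[1], task = df$task[1],
                   sample_rate = sample_rate,
                   values = as.matrix(df[, CHANNELS]),
                   event_log = ev),
              class = "sensor_recording")
  })
}
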