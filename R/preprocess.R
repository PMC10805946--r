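# Windowing, standardization and label construction.
#
# Recordings are smoothed, cut into 512-sample windows moved in 128-sample
# strides, standardized per (channel, participant, task), and paired with
# three label families: five standardized trait scores (c_BF), a one-hot
# person identity over the sorted roster (c_P), and an evenly spaced time
# label in [-1, 1] over each participant-task window sequence (c_T).

#' Smooth every channel of a recording
#'
#' Centered moving average per channel; at the edges the kernel shrinks so the
#' series length is preserved.
#'
#' @param recording a `sensor_recording`.
#' @param width odd kernel width in samples (default 5, i.e. 100 ms at 50 Hz).
#' @return the recording with smoothed `values`.
#' @export
smooth_channels <- function(recording, width = 5L) {
  stop_if(width < 1, "width must be >= 1")
  stop_if(width %% 2 == 0, "width must be odd, got ", width)
  recording$values <- apply(recording$values, 2, moving_average, width = width)
  if (is.null(dim(recording$values)))  # 0- or 1-row edge case
    recording$values <- matrix(recording$values, ncol = 9,
                               dimnames = list(NULL, CHANNELS))
  recording
}

#' Slice a recording into fixed-length windows
#'
#' Windows start at sample offsets 0, stride, 2 stride, ...; a trailing
#' stretch shorter than `window` is discarded.
#'
#' @param recording a `sensor_recording`.
#' @param window window length in samples.
#' @param stride hop size in samples.
#' @return list of `list(start_index, values)` where `start_index` is 0-based
#'   and `values` is a `window x 9` matrix.  Recordings shorter than `window`
#'   give an empty list with a warning.
#' @export
slice_windows <- function(recording, window = 512L, stride = 128L) {
  n <- nrow(recording$values)
  if (n < window) {
    warning("recording shorter than one window (", n, " < ", window, ")")
    return(list())
  }
  count <- (n - window) %/% stride + 1L
  starts <- (seq_len(count) - 1L) * stride
  lapply(starts, function(s) {
    list(start_index = s,
         values = recording$values[(s + 1L):(s + window), , drop = FALSE])
  })
}

#' Standardize windows per (channel, participant, task) group
#'
#' Every channel is standardized to mean 0 and SD 1 over all windows of one
#' participant on one task ("modality" is read as each of the 9 channels).
#'
#' @param windows `9 x L x N` array of window values.
#' @param meta data.frame with one row per window: `participant_id`, `task`.
#' @return the array with each group standardized.
#' @export
standardize_windows <- function(windows, meta) {
  stopifnot(dim(windows)[1] == 9, dim(windows)[3] == nrow(meta))
  grp <- interaction(meta$participant_id, meta$task, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    for (ch in 1:9) {
      v <- windows[ch, , idx]
      m <- mean(v); s <- pop_sd(as.numeric(v))
      stop_if(s == 0, "zero-variance group: channel ", CHANNELS[ch],
              ", group ", g)
      windows[ch, , idx] <- (v - m) / s
    }
  }
  windows
}

#' Build the three label families for a set of windows
#'
#' @param population a `population_table`.
#' @param meta window metadata (`participant_id`, `task`, `start_index`).
#' @param roster character vector fixing the one-hot order; defaults to the
#'   sorted participant ids of `population`.
#' @return list with `c_bf` (N x 5 standardized traits), `c_p` (N x R one-hot
#'   over the roster), `c_t` (length-N time labels in `[-1, 1]`; the first and
#'   last windows of a participant-task sequence map to -1 and +1, a single
#'   window maps to 0) and `roster`.
#' @export
build_labels <- function(population, meta,
                         roster = sort(unique(population$participant_id))) {
  unknown <- setdiff(unique(meta$participant_id), population$participant_id)
  stop_if(length(unknown) > 0, "unknown participant(s): ",
          paste(unknown, collapse = ", "))
  n <- nrow(meta)
  prow <- match(meta$participant_id, population$participant_id)
  c_bf <- as.matrix(population[prow, paste0("z_", TRAITS)])
  dimnames(c_bf) <- list(NULL, TRAITS)

  pid <- match(meta$participant_id, roster)
  stop_if(anyNA(pid), "participant(s) missing from roster")
  c_p <- matrix(0, n, length(roster), dimnames = list(NULL, roster))
  c_p[cbind(seq_len(n), pid)] <- 1

  c_t <- numeric(n)
  grp <- interaction(meta$participant_id, meta$task, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    ord <- idx[order(meta$start_index[idx])]
    K <- length(ord)
    c_t[ord] <- if (K == 1) 0 else -1 + 2 * (seq_len(K) - 1) / (K - 1)
  }
  list(c_bf = c_bf, c_p = c_p, c_t = c_t, roster = roster)
}

#' Assemble a standardized, labelled windowed dataset
#'
#' Full preprocessing pipeline: smooth each recording, slice into windows,
#' standardize per (channel, participant, task), attach labels.
#'
#' @param recordings list of `sensor_recording`.
#' @param population matching `population_table`.
#' @param window,stride windowing parameters in samples.
#' @param smooth_width odd moving-average width in samples.
#' @return object of class `windowed_dataset`: list with `windows`
#'   (`9 x window x N` array), `meta` (per-window `participant_id`, `task`,
#'   `start_index`), `c_bf`, `c_p`, `c_t`, `roster`, `tasks`.
#' @export
make_windowed_dataset <- function(recordings, population,
                                  window = 512L, stride = 128L,
                                  smooth_width = 5L) {
  pieces <- list(); metas <- list()
  for (rec in recordings) {
    sm <- smooth_channels(rec, smooth_width)
    ws <- slice_windows(sm, window, stride)
    for (w in ws) {
      pieces[[length(pieces) + 1]] <- t(w$values)  # 9 x window
      metas[[length(metas) + 1]] <-
        data.frame(participant_id = rec$participant_id, task = rec$task,
                   start_index = w$start_index, stringsAsFactors = FALSE)
    }
  }
  stop_if(length(pieces) == 0, "no windows produced; recordings too short?")
  meta <- do.call(rbind, metas)
  arr <- array(unlist(pieces), dim = c(9, window, length(pieces)))
  arr <- standardize_windows(arr, meta)
  lab <- build_labels(population, meta)
  structure(list(windows = arr, meta = meta, c_bf = lab$c_bf, c_p = lab$c_p,
                 c_t = lab$c_t, roster = lab$roster,
                 tasks = unique(meta$task)),
            class = "windowed_dataset")
}

#' Subset a windowed dataset by task and/or participants
#' @param dataset a `windowed_dataset`.
#' @param task optional single task name.
#' @param participants optional participant ids to keep.
#' @return the subsetted `windowed_dataset` (roster unchanged).
#' @export
dataset_subset <- function(dataset, task = NULL, participants = NULL) {
  keep <- rep(TRUE, nrow(dataset$meta))
  if (!is.null(task)) keep <- keep & dataset$meta$task %in% task
  if (!is.null(participants))
    keep <- keep & dataset$meta$participant_id %in% participants
  idx <- which(keep)
  stop_if(length(idx) == 0, "subset selects no windows")
  structure(list(windows = dataset$windows[, , idx, drop = FALSE],
                 meta = dataset$meta[idx, , drop = FALSE],
                 c_bf = dataset$c_bf[idx, , drop = FALSE],
                 c_p = dataset$c_p[idx, , drop = FALSE],
                 c_t = dataset$c_t[idx],
                 roster = dataset$roster,
                 tasks = unique(dataset$meta$task[idx])),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat("<windowed_dataset> ", dim(x$windows)[3], " windows of ",
      dim(x$windows)[1], "x", dim(x$windows)[2], "; ",
      length(x$roster), " participants; tasks: ",
      paste(x$tasks, collapse = ", "), "\n", sep = "")
  invisible(x)
}
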