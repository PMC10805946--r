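# Shared tiny fixtures, built in code.

# A small single-task world with a strong trait effect; used across tests.
tiny_sim_config <- function(tasks = "data_entry", duration_s = 60,
                            n_participants = 4, seed = 7) {
  sim_config(n_participants = n_participants, tasks = tasks,
             duration_s = duration_s,
             fixation_mean_base = c(data_entry = 1.6, conversation = 1.0,
                                    baseline = 1.2),
             trait_slope = c(data_entry = -0.3, conversation = 0.4,
                             baseline = 0),
             seed = seed)
}

tiny_dataset <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- tiny_sim_config()
      sim <- simulate_dataset(cfg, seed = 7)
      memo <<- make_windowed_dataset(sim$recordings, sim$population)
    }
    memo
  }
})

# A very small architecture for fast shape/gradient tests.
tiny_arch <- function() {
  arch_config("desk", g_channels = c(8, 6, 5, 4), d_channels = c(3, 4, 5, 6),
              head_hidden = 7)
}

# Reference power iteration for the largest singular value.
power_sigma <- function(W, iters = 200) {
  u <- rep(1, nrow(W)) / sqrt(nrow(W))
  for (i in seq_len(iters)) {
    v <- crossprod(W, u); v <- v / sqrt(sum(v^2))
    u <- W %*% v; u <- u / sqrt(sum(u^2))
  }
  as.numeric(t(u) %*% W %*% v)
}
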