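# Small engine fixtures built in code, shared across test files.

# tiny simple-variant network plus a short noisy episode stimulus
tiny_simple_fixture <- function(N = 8, n_steps = 2, n_presentations = 4,
                                duration_pad_ms = 200, seed = 11) {
  g <- build_simple(N = N, seed = seed)
  es <- allocate_episodes(N, "partitioned", n_episodes = 4,
                          fraction = 0.25, n_steps = n_steps,
                          seed = seed + 1)
  cfg <- stimulus_config(episode_overlap_steps = 1, nu = 0.5)
  stim <- make_stimulus(es, n_presentations, cfg, block_id = 1,
                        seed = seed + 2)
  stim$duration_ms <- stim$duration_ms + duration_pad_ms
  list(graph = g, episodes = es, stim = stim)
}

# deterministic single-presentation scenario with hand-computable groups
crafted_metric_scenario <- function(counts = c(active = 5, completion = 3,
                                               prospection = 2,
                                               background = 1),
                                    seed = 21) {
  n_input <- 24
  g <- build_simple(N = n_input, seed = seed)
  es <- allocate_episodes(n_input, "partitioned", n_episodes = 2,
                          fraction = 0.5, n_steps = 3, seed = seed + 1)
  cfg <- stimulus_config(episode_overlap_steps = 1)
  sched <- schedule_presentations(es, 1, 1, cfg, seed = seed + 2)
  stim <- render_episode_spikes(sched, es, cfg, seed = seed + 3)
  stim$duration_ms <- stim$duration_ms + 100
  ep <- es$episodes[[which(vapply(es$episodes, function(e) e$episode_id,
                                  integer(1)) == sched$presentations$episode_id[1])]]
  dropped <- stim$annotations$dropped
  cyc <- stim$annotations$cycles
  cyc <- cyc[!is.na(cyc$step), ]
  T_low <- stim$cycle_ms
  sp_t <- c(); sp_id <- c()
  for (r in seq_len(nrow(cyc))) {
    st <- cyc$step[r]
    mem <- ep$steps[[st]]
    dr <- dropped$neuron_id[dropped$pres_idx == cyc$pres_idx[r] &
                              dropped$step == st]
    stim_in <- unlist(ep$steps[max(1, st - 3):st])
    up <- if (st < es$n_steps)
      unlist(ep$steps[(st + 1):min(st + 2, es$n_steps)]) else integer(0)
    groups <- list(
      active = g$input$map[setdiff(mem, dr)],
      completion = g$input$map[dr],
      prospection = g$input$map[setdiff(up, stim_in)],
      background = setdiff(seq_len(n_input),
                           c(g$input$map[stim_in],
                             g$input$map[setdiff(up, stim_in)],
                             g$input$map[dr])))
    for (nm in names(groups)) {
      for (id in groups[[nm]]) {
        k <- counts[[nm]]
        if (k > 0) {
          sp_t <- c(sp_t, cyc$t_start[r] + seq_len(k) * T_low / (k + 2))
          sp_id <- c(sp_id, rep(id, k))
        }
      }
    }
  }
  result <- structure(list(
    spikes = data.frame(time_ms = sp_t, neuron_id = sp_id,
                        role = "excitatory")[order(sp_t), ],
    snapshots = list(), final = NULL, cfg = NULL, variant = "simple",
    N = n_input, duration_s = stim$duration_ms / 1000),
    class = "sim_result")
  list(result = result, stim = stim, graph = g)
}
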