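#' Stimulus calibration statistics
#'
#' Generates episode presentations with the default stimulus configuration
#' and measures the three drive statistics of the episode generator:
#' the mean number of episode-tagged spikes per participating (non-dropped)
#' input neuron per presentation; the firing rate of a driven neuron over
#' only the low-frequency cycles in which its step is being presented; and
#' the per-neuron episode-drive rate averaged over the whole trial (which
#' includes the chance of being dropped and of the neuron's episode not
#' being the one presented).
#'
#' @param n_presentations presentations to generate (>= 200 recommended)
#' @param n_input input population size
#' @param n_steps temporal steps per episode
#' @param fraction episode size as a fraction of the input population
#' @param cfg a [stimulus_config()]
#' @param seed seed
#' @return list with `spikes_per_presentation`, `active_rate_hz`,
#'   `trial_rate_hz`, `n_presentations`
#' @export
stimulus_statistics <- function(n_presentations = 220, n_input = 480,
                                n_steps = 30, fraction = 0.25,
                                cfg = stimulus_config(), seed = 1) {
  set.seed(seed)
  es <- allocate_episodes(n_input, "partitioned",
                          n_episodes = round(1 / fraction),
                          fraction = fraction, n_steps = n_steps)
  sched <- schedule_presentations(es, 1, n_presentations, cfg)
  stim <- render_episode_spikes(sched, es, cfg)
  sp <- stim$spikes
  dropped <- stim$annotations$dropped
  pres <- stim$annotations$presentations
  eps <- es$episodes
  ep_ids <- vapply(eps, function(e) e$episode_id, integer(1))
  n_trail <- length(cfg$trailing_intensities)
  driven_s <- n_trail * cfg$step_repeat / cfg$f_low
  counts_by_pres <- split(sp$neuron_id, factor(sp$pres,
                                               levels = pres$pres_idx))
  per_neuron_pres <- numeric(0)
  for (r in seq_len(nrow(pres))) {
    ep <- eps[[which(ep_ids == pres$episode_id[r])]]
    mem <- unlist(ep$steps, use.names = FALSE)
    dr <- if (is.null(dropped)) integer(0) else
      dropped$neuron_id[dropped$pres_idx == pres$pres_idx[r]]
    participants <- setdiff(mem, dr)
    cnt <- tabulate(counts_by_pres[[r]], nbins = n_input)[participants]
    per_neuron_pres <- c(per_neuron_pres, cnt)
  }
  trial_s <- stim$duration_ms / 1000
  all_members <- sort(unique(unlist(lapply(eps[vapply(eps, function(e)
    e$block_id == 1, logical(1))], function(e) unlist(e$steps)))))
  per_neuron_total <- tabulate(sp$neuron_id, nbins = n_input)[all_members]
  list(spikes_per_presentation = mean(per_neuron_pres),
       active_rate_hz = mean(per_neuron_pres / driven_s),
       trial_rate_hz = mean(per_neuron_total / trial_s),
       n_presentations = n_presentations)
}

#' Train a network on one block of episodes
#'
#' End-to-end driver: builds the requested variant, allocates a block of
#' episodes over the input population, renders the full noisy stimulus
#' (episodes, Poisson noise, pacing), and runs the engine for the whole
#' presentation schedule. The default scaled-down geometry (`N = 120`,
#' 6-step episodes, 4-episode block) keeps the per-step ensembles at the
#' same size (5 input neurons) as the full-size model's 4 while shrinking
#' the simulated duration.
#'
#' @param variant `"simple"` or `"preplay"`
#' @param N recurrent (and input) population size
#' @param n_steps temporal steps per episode
#' @param fraction episode size as a fraction of the input population
#' @param n_presentations number of presentations in the trial
#' @param cfg_stim a [stimulus_config()]
#' @param seed master seed; component seeds (topology, episode allocation,
#'   stimulus, engine noise) are derived from it
#' @param sigma_noise somatic noise s.d. (pA)
#' @param snapshot_period_s weight snapshot period (s); 0 disables
#' @param graph_args extra arguments passed to the builder
#' @return list with `graph`, `episodes`, `stim`, `result`, `trained`
#'   (the graph with final weights substituted) and `seed`
#' @export
train_episode_network <- function(variant = c("simple", "preplay"),
                                  N = 120, n_steps = 6, fraction = 0.25,
                                  n_presentations = 60,
                                  cfg_stim = stimulus_config(),
                                  seed = 1, sigma_noise = 80,
                                  snapshot_period_s = 0,
                                  graph_args = list()) {
  variant <- match.arg(variant)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 4)
  builder <- if (variant == "simple") build_simple else build_preplay
  graph <- do.call(builder, c(list(N = N, seed = sub[1]), graph_args))
  es <- allocate_episodes(N, "partitioned",
                          n_episodes = round(1 / fraction),
                          fraction = fraction, n_steps = n_steps,
                          seed = sub[2])
  stim <- make_stimulus(es, n_presentations, cfg_stim, block_id = 1,
                        seed = sub[3])
  cfg <- simulation_config(duration_s = stim$duration_ms / 1000,
                           seed = sub[4], sigma_noise = sigma_noise,
                           snapshot_period_s = snapshot_period_s)
  result <- run_network(graph, stim, cfg)
  trained <- graph
  trained$We <- result$final$We
  trained$Wi <- result$final$Wi
  list(graph = graph, episodes = es, stim = stim, result = result,
       trained = trained, seed = seed)
}

#' Relative-activity metrics of a training run
#'
#' Computes R for prospection and completion over the final
#' `tail_frac` of the presentations (after the learning curve has
#' plateaued), reusing one pass over the raster.
#'
#' @param run a [train_episode_network()] result
#' @param lookahead future steps in the prospection group
#' @param tail_frac final fraction of presentations to evaluate
#' @return list with `R_prospection`, `R_completion` (both
#'   `rmetric_result`) and the per-cycle `rows`
#' @export
evaluate_R <- function(run, lookahead = 2, tail_frac = 0.25) {
  rows <- rmetric_rows(run$result, run$stim, run$graph, lookahead)
  pres <- run$stim$annotations$presentations$pres_idx
  tail_set <- pres[pres > stats::quantile(pres, 1 - tail_frac)]
  list(R_prospection = compute_R_from_rows(rows, "prospection", tail_set,
                                           lookahead),
       R_completion = compute_R_from_rows(rows, "completion", tail_set,
                                          lookahead),
       rows = rows)
}

#' Cue-triggered recall of a trained episode
#'
#' Drives a trained network with noise, pacing and a single cue burst from
#' the first (`start`) or last (`end`) two temporal steps of one episode,
#' then scores the order of the recalled sequence in the window after the
#' cue. Forward recall from a start cue is preplay; reverse recall from an
#' end cue is replay.
#'
#' @param trained a `network_graph` with learned weights (e.g. the
#'   `trained` element of [train_episode_network()])
#' @param episode the episode to cue (an element of
#'   `episode_set$episodes`)
#' @param which_end `"start"` or `"end"`
#' @param cfg_stim a [stimulus_config()]
#' @param cue_t cue onset (ms)
#' @param duration_s run length (s)
#' @param window scoring window (ms, relative to 0); default from cue
#'   onset to the end of the run
#' @param seed seed
#' @param sigma_noise somatic noise s.d. (pA)
#' @return list with `score` (an `order_score`), `result`, `window`
#' @export
cue_recall <- function(trained, episode, which_end = c("start", "end"),
                       cfg_stim = stimulus_config(), cue_t = 1000,
                       duration_s = 6, window = NULL, seed = 1,
                       sigma_noise = 80) {
  which_end <- match.arg(which_end)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 2)
  es_dummy <- structure(list(episodes = list(episode),
                             n_input = trained$input$n_inputs,
                             mode = "cue", n_episodes = 1,
                             n_steps = length(episode$steps),
                             members_per_step = length(episode$steps[[1]]),
                             block_size = 1),
                        class = "episode_set")
  cue <- cue_pattern(episode, which_end, cfg_stim, t_start = cue_t)
  stim <- make_stimulus(es_dummy, cfg = cfg_stim, block_id = NULL,
                        duration_ms = duration_s * 1000,
                        extra = cue, seed = sub[1])
  cfg <- simulation_config(duration_s = duration_s, seed = sub[2],
                           sigma_noise = sigma_noise,
                           snapshot_period_s = 0)
  result <- run_network(trained, stim, cfg)
  if (is.null(window)) window <- c(cue_t, duration_s * 1000)
  score <- replay_order_score(result$spikes, episode, trained, window)
  list(score = score, result = result, window = window)
}
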