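test_that("partitioned allocation tiles the population in disjoint blocks of four", {
  es <- allocate_episodes(480, "partitioned", n_episodes = 12,
                          fraction = 0.25, n_steps = 30, seed = 2)
  expect_equal(es$members_per_step, 4) # 480 * 0.25 / 30
  for (b in 1:3) {
    blk <- Filter(function(e) e$block_id == b, es$episodes)
    expect_length(blk, 4)
    mem <- lapply(blk, function(e) unlist(e$steps))
    expect_true(all(lengths(mem) == 120))
    expect_equal(sort(unname(unlist(mem))), 1:480) # union covers, pairwise disjoint
  }
  steps1 <- es$episodes[[1]]$steps
  expect_length(steps1, 30)
  expect_true(all(lengths(steps1) == 4))
  expect_error(allocate_episodes(100, "partitioned", n_steps = 30),
               "divisible")
})

test_that("random allocation reuses input neurons and its usage histogram is multimodal", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  es <- allocate_episodes(8000, "random", n_episodes = 12,
                          fraction = 420 / 8000, n_steps = 30, seed = 3)
  usage <- tabulate(unlist(lapply(es$episodes, function(e)
    unlist(e$steps))), nbins = 8000)
  expect_gt(max(usage), 1) # redundant usage happens
  fit <- suppressWarnings(mclust::Mclust(usage, G = 1:3, verbose = FALSE))
  expect_gt(fit$G, 1) # >= 2 modes preferred over 1
})

test_that("presentations are uniform over the block and advance with 4-step overlap", {
  es <- allocate_episodes(480, "partitioned", n_episodes = 4,
                          fraction = 0.25, n_steps = 30, seed = 4)
  cfg <- stimulus_config()
  sched <- schedule_presentations(es, 1, 400, cfg, seed = 5)
  counts <- table(sched$presentations$episode_id)
  expect_length(counts, 4)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
  expect_equal(unique(diff(sched$presentations$start_cycle)), 30 - 4)
  # preplay step repetition: each temporal step occupies 7 consecutive cycles
  cfg7 <- stimulus_config(step_repeat = 7)
  sched7 <- schedule_presentations(es, 1, 2, cfg7, seed = 6)
  stim7 <- render_episode_spikes(sched7, es, cfg7, seed = 7)
  cyc <- stim7$annotations$cycles
  one <- cyc[cyc$pres_idx == 1 & !is.na(cyc$step), ]
  expect_equal(as.vector(table(one$step)), rep(7, 30))
  expect_equal(unique(diff(sched7$presentations$start_cycle)), (30 - 4) * 7)
})

test_that("a rendered presentation spans the episode plus trailing cycles and annotates dropout", {
  es <- allocate_episodes(480, "partitioned", n_episodes = 4,
                          fraction = 0.25, n_steps = 30, seed = 8)
  cfg <- stimulus_config()
  sched <- schedule_presentations(es, 1, 1, cfg, seed = 9)
  stim <- render_episode_spikes(sched, es, cfg, seed = 10)
  # 30 current-step cycles, trailing activity for 3 more
  expect_equal(stim$duration_ms, (30 + 3) * 1000 / 7)
  expect_equal(sum(!is.na(stim$annotations$cycles$step)), 30)
  # exactly one dropped member recorded per temporal step
  dr <- stim$annotations$dropped
  expect_equal(nrow(dr), 30)
  expect_setequal(dr$step, 1:30)
  # every spike is episode-tagged and timed inside the presentation
  expect_true(all(stim$spikes$source == "episode"))
  expect_true(all(stim$spikes$time_ms >= 0 &
                    stim$spikes$time_ms <= stim$duration_ms))
  # dropped neurons are silent for the whole presentation
  expect_length(intersect(stim$spikes$neuron_id, dr$neuron_id), 0)
})

test_that("degenerate intensities confine spikes to the cycle a step heads", {
  es <- allocate_episodes(120, "partitioned", n_episodes = 4,
                          fraction = 0.25, n_steps = 30, seed = 11)
  cfg <- stimulus_config(trailing_intensities = c(1, 0, 0, 0),
                         burst_spikes = 1, burst_scale = 1,
                         dropout_per_step = 0)
  sched <- schedule_presentations(es, 1, 1, cfg, seed = 12)
  stim <- render_episode_spikes(sched, es, cfg, seed = 13)
  counts <- table(stim$spikes$neuron_id)
  expect_true(all(counts <= 1)) # at most one spike, in the heading cycle
  ep <- es$episodes[[sched$presentations$episode_id[1]]]
  cyc <- stim$annotations$cycles
  T_low <- stim$cycle_ms
  for (r in which(!is.na(cyc$step))) {
    in_cycle <- stim$spikes[stim$spikes$time_ms >= cyc$t_start[r] &
                              stim$spikes$time_ms < cyc$t_start[r] + T_low, ]
    expect_true(all(in_cycle$neuron_id %in% ep$steps[[cyc$step[r]]]))
  }
})

test_that("episode drive calibration: ~6 spikes per participating neuron per presentation", {
  st <- stimulus_statistics(n_presentations = 120, seed = 14)
  expect_gt(st$spikes_per_presentation, 6 * 0.8)
  expect_lt(st$spikes_per_presentation, 6 * 1.2)
  expect_gt(st$active_rate_hz, 8)
  expect_lt(st$active_rate_hz, 12)
})

test_that("noise spikes are Poisson at rate nu per neuron and reproducible", {
  n <- 200; T_ms <- 2e5; nu <- 0.5
  sp <- noise_spikes(nu, 1:n, T_ms, seed = 15)
  lambda <- n * nu * T_ms / 1000
  expect_lt(abs(nrow(sp) - lambda), 3 * sqrt(lambda))
  expect_identical(noise_spikes(nu, 1:n, T_ms, seed = 16),
                   noise_spikes(nu, 1:n, T_ms, seed = 16))
  expect_equal(nrow(noise_spikes(0, 1:n, T_ms)), 0)
})

test_that("pacing train is regular at 250 Hz with fixed per-target delays in [1, 4] ms", {
  pt <- pacing_train(4000, n_targets = 100, seed = 17)
  expect_equal(length(pt$times[pt$times <= 1000]), 250)
  expect_equal(unique(diff(pt$times)), 4)
  expect_true(all(pt$delay_map >= 1 & pt$delay_map <= 4))
  expect_length(pt$delay_map, 100)
})

test_that("cue bursts come from exactly two end steps with 1-4 gamma-spaced spikes each", {
  es <- allocate_episodes(120, "partitioned", n_episodes = 4,
                          fraction = 0.25, n_steps = 6, seed = 18)
  ep <- es$episodes[[1]]
  cue_s <- cue_pattern(ep, "start", seed = 19)
  cue_e <- cue_pattern(ep, "end", seed = 20)
  expect_setequal(unique(cue_s$neuron_id), unlist(ep$steps[1:2]))
  expect_setequal(unique(cue_e$neuron_id), unlist(ep$steps[5:6]))
  expect_length(intersect(cue_s$neuron_id, cue_e$neuron_id), 0)
  sizes <- table(cue_s$neuron_id)
  expect_true(all(sizes >= 1 & sizes <= 4))
  # gamma spacing within each neuron's burst
  for (id in unique(cue_s$neuron_id)) {
    tt <- sort(cue_s$time_ms[cue_s$neuron_id == id])
    if (length(tt) > 1) expect_equal(unique(round(diff(tt), 9)),
                                     round(1000 / 49, 9))
  }
})

test_that("assembled stimuli tag every spike with a source that partitions the spike set", {
  fx <- tiny_simple_fixture()
  sp <- fx$stim$spikes
  expect_true(all(sp$source %in% c("episode", "noise", "pacing")))
  expect_false(is.unsorted(sp$time_ms))
  expect_true(all(sp$neuron_id[sp$source == "pacing"] == 0))
  # long-run episode-drive rate per participating neuron ~ 0.3 Hz at defaults
  st <- stimulus_statistics(n_presentations = 150, seed = 21)
  expect_gt(st$trial_rate_hz, 0.3 * 0.8)
  expect_lt(st$trial_rate_hz, 0.3 * 1.2)
})

test_that("stimulus rendering is deterministic under a fixed seed", {
  es <- allocate_episodes(120, "partitioned", n_episodes = 4,
                          fraction = 0.25, n_steps = 6, seed = 22)
  s1 <- make_stimulus(es, 10, stimulus_config(), seed = 23)
  s2 <- make_stimulus(es, 10, stimulus_config(), seed = 23)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$annotations$dropped, s2$annotations$dropped)
})
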