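test_that("a quiescent network stays silent with unchanged weights", {
  g <- build_simple(N = 5, seed = 1)
  es <- allocate_episodes(5, "random", n_episodes = 1, fraction = 0.2,
                          n_steps = 1, seed = 2)
  stim <- make_stimulus(es, cfg = stimulus_config(nu = 0, pacing_rate = 1e-9),
                        block_id = NULL, duration_ms = 2000, seed = 3)
  stim$spikes <- stim$spikes[0, ] # no input at all
  cfg <- simulation_config(duration_s = 2, seed = 4, sigma_noise = 0,
                           snapshot_period_s = 1)
  r <- run_network(g, stim, cfg)
  expect_equal(nrow(r$spikes), 0)
  expect_identical(r$final$We, g$We + 0)
  expect_identical(r$final$Wi, g$Wi + 0)
})

test_that("runs are bit-identical under the same configuration and seed", {
  fx <- tiny_simple_fixture()
  cfg <- simulation_config(duration_s = fx$stim$duration_ms / 1000,
                           seed = 7, sigma_noise = 80,
                           snapshot_period_s = 0)
  r1 <- run_network(fx$graph, fx$stim, cfg)
  r2 <- run_network(fx$graph, fx$stim, cfg)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$final$We, r2$final$We)
  expect_gt(nrow(r1$spikes), 0)
})

test_that("compiled engine and scalar reference produce identical spike streams (simple variant)", {
  fx <- tiny_simple_fixture(N = 8, n_presentations = 5)
  cfg <- simulation_config(duration_s = fx$stim$duration_ms / 1000,
                           seed = 31, sigma_noise = 80,
                           snapshot_period_s = 0.5)
  fast <- run_network(fx$graph, fx$stim, cfg)
  slow <- reference_run(fx$graph, fx$stim, cfg)
  expect_gt(nrow(fast$spikes), 0)
  expect_identical(fast$spikes, slow$spikes)
  expect_identical(fast$final$We, slow$final$We)
  expect_identical(fast$final$Wi, slow$final$Wi)
  expect_identical(fast$final$s, slow$final$s)
  expect_equal(length(fast$snapshots), length(slow$snapshots))
  last <- length(fast$snapshots)
  expect_identical(fast$snapshots[[last]]$We, slow$snapshots[[last]]$We)
})

test_that("compiled engine and scalar reference agree on the preplay variant", {
  g <- build_preplay(N = 6, seed = 41)
  es <- allocate_episodes(6, "partitioned", n_episodes = 2, fraction = 0.5,
                          n_steps = 3, seed = 42)
  stim <- make_stimulus(es, 3, stimulus_config(episode_overlap_steps = 1,
                                               step_repeat = 2, nu = 0.5),
                        block_id = 1, seed = 43)
  cfg <- simulation_config(duration_s = stim$duration_ms / 1000, seed = 44,
                           sigma_noise = 80, snapshot_period_s = 0)
  fast <- run_network(g, stim, cfg)
  slow <- reference_run(g, stim, cfg)
  expect_identical(fast$spikes, slow$spikes)
  expect_identical(fast$final$Wi, slow$final$Wi)
})

test_that("compiled engine and scalar reference agree on the alternate variant", {
  g <- build_alternate(Ne = 8, Ni = 3, seed = 51, input_weight = 6)
  es <- allocate_episodes(32, "random", n_episodes = 2, fraction = 0.25,
                          n_steps = 4, seed = 52)
  stim <- make_stimulus(es, 4, stimulus_config(episode_overlap_steps = 1,
                                               nu = 1), block_id = 1,
                        seed = 53)
  cfg <- simulation_config(duration_s = stim$duration_ms / 1000, seed = 54,
                           sigma_noise = 80, snapshot_period_s = 0)
  fast <- run_network(g, stim, cfg)
  slow <- reference_run(g, stim, cfg)
  expect_gt(nrow(fast$spikes), 0)
  expect_identical(fast$spikes, slow$spikes)
  expect_identical(fast$final$We, slow$final$We)
  expect_identical(fast$final$Wi, slow$final$Wi)
})

test_that("weights stay inside the plasticity bounds over a full noisy run", {
  fx <- tiny_simple_fixture(N = 16, n_presentations = 8)
  cfg <- simulation_config(duration_s = fx$stim$duration_ms / 1000,
                           seed = 61, sigma_noise = 120,
                           snapshot_period_s = 0.5)
  r <- run_network(fx$graph, fx$stim, cfg)
  for (sn in r$snapshots) {
    expect_true(all(sn$We >= 0 & sn$We <= fx$graph$triplet$w_max_e))
    expect_true(all(sn$Wi >= 0 & sn$Wi <= fx$graph$tophat$w_max_i))
  }
  expect_true(all(r$final$We >= 0 & r$final$We <= 0.8))
  expect_true(all(r$final$Wi >= 0 & r$final$Wi <= 0.8))
})

test_that("delay causality: no recurrent activity precedes the first input delivery", {
  g <- build_simple(N = 5, seed = 71, input_weight = 10)
  es <- allocate_episodes(5, "random", n_episodes = 1, fraction = 0.2,
                          n_steps = 1, seed = 72)
  one_spike <- data.frame(time_ms = 500, neuron_id = 3L, source = "noise")
  stim <- structure(list(spikes = one_spike, annotations = NULL,
                         cfg = stimulus_config(), episode_set = es,
                         n_steps = 1, cycle_ms = 1000 / 7,
                         duration_ms = 1500),
                    class = "stimulus_schedule")
  cfg <- simulation_config(duration_s = 1.5, seed = 73, sigma_noise = 0,
                           snapshot_period_s = 0)
  r <- run_network(g, stim, cfg)
  expect_gt(nrow(r$spikes), 0)
  expect_true(all(r$spikes$time_ms > 500 + g$input$delay - 0.5))
  # the driven neuron spikes and its deliveries reach every other neuron
  expect_true(all(r$final$Ge[-g$input$map[3]] > 0))
})

test_that("spike deliveries superpose linearly and homeostatic scale is absent at delivery", {
  pools <- list(Ge = 0, Gi = 0, Gi2 = 0)
  pools <- deliver_spike(pools, "e", 0.3)
  pools <- deliver_spike(pools, "e", 0.5)
  expect_equal(pools$Ge, 0.8)
  pools <- deliver_spike(pools, "i", 0.4)
  expect_equal(pools$Gi, 0.4)
  # with s = 0 the inhibitory current is fully retained
  expect_equal(synaptic_current(-60, s = 0, G_e = pools$Ge, G_i = pools$Gi),
               0.4 * (-81 + 60))
})

test_that("weight snapshots are pure copies and bound violations are hard failures", {
  g <- build_simple(N = 6, seed = 81)
  s1 <- snapshot_weights(g, 0)
  s2 <- snapshot_weights(g, 0)
  expect_identical(s1$We, s2$We)
  expect_identical(s1$We, g$We + 0)
  bad <- g
  bad$We[2, 3] <- 99
  expect_error(snapshot_weights(bad, 1), "invariant")
})

test_that("burst alarms fire on synchronous rasters and are monotone in the threshold", {
  quiet <- data.frame(time_ms = c(10, 500), neuron_id = c(1L, 2L))
  expect_equal(nrow(stability_monitor(quiet, 100, 20, 0.5)), 0)
  burst <- data.frame(time_ms = runif(100, 100, 110),
                      neuron_id = 1:100)
  expect_gt(nrow(stability_monitor(burst, 100, 20, 0.5)), 0)
  mixed <- rbind(burst, data.frame(time_ms = runif(60, 300, 310),
                                   neuron_id = 1:60))
  n_alarm <- vapply(c(0.1, 0.5, 0.9),
                    function(th) nrow(stability_monitor(mixed, 100, 20, th)),
                    numeric(1))
  expect_true(all(diff(n_alarm) <= 0))
})

test_that("noise-driven homeostasis pulls the median firing rate into the target band", {
  g <- build_simple(N = 30, seed = 91)
  es <- allocate_episodes(30, "partitioned", n_episodes = 2, fraction = 0.5,
                          n_steps = 3, seed = 92)
  stim <- make_stimulus(es, cfg = stimulus_config(), block_id = NULL,
                        duration_ms = 5000e3, seed = 93)
  cfg <- simulation_config(duration_s = 5000, seed = 94, sigma_noise = 80,
                           snapshot_period_s = 0)
  r <- run_network(g, stim, cfg)
  late <- r$spikes[r$spikes$time_ms >= 2500e3, ]
  rate <- tabulate(late$neuron_id, 30) / 2500
  med_target <- median(g$omega_D)
  expect_gt(median(rate), med_target / 2)
  expect_lt(median(rate), 2 * med_target)
})
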