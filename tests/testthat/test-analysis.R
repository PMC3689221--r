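test_that("the relative-activity metric evaluates the ratio of rate differences", {
  # crafted raster: background 1, prospection 2, completion 3, active 5
  # spikes per neuron per bin -> R_pros = (2-1)/(5-1), R_compl = (3-1)/(5-1)
  sc <- crafted_metric_scenario(c(active = 5, completion = 3,
                                  prospection = 2, background = 1))
  rp <- compute_R(sc$result, sc$stim, sc$graph, "prospection")
  rc <- compute_R(sc$result, sc$stim, sc$graph, "completion")
  expect_equal(rp$R, 0.25, tolerance = 1e-9)
  expect_equal(rc$R, 0.5, tolerance = 1e-9)
  # mu_group == mu_background -> R = 0; mu_group == mu_active -> R = 1
  sc0 <- crafted_metric_scenario(c(active = 5, completion = 5,
                                   prospection = 1, background = 1))
  expect_equal(compute_R(sc0$result, sc0$stim, sc0$graph, "prospection")$R, 0)
  expect_equal(compute_R(sc0$result, sc0$stim, sc0$graph, "completion")$R, 1)
})

test_that("the metric is invariant to uniform rescaling of all rates", {
  sc1 <- crafted_metric_scenario(c(active = 6, completion = 4,
                                   prospection = 2, background = 1))
  sc2 <- crafted_metric_scenario(c(active = 12, completion = 8,
                                   prospection = 4, background = 2))
  r1 <- compute_R(sc1$result, sc1$stim, sc1$graph, "prospection")$R
  r2 <- compute_R(sc2$result, sc2$stim, sc2$graph, "prospection")$R
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("an undefined denominator is flagged, not silently zeroed", {
  sc <- crafted_metric_scenario(c(active = 1, completion = 1,
                                  prospection = 1, background = 1))
  expect_warning(r <- compute_R(sc$result, sc$stim, sc$graph, "prospection"),
                 "undefined")
  expect_false(r$defined)
  expect_true(is.na(r$R))
})

test_that("learning curves are flat under a stationary null and rise for ramping prospection", {
  sc <- crafted_metric_scenario(c(active = 5, completion = 3,
                                  prospection = 2, background = 1))
  lc <- learning_curve(sc$result, sc$stim, sc$graph)
  expect_true(all(abs(lc$R_prospection - 0.25) < 1e-9))
  expect_equal(lc$aligned_idx, lc$pres_idx - min(lc$pres_idx))
})

test_that("rate maps are causal, unit-preserving, and conserve smoothed mass", {
  empty <- rate_map(data.frame(time_ms = numeric(0), neuron_id = integer(0)),
                    n_neurons = 3)
  expect_true(all(empty == 0))
  one <- data.frame(time_ms = 500, neuron_id = 2L)
  m <- rate_map(one, n_neurons = 3)
  bin_s <- 1 / 7
  b0 <- floor(0.5 / bin_s) + 1
  expect_true(all(m[, seq_len(b0 - 1)] == 0)) # zero before the spike bin
  expect_true(m[2, b0] > 0)
  k <- exp(-(0:2) * bin_s / (1 / 7)); k <- k / sum(k)
  expect_equal(m[2, b0 + 0:2] / m[2, b0], k / k[1], tolerance = 1e-9)
  expect_equal(sum(m[2, ]) * bin_s, 1, tolerance = 1e-9) # one spike of mass
  many <- data.frame(time_ms = runif(200, 0, 3000),
                     neuron_id = sample(1:3, 200, replace = TRUE))
  mm <- rate_map(many, n_neurons = 3)
  expect_equal(sum(mm) * bin_s, 200, tolerance = 1e-6)
})

test_that("order scores are +1 for forward templates, -1 for reverse, ~0 under shuffles", {
  g <- build_simple(N = 40, seed = 101)
  es <- allocate_episodes(40, "partitioned", n_episodes = 4,
                          fraction = 0.25, n_steps = 10, seed = 102)
  ep <- es$episodes[[1]]
  mem <- unlist(ep$steps)
  stp <- rep(1:10, each = 1)
  rid <- g$input$map[mem]
  fwd <- data.frame(time_ms = 100 + 10 * stp, neuron_id = rid)
  s_fwd <- replay_order_score(fwd, ep, g, c(0, 1000), seed = 103)
  expect_equal(s_fwd$rho, 1)
  expect_identical(s_fwd$direction, "forward")
  rev <- data.frame(time_ms = 100 + 10 * (11 - stp), neuron_id = rid)
  s_rev <- replay_order_score(rev, ep, g, c(0, 1000), seed = 104)
  expect_equal(s_rev$rho, -1)
  expect_identical(s_rev$direction, "reverse")
  # random orderings: mean rho near 0 and mostly below the shuffle threshold
  set.seed(105)
  rhos <- replicate(40, {
    rnd <- data.frame(time_ms = 100 + sample(10 * (1:10)), neuron_id = rid)
    replay_order_score(rnd, ep, g, c(0, 1000), n_shuffle = 200)$rho
  })
  expect_lt(abs(mean(rhos)), 0.2)
  # too few participants: no call
  few <- data.frame(time_ms = c(1, 2, 3), neuron_id = rid[1:3])
  expect_identical(replay_order_score(few, ep, g, c(0, 1000))$direction,
                   "none")
})

test_that("segment angles recover orthogonal and collinear synthetic trajectories", {
  set.seed(106)
  n_per <- 12
  seg <- function(dir, origin) {
    t(sapply(seq(0, 1, length.out = n_per), function(a) origin + a * dir)) +
      matrix(rnorm(n_per * 3, 0, 0.004), n_per, 3)
  }
  X <- rbind(seg(c(1, 0, 0), c(0, 0, 0)),
             seg(c(0, 1, 0), c(1, 0, 0)),
             seg(c(0, 0, 1), c(1, 1, 0)))
  snaps <- lapply(seq_len(nrow(X)), function(i) X[i, ])
  groups <- rep(c("g1", "g2", "g3"), each = n_per)
  res <- weight_segment_angles(snaps, groups, embed_dim = 3,
                               k = nrow(X) - 1)
  offd <- res$angles[upper.tri(res$angles)]
  expect_true(all(abs(offd - 90) < 5))
  expect_true(all(abs(res$angles_raw[upper.tri(res$angles_raw)] - 90) < 5))
  # collinear segments
  Xc <- rbind(seg(c(1, 0, 0), c(0, 0, 0)), seg(c(1, 0, 0), c(1, 0, 0)))
  resc <- weight_segment_angles(lapply(seq_len(nrow(Xc)),
                                       function(i) Xc[i, ]),
                                rep(c("a", "b"), each = n_per),
                                embed_dim = 3, k = nrow(Xc) - 1)
  expect_lt(resc$angles["a", "b"], 5)
  # deterministic under identical inputs
  res2 <- weight_segment_angles(snaps, groups, embed_dim = 3,
                                k = nrow(X) - 1)
  expect_identical(res$angles, res2$angles)
})
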