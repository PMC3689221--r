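test_that("resting potential is stationary and the reset map follows the spike rule", {
  p <- default_neuron()
  st <- neuron_state(v = p$vr, u = 0, s = 1)
  out <- integrate_step(st, p, I_syn = 0, I_noise = 0, dt = 0.5)
  expect_false(out$spiked)
  expect_equal(out$state$v, -60)
  expect_equal(out$state$u, 0)

  # v above the cutoff spikes and resets to c with u increased by d
  st2 <- neuron_state(v = 45, u = 0)
  out2 <- integrate_step(st2, p, dt = 0.5)
  expect_true(out2$spiked)
  expect_equal(out2$state$v, p$c)
  expect_equal(out2$state$v, -40)
  # u gains d = 55 pA on top of its Euler update
  du <- 0.5 * p$a * (p$b * (45 - p$vr) - 0)
  expect_equal(out2$state$u, du + 55)
})

test_that("spike reset decrements the homeostatic scale by 1/tau_omega and clamps at zero", {
  p <- default_neuron()
  h <- homeostasis_params(omega_D = 0.3, tau_omega = 600)
  st <- neuron_state(v = 45, u = 10, s = 1)
  st2 <- spike_reset(st, p, h)
  expect_equal(st2$s, 1 - 1 / 600)
  expect_equal(st2$u, 65)
  st3 <- spike_reset(st2, p, h)
  expect_equal(st3$s, 1 - 2 / 600)
  low <- spike_reset(neuron_state(v = 45, u = 0, s = 1e-4), p, h)
  expect_identical(low$s, 0)
})

test_that("homeostatic drift is linear and cancels per-spike decrements at the target rate", {
  h <- homeostasis_params(omega_D = 0.3, tau_omega = 600)
  st <- neuron_state(s = 1)
  st2 <- homeostatic_drift(st, h, dt = 600e3) # 600 s in ms
  expect_equal(st2$s - st$s, 0.3)
  # firing at exactly omega_D for T: drift == total decrement
  T_s <- 50
  n_spk <- 0.3 * T_s
  drift <- 0.3 * T_s / 600
  expect_equal(drift, n_spk / 600)
  # omega_D = 0: s is non-increasing under drift
  h0 <- homeostasis_params(omega_D = 0, tau_omega = 600)
  expect_equal(homeostatic_drift(st, h0, dt = 1e5)$s, st$s)
})

test_that("forced-rate homeostatic drift matches (omega_D - r) T / tau_omega within 3 s.e.", {
  set.seed(902)
  h <- homeostasis_params(omega_D = 0.3, tau_omega = 600)
  p <- default_neuron()
  r_force <- 1.2 # Hz
  T_s <- 40
  n_rep <- 150
  deltas <- replicate(n_rep, {
    st <- neuron_state(v = p$vr, u = 0, s = 5) # high start so the clamp never binds
    n_spk <- rpois(1, r_force * T_s)
    for (i in seq_len(n_spk)) st <- spike_reset(st, p, h)
    st <- homeostatic_drift(st, h, dt = T_s * 1000)
    st$s - 5
  })
  expected <- (0.3 - r_force) * T_s / 600
  se <- sd(deltas) / sqrt(n_rep)
  expect_lt(abs(mean(deltas) - expected), 3 * se + 1e-12)
})

test_that("synaptic current follows s*Ge*(Ee-v) + Gi*(Ei-v) with s on the excitatory term only", {
  expect_equal(synaptic_current(v = 0, s = 1, G_e = 5, G_i = 0, E_e = 0), 0)
  expect_equal(synaptic_current(v = -50, s = 0, G_e = 7, G_i = 0), 0)
  expect_equal(synaptic_current(v = -60, s = 1, G_e = 1, G_i = 0, E_e = 0), 60)
  # s = 0 leaves the inhibitory term untouched
  expect_equal(synaptic_current(v = -60, s = 0, G_e = 3, G_i = 2, E_i = -81),
               2 * (-81 + 60))
  # linear separately in G_e and G_i
  base <- synaptic_current(-55, 0.7, 2, 3)
  expect_equal(synaptic_current(-55, 0.7, 4, 3) - base,
               base - synaptic_current(-55, 0.7, 0, 3))
  expect_equal(synaptic_current(-55, 0.7, 2, 6) - base,
               base - synaptic_current(-55, 0.7, 2, 0))
  expect_error(synaptic_current(-55, 1, -1, 0), "non-negative")
})

test_that("conductance decay is exponential, monotone, and identity at dt = 0", {
  expect_equal(decay_conductance(1, tau = 50, dt = 50), exp(-1))
  expect_equal(decay_conductance(3.2, tau = 35, dt = 0), 3.2)
  expect_equal(decay_conductance(0, tau = 35, dt = 123), 0)
  g <- 1
  for (i in 1:10) {
    g2 <- decay_conductance(g, tau = 35, dt = 0.5)
    expect_lt(g2, g)
    g <- g2
  }
})

test_that("0.5 ms integration matches a 0.01 ms reference on spike counts for constant drive", {
  p <- default_neuron()
  count_spikes <- function(I, dt, T_ms) {
    st <- neuron_state(v = p$vr, u = 0)
    n <- 0L
    for (i in seq_len(round(T_ms / dt))) {
      out <- integrate_step(st, p, I_syn = I, dt = dt)
      st <- out$state
      if (out$spiked) n <- n + 1L
    }
    n
  }
  # exact to +/- 1 spike/s over the physiological drive range ...
  for (I in c(0, 30, 60, 100)) {
    expect_lte(abs(count_spikes(I, 0.5, 1000) - count_spikes(I, 0.01, 1000)),
               1)
  }
  # ... and within a few percent under sustained strong drive, where the
  # above-threshold reset (c = -40 > vt) makes the limit-cycle period
  # sensitive to the integration step
  for (I in c(200, 500)) {
    n_fine <- count_spikes(I, 0.01, 1000)
    expect_lte(abs(count_spikes(I, 0.5, 1000) - n_fine), 0.1 * n_fine)
  }
})

test_that("non-finite inputs are rejected with a diagnostic naming the quantity", {
  p <- default_neuron()
  st <- neuron_state()
  expect_error(integrate_step(st, p, I_syn = NaN), "I_syn")
  expect_error(integrate_step(st, p, I_noise = Inf), "I_noise")
  bad <- neuron_state(); bad$v <- Inf
  expect_error(integrate_step(bad, p), "v")
})
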