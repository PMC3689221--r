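#' Simulation configuration
#'
#' @param duration_s simulated duration (s)
#' @param dt integration step (ms)
#' @param seed seed for the engine's noise stream
#' @param sigma_noise standard deviation of the zero-mean gaussian somatic
#'   noise current (pA), drawn independently per neuron per step
#' @param snapshot_period_s period of weight-matrix snapshots (s);
#'   `0` disables periodic snapshots
#' @param record_spikes record the spike raster
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(duration_s, dt = 0.5, seed = 1,
                              sigma_noise = 80, snapshot_period_s = 10,
                              record_spikes = TRUE) {
  stopifnot(dt > 0, duration_s > 0, sigma_noise >= 0,
            snapshot_period_s >= 0,
            snapshot_period_s == 0 || snapshot_period_s * 1000 >= dt)
  structure(list(duration_s = duration_s, dt = dt, seed = seed,
                 sigma_noise = sigma_noise,
                 snapshot_period_s = snapshot_period_s,
                 record_spikes = record_spikes),
            class = "simulation_config")
}

# nearest-dt-multiple rounding, identical in both engines (no banker's
# rounding); delays are at least one step so no delivery is instantaneous
delay_steps <- function(delay_ms, dt) {
  pmax(1L, as.integer(floor(delay_ms / dt + 0.5)))
}

# branch parameterization of a top-hat rule: c(inner, outer, d_in, d_out)
tophat_branches <- function(p) {
  if (p$literal_mode) {
    c(p$tau_ltd_i, p$tau_ltp_i, -p$delta_ltd_i, p$delta_ltp_i)
  } else if (p$inverted) {
    c(p$tau_inner, p$tau_outer, -p$delta_ltd_i, p$delta_ltp_i)
  } else {
    c(p$tau_inner, p$tau_outer, p$delta_ltp_i, -p$delta_ltd_i)
  }
}

# shared, deterministic preparation of engine arguments so the compiled
# engine and the scalar reference receive bit-identical inputs
engine_inputs <- function(graph, stim, cfg) {
  dt <- cfg$dt
  n_total <- as.integer(ceiling(cfg$duration_s * 1000 / dt))
  N <- graph$N
  DeS <- matrix(0L, N, N)
  DiS <- matrix(0L, N, N)
  eidx <- graph$Ae == 1L
  iidx <- graph$Ai == 1L
  DeS[eidx] <- delay_steps(graph$De[eidx], dt)
  DiS[iidx] <- delay_steps(graph$Di[iidx], dt)
  sp <- stim$spikes
  sp <- sp[sp$time_ms >= 0 & sp$time_ms <= cfg$duration_s * 1000, ,
           drop = FALSE]
  ext_step <- as.integer(floor(sp$time_ms / dt))
  keep <- ext_step < n_total
  ext_step <- ext_step[keep]
  ext_id <- ifelse(sp$source[keep] == "pacing", -1L,
                   as.integer(sp$neuron_id[keep]) - 1L)
  o <- order(ext_step)
  input <- graph$input
  if (input$mode == "one_to_one") {
    in_off <- 0:input$n_inputs
    in_targets <- as.integer(input$map) - 1L
  } else {
    ed <- input$edges[order(input$edges$input), , drop = FALSE]
    cnt <- tabulate(ed$input, nbins = input$n_inputs)
    in_off <- c(0L, cumsum(cnt))
    in_targets <- as.integer(ed$target) - 1L
  }
  ihwin <- rbind(tophat_branches(graph$tophat),
                 tophat_branches(graph$tophat_ii))
  role_code <- match(graph$roles, c("excitatory", "inhibitory", "feedback"))
  list(
    N = N, roles = as.integer(role_code),
    pa = graph$neuron$a, pb = graph$neuron$b, pc = graph$neuron$c,
    pd = graph$neuron$d, pvr = graph$neuron$vr, pvt = graph$neuron$vt,
    pvp = graph$neuron$vp, pC = graph$neuron$C, pk = graph$neuron$k,
    pform = as.integer(graph$neuron$form),
    We = graph$We + 0, Wi = graph$Wi + 0,
    Ae = graph$Ae, Ai = graph$Ai, DeS = DeS, DiS = DiS,
    ruleE = graph$ruleE, ruleI = graph$ruleI,
    triplet = graph$triplet, ihwin = ihwin,
    wmax_i = graph$tophat$w_max_i,
    omegaD = graph$omega_D, tau_omega = graph$homeo$tau_omega,
    Ee = graph$syn$E_e, Ei = graph$syn$E_i,
    dec_e = exp(-dt / graph$syn$tau_e),
    dec_i1 = exp(-dt / graph$syn$tau_i),
    dec_i2 = exp(-dt / graph$syn$tau_i2),
    ipool = as.integer(graph$ipool),
    in_off = as.integer(in_off), in_targets = in_targets,
    in_w = input$weight,
    in_delay_steps = delay_steps(input$delay, dt),
    pacing_delay_steps = delay_steps(input$pacing_delay, dt),
    pacing_w = input$pacing_weight,
    ext_step = ext_step[o], ext_id = as.integer(ext_id[o]),
    dt = dt, n_total = n_total, sigma = cfg$sigma_noise,
    snap_period = if (cfg$snapshot_period_s > 0)
      as.integer(floor(cfg$snapshot_period_s * 1000 / dt + 0.5)) else 0L,
    record_spikes = isTRUE(cfg$record_spikes),
    v0 = graph$neuron$vr, u0 = rep(0, N), s0 = rep(1, N))
}

finish_run <- function(raw, args, graph, cfg) {
  spikes <- data.frame(
    time_ms = (raw$sp_step + 1) * args$dt,
    neuron_id = raw$sp_id,
    role = graph$roles[raw$sp_id])
  snaps <- c(list(list(time_s = 0, We = args$We, Wi = args$Wi)),
             raw$snapshots)
  structure(list(spikes = spikes, snapshots = snaps,
                 final = list(v = raw$v, u = raw$u, s = raw$s,
                              Ge = raw$Ge, Gi1 = raw$Gi1, Gi2 = raw$Gi2,
                              We = raw$We, Wi = raw$Wi),
                 cfg = cfg, variant = graph$variant,
                 N = graph$N, duration_s = cfg$duration_s),
            class = "sim_result")
}

#' Run a network simulation
#'
#' Advances the full network in fixed steps of `cfg$dt`. Each step, in
#' order: conductance pools decay; delayed deliveries due this step are
#' added; external input spikes emitted this step are enqueued through the
#' input projection (and the pacing input through its per-target fixed
#' delays); per-neuron gaussian noise currents are drawn; all neurons are
#' integrated (hybrid Euler, reset within the step); spikes trigger the
#' homeostatic decrement, STDP on their plastic afferent and efferent
#' synapses (against pre-step spike history; simultaneous spikes pair at
#' zero lag) and enqueue deliveries at `t + delay` with the post-update
#' weights; finally the homeostatic scale drifts upward. The run is fully
#' deterministic under `cfg$seed`. [reference_run()] is a scalar R
#' implementation of the identical schedule used for cross-validation.
#'
#' @param graph a `network_graph`
#' @param stim a `stimulus_schedule` (see [make_stimulus()])
#' @param cfg a [simulation_config()]
#' @return an object of class `sim_result`: `spikes` (data.frame `time_ms`,
#'   `neuron_id`, `role`), `snapshots` (list of `time_s`, `We`, `Wi`,
#'   including the initial state), and `final` state vectors and matrices
#' @export
run_network <- function(graph, stim, cfg) {
  args <- engine_inputs(graph, stim, cfg)
  set.seed(cfg$seed)
  raw <- do.call(engine_run_cpp, args)
  finish_run(raw, args, graph, cfg)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", x$variant, "variant,", x$N, "neurons,",
      x$duration_s, "s simulated\n")
  cat("  spikes:", nrow(x$spikes), "( mean rate",
      round(nrow(x$spikes) / x$N / x$duration_s, 3), "Hz )\n")
  cat("  weight snapshots:", length(x$snapshots), "\n")
  invisible(x)
}

#' Add a spike delivery to a conductance pool
#'
#' A delivered spike increases the target's conductance pool matching the
#' synapse's type by the synapse weight. The homeostatic scale `s` is
#' applied to the excitatory pool only when the synaptic current is
#' evaluated, never at delivery, so deliveries superpose linearly.
#'
#' @param pools `list(Ge = , Gi = , Gi2 = )` conductances (nS)
#' @param type `"e"`, `"i"` or `"i2"` (slow inhibitory pool)
#' @param weight synapse weight (nS)
#' @return the updated pools list
#' @export
deliver_spike <- function(pools, type = c("e", "i", "i2"), weight) {
  type <- match.arg(type)
  stopifnot(weight >= 0)
  slot <- switch(type, e = "Ge", i = "Gi", i2 = "Gi2")
  pools[[slot]] <- pools[[slot]] + weight
  pools
}

#' Snapshot the weight matrices
#'
#' Copies the current excitatory and inhibitory weight matrices, asserting
#' the plasticity bounds; a bound violation is an invariant breach and
#' raises an error.
#'
#' @param graph a `network_graph` (or any list with `We`, `Wi`, `triplet`,
#'   `tophat` entries)
#' @param t snapshot time (s)
#' @return `list(time_s, We, Wi)` of class `weight_snapshot`
#' @export
snapshot_weights <- function(graph, t = 0) {
  We <- graph$We + 0
  Wi <- graph$Wi + 0
  if (any(We < 0) || any(We > graph$triplet$w_max_e + 1e-12)) {
    stop("excitatory weight outside [0, w_max_e]: invariant breach")
  }
  if (any(Wi < 0) || any(Wi > graph$tophat$w_max_i + 1e-12)) {
    stop("inhibitory weight outside [0, w_max_i]: invariant breach")
  }
  structure(list(time_s = t, We = We, Wi = Wi), class = "weight_snapshot")
}

#' Population burst alarm monitor
#'
#' Scans a spike raster with a sliding window and emits an alarm event for
#' every window in which more than `threshold` of the recurrent population
#' spikes, a diagnostic for runaway cascade/burst activity. Never mutates
#' simulation state.
#'
#' @param spikes spike data.frame (`time_ms`, `neuron_id`)
#' @param n_neurons recurrent population size
#' @param window_ms window length (ms)
#' @param threshold fraction of the population
#' @return data.frame (`window_start_ms`, `fraction`) of alarm windows
#' @export
stability_monitor <- function(spikes, n_neurons, window_ms = 20,
                              threshold = 0.5) {
  stopifnot(window_ms > 0, n_neurons >= 1)
  if (nrow(spikes) == 0) {
    return(data.frame(window_start_ms = numeric(0), fraction = numeric(0)))
  }
  win <- floor(spikes$time_ms / window_ms)
  frac <- vapply(split(spikes$neuron_id, win),
                 function(id) length(unique(id)) / n_neurons, numeric(1))
  starts <- as.numeric(names(frac)) * window_ms
  alarm <- frac > threshold
  data.frame(window_start_ms = starts[alarm], fraction = frac[alarm],
             row.names = NULL)
}
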