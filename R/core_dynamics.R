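#' Neuron state
#'
#' Instantaneous state of one neuron: membrane voltage `v` (mV), recovery
#' variable `u` (pA) and the homeostatic excitatory input scale `s`
#' (dimensionless, clamped at 0 from below, initialized at 1).
#'
#' @param v membrane voltage (mV)
#' @param u recovery variable (pA)
#' @param s homeostatic excitatory scale
#' @return an object of class `neuron_state`
#' @export
neuron_state <- function(v = -60, u = 0, s = 1) {
  stopifnot(is.finite(v), is.finite(u), is.finite(s), s >= 0)
  structure(list(v = v, u = u, s = s), class = "neuron_state")
}

#' One forward-Euler / hybrid integration step of a single neuron
#'
#' Advances `u` by forward Euler and `v` by the hybrid scheme: after the
#' Euler update of `v`, the spike cutoff is checked and, if `v >= vp`, the
#' spike is registered and the reset applied within the same step. The spike
#' time is attributed to the end-of-step boundary. If `homeo` is supplied
#' the reset also applies the homeostatic decrement (see [spike_reset()]);
#' otherwise only `v` and `u` are reset.
#'
#' @param state a [neuron_state()]
#' @param params a [neuron_params()]
#' @param I_syn synaptic current (pA)
#' @param I_noise somatic noise current (pA)
#' @param dt time step (ms)
#' @param homeo optional [homeostasis_params()] applied on reset
#' @return `list(state = <neuron_state>, spiked = <logical>)`
#' @export
integrate_step <- function(state, params, I_syn = 0, I_noise = 0, dt = 0.5,
                           homeo = NULL) {
  if (!is.finite(I_syn)) stop("I_syn is not finite")
  if (!is.finite(I_noise)) stop("I_noise is not finite")
  if (!is.finite(state$v)) stop("membrane voltage v is not finite")
  if (!is.finite(state$u)) stop("recovery variable u is not finite")
  stopifnot(dt > 0)
  v <- state$v
  u <- state$u
  if (params$model_form == "quadratic_2007") {
    dv <- (params$k * (v - params$vr) * (v - params$vt) - u + I_syn + I_noise) / params$C
    du <- params$a * (params$b * (v - params$vr) - u)
  } else {
    dv <- (0.04 * v * v + 5 * v + 140 - u + I_syn + I_noise) / params$C
    du <- params$a * (params$b * v - u)
  }
  u_new <- u + dt * du
  v_new <- v + dt * dv
  st <- state
  st$u <- u_new
  st$v <- v_new
  if (v_new >= params$vp) {
    if (is.null(homeo)) {
      st$v <- params$c
      st$u <- st$u + params$d
    } else {
      st <- spike_reset(st, params, homeo)
    }
    list(state = st, spiked = TRUE)
  } else {
    list(state = st, spiked = FALSE)
  }
}

#' Post-spike reset
#'
#' Applies the discontinuous spike map: `v <- c`, `u <- u + d`, and the
#' homeostatic decrement `s <- s - 1 / tau_omega` (with `tau_omega` in
#' seconds), clamped at 0 from below.
#'
#' @inheritParams integrate_step
#' @param homeo a [homeostasis_params()]
#' @return the updated `neuron_state`
#' @export
spike_reset <- function(state, params, homeo) {
  state$v <- params$c
  state$u <- state$u + params$d
  state$s <- max(0, state$s - 1 / homeo$tau_omega)
  state
}

#' Homeostatic upward drift of the excitatory input scale
#'
#' Between spikes, the scale grows linearly at rate `omega_D / tau_omega`
#' per second: over an interval `dt` (ms), `s` increases by
#' `omega_D * (dt / 1000) / tau_omega`. Combined with the per-spike
#' decrement, `s` is stationary in expectation exactly when the neuron fires
#' at `omega_D`.
#'
#' @param state a [neuron_state()]
#' @param homeo a [homeostasis_params()]; a range `omega_D` uses its midpoint
#' @param dt elapsed time (ms)
#' @return the updated `neuron_state`
#' @export
homeostatic_drift <- function(state, homeo, dt) {
  stopifnot(dt >= 0)
  omega <- mean(homeo$omega_D)
  state$s <- state$s + omega * (dt / 1000) / homeo$tau_omega
  state
}

#' Total synaptic current from the conductance pools
#'
#' \deqn{I_{syn} = s G_e (E_e - v) + G_i (E_i - v)}
#' The homeostatic scale multiplies only the excitatory term.
#'
#' @param v membrane voltage (mV)
#' @param s homeostatic excitatory scale
#' @param G_e total excitatory conductance (nS)
#' @param G_i total inhibitory conductance (nS)
#' @param E_e,E_i reversal potentials (mV)
#' @return synaptic current (pA)
#' @export
synaptic_current <- function(v, s, G_e, G_i, E_e = 0, E_i = -81) {
  if (any(G_e < 0) || any(G_i < 0)) stop("conductances must be non-negative")
  s * G_e * (E_e - v) + G_i * (E_i - v)
}

#' Exponential conductance decay
#'
#' Conductance pools decay as `g * exp(-dt / tau)` between deliveries;
#' spike deliveries add weight-sized increments separately.
#'
#' @param g conductance (nS)
#' @param tau decay time constant (ms)
#' @param dt elapsed time (ms)
#' @return the decayed conductance (nS)
#' @export
decay_conductance <- function(g, tau, dt) {
  stopifnot(all(g >= 0), tau > 0, dt >= 0)
  g * exp(-dt / tau)
}
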