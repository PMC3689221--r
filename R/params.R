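#' Neuron parameter set
#'
#' Parameters of the hybrid Izhikevich neuron in one of two forms: the
#' nine-parameter quadratic form
#' \deqn{C v' = k (v - v_r)(v - v_t) - u + I_{syn} + I_{noise}}
#' \deqn{u' = a (b (v - v_r) - u)}
#' or the classic four-parameter form
#' \deqn{C v' = 0.04 v^2 + 5 v + 140 - u + I_{syn} + I_{noise}}
#' \deqn{u' = a (b v - u)}
#' where `C` acts as a capacitance-like divisor (1 in the classic
#' parameterization). On a spike (`v >= vp`), `v <- c` and `u <- u + d`.
#'
#' @param a recovery rate (1/ms)
#' @param b recovery coupling (nS)
#' @param c reset voltage (mV)
#' @param d recovery increment (pA)
#' @param vr resting potential (mV)
#' @param vt instantaneous threshold (mV)
#' @param vp spike peak / cutoff (mV)
#' @param C membrane capacitance (pF), or the capacitance-like divisor for
#'   the four-parameter form
#' @param k voltage-curvature gain (pA/mV^2); unused by the four-parameter form
#' @param model_form `"quadratic_2007"` or `"simple_2003"`
#' @return an object of class `neuron_params`
#' @export
neuron_params <- function(a = 0.02, b = 0.5, c = -40, d = 55,
                          vr = -60, vt = -45, vp = 40, C = 50, k = 0.5,
                          model_form = c("quadratic_2007", "simple_2003")) {
  model_form <- match.arg(model_form)
  stopifnot(is.finite(c(a, b, c, d, vr, vt, vp, C, k)))
  if (C <= 0) stop("C must be > 0")
  if (!(vr < vt && vt < vp)) stop("need vr < vt < vp")
  if (c >= vp) stop("reset voltage c must be below the spike peak vp")
  structure(list(a = a, b = b, c = c, d = d, vr = vr, vt = vt, vp = vp,
                 C = C, k = k, model_form = model_form),
            class = "neuron_params")
}

#' Default neuron parameter sets
#'
#' `default_neuron()` is the quadratic-form regular neuron used by the simple
#' network (a = 0.02, b = 0.5 nS, c = -40 mV, d = 55 pA, vr = -60 mV,
#' vt = -45 mV, vp = 40 mV, C = 50 pF, k = 0.5).
#' `fs_neuron()` is a classic four-parameter fast-spiking interneuron
#' (a = 0.1, b = 0.2, c = -65, d = 2) used for the inhibitory population of
#' the alternate variant. `preplay_neuron()` is the four-parameter
#' regular-spiking set (a = 0.02, b = 0.2, c = -65, d = 8) with the
#' capacitance-like divisor raised to 1000, `a` reduced 1000-fold and `d`
#' reduced 10-fold, giving the slow, stable dynamics of the preplay variant.
#'
#' @return a `neuron_params` object
#' @export
default_neuron <- function() neuron_params()

#' @rdname default_neuron
#' @export
fs_neuron <- function() {
  neuron_params(a = 0.1, b = 0.2, c = -65, d = 2,
                vr = -60, vt = -45, vp = 30, C = 1, k = 0,
                model_form = "simple_2003")
}

#' @rdname default_neuron
#' @export
preplay_neuron <- function() {
  neuron_params(a = 0.02 / 1000, b = 0.2, c = -65, d = 8 / 10,
                vr = -60, vt = -45, vp = 30, C = 1000, k = 0,
                model_form = "simple_2003")
}

#' Homeostatic scaling parameters
#'
#' Each neuron carries a slow multiplicative scale `s` on its total afferent
#' excitatory conductance. `s` drifts upward at rate `omega_D / tau_omega`
#' (per second) and is decremented by `1 / tau_omega` on every spike, so the
#' drift and the decrements cancel exactly when the neuron fires at its
#' target rate `omega_D`.
#'
#' @param omega_D target firing rate (Hz); a length-2 vector is interpreted
#'   as a uniform range from which per-neuron targets are drawn at build time
#' @param tau_omega homeostatic time constant (s)
#' @return an object of class `homeostasis_params`
#' @export
homeostasis_params <- function(omega_D = c(0.25, 0.35), tau_omega = 600) {
  stopifnot(tau_omega > 0, all(omega_D >= 0), length(omega_D) %in% c(1, 2))
  structure(list(omega_D = omega_D, tau_omega = tau_omega),
            class = "homeostasis_params")
}

#' Triplet excitatory STDP parameters
#'
#' Nearest-neighbour triplet rule: a pre-then-post pairing at lag
#' `dt >= 0` potentiates by `(delta_ltp_e + last_ltd) * exp(-dt / tau_ltp_e)`
#' where `last_ltd <= 0` is the most recent depression on that synapse
#' (floored at zero when the recent depression exceeds the potentiation
#' step); a post-then-pre pairing depresses by
#' `-delta_ltd_e * exp(-|dt| / tau_ltd_e)`. Weights are clamped to
#' `[w_min_e, w_max_e]`.
#'
#' @param tau_ltp_e LTP time constant (ms)
#' @param tau_ltd_e LTD time constant (ms)
#' @param delta_ltp_e LTP step (nS)
#' @param delta_ltd_e LTD step magnitude (nS)
#' @param w_min_e,w_max_e weight bounds (nS)
#' @return an object of class `triplet_params`
#' @export
triplet_params <- function(tau_ltp_e = 20, tau_ltd_e = 25,
                           delta_ltp_e = 0.020, delta_ltd_e = 0.024,
                           w_min_e = 0, w_max_e = 0.8) {
  stopifnot(tau_ltp_e > 0, tau_ltd_e > 0,
            delta_ltp_e >= 0, delta_ltd_e >= 0,
            w_min_e >= 0, w_min_e < w_max_e)
  structure(list(tau_ltp_e = tau_ltp_e, tau_ltd_e = tau_ltd_e,
                 delta_ltp_e = delta_ltp_e, delta_ltd_e = delta_ltd_e,
                 w_min_e = w_min_e, w_max_e = w_max_e),
            class = "triplet_params")
}

#' Top-hat inhibitory STDP parameters
#'
#' Symmetric piecewise-constant STDP window on inhibitory synapses. In the
#' default (inverted) orientation, near-coincident pre/post spikes
#' (`|dt| < tau_inner`) depress the inhibitory weight by `delta_ltd_i`
#' (co-active neurons decouple their inhibition), lags in the annulus
#' `[tau_inner, tau_outer]` potentiate it by `delta_ltp_i`, and larger lags
#' do nothing. The non-inverted orientation (used on
#' inhibitory-to-inhibitory synapses of the alternate variant) flips both
#' signs. `literal_mode` instead tests the depression window first with its
#' own constant (`-delta_ltd_i` when `|dt| < tau_ltd_i`, else
#' `+delta_ltp_i` when `|dt| <= tau_ltp_i`), retained for auditability:
#' with the default parameters (`tau_ltp_i = 40 < tau_ltd_i = 700` ms)
#' its potentiation branch is unreachable.
#'
#' @param tau_ltp_i LTP window bound (ms)
#' @param tau_ltd_i LTD window bound (ms)
#' @param delta_ltd_i depression step (nS)
#' @param delta_ltp_i potentiation step (nS)
#' @param w_min_i,w_max_i weight bounds (nS); `w_min_i` is used only for
#'   initialization, learning may take weights down to 0
#' @param literal_mode evaluate the branch order literally instead of the
#'   inner/outer-window orientation
#' @param inverted if `TRUE` (default) co-activity depresses; if `FALSE`
#'   co-activity potentiates
#' @return an object of class `tophat_params` with derived fields
#'   `tau_inner = min(tau_ltp_i, tau_ltd_i)` and
#'   `tau_outer = max(tau_ltp_i, tau_ltd_i)`
#' @export
tophat_params <- function(tau_ltp_i = 40, tau_ltd_i = 700,
                          delta_ltd_i = 0.05, delta_ltp_i = 0.02,
                          w_min_i = 0.5, w_max_i = 0.8,
                          literal_mode = FALSE, inverted = TRUE) {
  stopifnot(tau_ltp_i > 0, tau_ltd_i > 0,
            delta_ltd_i >= 0, delta_ltp_i >= 0,
            w_min_i >= 0, w_min_i <= w_max_i)
  structure(list(tau_inner = min(tau_ltp_i, tau_ltd_i),
                 tau_outer = max(tau_ltp_i, tau_ltd_i),
                 tau_ltp_i = tau_ltp_i, tau_ltd_i = tau_ltd_i,
                 delta_ltd_i = delta_ltd_i, delta_ltp_i = delta_ltp_i,
                 w_min_i = w_min_i, w_max_i = w_max_i,
                 literal_mode = isTRUE(literal_mode),
                 inverted = isTRUE(inverted)),
            class = "tophat_params")
}

#' Synaptic conductance parameters
#'
#' Reversal potentials and single-exponential decay time constants of the
#' per-neuron conductance pools. All excitatory synapses onto a neuron share
#' `tau_e` (so the total excitatory conductance is tracked as one pool);
#' inhibitory synapses use `tau_i`, with a second slow pool `tau_i2` for the
#' long-decay feedback pathway of the alternate variant.
#'
#' @param E_e,E_i reversal potentials (mV)
#' @param tau_e,tau_i,tau_i2 decay time constants (ms)
#' @return an object of class `synapse_params`
#' @export
synapse_params <- function(E_e = 0, E_i = -81, tau_e = 35, tau_i = 50,
                           tau_i2 = 50) {
  stopifnot(tau_e > 0, tau_i > 0, tau_i2 > 0)
  structure(list(E_e = E_e, E_i = E_i, tau_e = tau_e, tau_i = tau_i,
                 tau_i2 = tau_i2),
            class = "synapse_params")
}
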