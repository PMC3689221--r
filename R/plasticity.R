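#' Nearest-neighbour synapse trace
#'
#' Per-synapse bookkeeping for the triplet rule: time of the most recent
#' presynaptic and postsynaptic spike seen by this synapse, and the signed
#' magnitude of the most recent depression event (`last_ltd <= 0`), which
#' the potentiation branch adds to its step so that a recent large
#' depression suppresses subsequent potentiation.
#'
#' @param t_last_pre time of last presynaptic spike (ms), `NA` if none
#' @param t_last_post time of last postsynaptic spike (ms), `NA` if none
#' @param last_ltd most recent depression on this synapse (nS, `<= 0`)
#' @return an object of class `synapse_trace`
#' @export
synapse_trace <- function(t_last_pre = NA_real_, t_last_post = NA_real_,
                          last_ltd = 0) {
  stopifnot(last_ltd <= 0)
  structure(list(t_last_pre = t_last_pre, t_last_post = t_last_post,
                 last_ltd = last_ltd), class = "synapse_trace")
}

#' Triplet rule: postsynaptic spike (potentiation branch)
#'
#' Called when the postsynaptic neuron fires at `t_post`. If a presynaptic
#' spike has been seen, returns
#' `max(0, delta_ltp_e + last_ltd) * exp(-dt / tau_ltp_e)` with
#' `dt = t_post - t_last_pre >= 0`; simultaneous pre/post spikes
#' (`dt = 0`) are routed through this branch. Without a prior presynaptic
#' spike the change is 0.
#'
#' @param trace a [synapse_trace()]
#' @param p a [triplet_params()]
#' @param t_post postsynaptic spike time (ms)
#' @return `list(dw = <nS>, trace = <updated trace>)`
#' @export
triplet_on_post <- function(trace, p, t_post) {
  dw <- 0
  if (!is.na(trace$t_last_pre)) {
    dt <- t_post - trace$t_last_pre
    stopifnot(dt >= 0)
    dw <- max(0, p$delta_ltp_e + trace$last_ltd) * exp(-dt / p$tau_ltp_e)
  }
  trace$t_last_post <- t_post
  list(dw = dw, trace = trace)
}

#' Triplet rule: presynaptic spike (depression branch)
#'
#' Called when the presynaptic neuron fires at `t_pre` strictly after the
#' last postsynaptic spike. Returns
#' `-delta_ltd_e * exp(-|dt| / tau_ltd_e)` with `dt = t_pre - t_last_post`,
#' and records the result as the synapse's `last_ltd`. Without a prior
#' postsynaptic spike the change is 0.
#'
#' @inheritParams triplet_on_post
#' @param t_pre presynaptic spike time (ms)
#' @return `list(dw = <nS>, trace = <updated trace>)`
#' @export
triplet_on_pre <- function(trace, p, t_pre) {
  dw <- 0
  if (!is.na(trace$t_last_post)) {
    stopifnot(trace$t_last_post < t_pre)
    dt <- t_pre - trace$t_last_post
    dw <- -p$delta_ltd_e * exp(-dt / p$tau_ltd_e)
    trace$last_ltd <- dw
  }
  trace$t_last_pre <- t_pre
  list(dw = dw, trace = trace)
}

#' Top-hat inhibitory STDP window
#'
#' Evaluates the symmetric window at a pre/post lag `delta_t` (ms, either
#' sign). See [tophat_params()] for the three orientations (inverted
#' default, non-inverted, literal branch order).
#'
#' @param p a [tophat_params()]
#' @param delta_t `t_post - t_pre` (ms); vectorized
#' @return weight change (nS)
#' @export
tophat_update <- function(p, delta_t) {
  adt <- abs(delta_t)
  if (p$literal_mode) {
    ifelse(adt < p$tau_ltd_i, -p$delta_ltd_i,
           ifelse(adt <= p$tau_ltp_i, p$delta_ltp_i, 0))
  } else if (p$inverted) {
    ifelse(adt < p$tau_inner, -p$delta_ltd_i,
           ifelse(adt <= p$tau_outer, p$delta_ltp_i, 0))
  } else {
    ifelse(adt < p$tau_inner, p$delta_ltp_i,
           ifelse(adt <= p$tau_outer, -p$delta_ltd_i, 0))
  }
}

#' Clamp a synaptic weight to its bounds
#'
#' @param w weight (nS); vectorized
#' @param lo,hi bounds (nS)
#' @return `min(hi, max(lo, w))`
#' @export
clamp_weight <- function(w, lo, hi) {
  if (lo > hi) stop("lower bound exceeds upper bound")
  pmin(hi, pmax(lo, w))
}

#' Initial synaptic weights
#'
#' Excitatory weights are drawn i.i.d. uniform on `[0, 0.1 * w_max_e)`;
#' inhibitory weights uniform on `[w_min_i, w_max_i]`.
#'
#' @param kind `"excitatory"` or `"inhibitory"`
#' @param count number of weights
#' @param p a [triplet_params()] (excitatory) or [tophat_params()]
#'   (inhibitory)
#' @param seed optional integer seed for reproducibility
#' @return numeric vector of weights (nS)
#' @export
init_weights <- function(kind = c("excitatory", "inhibitory"), count, p,
                         seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(count >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "excitatory") {
    stats::runif(count, 0, 0.1 * p$w_max_e)
  } else {
    stats::runif(count, p$w_min_i, p$w_max_i)
  }
}
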