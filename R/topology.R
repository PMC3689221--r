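#' @useDynLib episodenet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Degree-balanced random directed adjacency: every neuron gets exactly
# round(p*(N-1)) afferent and efferent edges, no self-edges. Built as a
# union of d non-overlapping derangements (configuration-model style);
# at p = 1 this is the complete digraph.
balanced_adjacency <- function(N, p) {
  stopifnot(N > 1, p >= 0, p <= 1)
  A <- matrix(0L, N, N)
  if (p >= 1) {
    A[] <- 1L
    diag(A) <- 0L
    return(A)
  }
  d <- round(p * (N - 1))
  idx <- seq_len(N)
  for (m in seq_len(d)) {
    perm <- NULL
    for (try in 1:2000) {
      cand <- sample.int(N)
      if (all(cand != idx) && all(A[cbind(idx, cand)] == 0L)) {
        perm <- cand
        break
      }
    }
    if (is.null(perm)) {
      # repair a near-miss candidate by random transpositions
      perm <- sample.int(N)
      for (rep_i in 1:20000) {
        bad <- which(perm == idx | A[cbind(idx, perm)] == 1L)
        if (length(bad) == 0) break
        j <- bad[[1L]]
        k <- sample.int(N, 1L)
        tmp <- perm[j]; perm[j] <- perm[k]; perm[k] <- tmp
      }
      bad <- which(perm == idx | A[cbind(idx, perm)] == 1L)
      if (length(bad) > 0) {
        stop("could not balance degrees at p = ", p,
             "; use a smaller p or larger N")
      }
    }
    A[cbind(idx, perm)] <- 1L
  }
  A
}

new_network_graph <- function(variant, roles, neuron_df, We, Wi, Ae, Ai,
                              De, Di, ruleE, ruleI, triplet, tophat,
                              tophat_ii, syn, homeo, omega_D, ipool, input,
                              seed) {
  structure(list(variant = variant, N = length(roles), roles = roles,
                 neuron = neuron_df, We = We, Wi = Wi, Ae = Ae, Ai = Ai,
                 De = De, Di = Di, ruleE = ruleE, ruleI = ruleI,
                 triplet = triplet, tophat = tophat, tophat_ii = tophat_ii,
                 syn = syn, homeo = homeo, omega_D = omega_D, ipool = ipool,
                 input = input, seed = seed),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat("<network_graph> variant:", x$variant, "\n")
  cat("  neurons:", x$N, "(", paste(names(table(x$roles)), table(x$roles),
                                    collapse = ", "), ")\n")
  cat("  excitatory synapses:", sum(x$Ae), " inhibitory synapses:",
      sum(x$Ai), "\n")
  cat("  input mode:", x$input$mode, "with", x$input$n_inputs,
      "input neurons\n")
  invisible(x)
}

neuron_df_from <- function(params_list) {
  do.call(rbind, lapply(params_list, function(p) {
    data.frame(a = p$a, b = p$b, c = p$c, d = p$d, vr = p$vr, vt = p$vt,
               vp = p$vp, C = p$C, k = p$k,
               form = if (p$model_form == "quadratic_2007") 0L else 1L)
  }))
}

#' Build the simple (1-to-1) network variant
#'
#' All-to-all (at `p_e = 1`) recurrent network of `N` dual-role neurons: for
#' each excitatory connection between a pair, an inhibitory connection with
#' its own weight and delay is made between the same pair, both plastic
#' (triplet rule on excitatory, inverted top-hat on inhibitory). The weight
#' matrices are stored `N x N` with a structurally zero diagonal. Delays are
#' drawn uniformly from `delay_e` / `delay_i`. Each recurrent neuron
#' receives one large non-plastic excitatory synapse from exactly one input
#' neuron (a random bijection), plus the 250 Hz pacing inhibitory input with
#' a fixed per-target delay in `[1, 4]` ms.
#'
#' @param N number of recurrent neurons (and of input neurons)
#' @param p_e,p_i connection probabilities; degrees are balanced exactly and
#'   inhibitory edges are paired with excitatory ones, so `p_i` must equal
#'   `p_e`
#' @param delay_e,delay_i delay ranges (ms)
#' @param neuron a [neuron_params()] shared by all recurrent neurons
#' @param triplet a [triplet_params()]
#' @param tophat a [tophat_params()]
#' @param syn a [synapse_params()]
#' @param homeo a [homeostasis_params()]; per-neuron targets are drawn from
#'   its `omega_D` range
#' @param input_weight weight of the non-plastic input synapse (nS)
#' @param input_delay input synapse delay (ms)
#' @param pacing_weight weight of the pacing inhibitory synapse (nS)
#' @param pacing_delay_range fixed per-target pacing delay range (ms)
#' @param seed integer seed; the build is fully reproducible under it
#' @return an object of class `network_graph`
#' @export
build_simple <- function(N = 480, p_e = 1, p_i = p_e,
                         delay_e = c(11, 16), delay_i = c(1, 5),
                         neuron = default_neuron(),
                         triplet = triplet_params(),
                         tophat = tophat_params(),
                         syn = synapse_params(),
                         homeo = homeostasis_params(),
                         input_weight = 4, input_delay = 1,
                         pacing_weight = 0.1, pacing_delay_range = c(1, 4),
                         seed = 1, variant = "simple") {
  if (N <= 1) stop("N must be > 1")
  if (p_i != p_e) stop("inhibitory connections are paired with excitatory ones; p_i must equal p_e")
  set.seed(seed)
  Ae <- balanced_adjacency(N, p_e)
  Ai <- Ae # pairing rule: every excitatory pair also gets an inhibitory synapse
  nE <- sum(Ae)
  We <- matrix(0, N, N)
  Wi <- matrix(0, N, N)
  We[Ae == 1L] <- init_weights("excitatory", nE, triplet)
  Wi[Ai == 1L] <- init_weights("inhibitory", nE, tophat)
  De <- matrix(0, N, N)
  Di <- matrix(0, N, N)
  De[Ae == 1L] <- stats::runif(nE, delay_e[1], delay_e[2])
  Di[Ai == 1L] <- stats::runif(nE, delay_i[1], delay_i[2])
  ruleE <- Ae # 1 = plastic triplet
  ruleI <- Ai # 1 = plastic inverted top-hat
  omega_D <- stats::runif(N, min(homeo$omega_D), max(homeo$omega_D))
  proj <- build_input_projection("one_to_one", N, N)
  input <- list(mode = "one_to_one", n_inputs = N, map = proj$map,
                edges = proj$edges, weight = input_weight,
                delay = input_delay, pacing_weight = pacing_weight,
                pacing_delay = stats::runif(N, pacing_delay_range[1],
                                            pacing_delay_range[2]))
  params_df <- neuron_df_from(list(neuron))[rep(1, N), ]
  rownames(params_df) <- NULL
  new_network_graph(variant, rep("excitatory", N), params_df, We, Wi,
                    Ae, Ai, De, Di, ruleE, ruleI, triplet, tophat,
                    tophat_params(inverted = FALSE), syn, homeo, omega_D,
                    rep(1L, N), input, seed)
}

#' Build the preplay network variant
#'
#' Same topology, pairing and input scheme as [build_simple()] (identical
#' edges and delays under an equal seed), but with the slow four-parameter
#' regular-spiking neuron ([preplay_neuron()]: capacitance-like divisor
#' 1000, `a` 1000-fold smaller, `d` 10-fold smaller), slower synaptic decay
#' (`tau_e` = 120 ms, `tau_i` = 65 ms), excitatory reversal at 30 mV,
#' larger plasticity steps (`weight_step_scale`, default 10) and the
#' inverted inhibitory window (`tau_ltp_i` = 140 ms, `tau_ltd_i` = 56 ms, so
#' the co-activity depression window is the 56 ms inner disc). The input
#' synapse defaults to 16 nS: the high-capacitance neuron integrates
#' slowly against sustained pacing and recurrent inhibition, and this
#' weight makes one temporal step's input burst reliably suprathreshold.
#'
#' @inheritParams build_simple
#' @param weight_step_scale multiplier applied to the four STDP step sizes
#' @return an object of class `network_graph`
#' @export
build_preplay <- function(N = 480, p_e = 1, weight_step_scale = 10,
                          input_weight = 16, pacing_weight = 0.1, seed = 1) {
  tr <- triplet_params(delta_ltp_e = 0.020 * weight_step_scale,
                       delta_ltd_e = 0.024 * weight_step_scale)
  th <- tophat_params(tau_ltp_i = 140, tau_ltd_i = 56,
                      delta_ltd_i = 0.05 * weight_step_scale,
                      delta_ltp_i = 0.02 * weight_step_scale)
  build_simple(N = N, p_e = p_e, neuron = preplay_neuron(),
               triplet = tr, tophat = th,
               syn = synapse_params(E_e = 30, tau_e = 120, tau_i = 65),
               input_weight = input_weight, pacing_weight = pacing_weight,
               seed = seed, variant = "preplay")
}

#' Build the alternate (many-to-many) network variant
#'
#' Separate excitatory (`Ne`, quadratic-form neurons with `C` = 500 pF and
#' `E_e` = 30 mV) and fast-spiking inhibitory (`Ni`) populations with
#' independent Bernoulli(`p`) connectivity for the four population pairs.
#' Excitatory efferents (e-e and e-i) are plastic under the triplet rule;
#' inhibitory-to-excitatory synapses use the inverted top-hat rule and
#' inhibitory-to-inhibitory synapses the non-inverted one, both with a
#' 10-fold faster conductance decay (`tau_i` / 10). One extra non-plastic
#' feedback inhibitory neuron with the slow decay time constant is
#' connected to and from every excitatory neuron. Inputs are many-to-many:
#' `4 * Ne` input neurons each project onto 3 random excitatory neurons so
#' that every excitatory neuron receives exactly 12 input synapses.
#'
#' @inheritParams build_simple
#' @param Ne,Ni excitatory / inhibitory population sizes
#' @param p_ee,p_ei,p_ie,p_ii connection probabilities
#' @param E_e excitatory reversal potential (mV); the table value 30 mV is
#'   the default
#' @param w_feedback fixed weight of the feedback neuron's synapses (nS)
#' @return an object of class `network_graph`
#' @export
build_alternate <- function(Ne = 2000, Ni = 500,
                            p_ee = 0.3, p_ei = 0.3, p_ie = 0.3, p_ii = 0.3,
                            delay_e = c(11, 16), delay_i = c(1, 5),
                            triplet = triplet_params(),
                            tophat = tophat_params(),
                            syn = synapse_params(E_e = 30, tau_i = 5,
                                                 tau_i2 = 50),
                            homeo = homeostasis_params(),
                            E_e = 30,
                            input_weight = 4, input_delay = 1,
                            pacing_weight = 0.1,
                            pacing_delay_range = c(1, 4),
                            w_feedback = 0.5, seed = 1) {
  set.seed(seed)
  N <- Ne + Ni + 1L
  fb <- N
  exc <- seq_len(Ne)
  inh <- Ne + seq_len(Ni)
  roles <- c(rep("excitatory", Ne), rep("inhibitory", Ni), "feedback")
  Ae <- matrix(0L, N, N)
  Ai <- matrix(0L, N, N)
  Ae[exc, exc] <- matrix(stats::rbinom(Ne * Ne, 1, p_ee), Ne, Ne)
  Ae[exc, inh] <- matrix(stats::rbinom(Ne * Ni, 1, p_ei), Ne, Ni)
  Ai[inh, exc] <- matrix(stats::rbinom(Ni * Ne, 1, p_ie), Ni, Ne)
  Ai[inh, inh] <- matrix(stats::rbinom(Ni * Ni, 1, p_ii), Ni, Ni)
  diag(Ae) <- 0L
  diag(Ai) <- 0L
  ruleE <- Ae # all excitatory recurrent synapses plastic (triplet)
  ruleI <- Ai # i->e inverted top-hat ...
  ruleI[inh, inh] <- 2L * Ai[inh, inh] # ... i->i non-inverted
  # non-plastic feedback loop: e -> fb (excitatory), fb -> e (inhibitory)
  Ae[exc, fb] <- 1L
  Ai[fb, exc] <- 1L
  We <- matrix(0, N, N)
  Wi <- matrix(0, N, N)
  We[ruleE == 1L] <- init_weights("excitatory", sum(ruleE == 1L & Ae == 1L),
                                  triplet)
  Wi[ruleI > 0L] <- init_weights("inhibitory", sum(ruleI > 0L), tophat)
  We[exc, fb] <- w_feedback
  Wi[fb, exc] <- w_feedback
  De <- matrix(0, N, N)
  Di <- matrix(0, N, N)
  De[Ae == 1L] <- stats::runif(sum(Ae), delay_e[1], delay_e[2])
  Di[Ai == 1L] <- stats::runif(sum(Ai), delay_i[1], delay_i[2])
  syn$E_e <- E_e
  omega_D <- stats::runif(N, min(homeo$omega_D), max(homeo$omega_D))
  proj <- build_input_projection("many_to_many", 4L * Ne, Ne)
  input <- list(mode = "many_to_many", n_inputs = 4L * Ne, map = NULL,
                edges = proj$edges, weight = input_weight,
                delay = input_delay, pacing_weight = pacing_weight,
                pacing_delay = stats::runif(N, pacing_delay_range[1],
                                            pacing_delay_range[2]))
  exc_p <- default_neuron()
  exc_p$C <- 500
  params_df <- rbind(neuron_df_from(list(exc_p))[rep(1, Ne), ],
                     neuron_df_from(list(fs_neuron()))[rep(1, Ni + 1L), ])
  rownames(params_df) <- NULL
  ipool <- c(rep(1L, Ne + Ni), 2L) # feedback neuron uses the slow pool
  new_network_graph("alternate", roles, params_df, We, Wi, Ae, Ai, De, Di,
                    ruleE, ruleI, triplet, tophat,
                    tophat_params(inverted = FALSE), syn, homeo, omega_D,
                    ipool, input, seed)
}

#' Input-to-recurrent projection
#'
#' `one_to_one`: a random bijection, so each recurrent neuron has exactly
#' one input synapse. `many_to_many`: each input neuron projects onto
#' exactly `out_degree` (3) recurrent neurons and each recurrent neuron
#' receives exactly `in_degree` (12) input synapses; feasibility requires
#' `out_degree * n_inputs == in_degree * n_recurrent`.
#'
#' @param mode `"one_to_one"` or `"many_to_many"`
#' @param n_inputs,n_recurrent population sizes
#' @param out_degree,in_degree exact degrees for `many_to_many`
#' @param seed optional seed
#' @return a list with `mode`, `edges` (data.frame `input`, `target`) and,
#'   for `one_to_one`, `map` (`map[i]` = recurrent target of input `i`)
#' @export
build_input_projection <- function(mode = c("one_to_one", "many_to_many"),
                                   n_inputs, n_recurrent,
                                   out_degree = 3, in_degree = 12,
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "one_to_one") {
    if (n_inputs != n_recurrent) {
      stop("one_to_one projection needs n_inputs == n_recurrent")
    }
    map <- sample.int(n_recurrent)
    return(list(mode = mode, map = map,
                edges = data.frame(input = seq_len(n_inputs), target = map)))
  }
  if (out_degree * n_inputs != in_degree * n_recurrent) {
    stop("infeasible degrees: need out_degree * n_inputs == in_degree * n_recurrent")
  }
  inputs <- rep(seq_len(n_inputs), each = out_degree)
  targets <- sample(rep(seq_len(n_recurrent), each = in_degree))
  # repair duplicate (input, target) pairs by swapping targets
  for (rep_i in 1:10000) {
    key <- (inputs - 1) * n_recurrent + targets
    dup <- which(duplicated(key))
    if (length(dup) == 0) break
    j <- dup
    k <- sample.int(length(targets), length(dup), replace = TRUE)
    tmp <- targets[j]; targets[j] <- targets[k]; targets[k] <- tmp
  }
  if (anyDuplicated((inputs - 1) * n_recurrent + targets)) {
    stop("could not derandomize duplicate projection edges")
  }
  list(mode = mode, map = NULL,
       edges = data.frame(input = inputs, target = targets))
}

#' Export a network's synapses as a delimited edge list
#'
#' Writes one row per synapse: `pre`, `post`, `weight` (nS), `delay` (ms),
#' `type` (`e`/`i`) and `plastic` (0/1/2, the rule tag). The companion
#' [read_graph_edges()] reads the same format back.
#'
#' @param graph a `network_graph`
#' @param path output file
#' @return the edge data.frame, invisibly
#' @export
export_graph <- function(graph, path) {
  eidx <- which(graph$Ae == 1L, arr.ind = TRUE)
  iidx <- which(graph$Ai == 1L, arr.ind = TRUE)
  edges <- rbind(
    data.frame(pre = eidx[, 1], post = eidx[, 2],
               weight = graph$We[eidx], delay = graph$De[eidx],
               type = "e", plastic = graph$ruleE[eidx]),
    data.frame(pre = iidx[, 1], post = iidx[, 2],
               weight = graph$Wi[iidx], delay = graph$Di[iidx],
               type = "i", plastic = graph$ruleI[iidx]))
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges)
}

#' @rdname export_graph
#' @export
read_graph_edges <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("integer", "integer", "numeric",
                                   "numeric", "character", "integer"))
}
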