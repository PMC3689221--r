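#' Scalar reference simulation engine
#'
#' A straightforward R implementation of the simulation loop, written with
#' explicit per-neuron and per-synapse operations in the same event order
#' as the compiled engine: decay, due deliveries, external enqueue, noise,
#' integration, spike handling (reset, homeostatic decrement, STDP,
#' delivery enqueue), homeostatic drift, recording. It is intended for
#' small fixtures (around ten neurons, a few seconds): on those it must
#' produce spike streams identical to [run_network()] under the same seed,
#' which is asserted by the package's cross-validation tests.
#'
#' @inheritParams run_network
#' @return a `sim_result`, as from [run_network()]
#' @export
reference_run <- function(graph, stim, cfg) {
  a <- engine_inputs(graph, stim, cfg)
  set.seed(cfg$seed)
  N <- a$N
  tri <- a$triplet
  v <- a$v0; u <- a$u0; s <- a$s0
  Ge <- numeric(N); Gi1 <- numeric(N); Gi2 <- numeric(N)
  t_last <- rep(-1, N)
  lastLTD <- matrix(0, N, N)
  We <- a$We; Wi <- a$Wi
  maxdel <- max(a$in_delay_steps, a$pacing_delay_steps,
                a$DeS[a$Ae == 1L], a$DiS[a$Ai == 1L], 1L)
  L <- maxdel + 2L
  ringE <- matrix(0, L, N); ringI1 <- matrix(0, L, N)
  ringI2 <- matrix(0, L, N)
  sp_step <- integer(0); sp_id <- integer(0)
  snaps <- list()
  drift <- (a$dt / 1000) / a$tau_omega
  sdec <- 1 / a$tau_omega
  ihw <- a$ihwin
  tophat_w <- function(r, adt) {
    if (adt < ihw[r, 1]) ihw[r, 3]
    else if (adt >= ihw[r, 1] && adt <= ihw[r, 2]) ihw[r, 4]
    else 0
  }
  ext_ptr <- 1L
  n_ext <- length(a$ext_step)
  for (t in 0:(a$n_total - 1L)) {
    t_now <- (t + 1) * a$dt
    slot <- t %% L + 1L
    Ge <- Ge * a$dec_e + ringE[slot, ]
    Gi1 <- Gi1 * a$dec_i1 + ringI1[slot, ]
    Gi2 <- Gi2 * a$dec_i2 + ringI2[slot, ]
    ringE[slot, ] <- 0; ringI1[slot, ] <- 0; ringI2[slot, ] <- 0
    while (ext_ptr <= n_ext && a$ext_step[ext_ptr] == t) {
      id <- a$ext_id[ext_ptr]
      if (id < 0) {
        for (r in seq_len(N)) {
          te <- t + a$pacing_delay_steps[r]
          if (te < a$n_total) {
            sl <- te %% L + 1L
            ringI1[sl, r] <- ringI1[sl, r] + a$pacing_w
          }
        }
      } else {
        te <- t + a$in_delay_steps
        if (te < a$n_total) {
          sl <- te %% L + 1L
          if (a$in_off[id + 2L] > a$in_off[id + 1L]) {
            for (q in (a$in_off[id + 1L] + 1L):a$in_off[id + 2L]) {
              tg <- a$in_targets[q] + 1L
              ringE[sl, tg] <- ringE[sl, tg] + a$in_w
            }
          }
        }
      }
      ext_ptr <- ext_ptr + 1L
    }
    In <- if (a$sigma > 0) stats::rnorm(N, 0, a$sigma) else numeric(N)
    spikers <- integer(0)
    for (i in seq_len(N)) {
      vi <- v[i]; ui <- u[i]
      Isyn <- s[i] * Ge[i] * (a$Ee - vi) + (Gi1[i] + Gi2[i]) * (a$Ei - vi)
      if (a$pform[i] == 0L) {
        dv <- (a$pk[i] * (vi - a$pvr[i]) * (vi - a$pvt[i]) - ui + Isyn +
                 In[i]) / a$pC[i]
        du <- a$pa[i] * (a$pb[i] * (vi - a$pvr[i]) - ui)
      } else {
        dv <- (0.04 * vi * vi + 5 * vi + 140 - ui + Isyn + In[i]) / a$pC[i]
        du <- a$pa[i] * (a$pb[i] * vi - ui)
      }
      u_new <- ui + a$dt * du
      v_new <- vi + a$dt * dv
      if (!is.finite(v_new) || !is.finite(u_new)) {
        stop("numeric blow-up (non-finite state) in neuron ", i, " at t = ",
             t_now, " ms")
      }
      if (v_new >= a$pvp[i]) {
        v[i] <- a$pc[i]
        u[i] <- u_new + a$pd[i]
        s[i] <- max(0, s[i] - sdec)
        spikers <- c(spikers, i)
        if (a$record_spikes) {
          sp_step <- c(sp_step, t)
          sp_id <- c(sp_id, i)
        }
      } else {
        if (abs(v_new) > 10 * abs(a$pvp[i])) {
          stop("numeric blow-up (|v| = ", round(v_new, 1), " mV) in neuron ",
               i, " at t = ", t_now, " ms")
        }
        v[i] <- v_new
        u[i] <- u_new
      }
    }
    if (length(spikers) > 0) {
      isS <- logical(N)
      isS[spikers] <- TRUE
      for (j in spikers) {
        for (i in seq_len(N)) {
          if (a$ruleE[i, j] == 1L) {
            tpre <- if (isS[i]) t_now else t_last[i]
            if (tpre >= 0) {
              base <- tri$delta_ltp_e + lastLTD[i, j]
              if (base < 0) base <- 0
              dw <- base * exp(-(t_now - tpre) / tri$tau_ltp_e)
              We[i, j] <- clamp_weight(We[i, j] + dw, tri$w_min_e,
                                       tri$w_max_e)
            }
          }
        }
        for (k in seq_len(N)) {
          if (a$ruleE[j, k] == 1L && !isS[k] && t_last[k] >= 0) {
            dw <- -tri$delta_ltd_e * exp(-(t_now - t_last[k]) / tri$tau_ltd_e)
            lastLTD[j, k] <- dw
            We[j, k] <- clamp_weight(We[j, k] + dw, tri$w_min_e, tri$w_max_e)
          }
        }
        for (i in seq_len(N)) {
          r <- a$ruleI[i, j]
          if (r > 0L) {
            tpre <- if (isS[i]) t_now else t_last[i]
            if (tpre >= 0) {
              dw <- tophat_w(r, t_now - tpre)
              Wi[i, j] <- clamp_weight(Wi[i, j] + dw, 0, a$wmax_i)
            }
          }
        }
        for (k in seq_len(N)) {
          r <- a$ruleI[j, k]
          if (r > 0L) {
            tpost <- if (isS[k]) t_now else t_last[k]
            if (tpost >= 0) {
              dw <- tophat_w(r, t_now - tpost)
              Wi[j, k] <- clamp_weight(Wi[j, k] + dw, 0, a$wmax_i)
            }
          }
        }
      }
      for (j in spikers) {
        for (k in seq_len(N)) {
          if (a$Ae[j, k] == 1L) {
            te <- t + a$DeS[j, k]
            if (te < a$n_total) {
              sl <- te %% L + 1L
              ringE[sl, k] <- ringE[sl, k] + We[j, k]
            }
          }
        }
        for (k in seq_len(N)) {
          if (a$Ai[j, k] == 1L) {
            te <- t + a$DiS[j, k]
            if (te < a$n_total) {
              sl <- te %% L + 1L
              if (a$ipool[j] == 1L) {
                ringI1[sl, k] <- ringI1[sl, k] + Wi[j, k]
              } else {
                ringI2[sl, k] <- ringI2[sl, k] + Wi[j, k]
              }
            }
          }
        }
        t_last[j] <- t_now
      }
    }
    s <- s + a$omegaD * drift
    if (a$snap_period > 0L && (t + 1L) %% a$snap_period == 0L) {
      snaps[[length(snaps) + 1L]] <- list(time_s = t_now / 1000,
                                          We = We + 0, Wi = Wi + 0)
    }
  }
  raw <- list(sp_step = sp_step, sp_id = sp_id, snapshots = snaps,
              v = v, u = u, s = s, Ge = Ge, Gi1 = Gi1, Gi2 = Gi2,
              We = We, Wi = Wi)
  finish_run(raw, a, graph, cfg)
}
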