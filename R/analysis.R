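# map a set of input-neuron ids to their recurrent targets
map_inputs <- function(graph, members) {
  if (length(members) == 0) return(integer(0))
  if (graph$input$mode == "one_to_one") {
    graph$input$map[members]
  } else {
    ed <- graph$input$edges
    unique(ed$target[ed$input %in% members])
  }
}

# union of input neurons driven (current or trailing step) in each absolute
# low-frequency cycle, across overlapping presentations
stimulated_by_cycle <- function(stim) {
  eps <- stim$episode_set$episodes
  ids <- vapply(eps, function(e) e$episode_id, integer(1))
  cfg <- stim$cfg
  n_steps <- stim$n_steps
  n_trail <- length(cfg$trailing_intensities)
  pres <- stim$annotations$presentations
  out <- new.env(parent = emptyenv())
  cyc_per_pres <- (n_steps + (n_trail - 1L)) * cfg$step_repeat
  for (r in seq_len(nrow(pres))) {
    ep <- eps[[which(ids == pres$episode_id[r])]]
    for (j in 0:(cyc_per_pres - 1L)) {
      saq <- steps_at_offset(j, n_steps, cfg$step_repeat, n_trail)
      if (nrow(saq) == 0) next
      key <- as.character(pres$start_cycle[r] + j)
      mem <- unlist(ep$steps[saq$step], use.names = FALSE)
      out[[key]] <- c(out[[key]], mem)
    }
  }
  out
}

# per-cycle group mean firing rates feeding the relative-activity metric
rmetric_rows <- function(result, stim, graph, lookahead = 2) {
  sp <- result$spikes
  T_low <- stim$cycle_ms
  cyc <- stim$annotations$cycles
  cyc <- cyc[!is.na(cyc$step), , drop = FALSE]
  dropped <- stim$annotations$dropped
  dropped_by_key <- if (is.null(dropped)) list() else
    split(dropped$neuron_id, paste(dropped$pres_idx, dropped$step))
  eps <- stim$episode_set$episodes
  ep_ids <- vapply(eps, function(e) e$episode_id, integer(1))
  stim_env <- stimulated_by_cycle(stim)
  n_steps <- stim$n_steps
  recurrent <- which(graph$roles == "excitatory")
  # per-cycle-bin spike counts, computed once
  sp_bin <- floor(sp$time_ms / T_low)
  ids_by_bin <- split(sp$neuron_id, sp_bin)
  bin_rate <- function(cnt, group) {
    if (length(group) == 0) return(NA_real_)
    mean(cnt[group]) / (T_low / 1000)
  }
  n <- nrow(cyc)
  mu_act <- mu_bg <- mu_pro <- mu_com <- numeric(n)
  for (r in seq_len(n)) {
    ep <- eps[[which(ep_ids == cyc$episode_id[r])]]
    st <- cyc$step[r]
    mem <- ep$steps[[st]]
    dr <- dropped_by_key[[paste(cyc$pres_idx[r], st)]]
    if (is.null(dr)) dr <- integer(0)
    stim_in <- unique(stim_env[[as.character(cyc$cycle[r])]])
    up <- if (st < n_steps) {
      unlist(ep$steps[(st + 1L):min(st + lookahead, n_steps)],
             use.names = FALSE)
    } else integer(0)
    up <- setdiff(up, stim_in)
    active <- map_inputs(graph, setdiff(mem, dr))
    compl <- map_inputs(graph, dr)
    prosp <- map_inputs(graph, up)
    bg <- setdiff(recurrent,
                  c(map_inputs(graph, stim_in), prosp, compl))
    key <- as.character(cyc$cycle[r])
    in_bin <- ids_by_bin[[key]]
    cnt <- if (is.null(in_bin)) integer(graph$N) else
      tabulate(in_bin, nbins = graph$N)
    mu_act[r] <- bin_rate(cnt, active)
    mu_bg[r] <- bin_rate(cnt, bg)
    mu_pro[r] <- bin_rate(cnt, prosp)
    mu_com[r] <- bin_rate(cnt, compl)
  }
  data.frame(pres_idx = cyc$pres_idx, episode_id = cyc$episode_id,
             step = cyc$step, t_start = cyc$t_start,
             mu_active = mu_act, mu_background = mu_bg,
             mu_prospection = mu_pro, mu_completion = mu_com)
}

#' Relative-activity metric for prospection and pattern completion
#'
#' Quantifies how strongly neurons fire without direct input relative to
#' the directly stimulated neurons:
#' \deqn{R = \frac{\mu_{group} - \mu_{background}}
#'              {\mu_{active} - \mu_{background}}}
#' where the rates are mean firing rates in 1/7 s bins (one bin per
#' low-frequency cycle). The `prospection` group contains the recurrent
#' targets of the members of the next `lookahead` (default 2) temporal
#' steps that are not currently stimulated; the `completion` group the
#' targets of the members dropped from the current step; `active` the
#' targets of the current step's presented members; `background` the
#' input-silent non-member recurrent neurons of the same bin. Group means
#' are taken over neurons within each bin, averaged over each
#' presentation's bins, then over presentations. Because the prospection
#' and completion groups receive no direct input while homeostasis
#' regulates activity by total input, R is expected to lie strictly
#' between 0 and 1 after learning.
#'
#' @param result a `sim_result`
#' @param stim the `stimulus_schedule` that drove it (with annotations)
#' @param graph the `network_graph`
#' @param kind `"prospection"` or `"completion"`
#' @param lookahead number of future steps in the prospection group
#' @param presentations optional presentation indices to restrict to
#'   (e.g. the final presentations after learning has plateaued)
#' @return an object of class `rmetric_result` with fields `R`, `kind`,
#'   `mu_group`, `mu_active`, `mu_background`, `defined`
#' @export
compute_R <- function(result, stim, graph,
                      kind = c("prospection", "completion"),
                      lookahead = 2, presentations = NULL) {
  kind <- match.arg(kind)
  rows <- rmetric_rows(result, stim, graph, lookahead)
  compute_R_from_rows(rows, kind, presentations, lookahead)
}

compute_R_from_rows <- function(rows, kind, presentations = NULL,
                                lookahead = 2) {
  if (!is.null(presentations)) {
    rows <- rows[rows$pres_idx %in% presentations, , drop = FALSE]
  }
  gcol <- if (kind == "prospection") "mu_prospection" else "mu_completion"
  per_pres <- function(col) {
    v <- tapply(rows[[col]], rows$pres_idx, mean, na.rm = TRUE)
    mean(v, na.rm = TRUE)
  }
  mu_g <- per_pres(gcol)
  mu_a <- per_pres("mu_active")
  mu_b <- per_pres("mu_background")
  denom <- mu_a - mu_b
  defined <- is.finite(denom) && denom > 0
  if (!defined) {
    warning("R metric undefined: mu_active - mu_background <= 0")
  }
  structure(list(R = if (defined) (mu_g - mu_b) / denom else NA_real_,
                 kind = kind, lookahead = lookahead,
                 mu_group = mu_g, mu_active = mu_a, mu_background = mu_b,
                 n_presentations = length(unique(rows$pres_idx)),
                 defined = defined),
            class = "rmetric_result")
}

#' @export
print.rmetric_result <- function(x, ...) {
  cat("<rmetric_result>", x$kind, ": R =", round(x$R, 4), "\n")
  cat(sprintf("  mu_group = %.3f  mu_active = %.3f  mu_background = %.3f Hz (%d presentations)\n",
              x$mu_group, x$mu_active, x$mu_background, x$n_presentations))
  invisible(x)
}

#' Prospection learning curve
#'
#' The relative-activity metric for prospection computed per presentation,
#' aligned so that each block's curve starts at aligned index 0 at its own
#' first presentation.
#'
#' @inheritParams compute_R
#' @param rows optionally, precomputed per-cycle group rates (internal
#'   reuse); otherwise computed from `result`
#' @return data.frame (`pres_idx`, `aligned_idx`, `block_id`,
#'   `R_prospection`)
#' @export
learning_curve <- function(result, stim, graph, lookahead = 2,
                           rows = NULL) {
  if (is.null(rows)) rows <- rmetric_rows(result, stim, graph, lookahead)
  eps <- stim$episode_set$episodes
  blk <- vapply(eps, function(e) e$block_id, integer(1))
  names(blk) <- vapply(eps, function(e) e$episode_id, integer(1))
  out <- lapply(split(rows, rows$pres_idx), function(d) {
    mu_g <- mean(d$mu_prospection, na.rm = TRUE)
    mu_a <- mean(d$mu_active, na.rm = TRUE)
    mu_b <- mean(d$mu_background, na.rm = TRUE)
    data.frame(pres_idx = d$pres_idx[1],
               block_id = blk[[as.character(d$episode_id[1])]],
               R_prospection = if (mu_a > mu_b)
                 (mu_g - mu_b) / (mu_a - mu_b) else NA_real_)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$pres_idx), , drop = FALSE]
  res$aligned_idx <- stats::ave(res$pres_idx, res$block_id,
                                FUN = function(p) p - min(p))
  rownames(res) <- NULL
  res[, c("pres_idx", "aligned_idx", "block_id", "R_prospection")]
}

#' Smoothed firing-rate map
#'
#' Bins spikes per neuron in `bin_s` bins and smooths causally with an
#' exponential kernel of time constant `kernel_tau` truncated at
#' `kernel_span` bins (normalized to unit mass). The response to a spike
#' starts in its own bin and is zero before it.
#'
#' @param spikes spike data.frame (`time_ms`, `neuron_id`)
#' @param n_neurons number of rows of the map
#' @param bin_s bin width (s)
#' @param kernel_tau kernel time constant (s)
#' @param kernel_span kernel length (bins)
#' @param t_max_s map extent (s); defaults to the last spike's bin plus the
#'   kernel span
#' @return `n_neurons x n_bins` matrix of smoothed rates (Hz)
#' @export
rate_map <- function(spikes, n_neurons, bin_s = 1 / 7, kernel_tau = 1 / 7,
                     kernel_span = 3, t_max_s = NULL) {
  if (is.null(t_max_s)) {
    t_max_s <- if (nrow(spikes) == 0) bin_s * kernel_span else
      (floor(max(spikes$time_ms) / 1000 / bin_s) + kernel_span) * bin_s
  }
  n_bins <- max(1L, ceiling(t_max_s / bin_s))
  raw <- matrix(0, n_neurons, n_bins)
  if (nrow(spikes) > 0) {
    b <- floor(spikes$time_ms / 1000 / bin_s) + 1L
    keep <- b >= 1L & b <= n_bins & spikes$neuron_id >= 1 &
      spikes$neuron_id <= n_neurons
    if (any(keep)) {
      tb <- table(factor(spikes$neuron_id[keep], levels = seq_len(n_neurons)),
                  factor(b[keep], levels = seq_len(n_bins)))
      raw <- raw + unclass(tb)
    }
  }
  raw <- raw / bin_s
  k <- exp(-(0:(kernel_span - 1)) * bin_s / kernel_tau)
  k <- k / sum(k)
  sm <- matrix(0, n_neurons, n_bins)
  for (q in 0:(kernel_span - 1)) {
    if (q < n_bins) {
      sm[, (q + 1):n_bins] <- sm[, (q + 1):n_bins] +
        k[q + 1] * raw[, 1:(n_bins - q), drop = FALSE]
    }
  }
  dimnames(sm) <- NULL
  sm
}

#' Rank-order score for replay / preplay events
#'
#' Correlates the first-spike times of an episode's recurrent
#' representatives inside a candidate window with their temporal-step
#' indices (Spearman rank correlation; first-spike ties broken by neuron
#' id). Significance is assessed by shuffling the step indices; the
#' direction call is `forward` (positive rho) or `reverse` (negative rho)
#' only when `|rho|` exceeds the 95th percentile of the shuffle
#' distribution, and `none` otherwise or when fewer than 5 members
#' participate.
#'
#' @param spikes recurrent spike data.frame (`time_ms`, `neuron_id`)
#' @param episode one element of `episode_set$episodes` (the template)
#' @param graph the `network_graph` (for the input-to-recurrent map)
#' @param window `c(t0, t1)` ms; the candidate event
#' @param n_shuffle permutations for the significance gate
#' @param seed optional seed for the permutations
#' @return an object of class `order_score`: `rho`, `n_neurons`,
#'   `direction`, `threshold`
#' @export
replay_order_score <- function(spikes, episode, graph, window,
                               n_shuffle = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_steps <- length(episode$steps)
  mem <- unlist(episode$steps, use.names = FALSE)
  stp <- rep(seq_len(n_steps),
             vapply(episode$steps, length, integer(1)))
  rid <- map_inputs(graph, mem)
  sp <- spikes[spikes$time_ms >= window[1] & spikes$time_ms < window[2], ,
               drop = FALSE]
  ft <- rep(NA_real_, length(rid))
  for (i in seq_along(rid)) {
    tt <- sp$time_ms[sp$neuron_id == rid[i]]
    if (length(tt) > 0) ft[i] <- min(tt)
  }
  part <- which(!is.na(ft))
  if (length(part) < 5) {
    return(structure(list(rho = NA_real_, n_neurons = length(part),
                          direction = "none", threshold = NA_real_),
                     class = "order_score"))
  }
  ftp <- ft[part]; stpp <- stp[part]; ridp <- rid[part]
  rt <- integer(length(part))
  rt[order(ftp, ridp)] <- seq_along(part)
  rho <- stats::cor(rt, rank(stpp))
  perm <- replicate(n_shuffle, stats::cor(rt, rank(sample(stpp))))
  thr <- stats::quantile(abs(perm), 0.95, names = FALSE)
  dir <- if (!is.finite(rho) || abs(rho) <= thr) "none" else
    if (rho > 0) "forward" else "reverse"
  structure(list(rho = rho, n_neurons = length(part), direction = dir,
                 threshold = thr),
            class = "order_score")
}

#' @export
print.order_score <- function(x, ...) {
  cat("<order_score> rho =", round(x$rho, 3), "(", x$direction, ",",
      x$n_neurons, "neurons, |rho| threshold", round(x$threshold, 3), ")\n")
  invisible(x)
}

segment_direction <- function(pts) {
  if (nrow(pts) < 2) return(NULL)
  d <- if (nrow(pts) == 2) {
    pts[2, ] - pts[1, ]
  } else {
    stats::prcomp(pts, center = TRUE)$rotation[, 1]
  }
  len <- sqrt(sum(d^2))
  if (!is.finite(len) || len < 1e-12) return(NULL)
  d / len
}

pairwise_angles <- function(dirs) {
  g <- names(dirs)
  n <- length(dirs)
  ang <- matrix(NA_real_, n, n, dimnames = list(g, g))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!is.null(dirs[[i]]) && !is.null(dirs[[j]])) {
        cosv <- abs(sum(dirs[[i]] * dirs[[j]]))
        ang[i, j] <- acos(min(1, cosv)) * 180 / pi
      }
    }
  }
  ang
}

#' Angles between weight-trajectory segments
#'
#' Embeds a sequence of weight snapshots into a low-dimensional space with
#' an established neighborhood-preserving manifold method (isomap), fits
#' one direction per learning group's embedded segment (first principal
#' component of the group's points), and reports all pairwise angles
#' between group directions in degrees, in `[0, 90]`. The same angles
#' computed directly in the raw weight space are returned for comparison.
#' Degenerate (zero-length) segments yield `NA` angles with a warning.
#'
#' @param snapshots list of weight matrices (or vectors), one per snapshot,
#'   in time order
#' @param groups factor/vector assigning each snapshot to a learning group
#' @param embed_dim embedding dimension
#' @param k isomap neighborhood size
#' @return list with `angles` (embedded-space), `angles_raw`, `embedding`
#'   (snapshot coordinates), `groups`
#' @export
weight_segment_angles <- function(snapshots, groups, embed_dim = 3,
                                  k = NULL) {
  X <- do.call(rbind, lapply(snapshots, as.numeric))
  stopifnot(nrow(X) == length(groups))
  if (is.null(k)) k <- max(2L, min(10L, nrow(X) - 1L))
  emb <- vegan::isomap(stats::dist(X), ndim = embed_dim, k = k)
  Y <- emb$points[, seq_len(min(embed_dim, ncol(emb$points))), drop = FALSE]
  gl <- split(seq_len(nrow(X)), groups)
  dirs_emb <- lapply(gl, function(ix) segment_direction(Y[ix, , drop = FALSE]))
  dirs_raw <- lapply(gl, function(ix) segment_direction(X[ix, , drop = FALSE]))
  if (any(vapply(dirs_emb, is.null, logical(1)))) {
    warning("degenerate (zero-length) segment; its angles are NA")
  }
  list(angles = pairwise_angles(dirs_emb),
       angles_raw = pairwise_angles(dirs_raw),
       embedding = Y, groups = groups)
}
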