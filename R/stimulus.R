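#' Stimulus configuration
#'
#' Timing and noise parameters of the episode stimulus. An episode is split
#' into `n_steps` ordered temporal steps; one low-frequency (theta-like,
#' `f_low` = 7 Hz) cycle advances the current step by one, and within each
#' cycle the current step and its `length(trailing_intensities) - 1`
#' predecessors fire in successive high-frequency (gamma-like, `f_high` =
#' 49 Hz) blocks, the current step in the middle block of the cycle and
#' trailing steps in the blocks before it with decreasing intensity. Each
#' participating neuron emits up to `burst_spikes` spikes per active block,
#' each independently with probability `burst_scale * intensity`, jittered
#' uniformly within one high-frequency period. With the defaults the mean
#' episode drive is `3 * 0.8 * (1 + 0.75 + 0.5 + 0.25) = 6` spikes per
#' participating neuron per presentation.
#'
#' @param f_low low (theta-like) presentation frequency (Hz)
#' @param f_high high (gamma-like) block frequency (Hz)
#' @param trailing_intensities relative spike probability of the current
#'   step and its trailing steps (first entry = current)
#' @param burst_spikes maximum spikes per neuron per active block
#' @param burst_scale per-spike probability at intensity 1
#' @param dropout_per_step neurons removed from each step per presentation
#' @param episode_overlap_steps temporal overlap (in steps) between
#'   consecutive presentations
#' @param nu input noise rate (Hz per input neuron)
#' @param pacing_rate rate of the pacing inhibitory input neuron (Hz)
#' @param pacing_delay_range fixed per-target pacing delay range (ms)
#' @param step_repeat number of consecutive cycles each step occupies
#'   (1 for the simple/alternate variants, 7 for preplay)
#' @return an object of class `stimulus_config`
#' @export
stimulus_config <- function(f_low = 7, f_high = 49,
                            trailing_intensities = c(1, 0.75, 0.5, 0.25),
                            burst_spikes = 3, burst_scale = 0.8,
                            dropout_per_step = 1,
                            episode_overlap_steps = 4,
                            nu = 0.05, pacing_rate = 250,
                            pacing_delay_range = c(1, 4),
                            step_repeat = 1) {
  stopifnot(f_low > 0, f_high > 0,
            all(trailing_intensities >= 0), all(trailing_intensities <= 1),
            burst_spikes >= 1, burst_scale >= 0, burst_scale <= 1,
            dropout_per_step >= 0, episode_overlap_steps >= 0,
            nu >= 0, pacing_rate > 0, step_repeat >= 1)
  structure(list(f_low = f_low, f_high = f_high,
                 trailing_intensities = trailing_intensities,
                 burst_spikes = burst_spikes, burst_scale = burst_scale,
                 dropout_per_step = dropout_per_step,
                 episode_overlap_steps = episode_overlap_steps,
                 nu = nu, pacing_rate = pacing_rate,
                 pacing_delay_range = pacing_delay_range,
                 step_repeat = step_repeat),
            class = "stimulus_config")
}

#' Allocate input neurons to episodes
#'
#' Builds `n_episodes` episodes, each claiming `fraction` of the input
#' population split evenly over `n_steps` ordered temporal steps. In
#' `partitioned` mode episodes are grouped into blocks of `1 / fraction`
#' episodes; within a block the episodes are pairwise disjoint and their
#' union tiles the whole input population. In `random` mode members are
#' sampled independently per episode without regard for overlap or
#' redundant usage across episodes.
#'
#' @param n_input number of input neurons
#' @param mode `"partitioned"` or `"random"`
#' @param n_episodes number of episodes
#' @param fraction fraction of the input population per episode
#' @param n_steps temporal steps per episode
#' @param seed optional seed
#' @return an object of class `episode_set`
#' @export
allocate_episodes <- function(n_input, mode = c("partitioned", "random"),
                              n_episodes = 12, fraction = 0.25,
                              n_steps = 30, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  members <- as.integer(round(fraction * n_input))
  if (members %% n_steps != 0) {
    stop("fraction * n_input = ", members, " is not divisible by n_steps = ",
         n_steps, "; choose sizes so each temporal step gets an equal ",
         "number of input neurons")
  }
  m_step <- as.integer(members %/% n_steps)
  block_size <- round(1 / fraction)
  episodes <- vector("list", n_episodes)
  if (mode == "partitioned") {
    if (block_size * members != n_input) {
      stop("partitioned allocation needs fraction * n_input * (1/fraction) ",
           "== n_input; adjust fraction")
    }
    n_blocks <- ceiling(n_episodes / block_size)
    e <- 0L
    for (b in seq_len(n_blocks)) {
      perm <- sample.int(n_input)
      for (j in seq_len(block_size)) {
        e <- e + 1L
        if (e > n_episodes) break
        mem <- perm[(j - 1L) * members + seq_len(members)]
        episodes[[e]] <- list(
          episode_id = e, block_id = b,
          steps = split(mem, rep(seq_len(n_steps), each = m_step)))
      }
    }
  } else {
    for (e in seq_len(n_episodes)) {
      mem <- sample.int(n_input, members)
      episodes[[e]] <- list(
        episode_id = e, block_id = ceiling(e / block_size),
        steps = split(mem, rep(seq_len(n_steps), each = m_step)))
    }
  }
  structure(list(episodes = episodes, n_input = n_input, mode = mode,
                 n_episodes = n_episodes, n_steps = n_steps,
                 members_per_step = m_step, block_size = block_size),
            class = "episode_set")
}

#' @export
print.episode_set <- function(x, ...) {
  cat("<episode_set>", x$n_episodes, "episodes x", x$n_steps, "steps,",
      x$members_per_step, "input neurons per step (", x$mode,
      "allocation over", x$n_input, "inputs )\n")
  invisible(x)
}

#' Schedule episode presentations for one block
#'
#' Chooses which episode of a block is presented at each presentation slot
#' (i.i.d. uniform over the block) and when it starts. Consecutive
#' presentations overlap by `episode_overlap_steps` temporal steps: the
#' next presentation begins `(n_steps - overlap) * step_repeat`
#' low-frequency cycles after the previous one.
#'
#' @param episode_set an [allocate_episodes()] result
#' @param block_id which block to present
#' @param n_presentations number of presentations
#' @param cfg a [stimulus_config()]
#' @param seed optional seed
#' @return an object of class `presentation_schedule`
#' @export
schedule_presentations <- function(episode_set, block_id = 1,
                                   n_presentations, cfg = stimulus_config(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(episode_set$episodes, function(e) e$episode_id, integer(1))
  in_block <- ids[vapply(episode_set$episodes,
                         function(e) e$block_id == block_id, logical(1))]
  stopifnot(length(in_block) >= 1)
  n_steps <- episode_set$n_steps
  advance <- (n_steps - cfg$episode_overlap_steps) * cfg$step_repeat
  stopifnot(advance >= 1)
  pres <- data.frame(
    pres_idx = seq_len(n_presentations),
    episode_id = sample(in_block, n_presentations, replace = TRUE),
    start_cycle = (seq_len(n_presentations) - 1L) * advance)
  structure(list(presentations = pres, block_id = block_id, cfg = cfg,
                 n_steps = n_steps, cycle_ms = 1000 / cfg$f_low),
            class = "presentation_schedule")
}

# steps presented (with trailing index q = 0..n_trail-1) at cycle offset j
# (0-based) of a presentation; returns data.frame(step, q)
steps_at_offset <- function(j, n_steps, step_repeat, n_trail) {
  cs <- j %/% step_repeat + 1L # virtual current step (may exceed n_steps)
  q <- 0:(n_trail - 1L)
  st <- cs - q
  keep <- st >= 1L & st <= n_steps
  data.frame(step = st[keep], q = q[keep])
}

#' Render episode presentations into input spike trains
#'
#' Expands a presentation schedule into time-stamped, source-tagged input
#' spikes. Per low-frequency cycle the current step fires in the middle
#' high-frequency block and the trailing steps in the blocks before it with
#' decreasing intensity; every spike is jittered within one high-frequency
#' period. For each presentation, `dropout_per_step` members of every step
#' are chosen at random and omitted from the whole presentation; the
#' dropped identities are recorded in the annotations.
#'
#' @param schedule a [schedule_presentations()] result
#' @param episode_set the matching [allocate_episodes()] result
#' @param cfg a [stimulus_config()]; defaults to the schedule's
#' @param seed optional seed
#' @return an object of class `stimulus_schedule`: `spikes` (data.frame
#'   `time_ms`, `neuron_id`, `source`, `pres`), `annotations` (list of
#'   `cycles`, `dropped`, `presentations` data.frames) and `duration_ms`
#' @export
render_episode_spikes <- function(schedule, episode_set,
                                  cfg = schedule$cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_steps <- episode_set$n_steps
  n_trail <- length(cfg$trailing_intensities)
  T_low <- 1000 / cfg$f_low
  T_high <- 1000 / cfg$f_high
  blocks_per_cycle <- floor(cfg$f_high / cfg$f_low)
  mid <- blocks_per_cycle %/% 2
  if (mid < n_trail - 1L) {
    stop("not enough high-frequency blocks before mid-cycle for ",
         n_trail - 1L, " trailing steps")
  }
  rep_s <- cfg$step_repeat
  cyc_per_pres <- (n_steps + (n_trail - 1L)) * rep_s
  eps <- episode_set$episodes
  ids <- vapply(eps, function(e) e$episode_id, integer(1))
  pres <- schedule$presentations
  sp_t <- list(); sp_n <- list(); sp_p <- list()
  cyc_rows <- list(); drop_rows <- list()
  for (r in seq_len(nrow(pres))) {
    ep <- eps[[which(ids == pres$episode_id[r])]]
    dropped <- lapply(seq_len(n_steps), function(st) {
      mem <- ep$steps[[st]]
      nd <- min(cfg$dropout_per_step, length(mem) - 1L)
      if (nd <= 0) integer(0) else sample(mem, nd)
    })
    if (sum(lengths(dropped)) > 0) {
      drop_rows[[r]] <- data.frame(
        pres_idx = pres$pres_idx[r],
        step = rep(seq_len(n_steps),
                   vapply(dropped, length, integer(1))),
        neuron_id = unlist(dropped))
    }
    t0 <- pres$start_cycle[r] * T_low
    cur_step <- integer(cyc_per_pres); cur_step[] <- NA_integer_
    for (j in 0:(cyc_per_pres - 1L)) {
      saq <- steps_at_offset(j, n_steps, rep_s, n_trail)
      cs <- j %/% rep_s + 1L
      if (cs <= n_steps) cur_step[j + 1L] <- cs
      if (nrow(saq) == 0) next
      cyc_start <- t0 + j * T_low
      for (i in seq_len(nrow(saq))) {
        st <- saq$step[i]; q <- saq$q[i]
        mem <- setdiff(ep$steps[[st]], dropped[[st]])
        if (length(mem) == 0) next
        pr <- cfg$burst_scale * cfg$trailing_intensities[q + 1L]
        counts <- stats::rbinom(length(mem), cfg$burst_spikes, pr)
        tot <- sum(counts)
        if (tot == 0) next
        blk_start <- cyc_start + (mid - q) * T_high
        sp_t[[length(sp_t) + 1L]] <- blk_start + stats::runif(tot) * T_high
        sp_n[[length(sp_n) + 1L]] <- rep(mem, counts)
        sp_p[[length(sp_p) + 1L]] <- rep(pres$pres_idx[r], tot)
      }
    }
    jj <- which(!is.na(cur_step)) - 1L
    cyc_rows[[r]] <- data.frame(
      pres_idx = pres$pres_idx[r], episode_id = pres$episode_id[r],
      cycle = pres$start_cycle[r] + jj,
      t_start = t0 + jj * T_low,
      step = cur_step[jj + 1L])
  }
  spikes <- data.frame(time_ms = unlist(sp_t),
                       neuron_id = unlist(sp_n),
                       source = "episode",
                       pres = unlist(sp_p))
  o <- order(spikes$time_ms, spikes$neuron_id)
  spikes <- spikes[o, , drop = FALSE]
  rownames(spikes) <- NULL
  duration_ms <- (max(pres$start_cycle) + cyc_per_pres) * T_low
  structure(list(spikes = spikes,
                 annotations = list(
                   cycles = do.call(rbind, cyc_rows),
                   dropped = do.call(rbind, drop_rows),
                   presentations = pres),
                 cfg = cfg, episode_set = episode_set,
                 n_steps = n_steps, cycle_ms = T_low,
                 duration_ms = duration_ms),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat("<stimulus_schedule>", nrow(x$spikes), "input spikes over",
      round(x$duration_ms / 1000, 2), "s;",
      nrow(x$annotations$presentations), "presentations\n")
  cat("  sources:", paste(names(table(x$spikes$source)),
                          table(x$spikes$source), collapse = ", "), "\n")
  invisible(x)
}

#' Independent Poisson noise spikes
#'
#' @param nu rate (Hz per neuron)
#' @param neuron_ids input neurons to drive
#' @param duration_ms duration (ms)
#' @param seed optional seed
#' @return data.frame (`time_ms`, `neuron_id`, `source = "noise"`)
#' @export
noise_spikes <- function(nu, neuron_ids, duration_ms, seed = NULL) {
  stopifnot(nu >= 0, duration_ms >= 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(length(neuron_ids), nu * duration_ms / 1000)
  tot <- sum(counts)
  df <- data.frame(time_ms = stats::runif(tot) * duration_ms,
                   neuron_id = rep(neuron_ids, counts),
                   source = rep("noise", tot))
  df <- df[order(df$time_ms), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Pacing inhibitory input train
#'
#' The single fast inhibitory input neuron fires a strictly regular train
#' (default 250 Hz, 4 ms inter-spike interval). Each recurrent target is
#' assigned one fixed delay drawn uniformly from `delay_range`, constant
#' over the whole simulation.
#'
#' @param duration_ms duration (ms)
#' @param n_targets number of recurrent targets
#' @param rate firing rate (Hz)
#' @param delay_range per-target delay range (ms)
#' @param seed optional seed
#' @return `list(times = <ms>, delay_map = <ms per target>)`
#' @export
pacing_train <- function(duration_ms, n_targets, rate = 250,
                         delay_range = c(1, 4), seed = NULL) {
  stopifnot(duration_ms > 0, rate > 0)
  if (!is.null(seed)) set.seed(seed)
  period <- 1000 / rate
  list(times = if (period > duration_ms) numeric(0) else
         seq(period, duration_ms, by = period),
       delay_map = stats::runif(n_targets, delay_range[1], delay_range[2]))
}

#' Cue burst for preplay / replay recall
#'
#' After learning, an episode is reactivated by short gamma-frequency
#' bursts of 1-4 spikes from every member of its first (`start`, preplay)
#' or last (`end`, reverse replay) two temporal steps; all other inputs
#' stay silent apart from noise.
#'
#' @param episode one element of `episode_set$episodes`
#' @param which_end `"start"` or `"end"`
#' @param cfg a [stimulus_config()] (for the high-frequency period)
#' @param t_start cue onset (ms)
#' @param n_cue_steps number of steps cued (default 2)
#' @param seed optional seed
#' @return data.frame (`time_ms`, `neuron_id`, `source = "cue"`)
#' @export
cue_pattern <- function(episode, which_end = c("start", "end"),
                        cfg = stimulus_config(), t_start = 0,
                        n_cue_steps = 2, seed = NULL) {
  which_end <- match.arg(which_end)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- length(episode$steps)
  idx <- if (which_end == "start") seq_len(n_cue_steps) else
    (n_steps - n_cue_steps + 1L):n_steps
  members <- unlist(episode$steps[idx])
  T_high <- 1000 / cfg$f_high
  out_t <- list(); out_n <- list()
  for (m in members) {
    n_sp <- sample.int(4L, 1L)
    jit <- stats::runif(1) * T_high
    out_t[[length(out_t) + 1L]] <- t_start + jit + (0:(n_sp - 1L)) * T_high
    out_n[[length(out_n) + 1L]] <- rep(m, n_sp)
  }
  df <- data.frame(time_ms = unlist(out_t), neuron_id = unlist(out_n),
                   source = "cue")
  df <- df[order(df$time_ms), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assemble a complete engine-ready stimulus
#'
#' Combines a rendered episode schedule with Poisson noise over all input
#' neurons and the pacing train into a single source-tagged spike table
#' (pacing spikes carry `neuron_id = 0`). Extra spike tables (e.g. cue
#' bursts) can be appended via `extra`.
#'
#' @param episode_set an [allocate_episodes()] result
#' @param n_presentations presentations to schedule (ignored if
#'   `schedule` given)
#' @param cfg a [stimulus_config()]
#' @param block_id block to present; `NULL` presents nothing (noise and
#'   pacing only)
#' @param duration_ms total duration; defaults to the rendered schedule's
#'   span (required when `block_id` is `NULL`)
#' @param extra optional extra spike data.frame(s) to merge
#' @param seed optional seed
#' @return a `stimulus_schedule` whose `spikes` include all sources
#' @export
make_stimulus <- function(episode_set, n_presentations = 100,
                          cfg = stimulus_config(), block_id = 1,
                          duration_ms = NULL, extra = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(block_id)) {
    sched <- schedule_presentations(episode_set, block_id, n_presentations,
                                    cfg)
    stim <- render_episode_spikes(sched, episode_set, cfg)
    if (is.null(duration_ms)) duration_ms <- stim$duration_ms
  } else {
    if (is.null(duration_ms)) stop("duration_ms required without episodes")
    stim <- structure(list(
      spikes = data.frame(time_ms = numeric(0), neuron_id = integer(0),
                          source = character(0), pres = integer(0)),
      annotations = NULL, cfg = cfg, episode_set = episode_set,
      n_steps = episode_set$n_steps, cycle_ms = 1000 / cfg$f_low,
      duration_ms = duration_ms), class = "stimulus_schedule")
  }
  stim$duration_ms <- duration_ms
  noise <- noise_spikes(cfg$nu, seq_len(episode_set$n_input), duration_ms)
  pace <- pacing_train(duration_ms, 1, rate = cfg$pacing_rate)
  parts <- list(stim$spikes[, c("time_ms", "neuron_id", "source")],
                noise,
                data.frame(time_ms = pace$times,
                           neuron_id = rep(0L, length(pace$times)),
                           source = rep("pacing", length(pace$times))))
  if (!is.null(extra)) {
    if (is.data.frame(extra)) extra <- list(extra)
    parts <- c(parts, lapply(extra, function(d)
      d[, c("time_ms", "neuron_id", "source")]))
  }
  all_sp <- do.call(rbind, parts)
  all_sp <- all_sp[all_sp$time_ms <= duration_ms &
                     all_sp$time_ms >= 0, , drop = FALSE]
  o <- order(all_sp$time_ms, all_sp$neuron_id)
  all_sp <- all_sp[o, , drop = FALSE]
  rownames(all_sp) <- NULL
  stim$episode_spikes <- stim$spikes
  stim$spikes <- all_sp
  stim
}

#' Export a stimulus as delimited text
#'
#' Writes the spike table as tab-separated (`time_ms`, `neuron_id`,
#' `source`) and, if annotations exist, a sidecar keyed by presentation
#' index (`<path>.presentations.tsv`, `<path>.dropped.tsv`).
#'
#' @param stim a `stimulus_schedule`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_stimulus <- function(stim, path) {
  utils::write.table(stim$spikes[, c("time_ms", "neuron_id", "source")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(stim$annotations)) {
    utils::write.table(stim$annotations$presentations,
                       paste0(path, ".presentations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(stim$annotations$dropped)) {
      utils::write.table(stim$annotations$dropped,
                         paste0(path, ".dropped.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
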