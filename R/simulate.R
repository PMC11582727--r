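#' Simulate one block of the task for a synthetic agent
#'
#' Runs the trial loop of a single block: reward (or switch) assignment, the
#' agent's choice, and the reward logic (baiting + change-over delay in the
#' value task; instructed switches in the control task). In the value task the
#' agent is an LNP agent whose delivered-reward histories reset at the block
#' boundary (the reward ratio changes there); on a trial where the COD
#' withholds feedback the agent records a 0, since its history is defined by
#' delivered feedback only. In the control task the agent follows the
#' instruction with probability `compliance`, and its first choice is random.
#'
#' @param block_spec one block from [build_session_plan()].
#' @param config a [task_config()].
#' @param params an [lnp_params()] (value task).
#' @param compliance instruction-following probability (control task).
#' @param seed integer seed for this block.
#' @param t0 session clock at block start, seconds.
#' @return list with `trials` (data frame, one row per trial) and `t_end`.
#' @export
simulate_block <- function(block_spec, config, params, compliance = 0.95,
                           seed, t0 = 0) {
  tpb <- config$trials_per_block
  n <- filter_length(config)
  tm <- config$timing

  arrivals <- switches <- NULL
  if (block_spec$task == "value") {
    arrivals <- assign_rewards(block_spec, config, derive_seed(seed, 1))
  } else {
    switches <- assign_switches(block_spec, config, derive_seed(seed, 1))
  }

  restore <- local_seed(derive_seed(seed, 2))
  on.exit(restore())

  state <- new_bait_state()
  r1_hist <- r2_hist <- numeric(0)  # most recent first
  prev_choice <- NA_character_
  prev_feedback <- NA_character_

  choice <- character(tpb); feedback <- character(tpb)
  delivered <- logical(tpb); is_switch <- logical(tpb)
  gen_v1 <- gen_v2 <- gen_dv <- gen_p1 <- rep(NA_real_, tpb)
  sw_assigned <- rep(NA_integer_, tpb)
  arr1 <- arr2 <- asg1 <- asg2 <- rep(NA_integer_, tpb)
  onset_fix <- onset_stim <- onset_resp <- onset_fbk <- numeric(tpb)

  t <- t0
  for (i in seq_len(tpb)) {
    fix_dur <- stats::runif(1, tm$fixation_mean - tm$fixation_jitter,
                            tm$fixation_mean + tm$fixation_jitter)
    rt <- stats::runif(1, 0.4, 1.2)
    onset_fix[i] <- t
    onset_stim[i] <- t + fix_dur
    onset_resp[i] <- onset_stim[i] + rt
    onset_fbk[i] <- onset_stim[i] + tm$response_window
    t <- onset_fbk[i] + tm$feedback

    if (block_spec$task == "value") {
      ch <- lnp_choose(r1_hist, r2_hist, params, n, prev_choice)
      gen_v1[i] <- ch$v1; gen_v2[i] <- ch$v2
      gen_dv[i] <- ch$dv; gen_p1[i] <- ch$p1
      res <- step_value_trial(state, ch$choice, prev_choice,
                              arrivals[i, ], config)
      state <- res$state
      choice[i] <- ch$choice
      feedback[i] <- res$feedback
      delivered[i] <- res$reward_delivered
      is_switch[i] <- res$is_switch
      arr1[i] <- arrivals[i, 1L]; arr2[i] <- arrivals[i, 2L]
      asg1[i] <- res$assigned[1L]; asg2[i] <- res$assigned[2L]
      # delivered-reward history (most recent first)
      r1_hist <- c(as.numeric(delivered[i] && ch$choice == "S1"), r1_hist)
      r2_hist <- c(as.numeric(delivered[i] && ch$choice == "S2"), r2_hist)
      if (length(r1_hist) > n) {
        r1_hist <- r1_hist[seq_len(n)]; r2_hist <- r2_hist[seq_len(n)]
      }
    } else {
      if (is.na(prev_choice)) {
        chc <- sample(c("S1", "S2"), 1L)
      } else {
        chc <- instruction_choose(prev_choice, prev_feedback, compliance)
      }
      res <- step_control_trial(switches[i])
      choice[i] <- chc
      feedback[i] <- res$feedback
      delivered[i] <- FALSE
      is_switch[i] <- !is.na(prev_choice) && chc != prev_choice
      sw_assigned[i] <- switches[i]
    }
    prev_choice <- choice[i]
    prev_feedback <- feedback[i]
  }

  trials <- data.frame(
    session = block_spec$session,
    block = block_spec$block,
    trial = seq_len(tpb),
    task = block_spec$task,
    condition = block_spec$condition,
    ratio = if (is.null(block_spec$ratio)) NA_character_
            else paste(block_spec$ratio, collapse = ":"),
    s1_stim = block_spec$trials$s1_stim,
    s2_stim = block_spec$trials$s2_stim,
    s1_side = block_spec$trials$s1_side,
    arrival_s1 = arr1,
    arrival_s2 = arr2,
    assigned_s1 = asg1,
    assigned_s2 = asg2,
    switch_assigned = sw_assigned,
    choice = choice,
    is_switch = is_switch,
    feedback = feedback,
    reward_delivered = delivered,
    gen_v1 = gen_v1, gen_v2 = gen_v2, gen_dv = gen_dv, gen_p1 = gen_p1,
    onset_fix = onset_fix, onset_stim = onset_stim,
    onset_resp = onset_resp, onset_fbk = onset_fbk,
    stringsAsFactors = FALSE
  )
  list(trials = trials, t_end = t)
}

#' Simulate one synthetic participant
#'
#' Builds the session plan for `(config, seed)` and runs every block with a
#' single LNP agent (value task) / instruction follower (control task). Onset
#' times run on a continuous per-session clock.
#'
#' @param config a [task_config()].
#' @param params an [lnp_params()] — the agent's generative ground truth.
#' @param compliance instruction-following probability in the control task.
#' @param seed integer seed (all block streams derive from it).
#' @param participant participant identifier (integer).
#' @return a `behavioral_dataset`: the trial data frame with attributes
#'   `params`, `compliance`, `config`, `seed`, `participant`.
#' @export
simulate_participant <- function(config, params, compliance = 0.95, seed,
                                 participant = 1L) {
  plan <- build_session_plan(config, seed)
  out <- vector("list", length(plan))
  t_end <- stats::setNames(numeric(config$sessions), NULL)
  clock <- rep(0, config$sessions)
  for (i in seq_along(plan)) {
    b <- plan[[i]]
    res <- simulate_block(b, config, params, compliance,
                          seed = derive_seed(seed, 7, b$block),
                          t0 = clock[b$session])
    clock[b$session] <- res$t_end
    out[[i]] <- res$trials
  }
  trials <- do.call(rbind, out)
  trials <- cbind(participant = participant, trials)
  structure(trials,
            class = c("behavioral_dataset", "data.frame"),
            params = params, compliance = compliance,
            config = config, seed = seed, participant = participant)
}

#' Simulate a cohort of synthetic participants
#'
#' The generative stand-in for the study's group: `n_participants` agents run
#' the full experiment. `params_spec` is either a single [lnp_params()]
#' (shared ground truth) or a list `list(mean = lnp_params(...), sd = c(tau =,
#' mu =, sigma =))`, in which case each participant's parameters are drawn
#' from independent normals around the group mean (tau truncated below at
#' 0.1).
#'
#' @param config a [task_config()].
#' @param n_participants number of agents (> 0).
#' @param params_spec see above.
#' @param seed integer root seed.
#' @param compliance control-task instruction-following probability.
#' @return list of `behavioral_dataset` objects.
#' @export
simulate_cohort <- function(config, n_participants, params_spec, seed,
                            compliance = 0.95) {
  if (n_participants < 1) stop("n_participants must be positive")
  lapply(seq_len(n_participants), function(i) {
    p <- draw_params(params_spec, derive_seed(seed, 11, i))
    simulate_participant(config, p, compliance,
                         seed = derive_seed(seed, 13, i), participant = i)
  })
}

draw_params <- function(params_spec, seed) {
  if (inherits(params_spec, "lnp_params")) return(params_spec)
  stopifnot(is.list(params_spec), inherits(params_spec$mean, "lnp_params"))
  m <- params_spec$mean
  s <- params_spec$sd
  with_seed(seed, {
    tau <- max(0.1, stats::rnorm(1, m$tau, s[["tau"]]))
    mu <- stats::rnorm(1, m$mu, s[["mu"]])
    sigma <- max(0, stats::rnorm(1, m$sigma, s[["sigma"]]))
    lnp_params(tau, mu, sigma)
  })
}

#' Write / read a behavioural trial table
#'
#' Tab-separated text with a header naming the trial-record fields; metadata
#' (ground-truth parameters, seed, configuration hash) goes to a JSON sidecar
#' `<path>.meta.json`. `read_trials` restores the `behavioral_dataset` class
#' (metadata attributes are restored from the sidecar when present).
#'
#' @param dataset a `behavioral_dataset`.
#' @param path output file path (TSV).
#' @return `write_trials` returns `path` invisibly; `read_trials` a
#'   `behavioral_dataset`.
#' @export
write_trials <- function(dataset, path) {
  utils::write.table(as.data.frame(dataset), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  params <- attr(dataset, "params")
  meta <- list(
    participant = attr(dataset, "participant"),
    seed = attr(dataset, "seed"),
    compliance = attr(dataset, "compliance"),
    params = if (is.null(params)) NULL else unclass(params),
    config_hash = if (is.null(attr(dataset, "config"))) NULL
                  else config_hash(attr(dataset, "config"))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  attrs <- list()
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$params)) {
      attrs$params <- lnp_params(meta$params$tau, meta$params$mu,
                                 meta$params$sigma)
    }
    attrs$seed <- meta$seed
    attrs$participant <- meta$participant
    attrs$compliance <- meta$compliance
  }
  structure(df, class = c("behavioral_dataset", "data.frame"),
            params = attrs$params, seed = attrs$seed,
            participant = attrs$participant, compliance = attrs$compliance)
}
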