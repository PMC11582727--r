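#' Draw the reward-assignment clock for a value-task block
#'
#' Rewards are scheduled independently for the two options as per-trial
#' Bernoulli arrivals (a discrete-time rendering of a Poisson process, trials
#' being the task's time unit). The per-option rates split the overall reward
#' rate exactly in the block's programmed ratio, so at the defaults a block of
#' 72 trials receives 24 arrivals on average; a trial may carry an arrival for
#' neither, either, or both options. These are the raw clock ticks: during
#' play, [step_value_trial()] suspends the clock for an option whose bait
#' slot is occupied, so a tick then assigns no reward. With
#' `reward_schedule = "quota"` the expected per-option counts are rounded and
#' placed at uniformly random distinct trials instead.
#'
#' @param block_spec a value-task block from [build_session_plan()].
#' @param config a [task_config()].
#' @param seed integer seed for this block's arrival stream.
#' @return integer matrix with `trials_per_block` rows and columns
#'   `S1`, `S2`; entries are 0/1 bait arrivals.
#' @export
assign_rewards <- function(block_spec, config, seed) {
  stopifnot(identical(block_spec$task, "value"))
  tpb <- config$trials_per_block
  rr <- block_spec$ratio
  p <- config$overall_reward_rate * rr / sum(rr)
  arr <- with_seed(seed, {
    if (config$reward_schedule == "quota") {
      k <- round(p * tpb)
      m <- matrix(0L, tpb, 2)
      for (j in 1:2) if (k[j] > 0) m[sample.int(tpb, k[j]), j] <- 1L
      m
    } else {
      matrix(stats::rbinom(2L * tpb, 1L, rep(p, each = tpb)), ncol = 2)
    }
  })
  colnames(arr) <- c("S1", "S2")
  arr
}

#' Assign instructed switches to a control-task block
#'
#' Each trial independently carries an instructed switch with probability
#' `control_switch_rate` (default 1/3); the switch is earned by whichever
#' option is chosen on that trial, so a follower sees yellow ("switch")
#' feedback on one third of trials on average. There is no baiting and no
#' change-over delay in the control task.
#'
#' @param block_spec a control-task block from [build_session_plan()].
#' @param config a [task_config()].
#' @param seed integer seed.
#' @return integer 0/1 vector of per-trial instructed-switch flags.
#' @export
assign_switches <- function(block_spec, config, seed) {
  stopifnot(identical(block_spec$task, "control"))
  with_seed(seed,
            stats::rbinom(config$trials_per_block, 1L,
                          config$control_switch_rate))
}

#' Initial bait state of a value-task block
#'
#' @return a `bait_state`: per-option baited counts plus an optional pending
#'   change-over-delay record.
#' @export
new_bait_state <- function() {
  structure(list(baited = c(S1 = 0L, S2 = 0L), pending_cod = NULL),
            class = "bait_state")
}

#' Resolve one value-task trial against the bait state
#'
#' Applies the trial's reward logic in order: (i) this trial's Poisson-clock
#' ticks become assigned (baited) rewards on options whose bait slot is free
#' — as in concurrent variable-interval schedules, the clock is suspended
#' while an option already holds a bait or a pending withheld reward, so a
#' tick on an occupied slot assigns nothing; (ii) a pending change-over-delay
#' (COD) reward is delivered if the agent chose the same option again, and
#' otherwise reverts to a bait on its option (or is forfeited when
#' `cod_forfeit`); (iii) if the chosen option is baited, the reward is
#' delivered immediately on a stay trial, but on a switch trial the COD
#' withholds it for one trial (converted to a pending record). Feedback is
#' yellow iff a reward is delivered on this trial, else blue.
#'
#' @param state a `bait_state`.
#' @param choice `"S1"` or `"S2"` (missed trials are not stepped).
#' @param prev_choice previous trial's choice, or `NA` on the first trial of a
#'   block (the first choice is never a switch).
#' @param arrivals integer length-2 vector of this trial's Poisson-clock
#'   ticks (`S1`, `S2`).
#' @param config a [task_config()] (uses `cod_enabled`, `cod_forfeit`,
#'   `bait_cap`).
#' @return list with `feedback` (`"yellow"`/`"blue"`), `reward_delivered`
#'   (logical), `is_switch` (logical), `assigned` (integer length-2: ticks
#'   realized as assigned rewards this trial) and `state` (the updated
#'   `bait_state`).
#' @export
step_value_trial <- function(state, choice, prev_choice, arrivals, config) {
  if (is.na(choice) || !choice %in% c("S1", "S2")) {
    stop("step_value_trial requires a choice of S1 or S2")
  }
  baited <- state$baited
  pending <- state$pending_cod

  occupied <- baited >= config$bait_cap
  if (!is.null(pending)) occupied[pending$option] <- TRUE
  assigned <- as.integer(arrivals > 0 & !occupied)
  baited <- baited + assigned

  is_switch <- !is.na(prev_choice) && choice != prev_choice
  delivered <- FALSE

  if (!is.null(pending)) {
    if (choice == pending$option) {
      delivered <- TRUE
      pending <- NULL
    } else {
      if (!config$cod_forfeit) {
        baited[pending$option] <- min(baited[pending$option] + 1L,
                                      config$bait_cap)
      }
      pending <- NULL
    }
  }

  if (!delivered && baited[choice] > 0L) {
    if (is_switch && config$cod_enabled) {
      # earned on a switch trial: withheld for one trial
      baited[choice] <- baited[choice] - 1L
      pending <- list(option = choice)
    } else {
      baited[choice] <- baited[choice] - 1L
      delivered <- TRUE
    }
  }

  state$baited <- baited
  state["pending_cod"] <- list(pending)  # keep the element when NULL
  list(feedback = if (delivered) "yellow" else "blue",
       reward_delivered = delivered,
       is_switch = is_switch,
       assigned = assigned,
       state = state)
}

#' Resolve one control-task trial
#'
#' Yellow feedback iff an instructed switch was assigned on this trial (i.e.
#' earned by the chosen option), else blue.
#'
#' @param switch_assigned 0/1 flag for this trial.
#' @return list with `feedback` and `switch_assigned`.
#' @export
step_control_trial <- function(switch_assigned) {
  list(feedback = if (switch_assigned > 0) "yellow" else "blue",
       switch_assigned = as.logical(switch_assigned > 0))
}
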