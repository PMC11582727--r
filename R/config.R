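#' Task configuration for the dynamic-foraging experiment
#'
#' Builds a validated configuration object describing one participant's
#' experiment: block/session structure, the dynamic reward schedule of the
#' value task, the instructed-switch schedule of the control task, and trial
#' timing. Defaults reproduce the published design: 72-trial blocks, two
#' sessions of 9 value blocks (the 3 reward ratios crossed with the 3 modality
#' conditions) followed by 3 control blocks, an overall reward rate of 1/3
#' split across the two options in ratios 1:3, 1:1 or 3:1, baiting with a
#' change-over delay (COD), and a 33% instructed-switch rate in the control
#' task.
#'
#' @param trials_per_block trials per block (even; default 72).
#' @param blocks_per_session total blocks per session; must equal
#'   `value_blocks_per_session + control_blocks_per_session` (default 12).
#' @param value_blocks_per_session value-task blocks per session (default 9).
#' @param control_blocks_per_session control-task blocks per session (default 3).
#' @param sessions number of sessions (default 2).
#' @param overall_reward_rate probability that a reward is assigned somewhere
#'   on a given trial of the value task (default 1/3).
#' @param reward_ratios list of length-2 numeric vectors giving the S1:S2
#'   reward split of each schedule (default `list(c(1,3), c(1,1), c(3,1))`).
#' @param modality_conditions character vector of modality conditions.
#' @param cod_enabled logical; apply the change-over delay in the value task.
#' @param cod_forfeit logical; if `TRUE` a withheld COD reward is forfeited
#'   when the agent switches away again, otherwise it reverts to a bait
#'   (default `FALSE`).
#' @param bait_cap maximum number of simultaneously baited rewards per option
#'   (default 1; further arrivals on a baited option are absorbed).
#' @param reward_schedule `"stochastic"` (independent per-trial Bernoulli
#'   arrivals, mean 24 per block at the defaults) or `"quota"` (exactly
#'   `round(overall_reward_rate * trials_per_block)` arrivals placed at
#'   random trials).
#' @param control_switch_rate per-trial probability of an instructed switch in
#'   the control task (default 1/3).
#' @param timing named list of timing constants in seconds; see Details.
#' @param tr_seconds fMRI repetition time in seconds (default 1.5).
#'
#' @details `timing` accepts `fixation_mean` (1.8), `fixation_jitter` (0.45,
#'   giving uniform jitter on `fixation_mean` +/- `fixation_jitter`),
#'   `stimulus` (1.0), `response_window` (2.25) and `feedback` (0.25); the
#'   implied mean trial duration is 4.3 s.
#'
#' @return An object of class `task_config` (a named list).
#' @export
task_config <- function(trials_per_block = 72L,
                        blocks_per_session = 12L,
                        value_blocks_per_session = 9L,
                        control_blocks_per_session = 3L,
                        sessions = 2L,
                        overall_reward_rate = 1 / 3,
                        reward_ratios = list(c(1, 3), c(1, 1), c(3, 1)),
                        modality_conditions = c("AudAud", "VisVis", "AudVis"),
                        cod_enabled = TRUE,
                        cod_forfeit = FALSE,
                        bait_cap = 1L,
                        reward_schedule = c("stochastic", "quota"),
                        control_switch_rate = 1 / 3,
                        timing = list(),
                        tr_seconds = 1.5) {
  reward_schedule <- match.arg(reward_schedule)
  default_timing <- list(fixation_mean = 1.8, fixation_jitter = 0.45,
                         stimulus = 1.0, response_window = 2.25,
                         feedback = 0.25)
  timing <- utils::modifyList(default_timing, timing)

  cfg <- list(
    trials_per_block = as.integer(trials_per_block),
    blocks_per_session = as.integer(blocks_per_session),
    value_blocks_per_session = as.integer(value_blocks_per_session),
    control_blocks_per_session = as.integer(control_blocks_per_session),
    sessions = as.integer(sessions),
    overall_reward_rate = overall_reward_rate,
    reward_ratios = reward_ratios,
    modality_conditions = modality_conditions,
    cod_enabled = isTRUE(cod_enabled),
    cod_forfeit = isTRUE(cod_forfeit),
    bait_cap = as.integer(bait_cap),
    reward_schedule = reward_schedule,
    control_switch_rate = control_switch_rate,
    timing = timing,
    tr_seconds = tr_seconds
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

#' Validate a task configuration
#'
#' Checks the structural invariants of a [task_config()]: reward rate in
#' (0, 1), positive ratio entries, even trial counts, and a block layout that
#' covers the ratio-by-modality grid.
#'
#' @param config a `task_config`.
#' @return `config`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_task_config <- function(config) {
  stopifnot(inherits(config, "task_config"))
  if (!(config$overall_reward_rate > 0 && config$overall_reward_rate < 1)) {
    stop("overall_reward_rate must lie in (0, 1)")
  }
  if (config$trials_per_block %% 2L != 0L) {
    stop("trials_per_block must be even (side counterbalancing)")
  }
  if (config$blocks_per_session !=
      config$value_blocks_per_session + config$control_blocks_per_session) {
    stop("blocks_per_session must equal value + control blocks per session")
  }
  n_ratio <- length(config$reward_ratios)
  n_mod <- length(config$modality_conditions)
  if (config$value_blocks_per_session != n_ratio * n_mod) {
    stop("value_blocks_per_session must cover each (ratio, modality) pair once")
  }
  if (config$control_blocks_per_session != n_mod) {
    stop("control_blocks_per_session must be one block per modality")
  }
  for (rr in config$reward_ratios) {
    if (length(rr) != 2L || any(rr <= 0)) {
      stop("each reward ratio must be a length-2 positive vector")
    }
  }
  if (config$control_switch_rate < 0 || config$control_switch_rate > 1) {
    stop("control_switch_rate must lie in [0, 1]")
  }
  if (config$bait_cap < 1L) stop("bait_cap must be >= 1")
  invisible(config)
}

#' Reward-filter length implied by a configuration
#'
#' The linear filter spans half of the trials over which the reward ratio is
#' held constant, i.e. half a block: 36 lags for the default 72-trial blocks.
#'
#' @param config a `task_config` (or a number of trials per block).
#' @return integer filter length `n`.
#' @export
filter_length <- function(config) {
  tpb <- if (inherits(config, "task_config")) config$trials_per_block
         else as.integer(config)
  as.integer(tpb %/% 2L)
}

#' Stimulus identities of the two option sets per modality condition
#'
#' S1 = {low pitch, green, auditory}; S2 = {high pitch, red, visual}.
#'
#' @param condition one of `"AudAud"`, `"VisVis"`, `"AudVis"`.
#' @return named character vector with elements `S1`, `S2`.
#' @export
option_stimuli <- function(condition) {
  switch(condition,
         AudAud = c(S1 = "low_pitch", S2 = "high_pitch"),
         VisVis = c(S1 = "green", S2 = "red"),
         AudVis = c(S1 = "auditory", S2 = "visual"),
         stop("unknown modality condition: ", condition))
}

#' Read / write a task configuration as YAML
#'
#' The configuration round-trips losslessly through a nested key/value YAML
#' file whose keys mirror the `task_config` fields.
#'
#' @param path file path.
#' @param config a `task_config`.
#' @return `read_task_config` returns a `task_config`; `write_task_config`
#'   returns `path` invisibly.
#' @export
read_task_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$reward_ratios)) {
    raw$reward_ratios <- lapply(raw$reward_ratios, as.numeric)
  }
  do.call(task_config, raw)
}

#' @rdname read_task_config
#' @export
write_task_config <- function(config, path) {
  validate_task_config(config)
  out <- unclass(config)
  out$reward_ratios <- lapply(out$reward_ratios, as.numeric)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' A short hex digest of the deparsed configuration, used to tag outputs so a
#' run can be matched to the configuration that produced it. Not
#' cryptographic.
#'
#' @param config a `task_config`.
#' @return character scalar.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  %d sessions x %d blocks (%d value + %d control), %d trials/block\n",
              x$sessions, x$blocks_per_session, x$value_blocks_per_session,
              x$control_blocks_per_session, x$trials_per_block))
  cat(sprintf("  overall reward rate %.3f, ratios %s; control switch rate %.3f\n",
              x$overall_reward_rate,
              paste(vapply(x$reward_ratios,
                           function(r) paste(r, collapse = ":"), ""),
                    collapse = ", "),
              x$control_switch_rate))
  cat(sprintf("  baiting cap %d, COD %s, schedule %s\n",
              x$bait_cap, if (x$cod_enabled) "on" else "off",
              x$reward_schedule))
  invisible(x)
}
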