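#' Plan the block structure of one or more sessions
#'
#' Lays out every block of the experiment before any choice is made: each
#' session consists of the value-task blocks — the reward ratios crossed with
#' the modality conditions, each combination used exactly once per session, in
#' randomized order — followed by one control-task block per modality. Within
#' each block, option sides (and, in the inter-modal condition, the concrete
#' tone/checkerboard pairings) are pseudo-randomized with exact
#' counterbalancing over the block's trials.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the same `(config, seed)` pair always yields an
#'   identical plan.
#' @return A list of block specifications (class `session_plan`). Each block
#'   is a list with `session`, `block` (global index), `task`, `condition`,
#'   `ratio` (S1:S2 reward split, value task only), and a per-trial data frame
#'   `trials` with columns `trial`, `s1_side` (`"left"`/`"right"`), and
#'   `s1_stim`/`s2_stim` identities.
#' @export
build_session_plan <- function(config, seed) {
  validate_task_config(config)
  n_mod <- length(config$modality_conditions)
  n_ratio <- length(config$reward_ratios)

  plan <- list()
  blk <- 0L
  for (ses in seq_len(config$sessions)) {
    # randomized order of the ratio x modality grid for the value task
    grid <- expand.grid(ratio_idx = seq_len(n_ratio),
                        modality = config$modality_conditions,
                        stringsAsFactors = FALSE)
    ord <- with_seed(derive_seed(seed, ses, 0),
                     sample.int(nrow(grid)))
    grid <- grid[ord, , drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      blk <- blk + 1L
      plan[[blk]] <- make_block_spec(
        config, session = ses, block = blk, task = "value",
        condition = grid$modality[i],
        ratio = config$reward_ratios[[grid$ratio_idx[i]]],
        seed = derive_seed(seed, ses, blk)
      )
    }
    ctrl_mods <- with_seed(derive_seed(seed, ses, 999),
                           sample(config$modality_conditions))
    for (m in ctrl_mods) {
      blk <- blk + 1L
      plan[[blk]] <- make_block_spec(
        config, session = ses, block = blk, task = "control",
        condition = m, ratio = NULL,
        seed = derive_seed(seed, ses, blk)
      )
    }
  }
  structure(plan, class = "session_plan", seed = seed)
}

make_block_spec <- function(config, session, block, task, condition, ratio,
                            seed) {
  tpb <- config$trials_per_block
  stim <- option_stimuli(condition)

  if (condition == "AudVis") {
    # counterbalance side x (tone identity) x (colour identity): 8 cells
    cells <- expand.grid(s1_side = c("left", "right"),
                         s1_stim = c("low_pitch", "high_pitch"),
                         s2_stim = c("green", "red"),
                         stringsAsFactors = FALSE)
  } else {
    cells <- expand.grid(s1_side = c("left", "right"),
                         s1_stim = stim[["S1"]],
                         s2_stim = stim[["S2"]],
                         stringsAsFactors = FALSE)
  }
  if (tpb %% nrow(cells) != 0L) {
    stop(sprintf(
      "trials_per_block (%d) is not divisible by the %d counterbalancing cells",
      tpb, nrow(cells)))
  }
  reps <- tpb / nrow(cells)
  idx <- rep(seq_len(nrow(cells)), each = reps)
  idx <- with_seed(seed, sample(idx))
  trials <- data.frame(trial = seq_len(tpb),
                       s1_side = cells$s1_side[idx],
                       s1_stim = cells$s1_stim[idx],
                       s2_stim = cells$s2_stim[idx],
                       stringsAsFactors = FALSE)
  list(session = session, block = block, task = task, condition = condition,
       ratio = ratio, seed = seed, trials = trials)
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %d blocks (seed %d)\n", length(x),
              attr(x, "seed")))
  for (b in x) {
    cat(sprintf("  block %2d  ses %d  %-7s %-6s %s\n", b$block, b$session,
                b$task, b$condition,
                if (is.null(b$ratio)) "" else paste(b$ratio, collapse = ":")))
  }
  invisible(x)
}
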