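# shared fixtures: built in code, cached across test files within a run

group_params <- function() lnp_params(tau = 1.22, mu = 0.07, sigma = 0.81)

# small config for fast structural tests: 48-trial blocks (divisible by the
# 8 AudVis counterbalancing cells, and long enough for the default 20-bin
# choice fit on the single-session control blocks), one session
small_config <- function(...) {
  task_config(trials_per_block = 48L, sessions = 1L, ...)
}

# a cached default-config participant simulated at the group-mean parameters
fixture_env <- new.env(parent = emptyenv())

default_participant <- function(seed = 101L) {
  key <- paste0("p", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- simulate_participant(
      task_config(), group_params(), compliance = 0.95, seed = seed)
  }
  fixture_env[[key]]
}

# the full 20-agent cohort used by the acceptance tests (simulated once)
acceptance_cohort <- function(seed = 2024L, n = 20L) {
  key <- paste0("cohort", seed, "_", n)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- simulate_cohort(
      task_config(), n, group_params(), seed = seed, compliance = 0.95)
  }
  fixture_env[[key]]
}

# empty event table with the package's column layout
empty_event_table_for_test <- function() {
  ev <- data.frame(onset = numeric(0), duration = numeric(0),
                   event_kind = character(0), task = character(0),
                   condition = character(0), option = character(0),
                   modulator = character(0), value = numeric(0),
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

# hand-built trial table for value-computation tests: one value block with
# prescribed choices and feedback
manual_value_block <- function(choice, feedback, condition = "AudAud",
                               block = 1L) {
  n <- length(choice)
  data.frame(
    participant = 1L, session = 1L, block = block, trial = seq_len(n),
    task = "value", condition = condition, ratio = "1:1",
    s1_stim = "low_pitch", s2_stim = "high_pitch", s1_side = "left",
    arrival_s1 = 0L, arrival_s2 = 0L, assigned_s1 = 0L, assigned_s2 = 0L,
    switch_assigned = NA_integer_,
    choice = choice,
    is_switch = c(FALSE, choice[-1] != choice[-n]),
    feedback = feedback,
    reward_delivered = feedback == "yellow",
    gen_v1 = NA_real_, gen_v2 = NA_real_, gen_dv = NA_real_,
    gen_p1 = NA_real_,
    onset_fix = (seq_len(n) - 1) * 4.3, onset_stim = (seq_len(n) - 1) * 4.3 + 1.8,
    onset_resp = (seq_len(n) - 1) * 4.3 + 2.5,
    onset_fbk = (seq_len(n) - 1) * 4.3 + 4.05,
    stringsAsFactors = FALSE
  )
}
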