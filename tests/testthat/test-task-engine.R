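test_that("session plan covers the ratio x modality grid with counterbalanced sides", {
  cfg <- task_config()
  plan <- build_session_plan(cfg, seed = 1L)
  expect_length(plan, 24L)  # 2 sessions x 12 blocks

  for (ses in 1:2) {
    blocks <- Filter(function(b) b$session == ses, plan)
    value <- Filter(function(b) b$task == "value", blocks)
    control <- Filter(function(b) b$task == "control", blocks)
    expect_length(value, 9L)
    expect_length(control, 3L)
    combos <- vapply(value, function(b)
      paste(paste(b$ratio, collapse = ":"), b$condition), "")
    expect_setequal(combos, c(t(outer(c("1:3", "1:1", "3:1"),
                                      c("AudAud", "VisVis", "AudVis"),
                                      paste))))
    expect_setequal(vapply(control, `[[`, "", "condition"),
                    c("AudAud", "VisVis", "AudVis"))
  }

  # per 72-trial block each option appears on each side exactly 36 times
  for (b in plan) {
    expect_identical(sum(b$trials$s1_side == "left"), 36L)
    if (b$condition == "AudVis") {
      cells <- table(b$trials$s1_side, b$trials$s1_stim, b$trials$s2_stim)
      expect_true(all(cells == 9L))  # 8 cells x 9 repetitions
    }
  }
})

test_that("session plans are deterministic given the seed and reject bad trial counts", {
  cfg <- task_config()
  expect_identical(build_session_plan(cfg, 7L), build_session_plan(cfg, 7L))
  p1 <- build_session_plan(cfg, 7L)
  p2 <- build_session_plan(cfg, 8L)
  expect_false(identical(p1, p2))

  # 20 trials is not divisible by the 8 AudVis counterbalancing cells
  cfg20 <- task_config(trials_per_block = 20L)
  expect_error(build_session_plan(cfg20, 1L), "counterbalancing")
})

test_that("reward assignment follows the programmed rates", {
  cfg <- task_config()
  plan <- build_session_plan(cfg, 1L)
  b11 <- Filter(function(b) b$task == "value" &&
                  identical(b$ratio, c(1, 1)), plan)[[1]]

  tot <- per_opt <- 0
  n_blocks <- 300L
  for (i in seq_len(n_blocks)) {
    arr <- assign_rewards(b11, cfg, seed = i)
    tot <- tot + sum(arr)
    per_opt <- per_opt + sum(arr[, "S1"])
  }
  # mean arrivals 24/block at rate 1/3; per option 12 at ratio 1:1
  expect_equal(tot / n_blocks, 24, tolerance = 0.04)
  expect_equal(per_opt / n_blocks, 12, tolerance = 0.06)

  # degenerate rate: no arrivals ever
  cfg0 <- cfg
  cfg0$overall_reward_rate <- 0
  expect_true(all(assign_rewards(b11, cfg0, 1L) == 0L))

  # quota mode: exactly round(p * 72) arrivals per option
  cfgq <- task_config(reward_schedule = "quota")
  b13 <- Filter(function(b) b$task == "value" &&
                  identical(b$ratio, c(1, 3)), plan)[[1]]
  arr <- assign_rewards(b13, cfgq, 5L)
  expect_identical(colSums(arr), c(S1 = 6, S2 = 18))
})

test_that("value-trial resolution matches a hand-traced state-machine oracle", {
  cfg <- task_config()

  # independent oracle: literal transcription of the reward rules
  oracle <- function(choices, arrivals) {
    bait <- c(S1 = 0L, S2 = 0L); pend <- NULL; prev <- NA
    fb <- character(length(choices)); del <- logical(length(choices))
    for (t in seq_along(choices)) {
      ch <- choices[t]
      free <- c(bait["S1"] == 0L && !identical(pend, "S1"),
                bait["S2"] == 0L && !identical(pend, "S2"))
      bait <- bait + as.integer(arrivals[t, ] == 1L & free)
      delivered <- FALSE
      if (!is.null(pend)) {
        if (ch == pend) { delivered <- TRUE; pend <- NULL }
        else { bait[pend] <- bait[pend] + 1L; pend <- NULL }
      }
      if (!delivered && bait[ch] > 0L) {
        bait[ch] <- bait[ch] - 1L
        if (!is.na(prev) && ch != prev) pend <- ch else delivered <- TRUE
      }
      fb[t] <- if (delivered) "yellow" else "blue"
      del[t] <- delivered
      prev <- ch
    }
    list(feedback = fb, delivered = del)
  }

  run_engine <- function(choices, arrivals) {
    st <- new_bait_state(); prev <- NA
    fb <- character(length(choices)); del <- logical(length(choices))
    for (t in seq_along(choices)) {
      res <- step_value_trial(st, choices[t], prev, arrivals[t, ], cfg)
      st <- res$state; fb[t] <- res$feedback; del[t] <- res$reward_delivered
      prev <- choices[t]
    }
    list(feedback = fb, delivered = del)
  }

  # exhaustive: all 3-trial choice sequences x all per-trial arrival patterns
  opts <- c("S1", "S2")
  arr_patterns <- expand.grid(a1 = 0:1, a2 = 0:1)
  for (c1 in opts) for (c2 in opts) for (c3 in opts) {
    for (p1 in 1:4) for (p2 in 1:4) for (p3 in 1:4) {
      arrivals <- rbind(as.integer(arr_patterns[p1, ]),
                        as.integer(arr_patterns[p2, ]),
                        as.integer(arr_patterns[p3, ]))
      colnames(arrivals) <- c("S1", "S2")
      choices <- c(c1, c2, c3)
      expect_identical(run_engine(choices, arrivals),
                       oracle(choices, arrivals))
    }
  }
})

test_that("change-over delay withholds and then delivers a switched-onto bait", {
  cfg <- task_config()
  st <- new_bait_state()
  arr1 <- c(S1 = 0L, S2 = 1L)  # bait arrives on S2 while agent sits on S1
  r1 <- step_value_trial(st, "S1", NA, arr1, cfg)
  expect_identical(r1$feedback, "blue")

  none <- c(S1 = 0L, S2 = 0L)
  r2 <- step_value_trial(r1$state, "S2", "S1", none, cfg)  # switch onto bait
  expect_identical(r2$feedback, "blue")
  expect_false(r2$reward_delivered)

  r3 <- step_value_trial(r2$state, "S2", "S2", none, cfg)  # stay: delivered
  expect_identical(r3$feedback, "yellow")
  expect_true(r3$reward_delivered)

  # nothing baited, stay: blue, state unchanged
  st0 <- new_bait_state()
  r <- step_value_trial(st0, "S1", "S1", none, cfg)
  expect_identical(r$feedback, "blue")
  expect_identical(r$state, st0)

  # missed trials are not stepped
  expect_error(step_value_trial(st0, NA, "S1", none, cfg), "S1 or S2")
})

test_that("control task yields yellow on instructed-switch trials only", {
  cfg0 <- task_config(control_switch_rate = 0)
  plan <- build_session_plan(cfg0, 3L)
  ctrl <- Filter(function(b) b$task == "control", plan)[[1]]
  expect_true(all(assign_switches(ctrl, cfg0, 1L) == 0L))

  cfg1 <- task_config(control_switch_rate = 1)
  sw <- assign_switches(ctrl, cfg1, 1L)
  expect_true(all(sw == 1L))
  # a perfect follower alternates deterministically after trial 1
  d <- simulate_block(ctrl, cfg1, group_params(), compliance = 1,
                      seed = 9L)$trials
  expect_true(all(d$feedback == "yellow"))
  expect_true(all(d$choice[-1] != d$choice[-nrow(d)]))
})

test_that("rewards delivered never exceed rewards assigned, and an alternating collector gets nearly all", {
  cfg <- task_config()
  d <- default_participant()
  dv <- d[d$task == "value", ]
  for (b in unique(dv$block)) {
    sub <- dv[dv$block == b, ]
    expect_lte(sum(sub$reward_delivered),
               sum(sub$assigned_s1 + sub$assigned_s2))
  }

  # baiting completeness: COD off, strict alternation, long block
  cfg_nc <- task_config(cod_enabled = FALSE)
  plan <- build_session_plan(cfg_nc, 2L)
  blk <- Filter(function(b) b$task == "value", plan)[[1]]
  for (seed in 1:5) {
    arr <- assign_rewards(blk, cfg_nc, seed)
    st <- new_bait_state(); prev <- NA; delivered <- 0L; assigned <- 0L
    for (t in seq_len(nrow(arr))) {
      ch <- if (t %% 2L == 0L) "S1" else "S2"
      res <- step_value_trial(st, ch, prev, arr[t, ], cfg_nc)
      st <- res$state; prev <- ch
      delivered <- delivered + res$reward_delivered
      assigned <- assigned + sum(res$assigned)
    }
    expect_gte(delivered, assigned - 2L)
  }
})

test_that("identical config and seed give identical trial tables", {
  cfg <- small_config()
  d1 <- simulate_participant(cfg, group_params(), 0.95, seed = 5L)
  d2 <- simulate_participant(cfg, group_params(), 0.95, seed = 5L)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})
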