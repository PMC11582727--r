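test_that("a single unit event reproduces the closed-form double-gamma HRF", {
  ev <- empty_event_table_for_test()
  ev[1, ] <- list(0, 0, "stimulus", "value", "AudAud", NA, "none", 1)
  tr <- 1.5
  n_scans <- 22L  # scan grid inside the 32 s kernel support
  m <- convolve_hrf(ev, tr = tr, n_scans = n_scans)
  scan_t <- (seq_len(n_scans) - 1) * tr
  oracle <- dgamma(scan_t, shape = 6, rate = 1) -
    dgamma(scan_t, shape = 16, rate = 1) / 6
  expect_equal(unname(m[, 1]), oracle, tolerance = 1e-10)
  # peak near 5 s, undershoot trough near 15 s
  expect_equal(scan_t[which.max(m[, 1])], 4.5, tolerance = 1.5)
  expect_equal(scan_t[which.min(m[, 1])], 15, tolerance = 1.5)
})

test_that("convolution is linear: superposition and zero inputs", {
  base <- empty_event_table_for_test()
  e1 <- base; e1[1, ] <- list(3, 0, "stimulus", "value", "AudAud", NA,
                              "none", 1)
  e2 <- base; e2[1, ] <- list(12, 0, "stimulus", "value", "AudAud", NA,
                              "none", 1)
  both <- rbind(e1, e2)
  class(both) <- class(e1)
  n_scans <- 40L
  m1 <- convolve_hrf(e1, n_scans = n_scans)
  m2 <- convolve_hrf(e2, n_scans = n_scans)
  mb <- convolve_hrf(both, n_scans = n_scans)
  expect_equal(unname(mb[, 1]), unname(m1[, 1] + m2[, 1]), tolerance = 1e-12)

  # a modulator with no variance is mean-centered to an identically zero column
  ez <- base
  ez[1, ] <- list(3, 0, "stimulus", "value", "AudAud", "S1", "lpSV", 0.4)
  ez[2, ] <- list(9, 0, "stimulus", "value", "AudAud", "S1", "lpSV", 0.4)
  mz <- convolve_hrf(ez, n_scans = n_scans)
  expect_true(all(mz[, "lpSV"] == 0))

  # events after scan end are refused
  late <- base; late[1, ] <- list(1e4, 0, "stimulus", "value", "AudAud", NA,
                                  "none", 1)
  expect_error(convolve_hrf(late, n_scans = 10L), "after scan end")
})

test_that("serial orthogonalization residualizes later columns only", {
  set.seed(4)
  X <- cbind(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  X[, "b"] <- X[, "b"] + 0.7 * X[, "a"]
  X[, "c"] <- X[, "c"] + 0.3 * X[, "a"] - 0.5 * X[, "b"]
  out <- serial_orthogonalize(X, list(c("a", "b", "c")))

  expect_identical(out[, "a"], X[, "a"])
  expect_lt(abs(sum(out[, "a"] * out[, "b"])), 1e-10)
  expect_lt(abs(sum(out[, "a"] * out[, "c"])), 1e-10)
  expect_lt(abs(sum(out[, "b"] * out[, "c"])), 1e-10)

  # equals classical sequential projection computed independently
  b_oracle <- residuals(lm(X[, "b"] ~ 0 + X[, "a"]))
  c_oracle <- residuals(lm(X[, "c"] ~ 0 + X[, "a"] + b_oracle))
  expect_equal(unname(out[, "b"]), unname(b_oracle), tolerance = 1e-10)
  expect_equal(unname(out[, "c"]), unname(c_oracle), tolerance = 1e-10)

  # already-orthogonal columns pass through unchanged
  Q <- qr.Q(qr(matrix(rnorm(60), 20)))
  colnames(Q) <- c("x", "y", "z")
  expect_equal(serial_orthogonalize(Q, list(c("x", "y", "z")))[, ],
               Q[, ], tolerance = 1e-12)

  # the column span of the group is preserved
  v <- rnorm(100)
  proj <- function(M, v) M %*% qr.coef(qr(M), v)
  expect_equal(proj(X, v), proj(out[, c("a", "b", "c")], v),
               tolerance = 1e-8)

  # collinear later column collapses to zero with a warning
  Xc <- cbind(a = X[, "a"], b = 2 * X[, "a"])
  expect_warning(out2 <- serial_orthogonalize(Xc, list(c("a", "b"))),
                 "collinear")
  expect_true(all(out2[, "b"] == 0))
})

test_that("the event table carries identity events and per-option modulators", {
  d <- default_participant()
  fit <- fit_lnp(d, task = "value")
  ev <- build_event_table(d, fit$values, session = 1L)

  # an AudAud value trial: identity + lpSV + hpSV rows at the same onset
  dv <- d[d$task == "value" & d$condition == "AudAud" & d$session == 1, ]
  t0 <- dv$onset_stim[1]
  rows <- ev[ev$onset == t0 & ev$event_kind == "stimulus", ]
  expect_setequal(rows$modulator, c("none", "lpSV", "hpSV"))

  # the SV modulators equal the fitted value series exactly
  sv <- ev[ev$modulator %in% c("lpSV", "gSV", "aSV"), ]
  merged <- merge(
    data.frame(onset = d$onset_stim[d$task == "value" & d$session == 1],
               block = d$block[d$task == "value" & d$session == 1],
               trial = d$trial[d$task == "value" & d$session == 1]),
    fit$values, by = c("block", "trial"))
  m2 <- merge(sv, merged, by = "onset")
  expect_equal(m2$value, m2$v1, tolerance = 1e-12)

  # control trials carry 0/1 compliance modulators for both options
  ctl <- ev[ev$task == "control" & ev$modulator == "compliance", ]
  expect_true(all(ctl$value %in% c(0, 1)))
  expect_identical(nrow(ctl),
                   2L * sum(d$task == "control" & d$session == 1))
  # a high-compliance follower mostly earns modulator 1
  expect_gt(mean(ctl$value), 0.85)

  # an empty dataset produces an empty table with a valid header
  empty <- d[0, ]
  ev0 <- build_event_table(empty, fit$values, session = 1L)
  expect_identical(nrow(ev0), 0L)
  expect_true(all(c("onset", "duration", "event_kind", "modulator",
                    "value") %in% names(ev0)))
})

test_that("the full design matrix has the 35 published regressors", {
  d <- default_participant()
  fit <- fit_lnp(d, task = "value")
  # the two compliance modulators of a control condition are identical by
  # construction, so serial orthogonalization zeroes the second with a warning
  X <- suppressWarnings(build_design_matrix(d, fit$values, tr = 1.5))
  expect_identical(ncol(X), 35L)
  expect_true(all(X[, "ctl_AudAud_cmp2"] == 0))
  expect_true(all(c("lpSV", "hpSV", "gSV", "rSV", "aSV", "vSV",
                    "val_AudAud", "ctl_VisVis", "response", "feedback",
                    "instruction", "constant") %in% colnames(X)))
  # motion placeholders are identically zero; the constant is one
  expect_true(all(X[, paste0("motion", 1:6)] == 0))
  expect_true(all(X[, "constant"] == 1))
  # 7 run-indicator columns for the 8 runs
  expect_identical(sum(grepl("^run", colnames(X))), 7L)
  # orthogonalized modulator pairs
  expect_lt(abs(sum(X[, "lpSV"] * X[, "hpSV"])), 1e-10)
  expect_lt(abs(sum(X[, "aSV"] * X[, "vSV"])), 1e-10)
})

test_that("events, matrices, trial tables and configs round-trip through their files", {
  d <- default_participant()
  fit <- fit_lnp(d, task = "value")
  ev <- build_event_table(d, fit$values, session = 1L)
  tmp <- withr::local_tempdir()

  f_ev <- file.path(tmp, "events.tsv")
  export_events(ev, f_ev)
  ev2 <- read_events(f_ev)
  expect_equal(as.data.frame(ev2), as.data.frame(ev), tolerance = 1e-12)

  X <- convolve_hrf(ev[ev$onset < 60, ], n_scans = 70L)
  f_mx <- file.path(tmp, "design.tsv")
  export_matrix(X, f_mx)
  X2 <- read_matrix(f_mx)
  expect_equal(unclass(X2)[, ], unclass(X)[, ], tolerance = 1e-12)
  expect_equal(attr(X2, "tr"), attr(X, "tr"))

  f_tr <- file.path(tmp, "trials.tsv")
  write_trials(d, f_tr)
  d2 <- read_trials(f_tr)
  strip <- function(x) {
    attributes(x) <- attributes(x)[c("names", "row.names", "class")]
    class(x) <- "data.frame"
    x
  }
  expect_equal(strip(as.data.frame(d2)), strip(as.data.frame(d)),
               tolerance = 1e-12)
  expect_equal(attr(d2, "params")$tau, attr(d, "params")$tau)

  cfg <- task_config(sessions = 1L)
  f_cfg <- file.path(tmp, "config.yaml")
  write_task_config(cfg, f_cfg)
  expect_equal(read_task_config(f_cfg), cfg)

  # header-only file for empty events
  export_events(ev[0, ], file.path(tmp, "empty.tsv"))
  lines <- readLines(file.path(tmp, "empty.tsv"))
  expect_length(lines, 1L)
})
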