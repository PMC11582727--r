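test_that("composite series encodes choices, rewards and the switch exclusion", {
  choice <- c("S1", "S1", "S1", "S2", "S2", "S2", "S2", "S1", "S1", "S1")
  feedback <- c("yellow", "blue", "blue", "blue", "yellow", "blue", "blue",
                "blue", "yellow", "blue")
  d <- manual_value_block(choice, feedback)
  ser <- build_composite_series(d)

  expect_identical(ser$r[1], 1L)    # S1 chosen and rewarded
  expect_identical(ser$c[1], 1L)
  expect_identical(ser$r[6], 0L)    # S2 chosen, unrewarded
  expect_identical(ser$c[6], -1L)
  expect_identical(ser$r[5], -1L)   # S2 chosen and rewarded

  # exactly the two switch trials (4 and 8) are invalid
  expect_identical(which(!ser$valid), c(4L, 8L))
})

test_that("Wiener-Hopf weights equal ordinary least squares on the lagged design", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    Tn <- sample(60:200, 1)
    ser <- data.frame(block = rep(1L, Tn), trial = seq_len(Tn),
                      r = sample(c(-1L, 0L, 1L), Tn, replace = TRUE),
                      c = sample(c(-1L, 1L), Tn, replace = TRUE),
                      valid = TRUE)
    class(ser) <- c("composite_series", "data.frame")
    est <- estimate_filter_weights(ser, n = n)

    # independent oracle: lm on the explicitly built lagged design
    X <- sapply(seq_len(n), function(k) c(rep(0, k), ser$r[seq_len(Tn - k)]))
    fit <- lm(ser$c ~ X)
    expect_equal(unname(est$alpha_raw), unname(coef(fit)[-1]),
                 tolerance = 1e-8)
    expect_equal(sum(est$alpha_hat), 1, tolerance = 1e-10)
  }
})

test_that("reward histories with no predictive structure give near-zero weights", {
  set.seed(8)
  Tn <- 40000L
  ser <- data.frame(block = rep(seq_len(Tn %/% 200L), each = 200L),
                    trial = rep(seq_len(200L), Tn %/% 200L),
                    r = sample(c(-1L, 0L, 1L), Tn, replace = TRUE,
                               prob = c(1, 4, 1) / 6),
                    c = sample(c(-1L, 1L), Tn, replace = TRUE),
                    valid = TRUE)
  class(ser) <- c("composite_series", "data.frame")
  est <- estimate_filter_weights(ser, n = 5L)
  se <- 1 / sqrt(Tn * var(ser$r))
  expect_true(all(abs(est$alpha_raw) < 3 * se))
})

test_that("degenerate inputs to the filter estimator raise errors", {
  ser <- data.frame(block = 1L, trial = 1:50, r = 0L,
                    c = rep(c(-1L, 1L), 25), valid = TRUE)
  class(ser) <- c("composite_series", "data.frame")
  expect_error(estimate_filter_weights(ser, 3L), "degenerate reward history")

  ser2 <- data.frame(block = 1L, trial = 1:10,
                     r = rep(c(1L, 0L), 5), c = rep(c(1L, -1L), 5),
                     valid = TRUE)
  class(ser2) <- c("composite_series", "data.frame")
  expect_error(estimate_filter_weights(ser2, 9L), "valid trials")
})

test_that("exponential-decay fitting recovers its own functional form and matches a grid oracle", {
  k <- 1:36
  w <- 0.4 * exp(-k / 2)
  fit <- fit_exponential_decay(w)
  expect_equal(fit$tau, 2, tolerance = 1e-6)
  expect_equal(fit$A, 0.4, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  # noisy weights: best tau matches a dense grid search within the grid step
  set.seed(5)
  for (tau_true in c(0.5, 1, 2, 4)) {
    wn <- 0.5 * exp(-k / tau_true) + rnorm(36, sd = 0.02)
    fit <- fit_exponential_decay(wn)
    grid <- seq(0.05, 36, by = 0.01)
    rss_grid <- vapply(grid, function(tau) {
      ek <- exp(-k / tau)
      a <- sum(ek * wn) / sum(ek^2)  # profile out the amplitude
      sum((wn - a * ek)^2)
    }, 0)
    expect_lt(abs(fit$tau - grid[which.min(rss_grid)]), 0.02)
  }
})

test_that("subjective values are causal filter sums truncated at block starts", {
  # all-zero reward history
  d0 <- manual_value_block(rep("S1", 8), rep("blue", 8))
  w <- exp_filter_weights(2, 5)
  v0 <- compute_subjective_values(d0, w)
  expect_true(all(v0$v1 == 0 & v0$v2 == 0 & v0$dv == 0))

  # S1 rewarded on every past trial: v1 = 1 once n trials have elapsed
  d1 <- manual_value_block(rep("S1", 10), rep("yellow", 10))
  v1 <- compute_subjective_values(d1, w)
  expect_equal(v1$v1[6:10], rep(1, 5), tolerance = 1e-12)
  expect_equal(v1$v1[1], 0)

  # hand dot product: r1 = [1,0,1,0,0] most recent first
  hand <- manual_value_block(rep("S1", 6),
                             c("blue", "blue", "yellow", "blue", "yellow",
                               "blue"))
  alpha <- c(0.5, 0.25, 0.125, 0.0625, 0.0625)
  vh <- compute_subjective_values(hand, alpha)
  expect_equal(vh$v1[6], 0.625, tolerance = 1e-12)
})

test_that("future trials cannot influence present subjective values", {
  d <- manual_value_block(rep(c("S1", "S2"), 10),
                          rep(c("yellow", "blue"), 10))
  w <- exp_filter_weights(1.5, 8)
  v_before <- compute_subjective_values(d, w)
  d2 <- d
  d2$feedback[15:20] <- "yellow"
  d2$reward_delivered[15:20] <- TRUE
  v_after <- compute_subjective_values(d2, w)
  expect_equal(v_before[1:15, ], v_after[1:15, ], tolerance = 1e-12)

  # upgrading an S1 outcome to rewarded can only increase v1
  d3 <- d
  d3$feedback[3] <- "yellow"
  d3$reward_delivered[3] <- TRUE
  v3 <- compute_subjective_values(d3, w)
  expect_true(all(v3$v1 - v_before$v1 >= -1e-12))
})

test_that("the binned cumulative-normal fit recovers generative choice parameters", {
  # estimator-level recovery: choices sampled from the normal CDF on a frozen
  # dv stream (every trial a free choice)
  d <- default_participant()
  w <- exp_filter_weights(1.22, 36)
  vals <- compute_subjective_values(d, w, reward = "delivered")
  set.seed(11)
  p <- pnorm(vals$dv, 0.07, 0.81)
  cc <- ifelse(runif(nrow(vals)) < p, 1L, -1L)
  ser <- data.frame(block = vals$block, trial = vals$trial,
                    r = 0L, c = cc, valid = TRUE)
  class(ser) <- c("composite_series", "data.frame")
  fit <- fit_choice_probability(vals, ser, n_bins = 20L)
  expect_identical(nrow(fit$bins), 20L)
  expect_lt(abs(fit$mu - 0.07), 0.08)       # within simulation error
  expect_lt(abs(fit$sigma - 0.81), 0.15)

  # trial-level probit agrees with the binned estimate
  fit_ml <- fit_choice_probability(vals, ser, method = "probit")
  expect_lt(abs(fit_ml$mu - fit$mu), 0.08)
  expect_lt(abs(fit_ml$sigma - fit$sigma), 0.15)

  # fitted curve is monotone nondecreasing over the observed dv range
  grid <- seq(min(vals$dv), max(vals$dv), length.out = 50)
  expect_true(all(diff(pnorm(grid, fit$mu, fit$sigma)) >= 0))
})

test_that("choice-probability fitting validates its inputs", {
  vals <- data.frame(block = 1L, trial = 1:30, v1 = 0.5, v2 = 0.5,
                     dv = 0, absdv = 0)
  ser <- data.frame(block = 1L, trial = 1:30, r = 0L,
                    c = rep(c(1L, -1L), 15), valid = TRUE)
  class(ser) <- c("composite_series", "data.frame")
  expect_error(fit_choice_probability(vals, ser, n_bins = 10L),
               "no value variation")
  expect_error(fit_choice_probability(vals[1:5, ], ser[1:5, ],
                                      n_bins = 10L), "fewer valid trials")
})

test_that("deterministic prediction thresholds at the fitted bias and repeats on ties", {
  expect_identical(predict_choice(c(0.11, -0.3, 0.1), mu = 0.1),
                   c("S1", "S2", "S2"))
  # the tie at dv = mu repeats the preceding prediction
  expect_identical(predict_choice(c(0.5, 0.1, -0.5), mu = 0.1)[2], "S1")

  # on its own generator the rule attains the analytic accuracy ceiling
  set.seed(21)
  dv <- rnorm(30000, 0, 0.4)
  p <- pnorm(dv, 0.07, 0.81)
  actual <- ifelse(runif(length(dv)) < p, "S1", "S2")
  acc <- mean(predict_choice(dv, 0.07) == actual)
  ceiling_acc <- mean(pmax(p, 1 - p))
  expect_lt(abs(acc - ceiling_acc), 3 * sqrt(0.25 / length(dv)))
})

test_that("the full per-participant fit averages per-modality estimates", {
  d <- default_participant()
  fit <- fit_lnp(d, task = "value")
  expect_setequal(names(fit$fits), c("AudAud", "VisVis", "AudVis"))
  expect_equal(fit$tau, mean(vapply(fit$fits, function(f) f$exp$tau, 0)))
  expect_identical(fit$n, 36L)
  # pooled mode produces a single fit
  fitp <- fit_lnp(d, task = "value", by_modality = FALSE)
  expect_identical(names(fitp$fits), "pooled")
  # values stay on the reward-fraction scale
  expect_true(all(fit$values$v1 >= 0 & fit$values$v1 <= 1 + 1e-9))
  expect_true(all(abs(fit$values$dv) <= 1 + 1e-9))
})
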