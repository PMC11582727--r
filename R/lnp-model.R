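#' Composite reward and choice series
#'
#' Collapses the two options into signed composite series: per-trial composite
#' reward `r = r1 - r2` (+1 when S1 was chosen and rewarded, -1 when S2 was,
#' 0 otherwise) and composite choice `c = c1 - c2` (+1 for S1, -1 for S2).
#' Because the reward assignment is symmetric over the options, their impact
#' on choice is equal and opposite, so this single pair of series carries the
#' full learning signal. Trials on which the choice just changed (switch
#' trials, whose reward is withheld by the change-over delay) and missed
#' trials are flagged invalid: they are excluded as regression *targets*, but
#' their rewards remain part of the history.
#'
#' In the value task the reinforcing event is the delivered reward (yellow
#' feedback). The control task pays no rewards — its performance currency is
#' instruction-following — so when the same machinery is fitted there the
#' reward-analog is "chosen and instruction correctly followed"
#' (`signal = "auto"` picks the task-appropriate signal; both can be forced).
#'
#' @param dataset a `behavioral_dataset` (or its data frame).
#' @param task `"value"` (default) or `"control"`.
#' @param conditions optional character vector of modality conditions to keep.
#' @param min_valid minimum number of valid trials required (default 1).
#' @param signal reinforcement signal defining `r`: `"auto"` (default:
#'   delivered reward in the value task, compliance in the control task),
#'   `"reward"` (yellow feedback) or `"compliance"`.
#' @return a `composite_series` data frame with columns `block`, `trial`,
#'   `r`, `c`, `valid`.
#' @export
build_composite_series <- function(dataset, task = "value", conditions = NULL,
                                   min_valid = 1L,
                                   signal = c("auto", "reward", "compliance")) {
  signal <- match.arg(signal)
  if (signal == "auto") signal <- if (task == "control") "compliance"
                                  else "reward"
  df <- as.data.frame(dataset)
  df <- df[df$task == task, , drop = FALSE]
  if (!is.null(conditions)) df <- df[df$condition %in% conditions, , drop = FALSE]
  if (nrow(df) == 0L) stop("no trials for the requested task/conditions")
  df <- df[order(df$block, df$trial), , drop = FALSE]

  reinforced <- if (signal == "compliance") {
    unlist(lapply(split(seq_len(nrow(df)), df$block), function(idx) {
      control_compliance(df$choice[idx], df$feedback[idx]) == 1L
    }), use.names = FALSE)
  } else {
    df$feedback == "yellow"
  }
  s1 <- df$choice == "S1"
  s2 <- df$choice == "S2"
  missed <- !(s1 | s2)
  r <- ifelse(s1 & reinforced, 1L, ifelse(s2 & reinforced, -1L, 0L))
  cc <- ifelse(s1, 1L, ifelse(s2, -1L, NA_integer_))
  valid <- !df$is_switch & !missed
  out <- data.frame(block = df$block, trial = df$trial,
                    r = r, c = cc, valid = valid)
  if (sum(out$valid) < min_valid) {
    stop(sprintf("only %d valid trials; %d required", sum(out$valid),
                 min_valid))
  }
  class(out) <- c("composite_series", "data.frame")
  out
}

# lagged design matrix of r within blocks (zero-padded at block starts)
lagged_design <- function(series, n) {
  blocks <- split(seq_len(nrow(series)), series$block)
  X <- matrix(0, nrow(series), n)
  for (idx in blocks) {
    rb <- series$r[idx]
    Tb <- length(rb)
    for (k in seq_len(min(n, Tb))) {
      rows <- idx[(k + 1):Tb]
      if (k < Tb) X[rows, k] <- rb[seq_len(Tb - k)]
    }
  }
  X
}

#' Estimate linear reward-filter weights by the Wiener-Hopf equations
#'
#' Solves `alpha = Crr^{-1} Crc`, where `Crr` is the n-lag auto-covariance
#' matrix of the composite reward series and `Crc` the cross-covariance of the
#' lagged rewards with the composite choice. Covariances are computed on
#' mean-centered series with 1/T normalization, using only valid trials as
#' targets; lags never cross block boundaries (history before a block start
#' counts as 0). This is numerically identical to ordinary least squares of
#' `c` on the lagged-`r` design with an intercept. The returned relative
#' weights `alpha_hat` are normalized to sum to 1.
#'
#' @param series a [build_composite_series()] result.
#' @param n filter length in trials (default: 36, half of the default
#'   72-trial block over which the reward ratio is constant).
#' @param ridge_threshold condition number of `Crr` above which a small ridge
#'   penalty is applied (flagged in the diagnostics).
#' @return a `filter_estimate`: list with `alpha_raw`, `alpha_hat`, `n`,
#'   `condition_number`, `ridged`, `n_targets`.
#' @export
estimate_filter_weights <- function(series, n = 36L, ridge_threshold = 1e8) {
  stopifnot(n >= 1)
  if (stats::var(series$r) == 0) stop("degenerate reward history")
  X <- lagged_design(series, n)
  keep <- series$valid & !is.na(series$c)
  if (sum(keep) <= n + 1L) {
    stop(sprintf("need more than n + 1 = %d valid trials, have %d",
                 n + 1L, sum(keep)))
  }
  X <- X[keep, , drop = FALSE]
  y <- series$c[keep]
  Tn <- length(y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  Crr <- crossprod(Xc) / Tn
  Crc <- crossprod(Xc, yc) / Tn
  kap <- kappa(Crr, exact = FALSE)
  ridged <- FALSE
  if (!is.finite(kap) || kap > ridge_threshold) {
    ridged <- TRUE
    Crr <- Crr + diag(1e-6 * mean(diag(Crr)), n)
  }
  alpha <- drop(solve(Crr, Crc))
  s <- sum(alpha)
  alpha_hat <- if (abs(s) > .Machine$double.eps) alpha / s
               else rep(NA_real_, n)
  structure(list(alpha_raw = alpha, alpha_hat = alpha_hat, n = n,
                 condition_number = kap, ridged = ridged, n_targets = Tn),
            class = "filter_estimate")
}

#' @export
print.filter_estimate <- function(x, ...) {
  cat(sprintf("<filter_estimate> n = %d lags, %d target trials%s\n", x$n,
              x$n_targets, if (x$ridged) " (ridged)" else ""))
  cat("  alpha_hat[1:5]:", sprintf("%.4f", utils::head(x$alpha_hat, 5)), "\n")
  invisible(x)
}

#' Fit an exponential decay to filter weights
#'
#' Least-squares fit of `w(k) = A * exp(-k / tau)` to the filter weights over
#' lags `k = 1..n`, with `tau` constrained to `(0, n]`. Multiple starting
#' values guard against local minima; the best converged fit is returned.
#'
#' Given a `filter_estimate`, the fit is performed on the raw weights: the
#' time scale is invariant to the overall scale (the amplitude absorbs it),
#' so the fitted `tau` equals the fit to the normalized weights whenever
#' their sum is positive, while remaining well-defined when a noisy
#' normalization sum would flip or explode the relative weights.
#'
#' @param estimate a `filter_estimate`, or a numeric vector of weights.
#' @param tau_starts starting values for `tau`.
#' @return an `exp_fit`: list with `A`, `tau`, `rss`, `r2`, `converged`.
#' @export
fit_exponential_decay <- function(estimate,
                                  tau_starts = c(0.5, 1, 2, 4, 8, 16)) {
  w <- if (inherits(estimate, "filter_estimate")) estimate$alpha_raw
       else as.numeric(estimate)
  n <- length(w)
  if (anyNA(w)) stop("weights contain NA; cannot fit exponential decay")
  k <- seq_len(n)
  best <- NULL
  for (t0 in tau_starts) {
    a0 <- max(w[1], 1e-3) * exp(1 / t0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = list(A = a0, tau = t0),
        lower = c(A = -50, tau = 1e-3),
        upper = c(A = 50, tau = n),
        fn = function(p) w - p$A * exp(-k / p$tau),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(A = fit$par$A, tau = fit$par$tau, rss = rss,
                   info = fit$info)
    }
  }
  if (is.null(best)) stop("exponential-decay fit failed for all starts")
  tss <- sum((w - mean(w))^2)
  structure(list(A = best$A, tau = best$tau, rss = best$rss,
                 r2 = if (tss > 0) 1 - best$rss / tss else NA_real_,
                 converged = best$info %in% 1:4),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> tau = %.3f trials, A = %.3f, R^2 = %.3f\n",
              x$tau, x$A, x$r2))
  invisible(x)
}

#' Trial-by-trial subjective values from filter weights
#'
#' Applies Eq.-style causal filtering: the subjective value of option i on
#' trial t is the weighted sum of its delivered rewards on the previous `n`
#' trials, `v_i(t) = sum_k alpha_hat[k] * r_i(t - k)`, with lags truncated at
#' the block start (missing history counts 0). With nonnegative normalized
#' weights, values live in [0, 1] and the differential value `dv = v1 - v2`
#' in [-1, 1].
#'
#' @param dataset a `behavioral_dataset`.
#' @param alpha_hat numeric vector of (normalized) filter weights.
#' @param task `"value"` or `"control"`.
#' @param conditions optional modality filter.
#' @param reward what counts as a reward in the history: `"feedback"`
#'   (default; yellow feedback), `"delivered"` (actual delivered rewards; all
#'   zero in the control task, which is what makes value-task-fitted
#'   predictions fall to chance there) or `"compliance"` (chosen and
#'   instruction correctly followed — the control task's reinforcement
#'   currency, used when fitting the model to control-task behaviour).
#' @return a `value_series` data frame: `block`, `trial`, `v1`, `v2`, `dv`,
#'   `absdv`.
#' @export
compute_subjective_values <- function(dataset, alpha_hat, task = "value",
                                      conditions = NULL,
                                      reward = c("feedback", "delivered",
                                                 "compliance")) {
  reward <- match.arg(reward)
  df <- as.data.frame(dataset)
  df <- df[df$task == task, , drop = FALSE]
  if (!is.null(conditions)) df <- df[df$condition %in% conditions, , drop = FALSE]
  df <- df[order(df$block, df$trial), , drop = FALSE]
  n <- length(alpha_hat)
  yellow <- switch(reward,
    delivered = as.logical(df$reward_delivered),
    compliance = unlist(lapply(split(seq_len(nrow(df)), df$block),
                               function(idx) {
      control_compliance(df$choice[idx], df$feedback[idx]) == 1L
    }), use.names = FALSE),
    df$feedback == "yellow")
  r1 <- as.numeric(df$choice == "S1" & yellow)
  r2 <- as.numeric(df$choice == "S2" & yellow)
  v1 <- v2 <- numeric(nrow(df))
  for (idx in split(seq_len(nrow(df)), df$block)) {
    Tb <- length(idx)
    b1 <- r1[idx]; b2 <- r2[idx]
    w1 <- w2 <- numeric(Tb)
    for (k in seq_len(min(n, Tb - 1L))) {
      rows <- (k + 1L):Tb
      w1[rows] <- w1[rows] + alpha_hat[k] * b1[rows - k]
      w2[rows] <- w2[rows] + alpha_hat[k] * b2[rows - k]
    }
    v1[idx] <- w1; v2[idx] <- w2
  }
  out <- data.frame(block = df$block, trial = df$trial, v1 = v1, v2 = v2,
                    dv = v1 - v2, absdv = abs(v1 - v2))
  class(out) <- c("value_series", "data.frame")
  out
}

#' Fit the cumulative-normal choice-probability function
#'
#' Separates valid trials into `n_bins` equal-count bins by differential
#' value, computes the empirical probability of choosing S1 per bin, and fits
#' the normal CDF `Phi(dv; mu, sigma)` to the (bin mean dv, p) points by
#' nonlinear least squares. `mu` measures bias toward an option and `sigma`
#' sensitivity to value differences (the explore-exploit tendency). A
#' trial-level maximum-likelihood probit fit is available as an alternative.
#'
#' @param values a [compute_subjective_values()] result.
#' @param series the matching [build_composite_series()] result.
#' @param n_bins number of equal-count bins (default 20).
#' @param method `"binned"` (default, fits the binned proportions) or
#'   `"probit"` (trial-level ML probit).
#' @return a `choiceprob_fit`: `mu`, `sigma`, `bins` (data frame with
#'   `dv`, `p`, `n`), `rss`, `saturated`, `method`.
#' @export
fit_choice_probability <- function(values, series, n_bins = 20L,
                                   method = c("binned", "probit")) {
  method <- match.arg(method)
  m <- merge(as.data.frame(values), as.data.frame(series),
             by = c("block", "trial"))
  m <- m[m$valid & !is.na(m$c), , drop = FALSE]
  if (nrow(m) < n_bins) stop("fewer valid trials than bins")
  if (stats::sd(m$dv) == 0) stop("no value variation")

  ord <- order(m$dv, m$block, m$trial)  # deterministic tie-break
  m <- m[ord, , drop = FALSE]
  bin <- rep(seq_len(n_bins), each = ceiling(nrow(m) / n_bins))[seq_len(nrow(m))]
  bins <- data.frame(
    dv = tapply(m$dv, bin, mean),
    p = tapply(m$c == 1L, bin, mean),
    n = as.integer(table(bin))
  )

  if (method == "probit") {
    g <- stats::glm((c == 1L) ~ dv, family = stats::binomial("probit"),
                    data = m)
    b <- stats::coef(g)
    mu <- -b[[1]] / b[[2]]
    sigma <- 1 / b[[2]]
    fit <- list(mu = mu, sigma = sigma, rss = NA_real_)
  } else {
    best <- NULL
    for (mu0 in c(-0.3, 0, 0.3)) {
      for (s0 in c(0.2, 0.5, 1, 2)) {
        f <- tryCatch(
          minpack.lm::nls.lm(
            par = list(mu = mu0, sigma = s0),
            lower = c(mu = -2, sigma = 1e-3),
            upper = c(mu = 2, sigma = 20),
            fn = function(p) bins$p - stats::pnorm(bins$dv, p$mu, p$sigma),
            control = minpack.lm::nls.lm.control(maxiter = 200)
          ),
          error = function(e) NULL)
        if (is.null(f)) next
        rss <- sum(f$fvec^2)
        if (is.null(best) || rss < best$rss) {
          best <- list(mu = f$par$mu, sigma = f$par$sigma, rss = rss)
        }
      }
    }
    if (is.null(best)) stop("choice-probability fit failed for all starts")
    fit <- best
  }
  saturated <- all(bins$p %in% c(0, 1))
  structure(list(mu = fit$mu, sigma = fit$sigma, bins = bins,
                 rss = fit$rss, saturated = saturated, method = method,
                 n_trials = nrow(m)),
            class = "choiceprob_fit")
}

#' @export
print.choiceprob_fit <- function(x, ...) {
  cat(sprintf("<choiceprob_fit> mu = %.3f, sigma = %.3f (%s, %d trials)%s\n",
              x$mu, x$sigma, x$method, x$n_trials,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Deterministic choice prediction from fitted parameters
#'
#' Predicts S1 whenever the fitted probability exceeds one half, i.e.
#' `dv > mu`; at an exact tie the previous prediction is repeated (S1 on the
#' first trial of a run of ties with no precedent).
#'
#' @param dv numeric vector of differential values.
#' @param mu fitted bias.
#' @param sigma fitted sensitivity (unused by the threshold rule; kept for
#'   interface symmetry).
#' @return character vector of `"S1"`/`"S2"` predictions.
#' @export
predict_choice <- function(dv, mu, sigma = NULL) {
  pred <- ifelse(dv > mu, "S1", ifelse(dv < mu, "S2", NA_character_))
  if (anyNA(pred)) {
    prev <- "S1"
    for (i in seq_along(pred)) {
      if (is.na(pred[i])) pred[i] <- prev else prev <- pred[i]
    }
  }
  pred
}

#' Fit the full LNP model to one participant's data
#'
#' The default mirrors the published procedure: the filter, its exponential
#' time scale, the subjective values and the cumulative-normal choice function
#' are fitted separately within each sensory-modality condition, and the
#' behavioural parameters (tau, mu, sigma) are averaged across modalities.
#' `by_modality = FALSE` pools all blocks of the task into one fit.
#'
#' @param dataset a `behavioral_dataset`.
#' @param task `"value"` (default) or `"control"`.
#' @param n filter length (default from the block length via
#'   [filter_length()], i.e. 36).
#' @param by_modality fit per modality condition and average (default) or
#'   pool.
#' @param n_bins bins for the choice-probability fit.
#' @param weights weights used to compute the subjective values:
#'   `"exponential"` (default; the normalized exponential approximation at
#'   the fitted time scale, the model's parametric filter — robust to the
#'   lag-to-lag noise of the raw solution) or `"raw"` (the normalized
#'   Wiener-Hopf weights themselves).
#' @return an `lnp_fit`: list with `fits` (per condition: `filter`,
#'   `exp`, `values`, `choice`), `tau`, `mu`, `sigma` (averaged), `task`,
#'   `values` (row-bound value series over all fitted conditions).
#' @export
fit_lnp <- function(dataset, task = "value", n = NULL, by_modality = TRUE,
                    n_bins = 20L, weights = c("exponential", "raw")) {
  weights <- match.arg(weights)
  df <- as.data.frame(dataset)
  if (is.null(n)) {
    tpb <- max(df$trial)
    n <- filter_length(tpb)
  }
  conds <- if (by_modality) {
    sort(unique(df$condition[df$task == task]))
  } else "pooled"
  fits <- list()
  for (cd in conds) {
    sel <- if (identical(cd, "pooled")) NULL else cd
    series <- build_composite_series(dataset, task = task, conditions = sel)
    filt <- estimate_filter_weights(series, n = n)
    ef <- fit_exponential_decay(filt)
    w <- if (weights == "exponential") exp_filter_weights(ef$tau, n)
         else filt$alpha_hat
    vals <- compute_subjective_values(
      dataset, w, task = task, conditions = sel,
      reward = if (task == "control") "compliance" else "feedback")
    cp <- fit_choice_probability(vals, series, n_bins = n_bins)
    fits[[cd]] <- list(filter = filt, exp = ef, values = vals, choice = cp)
  }
  tau <- mean(vapply(fits, function(f) f$exp$tau, 0))
  mu <- mean(vapply(fits, function(f) f$choice$mu, 0))
  sigma <- mean(vapply(fits, function(f) f$choice$sigma, 0))
  values <- do.call(rbind, lapply(fits, `[[`, "values"))
  values <- values[order(values$block, values$trial), , drop = FALSE]
  rownames(values) <- NULL
  class(values) <- c("value_series", "data.frame")
  structure(list(fits = fits, tau = tau, mu = mu, sigma = sigma,
                 task = task, n = n, values = values),
            class = "lnp_fit")
}

#' @export
print.lnp_fit <- function(x, ...) {
  cat(sprintf("<lnp_fit> task = %s, n = %d; tau = %.3f, mu = %.3f, sigma = %.3f\n",
              x$task, x$n, x$tau, x$mu, x$sigma))
  cat(sprintf("  fitted conditions: %s\n", paste(names(x$fits),
                                                 collapse = ", ")))
  invisible(x)
}
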