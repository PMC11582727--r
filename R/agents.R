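#' Behavioural parameters of the LNP agent / model
#'
#' `tau` is the learning time scale in trials of the exponentially decaying
#' reward filter; `mu` the choice bias (location of the cumulative-normal
#' decision rule, in differential-value units); `sigma` the sensitivity /
#' explore-exploit parameter (its scale; `sigma = 0` is pure exploitation);
#' `A` an optional filter amplitude (by default the filter weights are
#' normalized to sum to 1, making subjective values live on a 0-1
#' reward-fraction scale).
#'
#' @param tau positive time scale in trials.
#' @param mu bias.
#' @param sigma nonnegative sensitivity.
#' @param A optional amplitude; `NULL` means normalize weights to sum 1.
#' @return an object of class `lnp_params`.
#' @export
lnp_params <- function(tau, mu = 0, sigma = 0.81, A = NULL) {
  stopifnot(tau > 0, sigma >= 0)
  structure(list(tau = tau, mu = mu, sigma = sigma, A = A),
            class = "lnp_params")
}

#' @export
print.lnp_params <- function(x, ...) {
  cat(sprintf("<lnp_params> tau = %.3f, mu = %.3f, sigma = %.3f%s\n",
              x$tau, x$mu, x$sigma,
              if (is.null(x$A)) "" else sprintf(", A = %.3f", x$A)))
  invisible(x)
}

#' Exponentially decaying filter weights
#'
#' Weights `w_k ~ exp(-k / tau)` over lags `k = 1..n`, normalized to sum to 1
#' unless an amplitude `A` is supplied.
#'
#' @param tau positive time scale in trials.
#' @param n filter length in trials.
#' @param A optional amplitude; if `NULL` (default) weights sum to 1.
#' @return numeric vector of length `n`.
#' @export
exp_filter_weights <- function(tau, n, A = NULL) {
  stopifnot(tau > 0, n >= 1)
  w <- exp(-(seq_len(n)) / tau)
  if (is.null(A)) w / sum(w) else A * w
}

#' Probability of choosing S1 given a differential value
#'
#' The cumulative-normal decision rule `p(S1) = Phi((dv - mu) / sigma)`,
#' clipped to `[1e-6, 1 - 1e-6]` to avoid absorbing states in long
#' simulations. With `sigma = 0` the rule degenerates to the deterministic
#' comparison `dv > mu` (ties handled by the caller).
#'
#' @param dv differential value `v1 - v2`.
#' @param mu bias.
#' @param sigma sensitivity (>= 0).
#' @return probability (or 0/1/NA for the degenerate rule; NA at the tie).
#' @export
choice_probability <- function(dv, mu, sigma) {
  if (sigma <= 0) {
    return(ifelse(dv > mu, 1, ifelse(dv < mu, 0, NA_real_)))
  }
  p <- stats::pnorm(dv, mean = mu, sd = sigma)
  pmin(pmax(p, 1e-6), 1 - 1e-6)
}

#' Sample one LNP choice
#'
#' Computes per-option subjective values by the agent's exponential filter
#' over its delivered-reward histories (most recent trial first), maps
#' `dv = v1 - v2` through the cumulative-normal rule and samples the choice.
#' With `sigma = 0` the choice is the deterministic value comparison, ties
#' broken toward repeating the previous choice (or at random when there is no
#' previous choice).
#'
#' @param r1,r2 0/1 vectors of delivered rewards for S1 and S2, most recent
#'   trial first (length <= filter length; shorter histories are zero-padded).
#' @param params an [lnp_params()].
#' @param n filter length.
#' @param prev_choice previous choice (`"S1"`/`"S2"`) or `NA`.
#' @return list with `choice`, `v1`, `v2`, `dv`, `p1`.
#' @export
lnp_choose <- function(r1, r2, params, n, prev_choice = NA) {
  w <- exp_filter_weights(params$tau, n)
  v1 <- filter_value(r1, w)
  v2 <- filter_value(r2, w)
  dv <- v1 - v2
  p1 <- choice_probability(dv, params$mu, params$sigma)
  if (is.na(p1)) {  # sigma = 0 tie
    choice <- if (!is.na(prev_choice)) prev_choice
              else sample(c("S1", "S2"), 1L)
  } else if (params$sigma <= 0) {
    choice <- if (p1 > 0.5) "S1" else "S2"
  } else {
    choice <- if (stats::runif(1) < p1) "S1" else "S2"
  }
  list(choice = choice, v1 = v1, v2 = v2, dv = dv, p1 = p1)
}

filter_value <- function(history, w) {
  k <- min(length(history), length(w))
  if (k == 0L) return(0)
  sum(w[seq_len(k)] * history[seq_len(k)])
}

#' Choice of an instruction-following agent in the control task
#'
#' Yellow feedback on the previous trial instructs a switch, blue a keep. The
#' agent follows the instruction with probability `compliance` and does the
#' opposite otherwise. The first trial of a block (no previous feedback) is a
#' random choice and is handled by the caller.
#'
#' @param prev_choice `"S1"` or `"S2"`.
#' @param prev_feedback `"yellow"` or `"blue"`.
#' @param compliance probability of following the instruction.
#' @return `"S1"` or `"S2"`.
#' @export
instruction_choose <- function(prev_choice, prev_feedback, compliance = 0.95) {
  stopifnot(prev_feedback %in% c("yellow", "blue"),
            prev_choice %in% c("S1", "S2"))
  follow <- stats::runif(1) < compliance
  instructed_switch <- prev_feedback == "yellow"
  do_switch <- xor(instructed_switch, !follow)
  if (do_switch) setdiff(c("S1", "S2"), prev_choice) else prev_choice
}
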