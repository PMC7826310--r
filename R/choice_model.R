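#' Hyperbolic subjective value of a delayed reward
#'
#' Devalues an amount `A` delivered after `D` days according to the
#' hyperbolic discount function `V = A / (1 + k * D)`, the standard
#' single-parameter model of temporal discounting.
#'
#' @param amount Reward amount in euros (> 0). Vectorized.
#' @param delay Delay to delivery in days (>= 0). Vectorized.
#' @param k Hyperbolic discount rate in 1/days (> 0). Vectorized.
#' @return Subjective value in euros; equals `amount` at `delay = 0` and is
#'   strictly decreasing in both `delay` and `k`.
#' @examples
#' subjective_value(40, 10, 0.1) # 20
#' @export
subjective_value <- function(amount, delay, k) {
  if (any(amount <= 0)) stop("'amount' must be positive")
  if (any(delay < 0)) stop("'delay' must be non-negative")
  if (any(k <= 0)) stop("'k' must be positive")
  amount / (1 + k * delay)
}

#' Delayed amount producing a given subjective value
#'
#' Algebraic inverse of [subjective_value()]: the amount that, delayed by
#' `delay` days under discount rate `k`, is worth `value` euros now,
#' `A = V * (1 + k * D)`.
#'
#' @param value Target subjective value in euros (> 0).
#' @param delay Delay in days (>= 0).
#' @param k Discount rate in 1/days (> 0).
#' @return Amount in euros.
#' @export
delayed_amount <- function(value, delay, k) {
  if (any(value <= 0)) stop("'value' must be positive")
  if (any(delay < 0)) stop("'delay' must be non-negative")
  if (any(k <= 0)) stop("'k' must be positive")
  value * (1 + k * delay)
}

#' Softmax probability of choosing option A
#'
#' Two-option softmax decision rule
#' `P(A) = exp(beta * V_A) / (exp(beta * V_A) + exp(beta * V_B))`,
#' evaluated as `plogis(beta * (V_A - V_B))` so it is numerically stable
#' for arbitrarily large `beta * value` products. `beta` (the inverse
#' temperature, in 1/euro) controls how deterministically the higher-valued
#' option is chosen; `beta = 0` is pure random choice.
#'
#' @param value_a,value_b Subjective values of the two options, in euros.
#' @param beta Inverse temperature (>= 0), applied to values in euros.
#' @return `P(choose A)` in (0, 1) (reaching 0/1 only in the beta -> Inf
#'   limit of floating point).
#' @export
choice_prob <- function(value_a, value_b, beta) {
  if (any(beta < 0)) stop("'beta' must be non-negative")
  if (any(!is.finite(value_a)) || any(!is.finite(value_b)))
    stop("values must be finite")
  stats::plogis(beta * (value_a - value_b))
}

# log P(choose A); same contract as choice_prob but on the log scale,
# used by the grid estimator where products of 90 likelihoods underflow.
log_choice_prob <- function(value_a, value_b, beta) {
  stats::plogis(beta * (value_a - value_b), log.p = TRUE)
}

#' Agent parameters for simulated decision-makers
#'
#' Bundles a discount rate `k` and inverse temperature `beta`. Parameters
#' are stored on the natural-log scale (the scale on which they are
#' approximately normal across subjects) alongside the natural scale;
#' `beta = 0` is permitted (pure random agent) and its log is clamped at
#' `log_beta_floor`.
#'
#' @param k Discount rate, 1/days (> 0).
#' @param beta Inverse temperature, 1/euro (>= 0).
#' @param log_beta_floor Clamp for `log(beta)` when `beta` is 0 or tiny.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(k, beta, log_beta_floor = -20) {
  stopifnot(length(k) == 1, length(beta) == 1)
  if (k <= 0) stop("'k' must be positive")
  if (beta < 0) stop("'beta' must be non-negative")
  if (!is.finite(log(k))) stop("log(k) must be finite")
  structure(
    list(
      k = k, beta = beta,
      log_k = log(k),
      log_beta = max(log(max(beta, 0)), log_beta_floor)
    ),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("agent: k = %.4g /day (log k = %.3f), beta = %.4g /EUR\n",
              x$k, x$log_k, x$beta))
  invisible(x)
}

#' One binary intertemporal offer
#'
#' @param immediate Immediate amount in euros (> 0).
#' @param delayed Delayed amount in euros (> 0).
#' @param delay Delay of the delayed amount, days (>= 0).
#' @return An object of class `offer_pair`.
#' @export
offer_pair <- function(immediate, delayed, delay) {
  if (immediate <= 0 || delayed <= 0) stop("amounts must be positive")
  if (delay < 0) stop("'delay' must be non-negative")
  structure(list(immediate = immediate, delayed = delayed, delay = delay),
            class = "offer_pair")
}

#' Simulate one softmax choice on an offer pair
#'
#' Draws a Bernoulli choice with `P(delayed)` given by the softmax over the
#' two subjective values at the agent's `(k, beta)`.
#'
#' @param pair An [offer_pair()].
#' @param params An [agent_params()].
#' @return `"immediate"` or `"delayed"`. Uses the current RNG stream; set a
#'   seed upstream for reproducibility.
#' @export
simulate_choice <- function(pair, params) {
  v_del <- subjective_value(pair$delayed, pair$delay, params$k)
  p_del <- choice_prob(v_del, pair$immediate, params$beta)
  if (stats::runif(1) < p_del) "delayed" else "immediate"
}

#' Simulate softmax choices over a table of offers
#'
#' Vectorized counterpart of [simulate_choice()] for a trial table as
#' produced by [build_schedule()] (columns `immediate`, `delayed`, `delay`).
#'
#' @param trials Data frame with columns `immediate`, `delayed`, `delay`.
#' @param params An [agent_params()].
#' @return Character vector of `"immediate"`/`"delayed"`, one per row.
#' @export
simulate_choices <- function(trials, params) {
  v_del <- subjective_value(trials$delayed, trials$delay, params$k)
  p_del <- choice_prob(v_del, trials$immediate, params$beta)
  ifelse(stats::runif(nrow(trials)) < p_del, "delayed", "immediate")
}
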