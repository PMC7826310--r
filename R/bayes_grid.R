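#' Discretized parameter grid for (log k, log beta)
#'
#' The posterior over the discount rate and inverse temperature is carried
#' on an equally spaced 2-D grid on the natural-log axes, honoring the
#' approximately lognormal population distribution of both parameters.
#' Default bounds cover the plausible range of human log k and log beta
#' with a margin of several population SDs.
#'
#' @param log_k_range Bounds of the log-k axis (1/days on the natural scale).
#' @param log_beta_range Bounds of the log-beta axis (1/EUR natural scale).
#' @param n_k,n_beta Grid sizes (>= 2).
#' @return An object of class `grid_spec` with axes `log_k`, `log_beta`.
#' @export
grid_spec <- function(log_k_range = c(-9, 0), log_beta_range = c(-5, 3),
                      n_k = 101, n_beta = 101) {
  if (n_k < 2 || n_beta < 2) stop("grid sizes must be >= 2")
  if (any(!is.finite(c(log_k_range, log_beta_range))))
    stop("grid bounds must be finite")
  if (diff(log_k_range) <= 0 || diff(log_beta_range) <= 0)
    stop("grid bounds must be increasing")
  structure(
    list(log_k = seq(log_k_range[1], log_k_range[2], length.out = n_k),
         log_beta = seq(log_beta_range[1], log_beta_range[2],
                        length.out = n_beta)),
    class = "grid_spec"
  )
}

#' Initialize the prior grid over (log k, log beta)
#'
#' Builds the joint prior as the outer product of two independent
#' discretized normals on the log axes (equivalently, lognormal priors on
#' the natural scale). With `k_center = NULL` the prior is uniform over the
#' grid. A pre-scan `k` estimate is the usual center for the k-prior.
#'
#' @param spec A [grid_spec()].
#' @param k_center Prior center for `k` on the natural scale (e.g. the
#'   pre-scan OLS fit), or `NULL` for a uniform prior. Clamped to the grid
#'   bounds with a warning if outside.
#' @param prior_sd_log_k,prior_sd_log_beta Prior SDs on the log axes (> 0).
#' @param log_beta_center Prior center for log beta (defaults to 0,
#'   i.e. beta = 1/EUR, a diffuse middle-of-the-road consistency).
#' @return An object of class `posterior_grid`: `spec` plus `joint`, an
#'   `n_k x n_beta` matrix of nonnegative weights summing to 1.
#' @export
init_prior <- function(spec = grid_spec(), k_center = NULL,
                       prior_sd_log_k = 1.5, prior_sd_log_beta = 1.5,
                       log_beta_center = 0) {
  stopifnot(inherits(spec, "grid_spec"))
  if (prior_sd_log_k <= 0 || prior_sd_log_beta <= 0)
    stop("prior SDs must be positive")
  if (is.null(k_center)) {
    mk <- rep(1, length(spec$log_k))
    mb <- rep(1, length(spec$log_beta))
  } else {
    if (k_center <= 0) stop("'k_center' must be positive")
    lkc <- log(k_center)
    rng <- range(spec$log_k)
    if (lkc < rng[1] || lkc > rng[2]) {
      warning("prior center outside grid bounds; clamped")
      lkc <- min(max(lkc, rng[1]), rng[2])
    }
    mk <- stats::dnorm(spec$log_k, lkc, prior_sd_log_k)
    mb <- stats::dnorm(spec$log_beta, log_beta_center, prior_sd_log_beta)
  }
  joint <- outer(mk / sum(mk), mb / sum(mb))
  structure(list(spec = spec, joint = joint), class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  s <- posterior_summary(x)
  cat(sprintf(
    "posterior grid %dx%d: log k = %.3f (var %.3f), log beta = %.3f (var %.3f)\n",
    length(x$spec$log_k), length(x$spec$log_beta),
    s$k_hat, s$var_k, s$beta_hat, s$var_beta))
  invisible(x)
}

# log-likelihood matrix (n_k x n_beta) of one observed choice
choice_loglik_matrix <- function(spec, immediate, delayed, delay, choice) {
  k <- exp(spec$log_k)
  beta <- exp(spec$log_beta)
  dv <- delayed / (1 + k * delay) - immediate # V(delayed) - V(immediate)
  sgn <- if (choice == "delayed") 1 else -1
  stats::plogis(sgn * outer(dv, beta), log.p = TRUE)
}

#' Single Bayesian update of the posterior grid
#'
#' Multiplies every grid cell by the softmax likelihood of the observed
#' choice under that cell's `(k, beta)` and renormalizes. Accumulation is
#' in log space with max-subtraction, so 90-trial products cannot
#' underflow; softmax likelihoods are strictly positive, but a fully
#' underflowed grid is still guarded with an error rather than silently
#' renormalizing zeros.
#'
#' @param grid A [posterior_grid][init_prior()].
#' @param pair An [offer_pair()] (or list with `immediate`, `delayed`,
#'   `delay`).
#' @param choice `"immediate"` or `"delayed"`.
#' @return The updated, renormalized `posterior_grid`.
#' @export
update_posterior <- function(grid, pair, choice) {
  stopifnot(inherits(grid, "posterior_grid"))
  choice <- match.arg(choice, c("immediate", "delayed"))
  ll <- choice_loglik_matrix(grid$spec, pair$immediate, pair$delayed,
                             pair$delay, choice)
  lw <- log(grid$joint) + ll
  m <- max(lw)
  if (!is.finite(m)) stop("posterior degenerated: all grid weights underflowed")
  w <- exp(lw - m)
  grid$joint <- w / sum(w)
  grid
}

#' Posterior summaries: parameter estimates and var(k)
#'
#' Means and variances of the marginal posteriors. Estimation lives on the
#' log axes, so `k_hat`/`beta_hat` are posterior means of log k / log beta
#' and `var_k` — the choice-consistency index — is the posterior variance
#' of log k by default (`var_scale = "natural"` computes moments of
#' `exp(log k)` instead).
#'
#' @param grid A `posterior_grid`.
#' @param var_scale `"log"` (default) or `"natural"`.
#' @return An object of class `estimate_result`: list with `k_hat`,
#'   `beta_hat`, `var_k`, `var_beta`, `n_trials_used`.
#' @export
posterior_summary <- function(grid, var_scale = c("log", "natural")) {
  stopifnot(inherits(grid, "posterior_grid"))
  var_scale <- match.arg(var_scale)
  mk <- rowSums(grid$joint)
  mb <- colSums(grid$joint)
  xk <- grid$spec$log_k
  xb <- grid$spec$log_beta
  if (var_scale == "natural") {
    xk_v <- exp(xk)
    xb_v <- exp(xb)
  } else {
    xk_v <- xk
    xb_v <- xb
  }
  k_mean <- sum(mk * xk) # estimates always reported on the log axis
  b_mean <- sum(mb * xb)
  vk <- sum(mk * (xk_v - sum(mk * xk_v))^2)
  vb <- sum(mb * (xb_v - sum(mb * xb_v))^2)
  structure(
    list(k_hat = k_mean, beta_hat = b_mean, var_k = vk, var_beta = vb,
         n_trials_used = NA_integer_),
    class = "estimate_result"
  )
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf(
    "estimate: log k = %.3f, log beta = %.3f, var(k) = %.4f, var(beta) = %.4f (%s trials)\n",
    x$k_hat, x$beta_hat, x$var_k, x$var_beta,
    ifelse(is.na(x$n_trials_used), "?", x$n_trials_used)))
  invisible(x)
}

#' Sequential Bayesian estimation over a choice sequence
#'
#' Runs [init_prior()] followed by one [update_posterior()] per trial and
#' summarizes after each, so the trajectory shows var(k) rising after
#' value-incongruent choices and shrinking under consistent ones. Because
#' each update multiplies independent likelihoods, the final posterior is
#' invariant to trial order and equal to a single batch update.
#'
#' @param trials Data frame with columns `immediate`, `delayed`, `delay`
#'   (e.g. `as.data.frame(build_schedule(...))`). Trials without a recorded
#'   choice (`NA`) are dropped.
#' @param choices Character vector of `"immediate"`/`"delayed"`, one per
#'   trial row.
#' @param spec A [grid_spec()].
#' @param k_center,prior_sd_log_k,prior_sd_log_beta,log_beta_center Prior
#'   arguments, passed to [init_prior()].
#' @param var_scale Scale for variances, see [posterior_summary()].
#' @param trajectory Keep per-trial summaries?
#' @return An `estimate_result` with fields `trajectory` (data frame:
#'   `trial`, `k_hat`, `beta_hat`, `var_k`, `var_beta`) and `grid` (final
#'   posterior) attached.
#' @export
estimate_sequence <- function(trials, choices, spec = grid_spec(),
                              k_center = NULL, prior_sd_log_k = 1.5,
                              prior_sd_log_beta = 1.5, log_beta_center = 0,
                              var_scale = c("log", "natural"),
                              trajectory = TRUE) {
  var_scale <- match.arg(var_scale)
  keep <- !is.na(choices)
  trials <- trials[keep, , drop = FALSE]
  choices <- choices[keep]
  grid <- init_prior(spec, k_center = k_center,
                     prior_sd_log_k = prior_sd_log_k,
                     prior_sd_log_beta = prior_sd_log_beta,
                     log_beta_center = log_beta_center)
  n <- nrow(trials)
  traj <- if (trajectory) vector("list", n) else NULL
  for (i in seq_len(n)) {
    grid <- update_posterior(
      grid,
      list(immediate = trials$immediate[i], delayed = trials$delayed[i],
           delay = trials$delay[i]),
      choices[i]
    )
    if (trajectory) {
      s <- posterior_summary(grid, var_scale)
      traj[[i]] <- data.frame(trial = i, k_hat = s$k_hat,
                              beta_hat = s$beta_hat, var_k = s$var_k,
                              var_beta = s$var_beta)
    }
  }
  res <- posterior_summary(grid, var_scale)
  res$n_trials_used <- n
  res$trajectory <- if (trajectory) do.call(rbind, traj) else NULL
  res$grid <- grid
  res
}
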