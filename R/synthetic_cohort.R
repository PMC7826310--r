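#' Specification of one cohort group
#'
#' Latent decision parameters are drawn per subject from group-level
#' normals on the log scale; the nicotine-dependence score (FTND, 0-10) is
#' a rounded truncated normal.
#'
#' @param label Group label, e.g. `"non_smoker"`, `"occasional"`,
#'   `"smoker"`.
#' @param n Number of subjects (>= 1).
#' @param mean_log_k,sd_log_k Group mean and SD of log k.
#' @param mean_log_beta,sd_log_beta Group mean and SD of log beta.
#' @param ftnd_mean,ftnd_sd FTND moments before truncation to [0, 10] and
#'   rounding.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, n, mean_log_k, sd_log_k,
                       mean_log_beta, sd_log_beta,
                       ftnd_mean = 0, ftnd_sd = 0) {
  if (n < 1) stop("'n' must be >= 1")
  if (sd_log_k < 0 || sd_log_beta < 0 || ftnd_sd < 0)
    stop("SDs must be non-negative")
  structure(
    list(label = label, n = as.integer(n),
         mean_log_k = mean_log_k, sd_log_k = sd_log_k,
         mean_log_beta = mean_log_beta, sd_log_beta = sd_log_beta,
         ftnd_mean = ftnd_mean, ftnd_sd = ftnd_sd),
    class = "group_spec"
  )
}

#' Default study groups
#'
#' Non-smokers, occasional smokers and treatment-seeking smokers with the
#' baseline group sizes and (log k, log beta, FTND) moments of the study
#' population the generator emulates.
#'
#' @return Named list of three [group_spec()]s.
#' @export
default_groups <- function() {
  list(
    non_smoker = group_spec("non_smoker", 29, -4.38, 1.4, -1.28, 1.4,
                            ftnd_mean = 0, ftnd_sd = 0),
    occasional = group_spec("occasional", 30, -4.06, 1.4, -0.65, 1.6,
                            ftnd_mean = 0.1, ftnd_sd = 0.4),
    smoker = group_spec("smoker", 44, -3.98, 1.2, -1.01, 1.5,
                        ftnd_mean = 5.0, ftnd_sd = 2.0)
  )
}

# truncated-normal draw on [lo, hi] by inverse CDF
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lo), hi))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Sample the latent fields of a cohort
#'
#' Draws per-subject log k, log beta and FTND from the group
#' specifications. FTND is truncated to [0, 10] and rounded to integers
#' where the group has any dependence (groups with `ftnd_sd = 0` get the
#' fixed mean).
#'
#' @param groups List of [group_spec()]s (default [default_groups()]).
#' @param seed Optional integer seed.
#' @return Data frame: `id`, `group`, `log_k`, `log_beta`, `ftnd`.
#' @export
sample_cohort <- function(groups = default_groups(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(groups, function(g) {
    lk <- stats::rnorm(g$n, g$mean_log_k, g$sd_log_k)
    lb <- stats::rnorm(g$n, g$mean_log_beta, g$sd_log_beta)
    ftnd <- if (g$ftnd_sd > 0) {
      round(rtruncnorm(g$n, g$ftnd_mean, g$ftnd_sd, 0, 10))
    } else {
      rep(g$ftnd_mean, g$n)
    }
    data.frame(group = g$label, log_k = lk, log_beta = lb, ftnd = ftnd)
  })
  out <- do.call(rbind, rows)
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Simulate one subject's full measurement session
#'
#' Composes the whole measurement chain for one latent `(k, beta)`:
#' staircase calibration giving a pre-scan `k`, an individualized 90-trial
#' schedule built at that `k`, softmax choices on the schedule, and
#' sequential Bayesian estimation with the pre-scan `k` as prior center.
#'
#' @param log_k,log_beta Latent parameters of the subject (log scale).
#' @param seed Optional integer seed for the whole session.
#' @param staircase A [staircase_config()].
#' @param design A [design_spec()].
#' @param grid A [grid_spec()].
#' @param ... Prior arguments passed to [estimate_sequence()].
#' @return List with `k_prescan`, `schedule`, `choices`, and `estimate`
#'   (an `estimate_result`).
#' @export
simulate_subject_session <- function(log_k, log_beta, seed = NULL,
                                     staircase = staircase_config(),
                                     design = design_spec(),
                                     grid = grid_spec(), ...) {
  if (!is.null(seed)) set.seed(seed)
  agent <- agent_params(exp(log_k), exp(log_beta))
  calib <- calibrate_agent(agent, staircase)
  schedule <- build_schedule(calib$k_prescan, design)
  trials <- schedule$trials
  choices <- simulate_choices(trials, agent)
  est <- estimate_sequence(trials, choices, spec = grid,
                           k_center = calib$k_prescan,
                           trajectory = FALSE, ...)
  list(k_prescan = calib$k_prescan, schedule = schedule,
       choices = choices, estimate = est)
}

#' Run measurement sessions for every cohort member
#'
#' Applies [simulate_subject_session()] to each row of a latent cohort and
#' appends the measured columns. Per-subject seeds are derived from `seed`
#' so the cohort is reproducible and insensitive to row order.
#'
#' @param cohort A [sample_cohort()] data frame.
#' @param seed Integer master seed.
#' @param ... Passed to [simulate_subject_session()].
#' @return The cohort with added columns `k_prescan`, `k_hat`, `beta_hat`,
#'   `var_k`, `var_beta`.
#' @export
simulate_sessions <- function(cohort, seed = 1, ...) {
  res <- lapply(seq_len(nrow(cohort)), function(i) {
    s <- simulate_subject_session(
      cohort$log_k[i], cohort$log_beta[i],
      seed = derive_seed(seed, paste0("subject", cohort$id[i])), ...)
    data.frame(k_prescan = s$k_prescan, k_hat = s$estimate$k_hat,
               beta_hat = s$estimate$beta_hat, var_k = s$estimate$var_k,
               var_beta = s$estimate$var_beta)
  })
  cbind(cohort, do.call(rbind, res))
}

#' Attach distribution-matched synthetic estimates to a latent cohort
#'
#' Fast alternative to [simulate_sessions()] for large survival
#' simulations: instead of running the full staircase + Bayesian chain,
#' measured quantities are drawn directly on the measurement scale —
#' `k_hat` as latent log k plus estimation noise, and `var_k` lognormal
#' with moments matched to observed cohorts and the inverse var(k)-beta
#' relation built in (consistent, high-beta subjects get narrow
#' posteriors). Marginal var(k) moments are calibrated to mean ~0.32,
#' SD ~0.6.
#'
#' @param cohort A [sample_cohort()] data frame.
#' @param seed Optional integer seed.
#' @param est_noise_sd SD of `k_hat` around latent log k.
#' @param vark_meanlog,vark_beta_slope,vark_noise_sdlog Location, log-beta
#'   slope and residual spread of log var(k).
#' @return The cohort with `k_hat` and `var_k` columns added.
#' @export
attach_synthetic_estimates <- function(cohort, seed = NULL,
                                       est_noise_sd = 0.25,
                                       vark_meanlog = -1.89,
                                       vark_beta_slope = 0.5,
                                       vark_noise_sdlog = 0.97) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  cohort$k_hat <- cohort$log_k + stats::rnorm(n, 0, est_noise_sd)
  mu <- vark_meanlog - vark_beta_slope *
    (cohort$log_beta - mean(cohort$log_beta))
  cohort$var_k <- exp(stats::rnorm(n, mu, vark_noise_sdlog))
  cohort
}

#' Planted proportional-hazards specification for relapse
#'
#' Constant baseline hazard with log-linear covariate effects on measured
#' quantities. The linear predictor is centered at reference covariate
#' values so `baseline_rate` keeps its marginal interpretation. Default
#' log hazard ratios plant an FTND effect of HR 1.24 per point and a
#' var(k) effect of HR 2.18 per unit, with no discount-rate effect.
#'
#' @param baseline_rate Baseline hazard, 1/days (> 0). The default makes
#'   ~43% of a reference cohort relapse within the 30-day window when all
#'   planted effects are null.
#' @param log_hr_ftnd,log_hr_vark,log_hr_logk Planted log hazard ratios.
#' @param ftnd_ref,vark_ref,logk_ref Centering references.
#' @param censor_day Administrative censoring, days.
#' @param relapse_window Early-relapse classification window, days.
#' @return An object of class `hazard_spec`.
#' @export
hazard_spec <- function(baseline_rate = -log(1 - 19 / 44) / 30,
                        log_hr_ftnd = log(1.24), log_hr_vark = log(2.18),
                        log_hr_logk = 0,
                        ftnd_ref = 5.0, vark_ref = 0.3, logk_ref = -3.98,
                        censor_day = 180, relapse_window = 30) {
  if (baseline_rate <= 0) stop("'baseline_rate' must be positive")
  if (censor_day <= relapse_window)
    stop("'censor_day' must exceed 'relapse_window'")
  structure(
    list(baseline_rate = baseline_rate, log_hr_ftnd = log_hr_ftnd,
         log_hr_vark = log_hr_vark, log_hr_logk = log_hr_logk,
         ftnd_ref = ftnd_ref, vark_ref = vark_ref, logk_ref = logk_ref,
         censor_day = censor_day, relapse_window = relapse_window),
    class = "hazard_spec"
  )
}

# per-subject hazard rate under a hazard_spec
hazard_rate <- function(cohort, hazard) {
  lp <- hazard$log_hr_ftnd * (cohort$ftnd - hazard$ftnd_ref) +
    hazard$log_hr_vark * (cohort$var_k - hazard$vark_ref) +
    hazard$log_hr_logk * (cohort$k_hat - hazard$logk_ref)
  hazard$baseline_rate * exp(lp)
}

#' Sample relapse times under a planted hazard
#'
#' Exponential (constant-hazard) event times at each subject's rate,
#' censored administratively at `censor_day`; subjects relapsing within
#' `relapse_window` days are flagged as early relapsers. The hazard acts
#' on the measured `var_k` and `k_hat` (the study's predictors are
#' measured quantities, not latent traits).
#'
#' @param cohort Cohort data frame with `ftnd`, `var_k`, `k_hat` columns.
#' @param hazard A [hazard_spec()].
#' @param seed Optional integer seed.
#' @return The cohort with `relapse_day`, `censored` (logical) and
#'   `relapser` (event within the window) added.
#' @export
sample_relapse <- function(cohort, hazard = hazard_spec(), seed = NULL) {
  stopifnot(inherits(hazard, "hazard_spec"))
  if (!is.null(seed)) set.seed(seed)
  rate <- hazard_rate(cohort, hazard)
  t_event <- stats::rexp(nrow(cohort), rate)
  censored <- t_event > hazard$censor_day
  cohort$relapse_day <- pmin(t_event, hazard$censor_day)
  cohort$censored <- censored
  cohort$relapser <- !censored & t_event <= hazard$relapse_window
  cohort
}

#' Calibrate the baseline hazard to a target early-relapse fraction
#'
#' Solves for the baseline rate at which the expected fraction of the
#' given cohort relapsing within the window equals `target`
#' (`mean_i 1 - exp(-rate_i * window)`), using the exponential closed form
#' — deterministic given the covariates.
#'
#' @param cohort Cohort with the hazard covariates.
#' @param hazard A [hazard_spec()] providing effects and references.
#' @param target Target early-relapse fraction (default 19/44).
#' @return The calibrated `hazard_spec`.
#' @export
calibrate_baseline <- function(cohort, hazard = hazard_spec(),
                               target = 19 / 44) {
  rel_rate <- hazard_rate(cohort, hazard) / hazard$baseline_rate
  f <- function(b) {
    mean(1 - exp(-b * rel_rate * hazard$relapse_window)) - target
  }
  sol <- stats::uniroot(f, c(1e-8, 10), tol = 1e-12)
  hazard$baseline_rate <- sol$root
  hazard
}
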