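test_that("prior initialization has the stated discrete moments", {
  spec <- small_grid()

  # uniform prior: mean at the grid midpoint, discrete-uniform variance
  u <- init_prior(spec)
  s <- posterior_summary(u)
  expect_equal(s$k_hat, mean(range(spec$log_k)), tolerance = 1e-12)
  expect_equal(s$var_k, mean((spec$log_k - mean(spec$log_k))^2),
               tolerance = 1e-12)

  # lognormal prior with no trials: summaries equal the discretized-normal
  # moments computed directly
  p <- init_prior(spec, k_center = 0.02, prior_sd_log_k = 1.0,
                  prior_sd_log_beta = 0.8)
  w <- dnorm(spec$log_k, log(0.02), 1.0)
  w <- w / sum(w)
  s2 <- posterior_summary(p)
  expect_equal(s2$k_hat, sum(w * spec$log_k), tolerance = 1e-12)
  expect_equal(s2$var_k, sum(w * (spec$log_k - sum(w * spec$log_k))^2),
               tolerance = 1e-12)

  # joint is exactly the outer product of its marginals at initialization
  expect_equal(p$joint, outer(rowSums(p$joint), colSums(p$joint)),
               tolerance = 1e-12)
  expect_equal(sum(p$joint), 1, tolerance = 1e-10)

  expect_error(init_prior(spec, k_center = 0.02, prior_sd_log_k = 0), "SD")
  expect_warning(init_prior(spec, k_center = 100), "clamped")
})

test_that("a beta ~ 0 slice is untouched by any observed choice", {
  # at beta = exp(-30) ~ 0 the softmax likelihood is 0.5 for either choice,
  # so relative weights along the k axis in that slice cannot move
  spec <- grid_spec(log_beta_range = c(-30, 3), n_k = 21, n_beta = 12)
  g <- init_prior(spec, k_center = 0.02)
  before <- g$joint[, 1] / sum(g$joint[, 1])
  g2 <- update_posterior(g, offer_pair(20, 80, 30), "immediate")
  after <- g2$joint[, 1] / sum(g2$joint[, 1])
  expect_equal(after, before, tolerance = 1e-12)
})

test_that("sequential updating equals the batch posterior and commutes", {
  spec <- small_grid()
  sched <- build_schedule(0.02, seed = 31)
  trials <- sched$trials[1:40, ]
  set.seed(32)
  choices <- simulate_choices(trials, agent_params(0.02, 0.4))

  seq_est <- estimate_sequence(trials, choices, spec = spec,
                               k_center = 0.02, trajectory = FALSE)

  # independent batch oracle: accumulate log-likelihoods cell by cell
  logpost <- log(init_prior(spec, k_center = 0.02)$joint)
  for (i in seq_len(nrow(trials))) {
    for (ik in seq_along(spec$log_k)) {
      k <- exp(spec$log_k[ik])
      dv <- trials$delayed[i] / (1 + k * trials$delay[i]) -
        trials$immediate[i]
      sgn <- if (choices[i] == "delayed") 1 else -1
      logpost[ik, ] <- logpost[ik, ] +
        plogis(sgn * exp(spec$log_beta) * dv, log.p = TRUE)
    }
  }
  batch <- exp(logpost - max(logpost))
  batch <- batch / sum(batch)
  expect_lt(max(abs(seq_est$grid$joint - batch)), 1e-10)

  # any permutation of the trials gives the same final posterior
  set.seed(33)
  perm <- sample.int(nrow(trials))
  perm_est <- estimate_sequence(trials[perm, ], choices[perm], spec = spec,
                                k_center = 0.02, trajectory = FALSE)
  expect_lt(max(abs(seq_est$grid$joint - perm_est$grid$joint)), 1e-10)
  expect_equal(sum(perm_est$grid$joint), 1, tolerance = 1e-10)
})

test_that("posterior summaries are the discrete marginal moments", {
  # hand-built symmetric two-point marginal: mean -4, variance 1
  spec <- grid_spec(log_k_range = c(-5, -3), log_beta_range = c(0, 1),
                    n_k = 2, n_beta = 2)
  g <- structure(list(spec = spec,
                      joint = matrix(c(0.5, 0.5, 0, 0), nrow = 2)),
                 class = "posterior_grid")
  s <- posterior_summary(g)
  expect_equal(s$k_hat, -4)
  expect_equal(s$var_k, 1)

  # point mass: zero variance
  pm <- structure(list(spec = spec,
                       joint = matrix(c(1, 0, 0, 0), nrow = 2)),
                  class = "posterior_grid")
  expect_equal(posterior_summary(pm)$var_k, 0)

  # arbitrary grid: agrees with brute-force direct summation over cells
  set.seed(44)
  spec2 <- small_grid()
  joint <- matrix(rexp(41 * 41), 41, 41)
  joint <- joint / sum(joint)
  g2 <- structure(list(spec = spec2, joint = joint),
                  class = "posterior_grid")
  s2 <- posterior_summary(g2)
  mk <- apply(joint, 1, sum)
  mu <- sum(mk * spec2$log_k)
  expect_equal(s2$k_hat, mu, tolerance = 1e-12)
  expect_equal(s2$var_k, sum(mk * (spec2$log_k - mu)^2), tolerance = 1e-12)

  # natural-scale option: moments of exp(log k)
  sn <- posterior_summary(g2, var_scale = "natural")
  kv <- exp(spec2$log_k)
  expect_equal(sn$var_k, sum(mk * (kv - sum(mk * kv))^2), tolerance = 1e-12)
})

test_that("empty choice sequences return the prior untouched", {
  spec <- small_grid()
  est <- estimate_sequence(data.frame(immediate = numeric(0),
                                      delayed = numeric(0),
                                      delay = numeric(0)),
                           character(0), spec = spec, k_center = 0.02)
  prior <- posterior_summary(init_prior(spec, k_center = 0.02))
  expect_equal(est$k_hat, prior$k_hat)
  expect_equal(est$var_k, prior$var_k)
  expect_equal(est$n_trials_used, 0)
})

test_that("posterior variance shrinks with consistent evidence and stays bounded", {
  spec <- small_grid()
  sched <- build_schedule(0.02, seed = 51)
  agent <- agent_params(0.02, 2)
  set.seed(52)
  choices <- simulate_choices(sched$trials, agent)
  est <- estimate_sequence(sched$trials, choices, spec = spec,
                           k_center = 0.02)
  prior_var <- posterior_summary(init_prior(spec, k_center = 0.02))$var_k
  expect_lt(est$var_k, prior_var)
  # var(k) can never exceed the variance of the grid-supported uniform
  expect_lt(est$var_k, mean((spec$log_k - mean(spec$log_k))^2))

  # expected var(k) is non-increasing in trial count (Monte Carlo on means)
  set.seed(53)
  traj_vars <- replicate(50, {
    ch <- simulate_choices(sched$trials, agent)
    e <- estimate_sequence(sched$trials, ch, spec = spec, k_center = 0.02)
    e$trajectory$var_k[c(10, 45, 90)]
  })
  means <- rowMeans(traj_vars)
  expect_true(all(diff(means) < 0))
})

test_that("var(k) is inversely related to the agent's true consistency", {
  spec <- small_grid()
  sched <- build_schedule(0.02, seed = 61)
  set.seed(62)
  n <- 120
  log_beta <- rnorm(n, -1.01, 1.5) # population spread of consistency
  log_k <- rnorm(n, -3.98, 1.2) # and of discounting
  var_k <- vapply(seq_len(n), function(i) {
    ch <- simulate_choices(sched$trials,
                           agent_params(exp(log_k[i]), exp(log_beta[i])))
    estimate_sequence(sched$trials, ch, spec = spec, k_center = 0.02,
                      trajectory = FALSE)$var_k
  }, numeric(1))
  ct <- cor.test(var_k, log_beta, method = "spearman", exact = FALSE)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
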