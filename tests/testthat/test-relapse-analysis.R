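test_that("group comparison is gated by normality and handles edge cases", {
  set.seed(202)
  d <- data.frame(
    g = rep(c("a", "b"), each = 60),
    normal = rnorm(120),
    skewed = exp(rnorm(120, sd = 1.5))
  )
  r_norm <- compare_groups(d, "normal", "g", "a", "b")
  expect_equal(r_norm$test, "t")
  expect_equal(r_norm$effect_type, "cohen_d")

  r_skew <- compare_groups(d, "skewed", "g", "a", "b")
  expect_equal(r_skew$test, "mann_whitney")
  expect_equal(r_skew$effect_type, "r")
  expect_true(r_skew$p >= 0 && r_skew$p <= 1)

  # forcing overrides the gate
  expect_equal(compare_groups(d, "skewed", "g", "a", "b", force = "t")$test,
               "t")

  # two identical samples: statistic at its null center, p ~ 1
  d2 <- data.frame(g = rep(c("a", "b"), each = 10), v = rep(1:10, 2))
  r_same <- compare_groups(d2, "v", "g", "a", "b", force = "wilcox")
  expect_equal(r_same$statistic, 50) # n1 * n2 / 2
  expect_equal(r_same$z, 0, tolerance = 1e-12)
  expect_gt(r_same$p, 0.99)

  d3 <- data.frame(g = rep(c("a", "b"), each = 10), v = rep(1, 20))
  expect_error(compare_groups(d3, "v", "g", "a", "b"), "degenerate")
})

test_that("the Mann-Whitney effect size follows r = |Z|/sqrt(N)", {
  set.seed(202)
  x <- rnorm(25)
  y <- rnorm(30, 1)
  mw <- tempodisc:::mann_whitney(x, y)
  mu <- 25 * 30 / 2
  sigma <- sqrt(25 * 30 * (25 + 30 + 1) / 12) # tie-free closed form
  expect_equal(mw$z, (mw$statistic - mu) / sigma, tolerance = 1e-12)
  expect_equal(mw$effect_size, abs(mw$z) / sqrt(55), tolerance = 1e-12)
})

test_that("a one-SD planted shift is detected with high power", {
  set.seed(203)
  rejections <- replicate(200, {
    d <- data.frame(g = rep(c("a", "b"), each = 100),
                    v = c(rnorm(100), rnorm(100, 1)))
    compare_groups(d, "v", "g", "a", "b", force = "wilcox")$p < 0.05
  })
  expect_gt(mean(rejections), 0.95)
})

test_that("longitudinal tests report change, no-change, and interactions", {
  set.seed(204)
  n <- 84
  d <- data.frame(id = 1:n, group = rep(c("x", "y"), n / 2),
                  v1 = exp(rnorm(n)), v2 = NA)

  # identical sessions: signed-rank sentinel
  d$v2 <- d$v1
  r0 <- longitudinal_tests(d, "v1", "v2", test = "wilcoxon")
  expect_true(is.na(r0$p))
  expect_equal(r0$note, "no nonzero differences")

  # planted uniform decrease is detected
  d$v2 <- d$v1 * 0.6
  r1 <- longitudinal_tests(d, "v1", "v2", test = "wilcoxon")
  expect_lt(r1$p, 0.05)

  # mixed ANOVA: a group-balanced time effect loads on time, not the
  # interaction
  d$v1 <- rnorm(n)
  d$v2 <- d$v1 + 1 + rnorm(n, 0, 0.5)
  ra <- longitudinal_tests(d, "v1", "v2", group = "group", test = "anova")
  expect_lt(ra$p_time, 0.001)
  expect_gt(ra$p_interaction, 0.05)
  expect_equal(ra$n, n)

  # incomplete pairs are dropped listwise
  d$v2[1:4] <- NA
  expect_equal(longitudinal_tests(d, "v1", "v2", test = "wilcoxon")$n,
               n - 4)
})

test_that("Cox fit matches the exponential rate-ratio closed form", {
  set.seed(205)
  n <- 1e4
  x <- rbinom(n, 1, 0.5)
  d <- data.frame(
    x = x,
    relapse_day = rexp(n, 0.01 * 2^x),
    censored = FALSE
  )
  d$censored <- d$relapse_day > 180
  d$relapse_day <- pmin(d$relapse_day, 180)
  fit <- cox_relapse(d, "x", horizon = 180)
  expect_lt(abs(fit$table$hr - 2) / 2, 0.05)
  expect_true(fit$table$ci_lo < fit$table$hr & fit$table$hr < fit$table$ci_hi)
})

test_that("null-cohort Cox CIs cover 1 at the nominal rate", {
  set.seed(206)
  hz0 <- hazard_spec(log_hr_ftnd = 0, log_hr_vark = 0, log_hr_logk = 0)
  covered <- replicate(300, {
    co <- smoker_cohort(500)
    co <- attach_synthetic_estimates(co)
    co <- sample_relapse(co, hz0)
    tab <- cox_relapse(co, c("k_hat", "ftnd", "var_k"))$table
    tab$ci_lo <= 1 & 1 <= tab$ci_hi
  })
  expect_true(all(rowMeans(covered) >= 0.93))
})

test_that("Cox guards degenerate inputs", {
  co <- smoker_cohort(50, seed = 207)
  co <- attach_synthetic_estimates(co, seed = 208)
  co$relapse_day <- 180
  co$censored <- TRUE
  expect_error(cox_relapse(co, "var_k"), "no relapse events")

  co2 <- sample_relapse(attach_synthetic_estimates(smoker_cohort(25, 209),
                                                   seed = 210),
                        seed = 211)
  expect_warning(cox_relapse(co2, c("k_hat", "ftnd", "var_k")),
                 "fewer than 10 events")
})

test_that("the recovery report scores perfect, real, and destroyed estimates", {
  co <- smoker_cohort(200, seed = 212)
  perfect <- co
  perfect$k_hat <- perfect$log_k
  perfect$var_k <- exp(-perfect$log_beta) # any monotone decreasing map
  rp <- recovery_report(perfect)
  get <- function(r, m) r$value[r$metric == m]
  expect_equal(get(rp, "bias_logk"), 0)
  expect_equal(get(rp, "rmse_logk"), 0)
  expect_equal(get(rp, "spearman_k"), 1)
  expect_equal(get(rp, "spearman_vark_logbeta"), -1)

  shuffled <- perfect
  set.seed(213)
  shuffled$k_hat <- sample(shuffled$k_hat)
  expect_lt(abs(get(recovery_report(shuffled), "spearman_k")), 0.2)
})

test_that("the survival table tracks at-risk counts and events", {
  co <- sample_relapse(attach_synthetic_estimates(smoker_cohort(300, 214),
                                                  seed = 215),
                       seed = 216)
  st <- survival_table(co)
  expect_equal(st$at_risk[1], 300)
  expect_true(all(diff(st$at_risk) < 0))
  expect_true(all(st$survival >= 0 & st$survival <= 1))
  expect_equal(sum(st$events), sum(!co$censored))
})
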