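#' Normality-gated two-group comparison
#'
#' Mirrors the study's testing scheme: each group is screened with a
#' Shapiro-Wilk test at alpha = 0.05; if both pass, a Student's t test
#' (equal variances) with Cohen's d is used, otherwise a Mann-Whitney U
#' test with effect size r = |Z| / sqrt(N). The gate decision is recorded.
#'
#' @param data Data frame.
#' @param variable Name of the numeric column to compare.
#' @param group Name of the grouping column.
#' @param a,b The two group levels to compare.
#' @param force `"auto"` (Shapiro gate), `"t"`, or `"wilcox"`.
#' @param alpha Gate level for the Shapiro-Wilk screen.
#' @return An object of class `test_result`: list with `test`,
#'   `statistic`, `z`, `p`, `effect_size`, `effect_type`, `n`, `gate`.
#' @export
compare_groups <- function(data, variable, group, a, b,
                           force = c("auto", "t", "wilcox"), alpha = 0.05) {
  force <- match.arg(force)
  x <- data[[variable]][data[[group]] == a]
  y <- data[[variable]][data[[group]] == b]
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 observations per group")
  if (stats::var(c(x, y)) == 0)
    stop("degenerate input: '", variable, "' is constant")

  gate <- NULL
  if (force == "auto") {
    sw_ok <- function(v) {
      if (stats::var(v) == 0) return(FALSE)
      stats::shapiro.test(v)$p.value > alpha
    }
    gate <- list(normal_a = sw_ok(x), normal_b = sw_ok(y))
    use_t <- gate$normal_a && gate$normal_b
  } else {
    use_t <- force == "t"
  }

  n <- c(a = length(x), b = length(y))
  if (use_t) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    res <- list(test = "t", statistic = unname(tt$statistic),
                z = NA_real_, p = tt$p.value,
                effect_size = (mean(x) - mean(y)) / sp,
                effect_type = "cohen_d", n = n, gate = gate)
  } else {
    res <- c(mann_whitney(x, y), list(n = n, gate = gate))
  }
  structure(res, class = "test_result")
}

# Mann-Whitney U with normal-approximation Z (tie-corrected) and
# r = |Z|/sqrt(N); p exact when min(n) <= 20 and tie-free, else
# continuity-corrected normal approximation.
mann_whitney <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(n1, n2) <= 20 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  u <- unname(wt$statistic)
  mu <- n1 * n2 / 2
  r_all <- rank(c(x, y))
  ties <- table(r_all)
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
  z <- if (sigma > 0) (u - mu) / sigma else 0
  list(test = "mann_whitney", statistic = u, z = z, p = wt$p.value,
       effect_size = abs(z) / sqrt(n1 + n2), effect_type = "r")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.3f, p = %.4g, %s = %.3f (n = %d/%d)\n",
              x$test, x$statistic, x$p, x$effect_type, x$effect_size,
              x$n[1], x$n[2]))
  invisible(x)
}

#' Longitudinal tests across two sessions
#'
#' Mixed ANOVA (time x group, with subject as the error stratum) for the
#' discount rate, and a Wilcoxon signed-rank test for the typically
#' non-normal var(k). Incomplete pairs are dropped listwise and the
#' retained count reported. If every paired difference is zero the
#' signed-rank test is meaningless and a no-change sentinel (`p = NA`) is
#' returned.
#'
#' @param data Data frame with one row per subject.
#' @param t1,t2 Column names of the two sessions' values.
#' @param group Optional grouping column name for the ANOVA interaction.
#' @param test `"anova"` (mixed ANOVA) or `"wilcoxon"` (signed rank).
#' @return For `"anova"`: list with `f_time`, `p_time`, `f_interaction`,
#'   `p_interaction`, `n`. For `"wilcoxon"`: list with `statistic`, `p`,
#'   `n`, `note`.
#' @export
longitudinal_tests <- function(data, t1, t2, group = NULL,
                               test = c("anova", "wilcoxon")) {
  test <- match.arg(test)
  keep <- is.finite(data[[t1]]) & is.finite(data[[t2]])
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 2) stop("need at least 2 complete pairs")

  if (test == "wilcoxon") {
    diffs <- d[[t2]] - d[[t1]]
    if (all(diffs == 0)) {
      return(list(statistic = NA_real_, p = NA_real_, n = nrow(d),
                  note = "no nonzero differences"))
    }
    wt <- suppressWarnings(stats::wilcox.test(d[[t1]], d[[t2]],
                                              paired = TRUE))
    return(list(statistic = unname(wt$statistic), p = wt$p.value,
                n = nrow(d), note = NULL))
  }

  long <- data.frame(
    id = factor(rep(seq_len(nrow(d)), 2)),
    time = factor(rep(c("t1", "t2"), each = nrow(d))),
    value = c(d[[t1]], d[[t2]]),
    group = if (is.null(group)) factor("all") else
      factor(rep(d[[group]], 2))
  )
  has_groups <- nlevels(long$group) > 1
  form <- if (has_groups) value ~ time * group else value ~ time
  fit <- stats::aov(stats::update(form, . ~ . + Error(id/time)), data = long)
  tab <- summary(fit)[["Error: id:time"]][[1]]
  rn <- trimws(rownames(tab))
  out <- list(
    f_time = tab[rn == "time", "F value"],
    p_time = tab[rn == "time", "Pr(>F)"],
    f_interaction = if (has_groups) tab[rn == "time:group", "F value"] else NA,
    p_interaction = if (has_groups) tab[rn == "time:group", "Pr(>F)"] else NA,
    n = nrow(d)
  )
  out
}

#' Cox proportional-hazards model of relapse
#'
#' Fits a Cox model (Efron tie handling) to relapse times over a follow-up
#' horizon and reports per-covariate hazard ratios with 95% CIs. Events
#' after the horizon are censored at the horizon. Warns when events per
#' covariate fall below 10 and flags non-converged/unstable fits.
#'
#' @param data Cohort data frame with `relapse_day` and `censored`.
#' @param covariates Character vector of covariate column names.
#' @param horizon Follow-up horizon, days.
#' @return An object of class `cox_result`: data frame `table` (`term`,
#'   `hr`, `ci_lo`, `ci_hi`, `p`) plus `n_events`, `n_censored`,
#'   `unstable` and the fitted `model`.
#' @export
cox_relapse <- function(data, covariates = c("k_hat", "ftnd", "var_k"),
                        horizon = 180) {
  time <- pmin(data$relapse_day, horizon)
  event <- !data$censored & data$relapse_day <= horizon
  if (sum(event) == 0) stop("no relapse events within the horizon")
  if (sum(event) < 10 * length(covariates))
    warning("fewer than 10 events per covariate; estimates may be unstable")

  df <- data[, covariates, drop = FALSE]
  df$.time <- time
  df$.event <- event
  form <- stats::as.formula(
    paste("survival::Surv(.time, .event) ~",
          paste(covariates, collapse = " + ")))
  unstable <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = df, ties = "efron"),
    warning = function(w) {
      unstable <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    hr = s$conf.int[, "exp(coef)"],
    ci_lo = s$conf.int[, "lower .95"],
    ci_hi = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(
    list(table = tab, n_events = sum(event), n_censored = sum(!event),
         unstable = unstable, model = fit),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox model: %d events / %d censored%s\n", x$n_events,
              x$n_censored, if (x$unstable) " [unstable fit]" else ""))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %s: HR = %.3f, CI = %.2f-%.2f, p = %.4g\n",
                tab$term[i], tab$hr[i], tab$ci_lo[i], tab$ci_hi[i],
                tab$p[i]))
  }
  invisible(x)
}

#' Kaplan-Meier-style life table of relapse
#'
#' @param data Cohort with `relapse_day` and `censored`.
#' @param horizon Follow-up horizon, days.
#' @return Data frame `day`, `at_risk`, `events`, `survival`.
#' @export
survival_table <- function(data, horizon = 180) {
  time <- pmin(data$relapse_day, horizon)
  event <- !data$censored & data$relapse_day <= horizon
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(day = fit$time, at_risk = fit$n.risk, events = fit$n.event,
             survival = fit$surv)
}

#' Parameter-recovery summary of a simulated cohort
#'
#' Compares measured against latent parameters: bias, RMSE and Spearman
#' rank correlation of `k_hat` vs latent log k, and the (expected
#' negative) Spearman correlation of var(k) with latent log beta.
#'
#' @param cohort Data frame with `log_k`, `log_beta`, `k_hat`, `var_k`.
#' @return Data frame with one row per metric (`metric`, `value`).
#' @export
recovery_report <- function(cohort) {
  err <- cohort$k_hat - cohort$log_k
  rho_k <- stats::cor(cohort$k_hat, cohort$log_k, method = "spearman")
  rho_vb <- stats::cor(cohort$var_k, cohort$log_beta, method = "spearman")
  data.frame(
    metric = c("bias_logk", "rmse_logk", "mae_logk", "spearman_k",
               "spearman_vark_logbeta"),
    value = c(mean(err), sqrt(mean(err^2)), stats::median(abs(err)),
              rho_k, rho_vb)
  )
}
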