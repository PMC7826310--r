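#' Configuration of the pre-scan staircase calibration
#'
#' Defaults reproduce the standard calibration session: a fixed immediate
#' amount of 20 EUR against a delayed amount starting at 40 EUR, five delay
#' levels (10, 30, 60, 120, 180 days) of 10 titration trials each (50
#' analysis trials), preceded by 3 practice trials that are excluded from
#' every estimate.
#'
#' @param immediate Immediate amount, euros.
#' @param initial_delayed First delayed amount of every block, euros; must
#'   exceed `immediate`.
#' @param delays Delay levels in days; one block per delay.
#' @param trials_per_delay Titration trials per delay block.
#' @param practice_trials Practice trials prepended at the first delay.
#' @param block_order `"ascending"` (default) or `"as_given"`.
#' @param min_step Clamp: a titrated delayed amount never falls below
#'   `immediate + min_step` (euros).
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(immediate = 20, initial_delayed = 40,
                             delays = c(10, 30, 60, 120, 180),
                             trials_per_delay = 10, practice_trials = 3,
                             block_order = c("ascending", "as_given"),
                             min_step = 0.01) {
  if (initial_delayed <= immediate)
    stop("'initial_delayed' must exceed 'immediate'")
  if (trials_per_delay < 1 || length(delays) < 1)
    stop("need at least one trial per delay and one delay")
  block_order <- match.arg(block_order)
  structure(
    list(immediate = immediate, initial_delayed = initial_delayed,
         delays = if (block_order == "ascending") sort(delays) else delays,
         trials_per_delay = trials_per_delay,
         practice_trials = practice_trials, min_step = min_step),
    class = "staircase_config"
  )
}

#' Run an adaptive staircase calibration session
#'
#' Simulates the titration session for one agent. Within each delay block
#' the first offer is `initial_delayed`; after a "delayed" choice the next
#' delayed amount is reduced by half the difference between the current
#' delayed amount and the immediate amount, and after an "immediate" choice
#' it is increased by the same half-difference, so the offer walks toward
#' the agent's indifference amount `immediate * (1 + k * D)`. Practice
#' trials are presented first (at the first delay, at the initial amount,
#' with no adaptation) and flagged.
#'
#' @param agent An [agent_params()].
#' @param config A [staircase_config()].
#' @param seed Optional integer seed for the choice draws.
#' @return An object of class `staircase_session`: a list with `trials`
#'   (data frame: `trial_index`, `block`, `delay`, `immediate`, `delayed`,
#'   `choice`, `is_practice`) and the `config`.
#' @export
run_staircase <- function(agent, config = staircase_config(), seed = NULL) {
  stopifnot(inherits(agent, "agent_params"),
            inherits(config, "staircase_config"))
  if (!is.null(seed)) set.seed(seed)

  imm <- config$immediate
  rows <- vector("list", 0L)
  idx <- 0L

  one_trial <- function(delayed, delay) {
    simulate_choice(offer_pair(imm, delayed, delay), agent)
  }

  if (config$practice_trials > 0) {
    for (i in seq_len(config$practice_trials)) {
      idx <- idx + 1L
      ch <- one_trial(config$initial_delayed, config$delays[1])
      rows[[idx]] <- data.frame(
        trial_index = idx, block = 0L, delay = config$delays[1],
        immediate = imm, delayed = config$initial_delayed,
        choice = ch, is_practice = TRUE
      )
    }
  }

  for (b in seq_along(config$delays)) {
    delay <- config$delays[b]
    a <- config$initial_delayed
    for (t in seq_len(config$trials_per_delay)) {
      idx <- idx + 1L
      ch <- one_trial(a, delay)
      rows[[idx]] <- data.frame(
        trial_index = idx, block = b, delay = delay,
        immediate = imm, delayed = a, choice = ch, is_practice = FALSE
      )
      step <- (a - imm) / 2
      a <- if (ch == "delayed") a - step else a + step
      if (a <= imm + config$min_step) a <- imm + config$min_step
    }
  }

  structure(list(trials = do.call(rbind, rows), config = config),
            class = "staircase_session")
}

#' @export
print.staircase_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("staircase session: %d analysis trials (%d practice), %d delays\n",
              sum(!tr$is_practice), sum(tr$is_practice),
              length(unique(tr$delay[!tr$is_practice]))))
  invisible(x)
}

#' @export
as.data.frame.staircase_session <- function(x, ...) x$trials

#' Per-delay indifference points of a staircase session
#'
#' For each delay block the indifference point is the mean of the maximum
#' delayed amount rejected (choice "immediate") and the minimum delayed
#' amount chosen. One-sided blocks: with no rejection the subject showed no
#' measurable discounting at that delay and the point is the immediate
#' amount; with no acceptance the point is the last amount plus the half
#' step that would have followed it. Practice trials are excluded.
#'
#' @param session A [run_staircase()] result.
#' @return An object of class `indifference_curve`: data frame `points`
#'   (`delay`, `point`, `one_sided`) plus the immediate amount.
#' @export
indifference_points <- function(session) {
  stopifnot(inherits(session, "staircase_session"))
  tr <- session$trials[!session$trials$is_practice, ]
  if (nrow(tr) == 0) stop("session has no analysis trials")
  imm <- session$config$immediate

  blocks <- split(tr, tr$block)
  pts <- lapply(blocks, function(bl) {
    rejected <- bl$delayed[bl$choice == "immediate"]
    chosen <- bl$delayed[bl$choice == "delayed"]
    last_amt <- bl$delayed[which.max(bl$trial_index)]
    if (length(rejected) > 0 && length(chosen) > 0) {
      point <- (max(rejected) + min(chosen)) / 2
      one_sided <- FALSE
    } else if (length(chosen) > 0) {
      point <- imm # never rejected a delayed offer: no measurable discounting
      one_sided <- TRUE
    } else {
      point <- last_amt + (last_amt - imm) / 2
      one_sided <- TRUE
    }
    data.frame(delay = bl$delay[1], point = max(point, imm),
               one_sided = one_sided)
  })
  points <- do.call(rbind, pts)
  points <- points[order(points$delay), ]
  rownames(points) <- NULL
  structure(list(points = points, immediate = imm),
            class = "indifference_curve")
}

#' @export
print.indifference_curve <- function(x, ...) {
  cat("indifference points (EUR):\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Least-squares hyperbolic fit of the pre-scan discount rate
#'
#' Fits `k` so that the discounted indifference amounts match the immediate
#' amount: minimizes `sum_d (immediate - point_d / (1 + k * d))^2` by
#' bounded one-dimensional minimization (golden-section/parabolic on the
#' log-k axis). This is the OLS hyperbolic fit used to seed the Bayesian
#' prior.
#'
#' @param curve An [indifference_points()] result, or a data frame with
#'   columns `delay` and `point`.
#' @param immediate Immediate amount, euros (taken from the curve if given).
#' @param interval Search interval for `k`, 1/days.
#' @return List with `k` (the fit), `at_bound` (TRUE with a warning if the
#'   optimum sits at a search bound, e.g. flat points), and `sse`.
#' @export
fit_hyperbolic_k <- function(curve, immediate = NULL,
                             interval = c(1e-5, 10)) {
  if (inherits(curve, "indifference_curve")) {
    if (is.null(immediate)) immediate <- curve$immediate
    pts <- curve$points
  } else {
    pts <- curve
    if (is.null(immediate)) stop("'immediate' required with a raw data frame")
  }
  pts <- pts[is.finite(pts$point), ]
  if (nrow(pts) < 2) stop("need at least 2 delays with finite points")

  sse <- function(logk) {
    k <- exp(logk)
    sum((immediate - pts$point / (1 + k * pts$delay))^2)
  }
  opt <- stats::optimize(sse, interval = log(interval), tol = 1e-12)
  k_hat <- exp(opt$minimum)
  at_bound <- opt$minimum < log(interval[1]) + 1e-6 ||
    opt$minimum > log(interval[2]) - 1e-6
  if (at_bound)
    warning("hyperbolic fit at search bound; indifference points may be flat")
  list(k = k_hat, at_bound = at_bound, sse = opt$objective)
}

#' Full calibration: staircase, indifference points, pre-scan k
#'
#' Convenience wrapper chaining [run_staircase()], [indifference_points()]
#' and [fit_hyperbolic_k()].
#'
#' @inheritParams run_staircase
#' @return List with `session`, `curve`, `k_prescan`, `at_bound`.
#' @export
calibrate_agent <- function(agent, config = staircase_config(), seed = NULL) {
  session <- run_staircase(agent, config, seed = seed)
  curve <- indifference_points(session)
  fit <- suppressWarnings(fit_hyperbolic_k(curve))
  list(session = session, curve = curve,
       k_prescan = fit$k, at_bound = fit$at_bound)
}
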