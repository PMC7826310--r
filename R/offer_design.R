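#' Design specification for the individualized 90-trial task
#'
#' Encodes the fixed constraints of the in-scanner offer set: 5 delays with
#' 18 subjective values each (9 below and 9 above the immediate amount),
#' the scaling coefficients `c` for the below-immediate values, a target
#' mean subjective value of 30 EUR after standardization, and a twentyfold
#' ratio between the largest and smallest value in the set.
#'
#' @param delays Delay levels in days.
#' @param c_set Coefficients for the below-immediate values, in (0, 1);
#'   9 values by default (0.10 to 0.50 in steps of 0.05).
#' @param target_mean_value Post-standardization mean subjective value, EUR.
#' @param range_ratio Max/min subjective-value ratio of the full set.
#' @param v0 Base immediate value before standardization, EUR.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(delays = c(10, 30, 60, 120, 180),
                        c_set = seq(0.10, 0.50, by = 0.05),
                        target_mean_value = 30, range_ratio = 20,
                        v0 = 20) {
  if (any(c_set <= 0) || any(c_set >= 1))
    stop("'c_set' coefficients must lie in (0, 1)")
  if (range_ratio <= 1) stop("'range_ratio' must exceed 1")
  if (v0 <= 0 || target_mean_value <= 0) stop("values must be positive")
  structure(
    list(delays = sort(delays), c_set = sort(c_set),
         target_mean_value = target_mean_value,
         range_ratio = range_ratio, v0 = v0),
    class = "design_spec"
  )
}

#' Below-immediate subjective values
#'
#' For each delay `D` and coefficient `c`, the value
#' `V_d = V0 * (1 + k*D*c) / (1 + k*D)`, which is always below `V0` (for
#' `c < 1`) while the corresponding delayed amount `V_d * (1 + k*D)` stays
#' above the immediate amount — the construction that keeps every delayed
#' offer nominally larger than the immediate one.
#'
#' @param v0 Base immediate value, EUR (> 0).
#' @param k Design discount rate, 1/days (> 0).
#' @param delays Delay levels, days.
#' @param c_set Coefficients in (0, 1).
#' @return Data frame `delay`, `c`, `value` (one row per combination).
#' @export
lower_values <- function(v0, k, delays, c_set) {
  if (v0 <= 0 || k <= 0) stop("'v0' and 'k' must be positive")
  if (any(c_set <= 0) || any(c_set >= 1)) stop("'c' must lie in (0, 1)")
  grid <- expand.grid(c = c_set, delay = delays)
  kd <- k * grid$delay
  data.frame(delay = grid$delay, c = grid$c,
             value = v0 * (1 + kd * grid$c) / (1 + kd))
}

#' Above-immediate subjective values
#'
#' The maximum value of the whole offer set is `range_ratio` times its
#' global minimum (the longest-delay, smallest-`c` entry of
#' [lower_values()]). The span between `v0` and that maximum is divided
#' into 9 equidistant categories per delay, giving values
#' `v0 + j * (v_max - v0) / 9`, `j = 1..9`, identical across delays (the
#' delayed amounts differ by delay through the hyperbola).
#'
#' @param v0 Base immediate value, EUR.
#' @param k Design discount rate, 1/days.
#' @param delays Delay levels, days.
#' @param spec A [design_spec()] (supplies `c_set`, `range_ratio`,
#'   `values_per_delay` split).
#' @return Data frame `delay`, `category` (1..9), `value`.
#' @export
upper_values <- function(v0, k, delays = NULL, spec = design_spec()) {
  if (is.null(delays)) delays <- spec$delays
  lo <- lower_values(v0, k, delays, spec$c_set)
  v_min <- min(lo$value)
  v_max <- spec$range_ratio * v_min
  if (v_max <= v0)
    stop("configuration error: maximum value does not exceed the immediate value")
  n_up <- length(spec$c_set) # 9 under defaults: mirrors the below split
  step <- (v_max - v0) / n_up
  grid <- expand.grid(category = seq_len(n_up), delay = delays)
  data.frame(delay = grid$delay, category = grid$category,
             value = v0 + step * grid$category)
}

#' Build a standardized, shuffled task schedule
#'
#' Assembles the full offer set (below- and above-immediate values at the
#' design `k`), rescales all values and the immediate amount by the single
#' factor that brings the mean subjective value to the target (30 EUR by
#' default) — which preserves the twentyfold max/min ratio exactly — then
#' derives the delayed amounts `A = V * (1 + k*D)` and shuffles trial
#' order. The adapted immediate amount is not shown during the task; it is
#' carried in its own column.
#'
#' @param k Design discount rate (typically the pre-scan fit), 1/days.
#' @param spec A [design_spec()].
#' @param seed Optional integer seed for the shuffle and screen-side draw.
#' @return An object of class `task_schedule`: data frame `trials`
#'   (`trial_index`, `delay`, `value`, `delayed`, `immediate`, `below_immediate`,
#'   `side`) plus `immediate`, `k_design`, `scale_factor`, `spec`.
#' @export
build_schedule <- function(k, spec = design_spec(), seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (k <= 0) stop("'k' must be positive")
  if (!is.null(seed)) set.seed(seed)

  lo <- lower_values(spec$v0, k, spec$delays, spec$c_set)
  up <- upper_values(spec$v0, k, spec$delays, spec)
  values <- c(lo$value, up$value)
  delays <- c(lo$delay, up$delay)
  below <- c(rep(TRUE, nrow(lo)), rep(FALSE, nrow(up)))

  f <- spec$target_mean_value / mean(values)
  values <- values * f
  immediate <- spec$v0 * f

  ord <- sample.int(length(values))
  trials <- data.frame(
    trial_index = seq_along(values),
    delay = delays[ord],
    value = values[ord],
    delayed = values[ord] * (1 + k * delays[ord]),
    immediate = immediate,
    below_immediate = below[ord],
    side = sample(c("L", "R"), length(values), replace = TRUE)
  )
  structure(
    list(trials = trials, immediate = immediate, k_design = k,
         scale_factor = f, spec = spec),
    class = "task_schedule"
  )
}

#' @export
print.task_schedule <- function(x, ...) {
  v <- x$trials$value
  cat(sprintf(
    "task schedule: %d trials, %d delays; mean value %.2f EUR, max/min ratio %.2f\n",
    nrow(x$trials), length(unique(x$trials$delay)), mean(v), max(v) / min(v)))
  cat(sprintf("immediate amount (hidden): %.2f EUR; design k = %.4g /day\n",
              x$immediate, x$k_design))
  invisible(x)
}

#' @export
as.data.frame.task_schedule <- function(x, ...) x$trials

#' Write a task schedule and its design manifest
#'
#' Exports the trial table as CSV and, alongside it, a JSON manifest with
#' the design spec, the `k` used, the scaling factor and the seed, so a
#' schedule can be reproduced exactly.
#'
#' @param schedule A [build_schedule()] result.
#' @param path CSV path; the manifest goes to `<path>.manifest.json`.
#' @param seed The seed used to build the schedule (recorded, not applied).
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path, seed = NULL) {
  stopifnot(inherits(schedule, "task_schedule"))
  utils::write.csv(schedule$trials, path, row.names = FALSE)
  manifest <- list(
    schema_version = 1L,
    k_design = schedule$k_design,
    scale_factor = schedule$scale_factor,
    immediate = schedule$immediate,
    seed = seed,
    spec = unclass(schedule$spec)
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
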