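# Shared fixtures, built in code at test time.

# near-deterministic decision maker: softmax is effectively a step function
deterministic_agent <- function(k) agent_params(k, beta = 1e6)

# small grid for tests where full resolution is not the point
small_grid <- function() grid_spec(n_k = 41, n_beta = 41)

# hand-built staircase session wrapping an arbitrary trial table
fake_session <- function(trials, config = staircase_config()) {
  structure(list(trials = trials, config = config),
            class = "staircase_session")
}

# one delay block as a trial table
make_block <- function(delayed, choice, delay = 30, block = 1L,
                       immediate = 20) {
  data.frame(
    trial_index = seq_along(delayed), block = block, delay = delay,
    immediate = immediate, delayed = delayed, choice = choice,
    is_practice = FALSE
  )
}

# single-group cohort of smokers at the default population moments
smoker_cohort <- function(n, seed = NULL) {
  sample_cohort(list(group_spec("smoker", n, -3.98, 1.2, -1.01, 1.5,
                                ftnd_mean = 5, ftnd_sd = 2)),
                seed = seed)
}
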