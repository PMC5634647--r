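# shared fixtures: small task configurations and light fitting options so
# unit tests stay fast; the acceptance tests use study-scale settings

small_config <- function(n_trials = 150L, block_length = 50L,
                         reward_flip_period = 10L) {
  task_config(n_trials = n_trials, block_length = block_length,
              block_change_ranges = list(c(3, 6), c(7, 10), c(11, 14)),
              reward_flip_period = reward_flip_period)
}

light_opts <- function(seed = 7L) {
  fit_options(n_restarts = 1L, max_iter = 4L, optim_maxit = 40L, seed = seed)
}

# deterministic one-subject log where the agent always picks A1 and trials
# alternate second-level and first-level starts
perseverating_log <- function(n_pairs = 10L) {
  n <- 2L * n_pairs
  starts <- rep(c("S1", "S0"), n_pairs)
  second <- ifelse(starts == "S0", "S1", starts)
  tibble::tibble(
    subject = 1L, trial = seq_len(n), block = 1L, group = 1L,
    start_state = starts,
    first_choice = ifelse(starts == "S0", "A1", NA_character_),
    second_state = second,
    terminal_state = ifelse(second == "S1", "S3", "S4"),
    reward = rep(c(0.9, 0.8), n_pairs),
    contingency_id = 0L, contingency_changed = FALSE,
    reward_flip = FALSE, high_state = "S3"
  )
}
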