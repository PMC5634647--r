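#' Configure the two-level contingency-change task
#'
#' Defines the environment of the sequential decision task: trials start at
#' the first-level state `S0` (with probability 0.5) or directly at one of
#' the second-level states `S1`/`S2` (0.25 each); first-level actions lead
#' deterministically to second-level states (`A1 -> S1`, `A2 -> S2`); the
#' mapping from second-level to terminal states (`S3`/`S4`) flips every few
#' trials, with the flip rate varying over three blocks; one terminal state
#' pays a high reward that drifts as a bounded Gaussian random walk while the
#' other pays its complement, and the high/low assignment itself swaps every
#' `reward_flip_period` trials (never on a contingency-flip trial).
#'
#' @param n_trials Total number of trials; must equal
#'   `block_length * length(block_change_ranges)`.
#' @param block_length Trials per block.
#' @param block_change_ranges List of inclusive `(min, max)` ranges for the
#'   gaps (in trials) between contingency flips, in canonical
#'   fast/medium/slow order.
#' @param block_order `"fast_medium_slow"` or `"medium_fast_slow"`; the two
#'   counterbalancing groups differ in the order of the fast and medium
#'   blocks (the slow block is always last).
#' @param start_probs Named probabilities over start states `S0`, `S1`, `S2`.
#' @param reward_flip_period High/low reward assignment swaps at trials that
#'   are multiples of this period.
#' @param walk_mean,walk_sd Mean and sd of the (truncated) Gaussian from
#'   which the initial high payoff is drawn.
#' @param walk_drift Standard deviation of the per-trial Gaussian increment
#'   of the high payoff.
#' @param reward_bounds Reflecting bounds of the payoff walk.
#'
#' @return A `flexmb_task_config` list.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$n_trials
task_config <- function(n_trials = 600,
                        block_length = 200,
                        block_change_ranges = list(c(3, 6), c(7, 10), c(11, 14)),
                        block_order = c("fast_medium_slow", "medium_fast_slow"),
                        start_probs = c(S0 = 0.5, S1 = 0.25, S2 = 0.25),
                        reward_flip_period = 40,
                        walk_mean = 0.5,
                        walk_sd = 0.2,
                        walk_drift = 0.15,
                        reward_bounds = c(0, 1)) {
  block_order <- match.arg(block_order)
  n_blocks <- length(block_change_ranges)
  stopifnot(
    n_trials == block_length * n_blocks,
    abs(sum(start_probs) - 1) < 1e-12,
    all(vapply(block_change_ranges, length, 1L) == 2L),
    all(vapply(block_change_ranges, function(r) r[1] >= 2 && r[2] >= r[1], TRUE)),
    reward_flip_period >= 2,
    walk_drift > 0, walk_sd > 0,
    reward_bounds[1] < reward_bounds[2]
  )
  # freq_class[b]: which canonical range (1 fast, 2 medium, 3 slow) block b uses
  freq_class <- if (block_order == "fast_medium_slow") 1:3 else c(2L, 1L, 3L)
  if (n_blocks != 3L) freq_class <- seq_len(n_blocks)
  structure(
    list(
      n_trials = as.integer(n_trials),
      block_length = as.integer(block_length),
      n_blocks = as.integer(n_blocks),
      block_change_ranges = block_change_ranges,
      block_order = block_order,
      freq_class = freq_class,
      start_probs = start_probs,
      reward_flip_period = as.integer(reward_flip_period),
      walk_mean = walk_mean,
      walk_sd = walk_sd,
      walk_drift = walk_drift,
      reward_bounds = reward_bounds
    ),
    class = "flexmb_task_config"
  )
}

block_of <- function(trial, config) {
  pmin(((trial - 1L) %/% config$block_length) + 1L, config$n_blocks)
}

range_of_block <- function(block, config) {
  config$block_change_ranges[[config$freq_class[block]]]
}

#' Schedule the contingency-flip trials of an episode
#'
#' Gaps between successive flips are drawn uniformly from the active block's
#' inclusive range. A proposed flip that crosses a block boundary is redrawn
#' from the new block's range; one that lands on a reward-assignment-flip
#' trial (a multiple of `reward_flip_period`) is redrawn so the two kinds of
#' change never coincide. Uses the current RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param config A [task_config()].
#' @return Sorted integer vector of trial indices at which the contingency
#'   flips (applied at trial onset).
#' @export
schedule_contingency_changes <- function(config) {
  flips <- integer(0)
  t <- 0L
  draw_gap <- function(r) sample.int(r[2] - r[1] + 1L, 1L) + r[1] - 1L
  repeat {
    blk <- block_of(min(t + 1L, config$n_trials), config)
    cand <- t + draw_gap(range_of_block(blk, config))
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 100L) {
        # degenerate ranges (e.g. width 0) can make a redraw futile; a
        # one-trial shift always clears the reward-flip grid
        if (cand %% config$reward_flip_period == 0L) cand <- cand + 1L
        break
      }
      blk2 <- block_of(min(cand, config$n_trials), config)
      if (blk2 != blk && cand <= config$n_trials) {
        blk <- blk2
        cand <- t + draw_gap(range_of_block(blk, config))
        next
      }
      if (cand %% config$reward_flip_period == 0L) {
        cand <- t + draw_gap(range_of_block(blk, config))
        next
      }
      break
    }
    if (cand > config$n_trials) break
    flips <- c(flips, cand)
    t <- cand
  }
  flips
}

reflect_bounds <- function(x, lo, hi) {
  # fold x back into [lo, hi]
  width <- hi - lo
  while (x < lo || x > hi) {
    if (x > hi) x <- 2 * hi - x
    if (x < lo) x <- 2 * lo - x
  }
  x
}

#' Initialise the mutable task state
#'
#' Draws the initial high payoff from a truncated Gaussian
#' `N(walk_mean, walk_sd)`, sets the contingency to mapping A
#' (`S1 -> S3`, `S2 -> S4`), places the high reward on `S3`, precomputes the
#' contingency-flip schedule and samples the start state of trial 1.
#'
#' @param config A [task_config()].
#' @return A `flexmb_task_state` list with fields `trial_index`,
#'   `contingency`, `next_change_trial`, `high_reward_state`, `payoff_high`,
#'   `payoff_low`, `next_start` and the flip schedule.
#' @export
init_task_state <- function(config) {
  repeat {
    p <- rnorm(1, config$walk_mean, config$walk_sd)
    if (p >= config$reward_bounds[1] && p <= config$reward_bounds[2]) break
  }
  flips <- schedule_contingency_changes(config)
  structure(
    list(
      trial_index = 0L,
      contingency = 0L,
      flips = flips,
      next_change_trial = if (length(flips)) flips[1] else NA_integer_,
      high_reward_state = "S3",
      payoff_high = p,
      payoff_low = 1 - p,
      next_start = sample(.start_levels, 1L, prob = config$start_probs)
    ),
    class = "flexmb_task_state"
  )
}

#' Advance the payoff random walk by one step
#'
#' Perturbs the high payoff by a Gaussian increment of sd `walk_drift`,
#' reflects it at `reward_bounds`, and keeps the low payoff at its
#' complement (the two always sum to 1).
#'
#' @param state A `flexmb_task_state`.
#' @param config A [task_config()].
#' @return The updated state.
#' @export
step_reward_walk <- function(state, config) {
  p <- reflect_bounds(state$payoff_high + rnorm(1, 0, config$walk_drift),
                      config$reward_bounds[1], config$reward_bounds[2])
  state$payoff_high <- p
  state$payoff_low <- 1 - p
  state
}

#' Advance the task by one trial
#'
#' Applies, at trial onset, any scheduled contingency flip and any
#' reward-assignment flip (the two never coincide), steps the payoff walk
#' (trials after the first), resolves the transition and reward for the
#' pre-sampled start state, and samples the start state of the next trial.
#' The upcoming start state is available as `state$next_start`, so callers
#' know whether a first-level choice is required.
#'
#' @param state A `flexmb_task_state`.
#' @param config A [task_config()].
#' @param first_choice `"A1"` or `"A2"` when `state$next_start == "S0"`,
#'   otherwise `NULL`.
#' @param subject Subject id written into the record.
#' @return A list with `record` (one-row tibble in the trial-log schema) and
#'   the updated `state`.
#' @export
advance_trial <- function(state, config, first_choice = NULL, subject = 1L) {
  t <- state$trial_index + 1L
  stopifnot(t <= config$n_trials)
  start <- state$next_start
  if (start == "S0" && is.null(first_choice)) {
    stop("a first-level trial requires `first_choice`")
  }
  if (start != "S0" && !is.null(first_choice)) {
    stop("`first_choice` supplied on a second-level-start trial")
  }

  changed <- !is.na(state$next_change_trial) && t == state$next_change_trial
  if (changed) {
    state$contingency <- 1L - state$contingency
    nxt <- state$flips[state$flips > t]
    state$next_change_trial <- if (length(nxt)) nxt[1] else NA_integer_
  }
  reward_flip <- t %% config$reward_flip_period == 0L
  if (reward_flip) {
    state$high_reward_state <- setdiff(.terminal_levels, state$high_reward_state)
  }
  if (t > 1L) state <- step_reward_walk(state, config)

  second <- if (start == "S0") {
    .second_levels[match(first_choice, .action_levels)]
  } else {
    start
  }
  s2i <- match(second, .second_levels) - 1L
  termi <- if (state$contingency == 0L) s2i else 1L - s2i
  terminal <- .terminal_levels[termi + 1L]
  reward <- if (terminal == state$high_reward_state) state$payoff_high else state$payoff_low

  record <- tibble::tibble(
    subject = subject,
    trial = t,
    block = block_of(t, config),
    group = ifelse(config$block_order == "fast_medium_slow", 1L, 2L),
    start_state = start,
    first_choice = if (start == "S0") first_choice else NA_character_,
    second_state = second,
    terminal_state = terminal,
    reward = reward,
    contingency_id = state$contingency,
    contingency_changed = changed,
    reward_flip = reward_flip,
    high_state = state$high_reward_state
  )

  state$trial_index <- t
  state$next_start <- sample(.start_levels, 1L, prob = config$start_probs)
  list(record = record, state = state)
}

#' Generate the agent-independent part of a task episode
#'
#' Start states, contingency sequence, payoff walk and reward-assignment
#' flips do not depend on the agent's choices, so a full episode's
#' environment can be drawn up front; [simulate_subject()] then runs an
#' agent through it. Uses the current RNG stream.
#'
#' @param config A [task_config()].
#' @return A tibble with one row per trial: `trial`, `block`, `start_state`,
#'   `contingency_id`, `contingency_changed`, `reward_flip`, `high_state`,
#'   `payoff_high`.
#' @export
generate_episode <- function(config) {
  n <- config$n_trials
  flips <- schedule_contingency_changes(config)
  contingency <- integer(n)
  cur <- 0L
  fl <- logical(n)
  fl[flips] <- TRUE
  for (t in seq_len(n)) {
    if (fl[t]) cur <- 1L - cur
    contingency[t] <- cur
  }
  # payoff walk
  payoff <- numeric(n)
  repeat {
    p <- rnorm(1, config$walk_mean, config$walk_sd)
    if (p >= config$reward_bounds[1] && p <= config$reward_bounds[2]) break
  }
  payoff[1] <- p
  steps <- rnorm(n - 1, 0, config$walk_drift)
  for (t in 2:n) {
    p <- reflect_bounds(p + steps[t - 1], config$reward_bounds[1], config$reward_bounds[2])
    payoff[t] <- p
  }
  # reward-assignment flips at multiples of the period, applied at onset
  reward_flip <- seq_len(n) %% config$reward_flip_period == 0L
  high <- integer(n) # 0 = S3, 1 = S4
  curh <- 0L
  for (t in seq_len(n)) {
    if (reward_flip[t]) curh <- 1L - curh
    high[t] <- curh
  }
  start <- sample(.start_levels, n, replace = TRUE, prob = config$start_probs)
  tibble::tibble(
    trial = seq_len(n),
    block = block_of(seq_len(n), config),
    start_state = start,
    contingency_id = contingency,
    contingency_changed = fl,
    reward_flip = reward_flip,
    high_state = .terminal_levels[high + 1L],
    payoff_high = payoff
  )
}
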