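#' Agent parameters
#'
#' Free parameters of the hybrid model-based / model-free learner.
#'
#' @param wMB Model-based weight in `[0,1]`; a scalar, or a 3-vector indexed
#'   per block or per contingency-change-frequency class (see
#'   [model_spec()]).
#' @param alpha_MF Model-free learning rate in `[0,1]`.
#' @param alpha_MB Model-based reward learning rate in `[0,1]`.
#' @param beta Softmax inverse temperature, `>= 0`.
#' @param lam Eligibility trace in `[0,1]`: 0 means first-level actions are
#'   credited only through second-level values, 1 means the terminal reward
#'   updates them directly within the trial.
#' @param stay_bias Additive bonus (value units) applied transiently at
#'   decision time to the previously chosen first-level action.
#' @param alpha_MB_transition Learning rate of the transition table; fixed
#'   at 1 in the standard model (one observation rewrites the mapping).
#'
#' @return A `flexmb_params` list.
#' @export
agent_params <- function(wMB = 0.56, alpha_MF = 0.5, alpha_MB = 0.5,
                         beta = 5, lam = 0.5, stay_bias = 0.2,
                         alpha_MB_transition = 1) {
  stopifnot(
    all(wMB >= 0 & wMB <= 1), length(wMB) %in% c(1L, 3L),
    alpha_MF >= 0, alpha_MF <= 1, alpha_MB >= 0, alpha_MB <= 1,
    beta >= 0, lam >= 0, lam <= 1,
    alpha_MB_transition >= 0, alpha_MB_transition <= 1
  )
  structure(
    list(wMB = wMB, alpha_MF = alpha_MF, alpha_MB = alpha_MB, beta = beta,
         lam = lam, stay_bias = stay_bias,
         alpha_MB_transition = alpha_MB_transition),
    class = "flexmb_params"
  )
}

#' Initialise an agent's learned state
#'
#' All cached values and subjective rewards start at 0.5, the indifference
#' point of the mirrored `[0,1]` reward scale; the transition table starts
#' at mapping A (`S1 -> S3`, `S2 -> S4`).
#'
#' @return A `flexmb_agent_state` list with `Q_MF` (entries `A1`, `A2` for
#'   the first level and `S1`, `S2` for the forced second-level actions),
#'   `P_T` (`p13 = P(S1 -> S3)`, `p24 = P(S2 -> S4)`; the other two cells
#'   are the complements), `R` (subjective reward of `S3`, `S4`) and
#'   `prev_first_choice`.
#' @export
init_agent_state <- function() {
  structure(
    list(
      Q_MF = c(A1 = 0.5, A2 = 0.5, S1 = 0.5, S2 = 0.5),
      P_T = c(p13 = 1, p24 = 1),
      R = c(S3 = 0.5, S4 = 0.5),
      prev_first_choice = NA_character_
    ),
    class = "flexmb_agent_state"
  )
}

#' Fictive mirror update
#'
#' The two second-level states (and the two terminal states) carry
#' complementary rewards, so updating a visited entry licenses setting its
#' unvisited counterpart to one minus the new value.
#'
#' @param state A `flexmb_agent_state` in which `entry` was just updated.
#' @param table `"Q_MF"` (second-level values; entries `"S1"`/`"S2"`) or
#'   `"R"` (terminal rewards; entries `"S3"`/`"S4"`).
#' @param entry Name of the entry that was just updated.
#' @return The state with the paired entry mirrored.
#' @export
mirror_update <- function(state, table = c("Q_MF", "R"), entry) {
  table <- match.arg(table)
  pairs <- if (table == "Q_MF") .second_levels else .terminal_levels
  stopifnot(entry %in% pairs)
  other <- setdiff(pairs, entry)
  state[[table]][other] <- 1 - state[[table]][entry]
  state
}

trial_fields <- function(trial) {
  if (inherits(trial, "data.frame")) trial <- as.list(trial)
  trial
}

#' Model-free TD(lambda) update for one trial
#'
#' The second-level value moves toward the terminal reward by the delta
#' rule; when the trial started at `S0`, the chosen first-level action is
#' updated by its own one-step prediction error (reward 0 at the first
#' level) plus `lam` times the second-level error, so `lam = 0` credits
#' first-level actions only through second-level values and `lam = 1`
#' credits them directly with the terminal reward. The unvisited
#' second-level value is mirrored unless `fictive = FALSE`.
#'
#' @param state A `flexmb_agent_state`.
#' @param trial List or one-row data frame with `start_state`,
#'   `first_choice` (may be `NA`), `second_state`, `reward`.
#' @param params An [agent_params()].
#' @param fictive Apply the mirror update to the unvisited second-level
#'   state.
#' @return The updated state.
#' @export
mf_update <- function(state, trial, params, fictive = TRUE) {
  tr <- trial_fields(trial)
  s2 <- tr$second_state
  delta2 <- tr$reward - state$Q_MF[s2]
  if (identical(tr$start_state, "S0") && !is.na(tr$first_choice)) {
    a <- tr$first_choice
    delta1 <- state$Q_MF[s2] - state$Q_MF[a] # first-level reward is 0
    state$Q_MF[a] <- state$Q_MF[a] + params$alpha_MF * (delta1 + params$lam * delta2)
  }
  state$Q_MF[s2] <- state$Q_MF[s2] + params$alpha_MF * delta2
  if (fictive) state <- mirror_update(state, "Q_MF", s2)
  state
}

#' Model-based observation update for one trial
#'
#' The observed second-to-terminal transition identifies one of the two
#' complementary mappings; both rows of the transition table move toward it
#' (fully, unless `alpha_MB_transition < 1`). The visited terminal state's
#' subjective reward moves toward the observed reward by the delta rule,
#' and the unvisited terminal state is mirrored unless `fictive = FALSE`.
#'
#' @inheritParams mf_update
#' @param trial List or one-row data frame with `second_state`,
#'   `terminal_state`, `reward`.
#' @return The updated state.
#' @export
mb_observe <- function(state, trial, params, fictive = TRUE) {
  tr <- trial_fields(trial)
  aT <- params$alpha_MB_transition
  # target 1 if the observation is consistent with mapping A
  targetA <- as.numeric((tr$second_state == "S1") == (tr$terminal_state == "S3"))
  state$P_T["p13"] <- state$P_T["p13"] + aT * (targetA - state$P_T["p13"])
  state$P_T["p24"] <- state$P_T["p24"] + aT * (targetA - state$P_T["p24"])
  term <- tr$terminal_state
  state$R[term] <- state$R[term] + params$alpha_MB * (tr$reward - state$R[term])
  if (fictive) state <- mirror_update(state, "R", term)
  state
}

#' First-level action values of the two systems and their mixture
#'
#' The model-based values are the expected subjective reward under the
#' learned transition table; the hybrid value is the `wMB`-weighted convex
#' combination of model-based and cached model-free values.
#'
#' @param state A `flexmb_agent_state`.
#' @param params An [agent_params()].
#' @param w_index Which component of `wMB` governs the current trial (by
#'   block or frequency class); ignored for scalar `wMB`.
#' @return List with numeric pairs `Q_MB`, `Q_MF`, `Q_hybrid` (named
#'   `A1`, `A2`).
#' @export
compute_q_values <- function(state, params, w_index = 1L) {
  p13 <- state$P_T[["p13"]]
  p24 <- state$P_T[["p24"]]
  q_mb <- c(
    A1 = p13 * state$R[["S3"]] + (1 - p13) * state$R[["S4"]],
    A2 = (1 - p24) * state$R[["S3"]] + p24 * state$R[["S4"]]
  )
  q_mf <- state$Q_MF[c("A1", "A2")]
  w <- if (length(params$wMB) == 1L) params$wMB else params$wMB[w_index]
  list(Q_MB = q_mb, Q_MF = q_mf, Q_hybrid = w * q_mb + (1 - w) * q_mf)
}

#' Softmax choice probabilities with stay bias
#'
#' Adds `stay_bias` to the previously chosen action's value (transiently,
#' at decision time only) and applies an overflow-safe softmax with inverse
#' temperature `beta`.
#'
#' @param q Numeric pair of first-level action values, named `A1`, `A2`.
#' @param params An [agent_params()].
#' @param prev_first_choice `"A1"`, `"A2"` or `NA` (no previous choice).
#' @return Named probability pair summing to 1.
#' @export
action_probabilities <- function(q, params, prev_first_choice = NA) {
  stopifnot(all(is.finite(q)))
  qb <- q
  if (!is.na(prev_first_choice)) {
    qb[prev_first_choice] <- qb[prev_first_choice] + params$stay_bias
  }
  z <- params$beta * (qb[["A1"]] - qb[["A2"]])
  p1 <- if (z > 0) 1 / (1 + exp(-z)) else exp(z) / (1 + exp(z))
  c(A1 = p1, A2 = 1 - p1)
}

#' Apply one trial's learning to both systems
#'
#' Convenience step interface: runs [mf_update()] and [mb_observe()] on an
#' experienced trial and tracks the most recent first-level choice (used by
#' the stay bias, across any intervening forced trials).
#'
#' @inheritParams mf_update
#' @return The updated state.
#' @export
agent_step <- function(state, trial, params, fictive = TRUE) {
  tr <- trial_fields(trial)
  state <- mf_update(state, tr, params, fictive = fictive)
  state <- mb_observe(state, tr, params, fictive = fictive)
  if (identical(tr$start_state, "S0") && !is.na(tr$first_choice)) {
    state$prev_first_choice <- tr$first_choice
  }
  state
}
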