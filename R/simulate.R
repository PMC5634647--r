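#' @keywords internal
# full engine parameter list from an agent_params object or a named list
as_full_params <- function(spec, params) {
  if (inherits(params, "flexmb_params")) {
    w <- params$wMB
    pl <- list(alpha_MF = params$alpha_MF, alpha_MB = params$alpha_MB,
               alpha = params$alpha_MF, beta = params$beta, lam = params$lam,
               stay = params$stay_bias, alpha_T = params$alpha_MB_transition)
    if (spec$weight_structure %in% c("hybrid_3block", "hybrid_3freq")) {
      if (length(w) == 1L) w <- rep(w, 3)
      pl$w1 <- w[1]; pl$w2 <- w[2]; pl$w3 <- w[3]
    } else {
      pl$w <- w[1]
    }
    params <- pl
  }
  # fixed values from the spec win over whatever the caller passed
  tab <- spec$param_table
  for (i in seq_len(nrow(tab))) {
    if (!is.na(tab$fixed[i])) params[[tab$name[i]]] <- tab$fixed[i]
  }
  params
}

#' Simulate one subject on the task
#'
#' Draws a task episode with [generate_episode()] and runs an agent through
#' it, choosing at every first-level trial by the softmax over the hybrid
#' action values. Uses the current RNG stream.
#'
#' @param spec A [model_spec()].
#' @param params An [agent_params()] (or named natural-scale list).
#' @param config A [task_config()]; its `block_order` determines the
#'   subject's counterbalancing group.
#' @param subject Subject id.
#' @return Tibble of trial records (one row per trial) in the trial-log
#'   schema (see [write_trials()]).
#' @export
simulate_subject <- function(spec, params, config = task_config(), subject = 1L) {
  full <- as_full_params(spec, params)
  ep <- generate_episode(config)
  n <- nrow(ep)
  u <- runif(n)
  group <- if (config$block_order == "fast_medium_slow") 1L else 2L
  w_idx <- w_index_for(spec, ep$block, rep(group, n)) - 1L
  res <- cpp_simulate(
    start = match(ep$start_state, .start_levels) - 1L,
    conting = ep$contingency_id,
    payoff_high = ep$payoff_high,
    high_state = match(ep$high_state, .terminal_levels) - 1L,
    u = u, w_idx = w_idx, eng = engine_args(spec, full)
  )
  tibble::tibble(
    subject = subject,
    trial = ep$trial,
    block = ep$block,
    group = group,
    start_state = ep$start_state,
    first_choice = .action_levels[res$choice + 1L],
    second_state = .second_levels[res$s2 + 1L],
    terminal_state = .terminal_levels[res$term + 1L],
    reward = res$reward,
    contingency_id = ep$contingency_id,
    contingency_changed = ep$contingency_changed,
    reward_flip = ep$reward_flip,
    high_state = ep$high_state
  )
}

#' Simulate a cohort of subjects
#'
#' Each subject runs an independent episode with its own deterministic
#' sub-seed; half the cohort is assigned to each counterbalancing group
#' (fast-medium-slow vs medium-fast-slow block order).
#'
#' @param spec A [model_spec()].
#' @param params A single [agent_params()] shared by all subjects, or a
#'   list of one parameter set per subject.
#' @param config Base [task_config()] (its `block_order` is overridden per
#'   group).
#' @param n_subjects Number of simulated subjects.
#' @param seed Cohort seed; per-subject seeds are derived from it.
#' @return A `flexmb_cohort`: list with `data` (trial tibble over all
#'   subjects), `true_params`, `spec`, `config`, `seed`.
#' @export
simulate_cohort <- function(spec, params, config = task_config(),
                            n_subjects = 16L, seed = 1L) {
  if (inherits(params, "flexmb_params")) params <- rep(list(params), n_subjects)
  stopifnot(length(params) == n_subjects)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  groups <- rep(1:2, each = ceiling(n_subjects / 2))[seq_len(n_subjects)]
  data <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    set.seed(sub_seeds[s])
    cfg <- config
    cfg$block_order <- if (groups[s] == 1L) "fast_medium_slow" else "medium_fast_slow"
    cfg$freq_class <- if (groups[s] == 1L) 1:3 else c(2L, 1L, 3L)
    simulate_subject(spec, params[[s]], cfg, subject = s)
  })
  structure(
    list(data = data, true_params = params, spec = spec, config = config,
         seed = seed),
    class = "flexmb_cohort"
  )
}

#' @export
print.flexmb_cohort <- function(x, ...) {
  cat("<flexmb_cohort>", x$spec$name, "-", length(x$true_params), "subjects,",
      nrow(x$data), "trials (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Build the parameter-recovery grid of cohorts
#'
#' One block's model-based weight is varied over a grid of values while the
#' other two blocks are held at a reference weight; every setting is
#' simulated as a fresh cohort under the three-block hybrid. The default
#' grid (11 values per block, 33 settings, 16 subjects each) matches the
#' full recovery design; a coarser grid can be requested for speed.
#'
#' @param seed Grid seed; each cohort gets a derived seed.
#' @param values Weight grid values in `[0,1]`.
#' @param ref Reference [agent_params()] for the non-varied blocks and the
#'   remaining parameters.
#' @param config A [task_config()].
#' @param n_subjects Subjects per cohort.
#' @return List of `flexmb_cohort`s; each carries attributes
#'   `varied_block` and `true_value`.
#' @export
recovery_grid <- function(seed = 1L, values = seq(0, 1, by = 0.1),
                          ref = agent_params(), config = task_config(),
                          n_subjects = 16L) {
  spec <- model_spec("hybrid_3block")
  set.seed(seed)
  settings <- tidyr::expand_grid(block = 1:3, value = values)
  cohort_seeds <- sample.int(.Machine$integer.max - 1L, nrow(settings))
  purrr::pmap(list(settings$block, settings$value, cohort_seeds),
    function(b, v, s) {
      w <- rep(ref$wMB[1], 3)
      w[b] <- v
      p <- ref
      p$wMB <- w
      ch <- simulate_cohort(spec, p, config, n_subjects, seed = s)
      attr(ch, "varied_block") <- b
      attr(ch, "true_value") <- v
      ch
    })
}
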