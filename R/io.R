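trial_col_classes <- c(
  subject = "integer", trial = "integer", block = "integer",
  group = "integer", start_state = "character", first_choice = "character",
  second_state = "character", terminal_state = "character",
  reward = "numeric", contingency_id = "integer",
  contingency_changed = "logical", reward_flip = "logical",
  high_state = "character"
)

#' Validate a trial-log tibble
#'
#' Checks the deterministic structure of the task: state labels are legal,
#' a recorded first-level choice implies its second-level state
#' (`A1 -> S1`, `A2 -> S2`), and the terminal state is consistent with the
#' recorded contingency. Offending rows are listed in the error.
#'
#' @param data Trial-log tibble.
#' @return The data, invisibly, if valid.
#' @export
validate_trials <- function(data) {
  required <- c("subject", "trial", "start_state", "first_choice",
                "second_state", "terminal_state", "reward", "block",
                "contingency_id")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_state <- which(!(data$start_state %in% .start_levels) |
                       !(is.na(data$second_state) | data$second_state %in% .second_levels) |
                       !(is.na(data$terminal_state) | data$terminal_state %in% .terminal_levels) |
                       !(is.na(data$first_choice) | data$first_choice %in% .action_levels))
  implied <- c(A1 = "S1", A2 = "S2")[data$first_choice]
  bad_choice <- which(data$start_state == "S0" & !is.na(data$first_choice) &
                        !is.na(data$second_state) & implied != data$second_state)
  s2i <- match(data$second_state, .second_levels)
  expected_term <- ifelse(data$contingency_id == 0L,
                          .terminal_levels[s2i], .terminal_levels[3L - s2i])
  bad_term <- which(!is.na(data$second_state) & !is.na(data$terminal_state) &
                      data$terminal_state != expected_term)
  problems <- sort(unique(c(bad_state, bad_choice, bad_term)))
  if (length(problems) > 0) {
    stop("invalid trial rows: ", paste(utils::head(problems, 20), collapse = ", "),
         if (length(problems) > 20) " ..." else "")
  }
  invisible(data)
}

#' Read and write trial logs as CSV
#'
#' The canonical interchange format is a UTF-8 CSV with a header row and
#' one row per trial; a missing first-level choice (second-level-start or
#' missed trial) is an empty field. `read_trials()` validates the
#' deterministic task structure on load.
#'
#' @param path File path.
#' @param data Trial-log tibble.
#' @return `read_trials()`: the validated tibble. `write_trials()`: the
#'   data, invisibly.
#' @export
read_trials <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  classes <- trial_col_classes[intersect(names(trial_col_classes), header)]
  data <- utils::read.csv(path, na.strings = "", colClasses = classes,
                          stringsAsFactors = FALSE)
  data <- tibble::as_tibble(data)
  validate_trials(data)
  data
}

#' @rdname read_trials
#' @export
write_trials <- function(data, path) {
  out <- as.data.frame(data)
  # %.17g preserves doubles exactly across the write/parse round trip
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA_character_
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(data)
}

#' Read and write run configurations
#'
#' A run configuration is a plain list (task settings, model list, fitting
#' and evaluation options, seeds) serialised as YAML; the round-trip is
#' lossless for numeric, character and logical fields.
#'
#' @param config Named list.
#' @param path File path.
#' @return `read_run_config()`: the list. `write_run_config()`: the
#'   config, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(config)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

# the hand-enumerable 6-trial stay-probability fixture (built in code; the
# corresponding expected tables are enumerated in the test suite)
stay_fixture <- function() {
  tibble::tibble(
    subject = 1L,
    trial = 1:6,
    block = 1L,
    group = 1L,
    start_state = c("S1", "S0", "S0", "S2", "S0", "S0"),
    first_choice = c(NA, "A1", "A2", NA, "A1", "A1"),
    second_state = c("S1", "S1", "S2", "S2", "S1", "S1"),
    terminal_state = c("S3", "S3", "S4", "S3", "S4", "S4"),
    reward = c(0.9, 0.8, 0.2, 0.85, 0.1, 0.15),
    contingency_id = c(0L, 0L, 0L, 1L, 1L, 1L),
    contingency_changed = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    reward_flip = FALSE,
    high_state = "S3"
  )
}

#' Write the package's small test fixtures
#'
#' Writes the hand-enumerable 6-trial stay-probability fixture, a 10-trial
#' likelihood fixture together with its reference negative log-likelihood
#' (computed by replaying the learning updates step by step with the
#' agents-module functions), and one small simulated cohort per candidate
#' model, each with a manifest of its true parameters.
#'
#' @param dir Output directory.
#' @param seed Seed for the simulated fixtures.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir, seed = 20170928L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  p <- file.path(dir, "stay_fixture.csv")
  write_trials(stay_fixture(), p)
  paths <- c(paths, p)

  # 10-trial likelihood fixture
  cfg <- task_config(n_trials = 10, block_length = 10,
                     block_change_ranges = list(c(3, 6)),
                     reward_flip_period = 5)
  params <- agent_params(wMB = 0.6, alpha_MF = 0.4, alpha_MB = 0.7,
                         beta = 3, lam = 0.5, stay_bias = 0.2)
  spec <- model_spec("hybrid_1w")
  set.seed(seed)
  ds <- simulate_subject(spec, params, cfg)
  p <- file.path(dir, "nll_fixture.csv")
  write_trials(ds, p)
  nll <- replay_nll(ds, params)
  write_run_config(
    list(params = params[c("wMB", "alpha_MF", "alpha_MB", "beta", "lam",
                           "stay_bias")],
         nll = nll),
    file.path(dir, "nll_fixture_expected.yaml"))
  paths <- c(paths, p, file.path(dir, "nll_fixture_expected.yaml"))

  # one small cohort per candidate model
  small_cfg <- task_config(n_trials = 60, block_length = 20,
                           block_change_ranges = list(c(3, 6), c(7, 10), c(11, 14)),
                           reward_flip_period = 10)
  candidates <- list(
    pure_MF = list(model_spec("pure_MF"), agent_params(wMB = 0)),
    pure_MB = list(model_spec("pure_MB"), agent_params(wMB = 1)),
    hybrid_1w = list(model_spec("hybrid_1w"), agent_params(wMB = 0.56)),
    hybrid_3block = list(model_spec("hybrid_3block"),
                         agent_params(wMB = c(0.3, 0.5, 0.7))),
    hybrid_3freq = list(model_spec("hybrid_3freq"),
                        agent_params(wMB = c(0.5, 0.5, 0.5)))
  )
  for (nm in names(candidates)) {
    ch <- simulate_cohort(candidates[[nm]][[1]], candidates[[nm]][[2]],
                          small_cfg, n_subjects = 2L, seed = seed)
    p <- file.path(dir, paste0("cohort_", nm, ".csv"))
    write_trials(ch$data, p)
    write_run_config(
      list(model = nm, seed = seed,
           params = candidates[[nm]][[2]][c("wMB", "alpha_MF", "alpha_MB",
                                            "beta", "lam", "stay_bias")]),
      file.path(dir, paste0("cohort_", nm, "_manifest.yaml")))
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Replay a trial log through the step-by-step agent functions
#'
#' Reference (non-compiled) computation of the choice negative
#' log-likelihood: walks the log trial by trial, querying
#' [action_probabilities()] on the hybrid values before applying
#' [agent_step()]. Used to generate fixture reference values and as the
#' cross-check for [subject_nll()].
#'
#' @param data Trial-log tibble for one subject.
#' @param params An [agent_params()].
#' @param fictive Apply mirrored updates.
#' @return The negative log-likelihood.
#' @export
replay_nll <- function(data, params, fictive = TRUE) {
  state <- init_agent_state()
  nll <- 0
  spec_like <- list(weight_structure = if (length(params$wMB) == 3) "hybrid_3block" else "hybrid_1w")
  for (i in seq_len(nrow(data))) {
    tr <- as.list(data[i, ])
    if (identical(tr$start_state, "S0") && !is.na(tr$first_choice)) {
      wi <- w_index_for(spec_like, tr$block, tr$group %||% 1L)
      q <- compute_q_values(state, params, w_index = wi)
      pr <- action_probabilities(q$Q_hybrid, params, state$prev_first_choice)
      nll <- nll - log(pr[[tr$first_choice]])
    }
    if (!is.na(tr$second_state) && !is.na(tr$terminal_state) &&
        is.finite(tr$reward)) {
      state <- agent_step(state, tr, params, fictive = fictive)
    }
  }
  nll
}
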