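#' Stay probabilities conditioned on previous reward and contingency change
#'
#' Stay probability is the probability of choosing the first-level action
#' that leads (deterministically) to the same second-level state as was
#' visited on the previous trial. An analysis trial must itself start at
#' `S0` with a recorded choice; under the main variant
#' (`"second_level_start"`) the previous trial must have started at a
#' second-level state — only those trials separate model-based from
#' model-free control, because no first-level action was experienced under
#' the (possibly new) contingency — while `"first_level_start"` conditions
#' on previous trials that started at `S0`. Cells cross the previous
#' trial's reward (high/low: whether the received payoff was the larger of
#' the two complementary payoffs then in force, i.e. above 0.5) with
#' whether the previous trial's transition had
#' changed relative to the trial before it. Trials following a missed
#' trial are ineligible.
#'
#' @param data Trial-log tibble (one or more subjects).
#' @param variant `"second_level_start"` (default) or `"first_level_start"`.
#' @return A tibble with one row per subject x reward x contingency cell:
#'   `stay_prob` (NA when the cell has no eligible trials) and `n_trials`.
#' @export
stay_probabilities <- function(data, variant = c("second_level_start",
                                                 "first_level_start")) {
  variant <- match.arg(variant)
  out <- data |>
    dplyr::group_by(.data$subject) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(
      prev_start = dplyr::lag(.data$start_state),
      prev_second = dplyr::lag(.data$second_state),
      prev_reward = dplyr::lag(.data$reward),
      prev_changed = dplyr::lag(.data$contingency_changed),
      has_prev2 = dplyr::row_number() >= 3L,
      eligible = .data$start_state == "S0" & !is.na(.data$first_choice) &
        .data$has_prev2 & !is.na(.data$prev_second) &
        (if (variant == "second_level_start") .data$prev_start %in% c("S1", "S2")
         else .data$prev_start == "S0"),
      stay = .data$first_choice == c(S1 = "A1", S2 = "A2")[.data$prev_second],
      reward_cond = ifelse(.data$prev_reward > 0.5, "high", "low"),
      conting_cond = ifelse(.data$prev_changed, "changed", "fixed")
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$eligible) |>
    dplyr::group_by(.data$subject, .data$reward_cond, .data$conting_cond) |>
    dplyr::summarise(stay_prob = mean(.data$stay), n_trials = dplyr::n(),
                     .groups = "drop")
  # make empty cells explicit: count 0, probability undefined
  out <- out |>
    tidyr::complete(
      subject = unique(data$subject),
      reward_cond = c("high", "low"),
      conting_cond = c("changed", "fixed"),
      fill = list(n_trials = 0L)
    ) |>
    dplyr::mutate(variant = variant) |>
    dplyr::arrange(.data$subject, .data$reward_cond, .data$conting_cond)
  out
}

#' Two-way ANOVA on stay-probability condition means
#'
#' Tests the main effects of previous-trial reward (high/low) and
#' contingency (changed/fixed), and their interaction, on the per-subject
#' cell means from [stay_probabilities()]. The default treats the four
#' cells per subject as independent observations (error df `4N - 4`); a
#' repeated-measures variant partitions subject variance instead. Subjects
#' with any undefined cell are excluded (with a message).
#'
#' @param tables Output of [stay_probabilities()].
#' @param design `"between"` (default) or `"within"` (repeated measures).
#' @return Tibble of terms with `df`, `df_residual`, `statistic` (F) and
#'   `p.value`; attribute `n_subjects` gives the number analysed.
#' @export
condition_anova <- function(tables, design = c("between", "within")) {
  design <- match.arg(design)
  bad <- tables |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(any_na = any(is.na(.data$stay_prob)), .groups = "drop") |>
    dplyr::filter(.data$any_na)
  if (nrow(bad) > 0) {
    message("excluding ", nrow(bad), " subject(s) with undefined cells")
    tables <- dplyr::anti_join(tables, bad["subject"], by = "subject")
  }
  n_sub <- dplyr::n_distinct(tables$subject)
  if (n_sub < 2) stop("need at least 2 subjects with all four cells defined")
  df <- tables |>
    dplyr::mutate(
      reward = factor(.data$reward_cond, c("low", "high")),
      contingency = factor(.data$conting_cond, c("fixed", "changed")),
      subject = factor(.data$subject)
    )
  if (design == "between") {
    fit <- aov(stay_prob ~ reward * contingency, data = df)
    tab <- summary(fit)[[1]]
    terms <- trimws(rownames(tab))
    resid_df <- tab[terms == "Residuals", "Df"]
    out <- tibble::tibble(
      term = terms[terms != "Residuals"],
      df = tab[terms != "Residuals", "Df"],
      df_residual = resid_df,
      statistic = tab[terms != "Residuals", "F value"],
      p.value = tab[terms != "Residuals", "Pr(>F)"]
    )
  } else {
    fit <- aov(stay_prob ~ reward * contingency +
                 Error(subject / (reward * contingency)), data = df)
    sm <- summary(fit)
    out <- purrr::map_dfr(sm, function(stratum) {
      tab <- stratum[[1]]
      terms <- trimws(rownames(tab))
      keep <- terms != "Residuals"
      if (!any(keep)) return(NULL)
      tibble::tibble(
        term = terms[keep],
        df = tab[keep, "Df"],
        df_residual = tab[terms == "Residuals", "Df"][1],
        statistic = tab[keep, "F value"],
        p.value = tab[keep, "Pr(>F)"]
      )
    })
    out <- dplyr::filter(out, !is.na(.data$statistic))
  }
  attr(out, "n_subjects") <- n_sub
  out
}

#' Per-block performance summaries
#'
#' High-reward choice probability is the fraction of first-level choice
#' trials whose chosen action led, under the contingency in force, to the
#' terminal state then paying the larger of the two complementary rewards;
#' reward rate is the mean reward per trial within the block.
#'
#' @param data Trial-log tibble.
#' @return Tibble with one row per subject x block: `n_choice_trials`,
#'   `high_choice_prob`, `reward_rate`.
#' @export
performance_summaries <- function(data) {
  data |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::summarise(
      n_choice_trials = sum(.data$start_state == "S0" & !is.na(.data$first_choice)),
      high_choice_prob = mean(
        (.data$reward > 0.5)[
          .data$start_state == "S0" & !is.na(.data$first_choice)]),
      reward_rate = mean(.data$reward, na.rm = TRUE),
      .groups = "drop"
    )
}
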