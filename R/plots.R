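#' Bar plot of stay probabilities by condition
#'
#' Condition means (with across-subject standard errors) of the 2 x 2
#' stay-probability table: previous-trial reward (high/low) crossed with
#' previous-trial contingency (changed/fixed).
#'
#' @param tables Output of [stay_probabilities()].
#' @return A ggplot object.
#' @export
plot_stay_probabilities <- function(tables) {
  summ <- tables |>
    dplyr::filter(!is.na(.data$stay_prob)) |>
    dplyr::group_by(.data$reward_cond, .data$conting_cond) |>
    dplyr::summarise(mean = mean(.data$stay_prob),
                     se = sd(.data$stay_prob) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(reward_cond = factor(.data$reward_cond, c("high", "low")),
                  conting_cond = factor(.data$conting_cond, c("fixed", "changed")))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$reward_cond, y = .data$mean,
                                     fill = .data$conting_cond)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "previous reward", y = "stay probability",
                  fill = "contingency") +
    ggplot2::theme_minimal()
}

#' @method autoplot flexmb_recovery
#' @export
autoplot.flexmb_recovery <- function(object, ...) {
  ggplot2::ggplot(object$settings,
                  ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ block, labeller = ggplot2::label_both) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "true model-based weight",
                  y = "median recovered weight") +
    ggplot2::theme_minimal()
}

#' @method autoplot flexmb_fit
#' @export
autoplot.flexmb_fit <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$parameter, y = .data$map_natural)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "per-subject MAP (natural scale)",
                  title = object$spec$name) +
    ggplot2::theme_minimal()
}

#' @method autoplot flexmb_perm
#' @export
autoplot.flexmb_perm <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object$perm),
                              dplyr::everything(),
                              names_to = "statistic", values_to = "value")
  obs <- tibble::tibble(statistic = names(object$observed),
                        observed = unname(object$observed))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~ statistic, scales = "free") +
    ggplot2::labs(x = "permutation statistic", y = "count") +
    ggplot2::theme_minimal()
}
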