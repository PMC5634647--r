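#' Tidy a hierarchical fit
#'
#' One row per free parameter: the Gaussian group prior on the transformed
#' scale and the across-subject median of the natural-scale MAP estimates.
#'
#' @param x A `flexmb_fit`.
#' @param ... Unused.
#' @return A tibble with `parameter`, `group_mean`, `group_sd`
#'   (transformed scale) and `natural_median`.
#' @method tidy flexmb_fit
#' @export
tidy.flexmb_fit <- function(x, ...) {
  nat <- x$estimates |>
    dplyr::group_by(parameter = .data$parameter) |>
    dplyr::summarise(natural_median = median(.data$map_natural),
                     .groups = "drop")
  tibble::tibble(
    parameter = names(x$prior$mu),
    group_mean = unname(x$prior$mu),
    group_sd = sqrt(unname(x$prior$sigma2))
  ) |>
    dplyr::left_join(nat, by = "parameter")
}

#' Glance at a hierarchical fit
#'
#' @param x A `flexmb_fit`.
#' @param ... Unused.
#' @return A one-row tibble: subjects, free parameters, total negative
#'   log-likelihood, EM iterations, convergence flag.
#' @method glance flexmb_fit
#' @export
glance.flexmb_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$subjects),
    n_params = length(x$prior$mu),
    total_nll = sum(x$subject_nll),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @method tidy flexmb_recovery
#' @export
tidy.flexmb_recovery <- function(x, ...) x$correlations

#' @method glance flexmb_recovery
#' @export
glance.flexmb_recovery <- function(x, ...) {
  tibble::tibble(
    n_settings = nrow(x$settings),
    n_failed = sum(is.na(x$settings$recovered)),
    overall_r = x$correlations$r[x$correlations$block == "overall"]
  )
}

#' @method tidy flexmb_perm
#' @export
tidy.flexmb_perm <- function(x, ...) {
  tibble::tibble(statistic = names(x$observed),
                 observed = unname(x$observed),
                 p.value = unname(x$p))
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
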