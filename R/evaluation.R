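#' Run the parameter-recovery pipeline on a grid of cohorts
#'
#' Fits the model to every cohort of a [recovery_grid()]; the recovered
#' value of a setting is the across-subject median of the MAP estimate of
#' the varied block's weight. Correlations between true and recovered
#' values are computed per block and over the whole grid. Cohorts whose
#' fit fails are flagged and excluded (with a message).
#'
#' @param grid List of cohorts from [recovery_grid()].
#' @param spec A [model_spec()] (default: the three-block hybrid the grid
#'   was simulated from).
#' @param options A [fit_options()].
#' @return A `flexmb_recovery`: `settings` tibble (block, true, recovered,
#'   total negative log-likelihood), `correlations` tibble (one row per
#'   block plus `"overall"`), and the per-setting fits.
#' @export
run_recovery <- function(grid, spec = model_spec("hybrid_3block"),
                         options = fit_options()) {
  rows <- purrr::imap(grid, function(ch, i) {
    b <- attr(ch, "varied_block")
    v <- attr(ch, "true_value")
    fit <- tryCatch(fit_em(ch, spec, options), error = function(e) e)
    if (inherits(fit, "error")) {
      message("setting ", i, " (block ", b, ", w = ", v, ") failed: ",
              conditionMessage(fit))
      return(list(row = tibble::tibble(setting = i, block = b, true = v,
                                       recovered = NA_real_, nll = NA_real_),
                  fit = NULL))
    }
    wname <- paste0("w", b)
    est <- fit$estimates
    rec <- median(est$map_natural[est$parameter == wname])
    list(row = tibble::tibble(setting = i, block = b, true = v,
                              recovered = rec, nll = sum(fit$subject_nll)),
         fit = fit)
  })
  settings <- purrr::map_dfr(rows, "row")
  fits <- purrr::map(rows, "fit")
  ok <- settings[!is.na(settings$recovered), ]
  cor_safe <- function(x, y) {
    if (length(x) < 3 || sd(x) == 0) NA_real_ else cor(x, y)
  }
  correlations <- dplyr::bind_rows(
    ok |>
      dplyr::group_by(block = as.character(.data$block)) |>
      dplyr::summarise(n = dplyr::n(),
                       r = cor_safe(.data$true, .data$recovered),
                       .groups = "drop"),
    tibble::tibble(block = "overall", n = nrow(ok),
                   r = cor_safe(ok$true, ok$recovered))
  )
  structure(list(settings = settings, correlations = correlations, fits = fits),
            class = "flexmb_recovery")
}

#' @export
print.flexmb_recovery <- function(x, ...) {
  cat("<flexmb_recovery>", nrow(x$settings), "settings\n")
  print(x$correlations)
  invisible(x)
}

#' Hellinger distance between two Gaussians
#'
#' Closed form: `H^2 = 1 - sqrt(2 s1 s2 / (s1^2 + s2^2)) *
#' exp(-(m1 - m2)^2 / (4 (s1^2 + s2^2)))`.
#'
#' @param mu1,sd1,mu2,sd2 Means and standard deviations.
#' @return The distance in `[0, 1]`.
#' @export
hellinger_gaussian <- function(mu1, sd1, mu2, sd2) {
  stopifnot(sd1 > 0, sd2 > 0)
  bc <- sqrt(2 * sd1 * sd2 / (sd1^2 + sd2^2)) *
    exp(-(mu1 - mu2)^2 / (4 * (sd1^2 + sd2^2)))
  sqrt(max(0, 1 - bc))
}

#' Hellinger distance between two samples via common histograms
#'
#' Bins both samples on a shared grid and computes the discrete Hellinger
#' distance `sqrt(1 - sum(sqrt(p * q)))` of the bin frequencies.
#'
#' @param x,y Numeric samples.
#' @param n_bins Number of shared bins.
#' @return The distance in `[0, 1]`.
#' @export
hellinger_empirical <- function(x, y, n_bins = 10L) {
  rng <- range(c(x, y))
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  p <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins) / length(x)
  q <- tabulate(findInterval(y, breaks, all.inside = TRUE), n_bins) / length(y)
  sqrt(max(0, 1 - sum(sqrt(p * q))))
}

# MAP natural-scale estimates of one parameter across subjects
map_of <- function(fit, parameter) {
  est <- fit$estimates
  est$map_natural[est$parameter == parameter]
}

#' Permutation test for block-wise differences in the model-based weight
#'
#' Fits the three-block hybrid on the true block labels, then repeatedly
#' reassigns every subject's trials at random among three equal
#' pseudo-blocks (labels only; trial order and learning dynamics are
#' untouched — the labels decide which weight component governs each
#' trial's choice probability), refits, and recomputes the across-subject
#' fraction of subjects whose later-block weight exceeds the earlier one.
#' The one-tailed p-value is the (add-one corrected) fraction of
#' permutations whose statistic reaches the true-label statistic.
#'
#' @param data Trial-log tibble or `flexmb_cohort`.
#' @param n_perm Number of permutations (each is a full refit).
#' @param seed Seed governing the permutations.
#' @param options A [fit_options()] (reduced settings make the refits
#'   affordable).
#' @return A `flexmb_perm`: observed statistics (`b2_gt_b1`, `b3_gt_b2`),
#'   permutation matrix, p-values, the true-label fit, `n_perm`, `seed`.
#' @export
permutation_test_blocks <- function(data, n_perm = 100L, seed = 1L,
                                    options = fit_options()) {
  stopifnot(n_perm >= 1)
  if (inherits(data, "flexmb_cohort")) data <- data$data
  spec <- model_spec("hybrid_3block")
  stat_of <- function(fit) {
    c(b2_gt_b1 = mean(map_of(fit, "w2") > map_of(fit, "w1")),
      b3_gt_b2 = mean(map_of(fit, "w3") > map_of(fit, "w2")))
  }
  fit_true <- fit_em(data, spec, options)
  observed <- stat_of(fit_true)
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  perm <- matrix(NA_real_, n_perm, 2,
                 dimnames = list(NULL, c("b2_gt_b1", "b3_gt_b2")))
  for (i in seq_len(n_perm)) {
    set.seed(perm_seeds[i])
    pd <- data |>
      dplyr::group_by(.data$subject) |>
      dplyr::mutate(block = {
        n <- dplyr::n()
        sample(rep(1:3, length.out = n))
      }) |>
      dplyr::ungroup()
    perm[i, ] <- stat_of(fit_em(pd, spec, options))
  }
  p <- (colSums(sweep(perm, 2, observed, ">=")) + 1) / (n_perm + 1)
  structure(list(observed = observed, perm = perm, p = p, fit_true = fit_true,
                 n_perm = n_perm, seed = seed, kind = "blocks"),
            class = "flexmb_perm")
}

#' Permutation test for frequency-wise differences in the model-based
#' weight
#'
#' Fits the three-frequency hybrid (one weight per contingency-change
#' rate: fast, medium, slow), then repeatedly reassigns each subject at
#' random to one of the two counterbalancing groups — which fixes the
#' mapping from blocks to frequency classes — refits, and compares the
#' fast-vs-medium and medium-vs-slow weights. Both the one-tailed tally
#' statistic (fraction of subjects with the later-frequency weight larger)
#' and a two-tailed Hellinger-distance statistic between the
#' across-subject distributions of the two compared weights are reported.
#'
#' @inheritParams permutation_test_blocks
#' @param estimator Hellinger estimator: `"gaussian"` (moment-matched
#'   closed form on the transformed MAP estimates) or `"empirical"`
#'   (shared-histogram distance on the natural-scale MAPs).
#' @return A `flexmb_perm` with tally and Hellinger statistics and
#'   p-values for both comparisons.
#' @export
permutation_test_frequency <- function(data, n_perm = 100L, seed = 1L,
                                       options = fit_options(),
                                       estimator = c("gaussian", "empirical")) {
  stopifnot(n_perm >= 1)
  estimator <- match.arg(estimator)
  if (inherits(data, "flexmb_cohort")) data <- data$data
  spec <- model_spec("hybrid_3freq")
  hell <- function(x, y) {
    if (estimator == "gaussian") {
      hellinger_gaussian(mean(x), max(sd(x), 1e-6), mean(y), max(sd(y), 1e-6))
    } else {
      hellinger_empirical(x, y)
    }
  }
  stat_of <- function(fit) {
    wf <- map_of(fit, "w1") # fast
    wm <- map_of(fit, "w2") # medium
    ws <- map_of(fit, "w3") # slow
    c(med_gt_fast = mean(wm > wf), slow_gt_med = mean(ws > wm),
      hell_fast_med = hell(wf, wm), hell_med_slow = hell(wm, ws))
  }
  fit_true <- fit_em(data, spec, options)
  observed <- stat_of(fit_true)
  subjects <- unique(data$subject)
  set.seed(seed)
  perm_groups <- matrix(sample(1:2, n_perm * length(subjects), replace = TRUE),
                        n_perm, length(subjects))
  perm <- matrix(NA_real_, n_perm, 4, dimnames = list(NULL, names(observed)))
  for (i in seq_len(n_perm)) {
    g <- stats::setNames(perm_groups[i, ], subjects)
    pd <- dplyr::mutate(data, group = unname(g[as.character(.data$subject)]))
    perm[i, ] <- stat_of(fit_em(pd, spec, options))
  }
  p <- (colSums(sweep(perm, 2, observed, ">=")) + 1) / (n_perm + 1)
  structure(list(observed = observed, perm = perm, p = p, fit_true = fit_true,
                 n_perm = n_perm, seed = seed, kind = "frequency",
                 estimator = estimator),
            class = "flexmb_perm")
}

#' @export
print.flexmb_perm <- function(x, ...) {
  cat("<flexmb_perm>", x$kind, "-", x$n_perm, "permutations (seed",
      paste0(x$seed, ")"), "\n")
  print(tibble::tibble(statistic = names(x$observed),
                       observed = unname(x$observed), p = unname(x$p)))
  invisible(x)
}
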