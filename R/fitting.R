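#' Negative log-likelihood of one subject's choices
#'
#' Sums `-log` softmax probability of the observed first-level choice over
#' all trials that started at `S0` with a recorded choice. Learning updates
#' are applied on every experienced trial, including second-level-start
#' trials; missed trials (no recorded transition) contribute neither
#' likelihood nor learning, but the choice history they interrupt is kept.
#'
#' @param data Trial-log tibble for a single subject.
#' @param spec A [model_spec()].
#' @param params Natural-scale parameters: an [agent_params()] or a named
#'   list/vector covering the spec's free parameters.
#' @return The negative log-likelihood (scalar).
#' @export
subject_nll <- function(data, spec, params) {
  full <- as_full_params(spec, params)
  enc <- encode_dataset(data, spec)
  cpp_nll(enc$start, enc$choice, enc$s2, enc$term, enc$reward,
          enc$w_idx, engine_args(spec, full))
}

n_choice_trials <- function(data) {
  sum(data$start_state == "S0" & !is.na(data$first_choice))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Options for the hierarchical EM fit
#'
#' @param n_restarts Random restarts per subject per E-step, drawn from the
#'   current group prior (the previous MAP is always added as a start from
#'   the second EM iteration on).
#' @param max_iter Maximum EM iterations.
#' @param tol EM stops when every group mean changes by less than this on
#'   the transformed scale.
#' @param optim_maxit Iteration cap for each BFGS run.
#' @param m_step `"laplace"` folds the per-subject Laplace covariances into
#'   the group-variance update; `"map"` uses the MAP points only.
#' @param init_mu,init_sigma2 Optional named initial group prior on the
#'   transformed scale (defaults: mean 0, variance 2.25).
#' @param seed Seed for the restart draws.
#' @return Options list for [fit_em()].
#' @export
fit_options <- function(n_restarts = 5L, max_iter = 50L, tol = 1e-3,
                        optim_maxit = 100L, m_step = c("laplace", "map"),
                        init_mu = NULL, init_sigma2 = NULL, seed = 1L) {
  list(n_restarts = n_restarts, max_iter = max_iter, tol = tol,
       optim_maxit = optim_maxit, m_step = match.arg(m_step),
       init_mu = init_mu, init_sigma2 = init_sigma2, seed = seed)
}

# Generic EM over arbitrary per-subject negative log-likelihood functions
# of an unconstrained d-vector. Returns prior, MAPs, Laplace covariances.
em_core <- function(nll_funs, d, options = fit_options()) {
  n_sub <- length(nll_funs)
  mu <- if (!is.null(options$init_mu)) options$init_mu else rep(0, d)
  sigma2 <- if (!is.null(options$init_sigma2)) options$init_sigma2 else rep(2.25, d)
  map <- matrix(NA_real_, n_sub, d)
  map_cov <- vector("list", n_sub)
  nll_at_map <- obj_at_map <- rep(NA_real_, n_sub)
  set.seed(options$seed)
  trace <- list()
  converged <- FALSE

  for (iter in seq_len(options$max_iter)) {
    for (s in seq_len(n_sub)) {
      nf <- nll_funs[[s]]
      obj <- function(x) {
        v <- nf(x) + sum((x - mu)^2 / (2 * sigma2)) + 0.5 * sum(log(2 * pi * sigma2))
        if (!is.finite(v)) 1e10 else v
      }
      starts <- replicate(options$n_restarts, rnorm(d, mu, sqrt(sigma2)),
                          simplify = FALSE)
      if (iter > 1L) starts <- c(list(map[s, ]), starts)
      best <- NULL
      for (st in starts) {
        fit <- tryCatch(
          optim(st, obj, method = "BFGS",
                control = list(maxit = options$optim_maxit)),
          error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
      }
      if (is.null(best)) stop("all E-step optimizations failed for subject ", s)
      map[s, ] <- best$par
      obj_at_map[s] <- best$value
      nll_at_map[s] <- nf(best$par)
      H <- tryCatch(optimHess(best$par, obj), error = function(e) NULL)
      cv <- NULL
      if (!is.null(H)) {
        cv <- tryCatch(solve(H), error = function(e) NULL)
        if (!is.null(cv) && any(diag(cv) <= 0)) cv <- NULL
      }
      if (is.null(cv)) cv <- diag(1e-4, d) # flat curvature fallback
      map_cov[[s]] <- cv
    }
    mu_new <- colMeans(map)
    cov_diags <- matrix(vapply(map_cov, diag, numeric(d)), n_sub, d, byrow = TRUE)
    sigma2_new <- if (options$m_step == "laplace") {
      colMeans(map^2 + cov_diags) - mu_new^2
    } else {
      colMeans(map^2) - mu_new^2
    }
    sigma2_new <- pmax(sigma2_new, 1e-4)
    trace[[iter]] <- c(iter = iter, mu_new)
    delta <- max(abs(mu_new - mu))
    mu <- mu_new
    sigma2 <- sigma2_new
    if (delta < options$tol) {
      converged <- TRUE
      break
    }
  }
  list(mu = mu, sigma2 = sigma2, map = map, map_cov = map_cov,
       nll = nll_at_map, obj = obj_at_map, iterations = iter,
       converged = converged, trace = trace)
}

#' Fit a model to a cohort by hierarchical expectation-maximization
#'
#' Mixed-effects fit with a diagonal Gaussian group prior over the
#' transformed parameters. Each E-step maximizes, per subject, the log
#' posterior (choice log-likelihood plus log group prior) from multiple
#' restarts, taking a Laplace covariance from the curvature at the optimum;
#' the M-step re-estimates the group means and variances from the MAP
#' estimates (and, by default, their covariances). Deterministic given the
#' options seed.
#'
#' @param data A `flexmb_cohort` or trial-log tibble with a `subject`
#'   column.
#' @param spec A [model_spec()].
#' @param options A [fit_options()] list.
#' @return A `flexmb_fit`: group prior, per-subject MAP estimates (both
#'   scales), per-subject negative log-likelihood, Laplace covariances and
#'   evidences, EM trace, convergence flag.
#' @export
fit_em <- function(data, spec, options = fit_options()) {
  if (inherits(data, "flexmb_cohort")) data <- data$data
  subjects <- unique(data$subject)
  if (length(subjects) < 2) stop("hierarchical fitting needs at least 2 subjects")
  free <- spec_free_names(spec)
  d <- length(free)
  by_sub <- lapply(subjects, function(s) data[data$subject == s, ])
  nll_funs <- lapply(by_sub, function(ds) {
    make_subject_nll_fun(encode_dataset(ds, spec), spec)
  })
  core <- em_core(nll_funs, d, options)
  colnames(core$map) <- free
  # per-subject Laplace log evidence
  logev <- vapply(seq_along(by_sub), function(s) {
    det_cv <- det(core$map_cov[[s]])
    -core$obj[s] + d / 2 * log(2 * pi) + 0.5 * log(max(det_cv, 1e-300))
  }, numeric(1))
  natural <- t(apply(core$map, 1, function(x) {
    untransform_params(spec, stats::setNames(x, free))
  }))
  if (d == 1L) natural <- matrix(natural, ncol = 1, dimnames = list(NULL, free))
  estimates <- tibble::tibble(
    subject = rep(subjects, each = d),
    parameter = rep(free, length(subjects)),
    map_transformed = as.vector(t(core$map)),
    map_natural = as.vector(t(natural))
  )
  structure(
    list(
      spec = spec,
      prior = list(mu = stats::setNames(core$mu, free),
                   sigma2 = stats::setNames(core$sigma2, free)),
      estimates = estimates,
      map = core$map,
      map_cov = core$map_cov,
      subject_nll = stats::setNames(core$nll, subjects),
      subject_logev_laplace = stats::setNames(logev, subjects),
      n_choice_trials = vapply(by_sub, n_choice_trials, integer(1)),
      iterations = core$iterations,
      converged = core$converged,
      trace = core$trace,
      options = options,
      subjects = subjects
    ),
    class = "flexmb_fit"
  )
}

#' @export
print.flexmb_fit <- function(x, ...) {
  cat("<flexmb_fit>", x$spec$name, "-", length(x$subjects), "subjects,",
      x$iterations, "EM iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  total NLL:", round(sum(x$subject_nll), 2), "\n")
  invisible(x)
}

#' Monte-Carlo integrated evidence per subject
#'
#' Estimates, for each subject, the log marginal likelihood of the choices
#' under the fitted group prior by averaging the likelihood over draws of
#' the parameters from that prior (log-sum-exp stabilised). The standard
#' error of each estimate is returned so the sample count can be judged.
#'
#' @param data Trial-log tibble (or `flexmb_cohort`).
#' @param spec A [model_spec()].
#' @param prior List with named `mu` and `sigma2` on the transformed scale.
#' @param n_mc Number of Monte-Carlo draws per subject.
#' @param seed Seed for the draws.
#' @return Tibble with `subject`, `log_evidence`, `se`.
#' @export
integrated_evidence <- function(data, spec, prior, n_mc = 2000L, seed = 1L) {
  if (inherits(data, "flexmb_cohort")) data <- data$data
  free <- spec_free_names(spec)
  d <- length(free)
  subjects <- unique(data$subject)
  set.seed(seed)
  draws <- if (d > 0) {
    matrix(rnorm(n_mc * d, rep(prior$mu[free], each = n_mc),
                 rep(sqrt(prior$sigma2[free]), each = n_mc)),
           n_mc, d, dimnames = list(NULL, free))
  } else {
    matrix(0, 1, 0)
  }
  purrr::map_dfr(subjects, function(s) {
    ds <- data[data$subject == s, ]
    nf <- make_subject_nll_fun(encode_dataset(ds, spec), spec)
    ll <- -vapply(seq_len(nrow(draws)), function(i) nf(draws[i, ]), numeric(1))
    if (d == 0) {
      tibble::tibble(subject = s, log_evidence = ll[1], se = 0)
    } else {
      lz <- logsumexp(ll) - log(n_mc)
      w <- exp(ll - max(ll))
      se <- sd(w) / (sqrt(n_mc) * mean(w)) # delta method on the log
      tibble::tibble(subject = s, log_evidence = lz, se = se)
    }
  })
}

#' Integrated Bayesian information criterion
#'
#' `iBIC = -2 * sum_s log p(data_s | group prior) + k * log(n)`, where the
#' marginal likelihood integrates over the fitted group prior (Monte-Carlo
#' estimate), `k` counts the group hyperparameters (a mean and a variance
#' per free parameter) and `n` is the total number of choice trials. Lower
#' is better. A warning reports the aggregate Monte-Carlo standard error
#' when it is large enough to blur model comparison.
#'
#' @param fit A `flexmb_fit`.
#' @param data The fitted trial-log tibble (or `flexmb_cohort`).
#' @param n_mc Monte-Carlo draws per subject.
#' @param seed Seed for the draws.
#' @return List with `ibic`, `log_evidence` (summed), `se`, `k`,
#'   `n_observations`, and the per-subject evidence tibble.
#' @export
ibic <- function(fit, data, n_mc = 2000L, seed = 1L) {
  if (inherits(data, "flexmb_cohort")) data <- data$data
  ev <- integrated_evidence(data, fit$spec, fit$prior, n_mc = n_mc, seed = seed)
  k <- 2L * length(spec_free_names(fit$spec))
  n_obs <- sum(vapply(split(data, data$subject), n_choice_trials, integer(1)))
  total_se <- sqrt(sum(ev$se^2))
  if (total_se > 1) {
    warning("Monte-Carlo SE of the summed log evidence is ", round(total_se, 2),
            "; consider raising n_mc")
  }
  list(ibic = -2 * sum(ev$log_evidence) + k * log(n_obs),
       log_evidence = sum(ev$log_evidence), se = total_se, k = k,
       n_observations = n_obs, per_subject = ev)
}

#' Exceedance probabilities from random-effects model selection
#'
#' Treats the model identity of each subject as drawn from an unknown
#' population frequency vector with a Dirichlet prior, estimates the
#' Dirichlet posterior by the standard variational scheme from the
#' per-subject log evidences, and reports for each model the posterior
#' probability that its frequency exceeds all others (estimated by
#' sampling the posterior).
#'
#' @param log_evidence Numeric matrix, subjects x models, of per-subject
#'   log model evidence (column names label the models).
#' @param alpha0 Symmetric Dirichlet prior count (default 1).
#' @param n_samples Dirichlet posterior samples for the exceedance
#'   estimate.
#' @param seed Seed for the sampling step.
#' @return Tibble with `model`, `alpha` (posterior Dirichlet counts),
#'   `expected_freq` and `exceedance` (sums to 1 across models).
#' @export
exceedance_probabilities <- function(log_evidence, alpha0 = 1,
                                     n_samples = 100000L, seed = 1L) {
  log_evidence <- as.matrix(log_evidence)
  k <- ncol(log_evidence)
  if (k < 2) stop("need at least 2 models")
  models <- colnames(log_evidence)
  if (is.null(models)) models <- paste0("model", seq_len(k))
  alpha <- rep(alpha0, k)
  for (it in 1:200) {
    lg <- digamma(alpha) - digamma(sum(alpha))
    lu <- sweep(log_evidence, 2, lg, "+")
    u <- exp(lu - apply(lu, 1, max))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < 1e-8) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  set.seed(seed)
  g <- matrix(rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
              n_samples, k)
  winner <- max.col(g, ties.method = "random")
  xp <- tabulate(winner, k) / n_samples
  tibble::tibble(model = models, alpha = alpha,
                 expected_freq = alpha / sum(alpha), exceedance = xp)
}

#' Fit and compare a set of candidate models
#'
#' Fits each candidate with [fit_em()], scores it with [ibic()], and runs
#' random-effects model selection on the per-subject Monte-Carlo
#' evidences.
#'
#' @param data Trial-log tibble or `flexmb_cohort`.
#' @param specs List of [model_spec()]s.
#' @param options A [fit_options()].
#' @param n_mc Monte-Carlo draws per subject for the evidence.
#' @param seed Seed for the evidence draws and exceedance sampling.
#' @return List with `table` (model, n_params, total_nll, ibic,
#'   exceedance) and `fits`.
#' @export
compare_models <- function(data, specs, options = fit_options(),
                           n_mc = 2000L, seed = 1L) {
  if (inherits(data, "flexmb_cohort")) data <- data$data
  fits <- lapply(specs, function(sp) fit_em(data, sp, options))
  scores <- lapply(fits, function(f) ibic(f, data, n_mc = n_mc, seed = seed))
  ev <- do.call(cbind, lapply(scores, function(s) s$per_subject$log_evidence))
  colnames(ev) <- vapply(specs, function(sp) sp$name, character(1))
  xp <- exceedance_probabilities(ev, seed = seed)
  tab <- tibble::tibble(
    model = colnames(ev),
    n_params = vapply(specs, function(sp) length(spec_free_names(sp)), integer(1)),
    total_nll = vapply(fits, function(f) sum(f$subject_nll), numeric(1)),
    ibic = vapply(scores, function(s) s$ibic, numeric(1)),
    exceedance = xp$exceedance
  )
  list(table = dplyr::arrange(tab, .data$ibic), fits = fits, evidence = ev)
}
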