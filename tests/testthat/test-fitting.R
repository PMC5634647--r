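test_that("the choice likelihood has its closed-form values in degenerate cases", {
  cfg <- small_config()
  spec <- model_spec("hybrid_1w")
  set.seed(61)
  ds <- simulate_subject(spec, agent_params(), cfg)
  n_choices <- sum(ds$start_state == "S0")
  # beta = 0: every choice has probability 1/2
  p0 <- agent_params(beta = 0)
  expect_equal(subject_nll(ds, spec, p0), n_choices * log(2), tolerance = 1e-12)
  # a single first-level trial from a fresh symmetric state: p = 1/2
  one <- ds[ds$start_state == "S0", ][1, ]
  expect_equal(subject_nll(one, spec, agent_params(beta = 7)), log(2),
               tolerance = 1e-12)
})

test_that("the likelihood equals the hand replay on the 10-trial fixture", {
  dir <- withr::local_tempdir()
  make_fixtures(dir, seed = 20170928)
  ds <- read_trials(file.path(dir, "nll_fixture.csv"))
  expect_identical(nrow(ds), 10L)
  expected <- read_run_config(file.path(dir, "nll_fixture_expected.yaml"))
  p <- agent_params(wMB = expected$params$wMB, alpha_MF = expected$params$alpha_MF,
                    alpha_MB = expected$params$alpha_MB, beta = expected$params$beta,
                    lam = expected$params$lam, stay_bias = expected$params$stay_bias)
  spec <- model_spec("hybrid_1w")
  # step-by-step trace with the agent-module operations
  state <- init_agent_state()
  nll_trace <- 0
  for (i in seq_len(nrow(ds))) {
    tr <- as.list(ds[i, ])
    if (tr$start_state == "S0" && !is.na(tr$first_choice)) {
      q <- compute_q_values(state, p)
      pr <- action_probabilities(q$Q_hybrid, p, state$prev_first_choice)
      nll_trace <- nll_trace - log(pr[[tr$first_choice]])
    }
    state <- agent_step(state, tr, p)
  }
  expect_equal(subject_nll(ds, spec, p), nll_trace, tolerance = 1e-12)
  expect_equal(subject_nll(ds, spec, p), expected$nll, tolerance = 1e-8)
})

test_that("the EM fixed point matches the conjugate-Gaussian closed form", {
  # toy: each subject contributes a quadratic negative log-likelihood
  # -log N(y_s; x, tau^2); with a Gaussian prior the MAP is the precision-
  # weighted mean, and the EM group mean converges to mean(y)
  set.seed(5)
  y <- c(-1.3, -0.2, 0.4, 1.1, 2.0, 0.7)
  tau2 <- 0.5
  funs <- lapply(y, function(ys) function(x) (x - ys)^2 / (2 * tau2))
  core <- flexmb:::em_core(funs, d = 1L,
                           fit_options(n_restarts = 3, max_iter = 200,
                                       tol = 1e-8, seed = 2))
  expect_true(core$converged)
  mu <- core$mu
  sigma2 <- core$sigma2
  map_closed <- (y / tau2 + mu / sigma2) / (1 / tau2 + 1 / sigma2)
  expect_equal(as.vector(core$map), map_closed, tolerance = 1e-4)
  # EM for the Gaussian-Gaussian hierarchy converges to the sample mean
  expect_equal(unname(mu), mean(y), tolerance = 1e-3)
})

test_that("identical subjects get identical MAP estimates", {
  cfg <- small_config()
  spec <- model_spec("hybrid_1w")
  set.seed(71)
  ds <- simulate_subject(spec, agent_params(), cfg, subject = 1L)
  ds2 <- dplyr::mutate(ds, subject = 2L)
  fit <- fit_em(dplyr::bind_rows(ds, ds2), spec,
                fit_options(n_restarts = 3, max_iter = 6, seed = 3))
  m <- tidyr::pivot_wider(fit$estimates, names_from = "subject",
                          values_from = c("map_transformed", "map_natural"))
  expect_equal(m$map_natural_1, m$map_natural_2, tolerance = 1e-3)
})

test_that("hierarchical EM recovers a point parameter set at moderate scale", {
  spec <- model_spec("hybrid_1w")
  truth <- agent_params(wMB = 0.7, alpha_MF = 0.5, alpha_MB = 0.5,
                        beta = 5, lam = 0.5, stay_bias = 0.2)
  ch <- simulate_cohort(spec, truth, task_config(), n_subjects = 8, seed = 19)
  fit <- fit_em(ch, spec, fit_options(n_restarts = 2, max_iter = 12, seed = 4))
  est <- tidy(fit)
  expect_lt(abs(est$natural_median[est$parameter == "w"] - 0.7), 0.15)
  expect_lt(abs(est$natural_median[est$parameter == "stay"] - 0.2), 0.1)
  expect_gt(est$natural_median[est$parameter == "beta"], 2)
})

test_that("iBIC is exact for a parameter-free model and penalizes hyperparameters", {
  cfg <- small_config()
  spec_fixed <- model_spec("hybrid_1w",
                           fixed = list(w = 0.5, alpha_MF = 0.5, alpha_MB = 0.5,
                                        lam = 0.5, beta = 0, stay = 0))
  expect_length(flexmb:::spec_free_names(spec_fixed), 0)
  ch <- simulate_cohort(model_spec("hybrid_1w"), agent_params(), cfg,
                        n_subjects = 3, seed = 23)
  n_choices <- sum(ch$data$start_state == "S0")
  fake_fit <- list(spec = spec_fixed, prior = list(mu = numeric(0), sigma2 = numeric(0)))
  class(fake_fit) <- "flexmb_fit"
  out <- ibic(fake_fit, ch, n_mc = 10, seed = 1)
  # beta = 0 makes every choice probability 1/2 exactly, and there are no
  # group hyperparameters to penalize
  expect_equal(out$ibic, 2 * n_choices * log(2), tolerance = 1e-10)
  expect_identical(out$k, 0L)
  expect_identical(out$n_observations, n_choices)
})

test_that("Monte-Carlo integrated evidence matches 1-D quadrature on a tiny model", {
  spec <- model_spec("hybrid_1w",
                     fixed = list(w = 0.5, alpha_MF = 0.5, alpha_MB = 0.5,
                                  lam = 0.5, stay = 0.2))
  cfg <- task_config(n_trials = 5, block_length = 5,
                     block_change_ranges = list(c(3, 6)),
                     reward_flip_period = 4)
  set.seed(3)
  ds <- simulate_subject(model_spec("hybrid_1w"), agent_params(), cfg)
  prior <- list(mu = c(beta = 0.3), sigma2 = c(beta = 1))
  ev <- integrated_evidence(ds, spec, prior, n_mc = 4000, seed = 9)
  nf <- flexmb:::make_subject_nll_fun(flexmb:::encode_dataset(ds, spec), spec)
  f <- Vectorize(function(x) exp(-nf(x)) * dnorm(x, 0.3, 1))
  log_quad <- log(integrate(f, -8, 8)$value)
  expect_lt(abs(ev$log_evidence - log_quad), 3 * ev$se)
})

test_that("exceedance probabilities respect symmetry, dominance, and the sampling oracle", {
  # identical evidences: exact symmetry
  L <- matrix(0, 6, 2, dimnames = list(NULL, c("a", "b")))
  xp <- exceedance_probabilities(L, n_samples = 200000, seed = 2)
  expect_equal(xp$exceedance, c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(xp$exceedance), 1)
  # one model better by e^10 for every subject: near-certain winner
  L2 <- cbind(a = rep(10, 6), b = rep(0, 6))
  xp2 <- exceedance_probabilities(L2, seed = 3)
  expect_gt(xp2$exceedance[1], 0.99)
  # 3-model toy: independent brute-force sampling over the Dirichlet posterior
  set.seed(7)
  L3 <- matrix(rnorm(30, sd = 1.5), 10, 3,
               dimnames = list(NULL, paste0("m", 1:3)))
  L3[, 1] <- L3[, 1] + 1
  xp3 <- exceedance_probabilities(L3, n_samples = 200000, seed = 11)
  al <- xp3$alpha
  set.seed(99) # oracle: fresh gamma draws, coded independently
  gd <- vapply(al, function(a) rgamma(200000, a), numeric(200000))
  rd <- gd / rowSums(gd)
  oracle <- tabulate(apply(rd, 1, which.max), 3) / nrow(rd)
  expect_lt(max(abs(xp3$exceedance - oracle)), 0.02)
  expect_error(exceedance_probabilities(L3[, 1, drop = FALSE]), "2 models")
})

test_that("simulated pure-MF data is not attributed to the pure-MB model (and vice versa)", {
  cfg <- task_config()
  opts <- fit_options(n_restarts = 2, max_iter = 6, seed = 5)
  specs <- list(model_spec("pure_MF"), model_spec("pure_MB"))
  ch_mf <- simulate_cohort(model_spec("pure_MF"), agent_params(wMB = 0),
                           cfg, n_subjects = 6, seed = 81)
  cmp_mf <- compare_models(ch_mf, specs, opts, n_mc = 300, seed = 6)
  expect_identical(cmp_mf$table$model[1], "pure_MF")
  ch_mb <- simulate_cohort(model_spec("pure_MB"), agent_params(wMB = 1),
                           cfg, n_subjects = 6, seed = 82)
  cmp_mb <- compare_models(ch_mb, specs, opts, n_mc = 300, seed = 6)
  expect_identical(cmp_mb$table$model[1], "pure_MB")
})
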