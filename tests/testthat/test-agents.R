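test_that("model-free delta-rule updates match hand evaluation", {
  p <- agent_params(alpha_MF = 0.5, lam = 0.5)
  st <- init_agent_state()
  tr <- list(start_state = "S1", first_choice = NA_character_,
             second_state = "S1", terminal_state = "S3", reward = 1)
  st2 <- mf_update(st, tr, p)
  expect_equal(unname(st2$Q_MF["S1"]), 0.75) # 0.5 + 0.5 * (1 - 0.5)
  expect_equal(unname(st2$Q_MF["S2"]), 0.25) # mirrored
  expect_equal(unname(st2$Q_MF[c("A1", "A2")]), c(0.5, 0.5)) # untouched

  # without fictive updates, zero prediction error is a fixed point
  st0 <- init_agent_state()
  st0$Q_MF[] <- 0
  tr0 <- list(start_state = "S1", first_choice = NA_character_,
              second_state = "S1", terminal_state = "S3", reward = 0)
  expect_identical(mf_update(st0, tr0, p, fictive = FALSE)$Q_MF, st0$Q_MF)
})

test_that("the eligibility trace carries terminal reward to first-level actions", {
  # lam = 1: first-level action credited directly with the terminal reward
  p <- agent_params(alpha_MF = 0.5, lam = 1)
  st <- init_agent_state()
  st$Q_MF[] <- 0
  tr <- list(start_state = "S0", first_choice = "A1",
             second_state = "S1", terminal_state = "S3", reward = 1)
  st2 <- mf_update(st, tr, p)
  # delta1 = Q(S1) - Q(A1) = 0; delta2 = 1; dQ(A1) = alpha*(0 + lam*1)
  expect_equal(unname(st2$Q_MF["A1"]), 0.5)
  # lam = 0: first level moves only toward second-level values
  p0 <- agent_params(alpha_MF = 0.5, lam = 0)
  st3 <- init_agent_state()
  st3$Q_MF["S1"] <- 0.9
  st3$Q_MF["A1"] <- 0.1
  st4 <- mf_update(st3, tr, p0)
  expect_equal(unname(st4$Q_MF["A1"]), 0.1 + 0.5 * (0.9 - 0.1))
})

test_that("model-based observation rewrites transitions and updates rewards", {
  p <- agent_params(alpha_MB = 1)
  st <- init_agent_state()
  tr <- list(second_state = "S1", terminal_state = "S4", reward = 0.9)
  st2 <- mb_observe(st, tr, p)
  # observing S1 -> S4 implies mapping B: P(S1->S4) = P(S2->S3) = 1
  expect_equal(unname(st2$P_T["p13"]), 0)
  expect_equal(unname(st2$P_T["p24"]), 0)
  expect_equal(unname(st2$R["S4"]), 0.9) # full-rate update
  expect_equal(unname(st2$R["S3"]), 0.1) # mirrored

  # partial transition learning
  p2 <- agent_params(alpha_MB_transition = 0.5)
  st3 <- mb_observe(init_agent_state(), tr, p2)
  expect_equal(unname(st3$P_T["p13"]), 0.5)
})

test_that("mirror updates set the paired entry to one minus the visited value", {
  st <- init_agent_state()
  st$Q_MF["S1"] <- 0.75
  expect_equal(unname(mirror_update(st, "Q_MF", "S1")$Q_MF["S2"]), 0.25)
  st$R["S4"] <- 0.9
  expect_equal(unname(mirror_update(st, "R", "S4")$R["S3"]), 0.1)
  st$Q_MF["S2"] <- 0.5
  expect_equal(unname(mirror_update(st, "Q_MF", "S2")$Q_MF["S1"]), 0.5)
})

test_that("hybrid action values are the weighted mixture of the two systems", {
  st <- init_agent_state()
  st$R["S3"] <- 0.8
  st$R["S4"] <- 0.2
  q <- compute_q_values(st, agent_params(wMB = 1))
  expect_equal(unname(q$Q_MB["A1"]), 0.8) # P(S1->S3) = 1 degenerate expectation
  expect_equal(q$Q_hybrid, q$Q_MB)
  q0 <- compute_q_values(st, agent_params(wMB = 0))
  expect_equal(q0$Q_hybrid, q0$Q_MF)
  st$Q_MF["A1"] <- 0.4
  qh <- compute_q_values(st, agent_params(wMB = 0.5))
  expect_equal(unname(qh$Q_hybrid["A1"]), 0.5 * 0.8 + 0.5 * 0.4)
})

test_that("softmax probabilities are symmetric, flat at beta 0, and exact at ln 3", {
  p <- agent_params(beta = 5, stay_bias = 0)
  expect_equal(unname(action_probabilities(c(A1 = 0.4, A2 = 0.4), p)),
               c(0.5, 0.5))
  p0 <- agent_params(beta = 0)
  expect_equal(unname(action_probabilities(c(A1 = 3, A2 = -1), p0, "A2")),
               c(0.5, 0.5))
  p3 <- agent_params(beta = log(3), stay_bias = 0)
  pr <- action_probabilities(c(A1 = 1, A2 = 0), p3)
  expect_equal(unname(pr), c(0.75, 0.25))
  expect_equal(sum(pr), 1)
  expect_error(action_probabilities(c(A1 = NaN, A2 = 0), p), "finite")
  # stay bias shifts preference toward the previous action
  pb <- agent_params(beta = 2, stay_bias = 0.3)
  expect_gt(action_probabilities(c(A1 = 0.5, A2 = 0.5), pb, "A1")[["A1"]], 0.5)
})

test_that("values stay in [0,1] and transition rows stay stochastic under random experience", {
  set.seed(99)
  p <- agent_params(alpha_MF = 0.7, alpha_MB = 0.9, lam = 0.8)
  st <- init_agent_state()
  for (i in 1:500) {
    s0 <- sample(c(TRUE, FALSE), 1)
    ch <- if (s0) sample(c("A1", "A2"), 1) else NA_character_
    s2 <- if (s0) c(A1 = "S1", A2 = "S2")[[ch]] else sample(c("S1", "S2"), 1)
    cont <- sample(0:1, 1)
    term <- if (cont == 0) c(S1 = "S3", S2 = "S4")[[s2]] else c(S1 = "S4", S2 = "S3")[[s2]]
    tr <- list(start_state = if (s0) "S0" else s2, first_choice = ch,
               second_state = s2, terminal_state = term, reward = runif(1))
    st <- agent_step(st, tr, p)
    expect_true(all(st$Q_MF >= 0 & st$Q_MF <= 1))
    expect_true(all(st$R >= 0 & st$R <= 1))
    expect_true(all(st$P_T >= 0 & st$P_T <= 1))
  }
})

test_that("compiled likelihood equals the step-by-step replay across model families", {
  cfg <- small_config()
  cases <- list(
    list(model_spec("hybrid_1w"), agent_params(wMB = 0.56)),
    list(model_spec("pure_MF"), agent_params(wMB = 0)),
    list(model_spec("pure_MB"), agent_params(wMB = 1)),
    list(model_spec("hybrid_3block"), agent_params(wMB = c(0.2, 0.5, 0.8)))
  )
  for (i in seq_along(cases)) {
    spec <- cases[[i]][[1]]
    p <- cases[[i]][[2]]
    set.seed(100 + i)
    ds <- simulate_subject(spec, p, cfg)
    expect_equal(subject_nll(ds, spec, p), replay_nll(ds, p), tolerance = 1e-12)
  }
})

test_that("a hybrid agent at the weight endpoints reproduces the pure agents exactly", {
  cfg <- small_config()
  set.seed(55)
  mb <- simulate_subject(model_spec("pure_MB"), agent_params(wMB = 1), cfg)
  set.seed(55)
  hy <- simulate_subject(model_spec("hybrid_1w"), agent_params(wMB = 1), cfg)
  expect_identical(mb$first_choice, hy$first_choice)
  expect_identical(mb$reward, hy$reward)
  set.seed(56)
  mf <- simulate_subject(model_spec("pure_MF"), agent_params(wMB = 0), cfg)
  set.seed(56)
  hy0 <- simulate_subject(model_spec("hybrid_1w"), agent_params(wMB = 0), cfg)
  expect_identical(mf$first_choice, hy0$first_choice)
})

test_that("control hybrids collapse to the matching single system at the weight endpoints", {
  cfg <- small_config()
  set.seed(77)
  ds <- simulate_subject(model_spec("hybrid_1w"), agent_params(), cfg)
  # MF+MF control with full weight on the alpha = 0.25 system
  ctrl <- model_spec("hybrid_1w", control = "mf_mf")
  nll_ctrl <- subject_nll(ds, ctrl, list(w = 1, lam = 0.5, beta = 4, stay = 0.1))
  pure <- model_spec("pure_MF")
  nll_pure <- subject_nll(ds, pure,
                          list(alpha_MF = 0.25, lam = 0.5, beta = 4, stay = 0.1))
  expect_equal(nll_ctrl, nll_pure, tolerance = 1e-12)
})
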