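test_that("stay probabilities on the 6-trial fixture match exhaustive enumeration", {
  ds <- flexmb:::stay_fixture()
  # enumeration by hand:
  # main variant: only trial 5 is eligible (starts S0, trial 4 started S2).
  #   trial 4 paid 0.85 (high) and its transition had changed -> cell
  #   (high, changed); choice A1 does not return to S2 -> no stay.
  main <- stay_probabilities(ds, "second_level_start")
  cell <- function(tb, r, cc) tb[tb$reward_cond == r & tb$conting_cond == cc, ]
  expect_equal(cell(main, "high", "changed")$stay_prob, 0)
  expect_identical(cell(main, "high", "changed")$n_trials, 1L)
  expect_identical(cell(main, "high", "fixed")$n_trials, 0L)
  expect_true(is.na(cell(main, "high", "fixed")$stay_prob))
  expect_identical(cell(main, "low", "changed")$n_trials, 0L)
  expect_identical(cell(main, "low", "fixed")$n_trials, 0L)
  # first-level variant: trials 3 and 6 are eligible.
  #   trial 3 after trial 2 (paid 0.8 high, fixed): A2 leaves S1 -> no stay.
  #   trial 6 after trial 5 (paid 0.1 low, fixed): A1 returns to S1 -> stay.
  fl <- stay_probabilities(ds, "first_level_start")
  expect_equal(cell(fl, "high", "fixed")$stay_prob, 0)
  expect_identical(cell(fl, "high", "fixed")$n_trials, 1L)
  expect_equal(cell(fl, "low", "fixed")$stay_prob, 1)
  expect_identical(cell(fl, "low", "fixed")$n_trials, 1L)
  expect_identical(cell(fl, "high", "changed")$n_trials, 0L)
})

test_that("a perseverating chooser has stay probability one in every defined cell", {
  ds <- perseverating_log(12)
  tb <- stay_probabilities(ds, "second_level_start")
  defined <- tb[tb$n_trials > 0, ]
  expect_gt(nrow(defined), 0)
  expect_true(all(defined$stay_prob == 1))
})

test_that("the condition ANOVA matches a textbook sum-of-squares computation", {
  set.seed(17)
  tb <- tidyr::expand_grid(subject = 1:8, reward_cond = c("high", "low"),
                           conting_cond = c("changed", "fixed")) |>
    dplyr::mutate(stay_prob = plogis(rnorm(dplyr::n()) +
                                       (reward_cond == "high") * 1.2 +
                                       (conting_cond == "fixed") * 0.4),
                  n_trials = 10L)
  out <- condition_anova(tb)
  # from-scratch two-way between-subjects ANOVA oracle
  y <- tb$stay_prob
  A <- tb$reward_cond
  B <- tb$conting_cond
  gm <- mean(y)
  ssa <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, list(A, B), mean)
  n_cell <- length(y) / 4
  ssab <- n_cell * sum((cellm - outer(tapply(y, A, mean), tapply(y, B, mean), "+") + gm)^2)
  sse <- sum((y - ave(y, A, B))^2)
  dfe <- length(y) - 4
  f_oracle <- c(reward = (ssa / 1) / (sse / dfe),
                contingency = (ssb / 1) / (sse / dfe),
                interaction = (ssab / 1) / (sse / dfe))
  expect_equal(out$statistic[out$term == "reward"], f_oracle[["reward"]])
  expect_equal(out$statistic[out$term == "contingency"], f_oracle[["contingency"]])
  expect_equal(out$statistic[out$term == "reward:contingency"],
               f_oracle[["interaction"]])
  expect_equal(unique(out$df_residual), dfe)
  # at N = 16 subjects the error df is 60, giving the reference F(1,60) layout
  tb16 <- tidyr::expand_grid(subject = 1:16, reward_cond = c("high", "low"),
                             conting_cond = c("changed", "fixed")) |>
    dplyr::mutate(stay_prob = runif(dplyr::n()), n_trials = 10L)
  expect_equal(unique(condition_anova(tb16)$df_residual), 60)
})

test_that("condition effects vanish when every subject's cells are equal", {
  tb <- tidyr::expand_grid(subject = 1:6, reward_cond = c("high", "low"),
                           conting_cond = c("changed", "fixed")) |>
    dplyr::mutate(stay_prob = 0.4 + 0.02 * subject, n_trials = 10L)
  out <- condition_anova(tb)
  expect_true(all(out$statistic < 1e-20))
})

test_that("the repeated-measures variant partitions subject variance", {
  set.seed(18)
  tb <- tidyr::expand_grid(subject = 1:8, reward_cond = c("high", "low"),
                           conting_cond = c("changed", "fixed")) |>
    dplyr::mutate(stay_prob = plogis(rnorm(dplyr::n(), sd = 0.3) +
                                       (reward_cond == "high") * 2),
                  n_trials = 10L)
  out <- condition_anova(tb, design = "within")
  expect_setequal(out$term, c("reward", "contingency", "reward:contingency"))
  # each within-subject stratum has N - 1 = 7 error df
  expect_equal(unique(out$df_residual), 7)
  expect_lt(out$p.value[out$term == "reward"], 0.001)
})

test_that("subjects with undefined cells are excluded with a message", {
  tb <- tidyr::expand_grid(subject = 1:3, reward_cond = c("high", "low"),
                           conting_cond = c("changed", "fixed")) |>
    dplyr::mutate(stay_prob = runif(dplyr::n()), n_trials = 10L)
  tb$stay_prob[1] <- NA
  tb$n_trials[1] <- 0L
  expect_message(out <- condition_anova(tb), "excluding 1")
  expect_identical(attr(out, "n_subjects"), 2L)
})

test_that("a uniform random policy earns the high reward half the time", {
  cfg <- small_config(300, 100)
  ch <- simulate_cohort(model_spec("hybrid_1w"), agent_params(beta = 0),
                        cfg, n_subjects = 8, seed = 21)
  ps <- performance_summaries(ch$data)
  expect_lt(abs(mean(ps$high_choice_prob) - 0.5), 0.04)
  expect_lt(abs(mean(ps$reward_rate) - 0.5), 0.04)
})

test_that("model-free and model-based cohorts separate in the stay-probability pattern", {
  cfg <- task_config()
  cells <- function(spec, p, seed) {
    ch <- simulate_cohort(spec, p, cfg, n_subjects = 100, seed = seed)
    stay_probabilities(ch$data) |>
      dplyr::group_by(reward_cond, conting_cond) |>
      dplyr::summarise(m = mean(stay_prob, na.rm = TRUE), .groups = "drop")
  }
  mf <- cells(model_spec("pure_MF"), agent_params(wMB = 0), 41)
  mb <- cells(model_spec("pure_MB"), agent_params(wMB = 1), 42)
  pick <- function(tb, r, cc) tb$m[tb$reward_cond == r & tb$conting_cond == cc]
  # MF is flexible only when it experienced the first-level action: stays
  # more after fixed than changed high-reward trials, and vice versa for low
  expect_gt(pick(mf, "high", "fixed"), pick(mf, "high", "changed"))
  expect_gt(pick(mf, "low", "changed"), pick(mf, "low", "fixed"))
  # MB adapts immediately: large reward effect in both contingency conditions
  expect_gt(pick(mb, "high", "fixed") - pick(mb, "low", "fixed"), 0.4)
  expect_gt(pick(mb, "high", "changed") - pick(mb, "low", "changed"), 0.4)
})
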