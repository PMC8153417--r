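g <- default_graph

# a minimal hand-built log: S1 -L-> S2 -L-> O1 (red, 40)
toy_log <- function(a1, rewards, goal = "red", uncertainty = "low",
                    session = 1) {
  n <- length(a1)
  data.frame(subject_id = "s1", session = session, trial = seq_len(n),
             is_pretraining = FALSE, goal = goal, uncertainty = uncertainty,
             s1 = "S1", a1 = a1, s2 = "S2", a2 = "L", s_outcome = "O1",
             reward = rewards, stringsAsFactors = FALSE)
}

test_that("accumulated reward sums main-session rewards only", {
  log1 <- toy_log(c("L", "L", "R"), c(40, 0, 10))
  expect_equal(accumulated_reward(log1), 50)
  log1$reward <- 0
  expect_equal(accumulated_reward(log1), 0)
  pre <- toy_log("L", 40); pre$is_pretraining <- TRUE; pre$session <- 0
  expect_equal(accumulated_reward(rbind(pre, log1)), 0)
  expect_error(accumulated_reward(log1[0, ]), "empty")
})

test_that("accumulated reward is consistent with goal_reward of outcomes", {
  sim <- simulate_subject(t3_par(), config = task_config(
    n_pretraining = 10, n_sessions = 1, session_trials = 30), seed = 21)
  main <- sim$trials[!sim$trials$is_pretraining, ]
  recomputed <- sum(mapply(function(s, goal) goal_reward(s, goal, g),
                           main$s_outcome, main$goal))
  expect_equal(accumulated_reward(sim$trials), recomputed)
})

test_that("ideal agent is greedy with uniform tie-splitting", {
  # low uncertainty, specific red goal: unique greedy actions exist
  pol <- ideal_policy(g, 2L, "red", "low")
  expect_equal(sum(pol), 1)
  expect_true(any(pol == 1))  # unique greedy action at S2 under red goal
  # high uncertainty at second stage: both actions reach the same outcome
  # pair, so the ideal agent is indifferent
  expect_equal(ideal_policy(g, 2L, "flexible", "high"), c(0.5, 0.5))
})

test_that("choice optimality scores matches against the ideal agent", {
  # always the unique greedy action -> 1; toy log: red goal, low
  # uncertainty, S1-L and S2-L are the greedy moves (red coin at O1)
  log_good <- toy_log(rep("L", 4), rep(40, 4))
  co <- choice_optimality(log_good, g)
  expect_equal(co$overall, 1)
  # 3 greedy of 4 tie-free first-stage decisions, second stage all greedy
  log_mixed <- toy_log(c("L", "L", "L", "R"), rep(40, 4))
  co2 <- choice_optimality(log_mixed, g)
  expect_equal(mean(co2$per_decision[, 1]), 0.75)
  # ties everywhere (high uncertainty) pin optimality at 0.5
  log_tie <- toy_log(c("L", "R", "L", "R"), rep(40, 4),
                     goal = "flexible", uncertainty = "high")
  log_tie$s2 <- "S4"; log_tie$s_outcome <- "O5"; log_tie$reward <- 0
  expect_equal(choice_optimality(log_tie, g)$overall, 0.5)
})

test_that("choice consistency counts first-stage repeats within sessions", {
  expect_equal(choice_consistency(toy_log(c("L", "L", "R", "R"),
                                          rep(0, 4)))$overall, 2 / 3)
  expect_equal(choice_consistency(toy_log(rep("L", 5), rep(0, 5)))$overall, 1)
  expect_equal(choice_consistency(toy_log(c("L", "R", "L", "R"),
                                          rep(0, 4)))$overall, 0)
  # no carry-over across sessions: two one-trial... two sessions whose
  # boundary transition (R -> L) must not be counted
  two <- rbind(toy_log(c("L", "R"), c(0, 0), session = 1),
               toy_log(c("L", "L"), c(0, 0), session = 2))
  expect_equal(choice_consistency(two)$overall, 0.5)
  expect_error(choice_consistency(toy_log("L", 0)), "at least 2")
})

test_that("calibration bins recover the behaviour of simple agents", {
  # all probabilities 0.5: a single occupied bin near 0.5
  set.seed(31)
  p <- rep(0.5, 400)
  choice <- runif(400) < p
  cal <- calibration_curve(p, choice, n_bins = 10)
  occ <- cal[cal$n > 0, ]
  expect_equal(nrow(occ), 1L)
  expect_lt(abs(occ$prop_right - 0.5), 3 * sqrt(0.25 / 400))
  # deterministic agent: top bin only, proportion 1
  cal2 <- calibration_curve(rep(1, 50), rep(1, 50), n_bins = 5)
  expect_equal(cal2$prop_right[5], 1)
  expect_true(all(cal2$n[1:4] == 0))
  expect_error(calibration_curve(0.5, 1, n_bins = 1), "n_bins")
  expect_error(calibration_curve(1.5, 1), "0, 1")
})

test_that("condition breakdown reproduces brute-force F statistics", {
  # identical values in all cells: all F ~ 0 (NaN-free via tiny noise-free
  # zero SS -> F = 0/0 handled by aov as NaN; use exact-zero contrast case)
  set.seed(41)
  gc <- rep(c("flexible", "specific"), each = 20)
  un <- rep(rep(c("low", "high"), each = 10), 2)
  v_goal <- ifelse(gc == "flexible", 1, 0)
  bd <- condition_breakdown(v_goal + rnorm(40, 0, 1e-8), gc, un)
  expect_gt(bd$anova$F[bd$anova$term == "goal_class"], 1e6)
  expect_lt(bd$anova$F[bd$anova$term == "goal_class:uncertainty"], 10)
  # random balanced data matches the sums-of-squares oracle
  v <- rnorm(40)
  bd2 <- condition_breakdown(v, gc, un)
  oracle <- anova_ss_oracle(v, gc, un)
  expect_equal(bd2$anova$F, oracle$F, tolerance = 1e-8)
  expect_error(condition_breakdown(v[1:20], gc[1:20], rep("low", 20)),
               "occupied")
})

test_that("score correlations behave and match a hand-computed Spearman", {
  x <- c(3, 1, 4, 1.5, 5)
  expect_equal(correlate_with_score(x, x, "pearson")$estimate, 1)
  # monotone transform leaves Spearman unchanged
  y <- c(10, 2, 30, 4, 50)
  expect_equal(correlate_with_score(x, y, "spearman")$estimate,
               correlate_with_score(exp(x), y^3, "spearman")$estimate)
  # hand computation: ranks of x = (3,1,4,2,5), y = (3,1,4,2,5) -> rho = 1;
  # perturbed pair swaps two ranks: rho = 1 - 6*sum(d^2)/(n(n^2-1)) = 0.9
  y2 <- c(10, 2, 4, 3, 50)  # ranks 4,1,3,2,5 vs x ranks 3,1,4,2,5
  expect_equal(correlate_with_score(x, y2, "spearman")$estimate,
               1 - 6 * 2 / (5 * 24))
  expect_error(correlate_with_score(rep(1, 5), y, "pearson"), "variance")
  expect_error(correlate_with_score(x[1:3], y[1:3]), "at least 4")
})
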