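small_cfg <- task_config(n_pretraining = 20, n_sessions = 1,
                         session_trials = 40)

test_that("cohort sampling is deterministic and respects the effect links", {
  spec <- cohort_spec(n_subjects = 30, seed = 9)
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(c1, c2)
  expect_true(all(c1$ces_d >= 0 & c1$ces_d <= 60))
  ms <- model_spec("Arb_a_t3")
  for (p in ms$params)
    expect_true(all(c1[[p]] > 0 & c1[[p]] <= ms$upper[p]))
  # zero-noise links make eta a deterministic increasing (and tau_mb a
  # decreasing) function of CES-D: rank correlations +-1
  spec0 <- cohort_spec(n_subjects = 25, seed = 10,
                       eta_link = list(intercept = qlogis(0.2), slope = 0.06,
                                       center = 20, noise_sd = 0),
                       tau_mb_link = list(intercept = log(0.2),
                                          slope = -0.03, center = 20,
                                          noise_sd = 0))
  c0 <- sample_cohort(spec0)
  expect_equal(cor(c0$eta, c0$ces_d, method = "spearman"), 1)
  expect_equal(cor(c0$tau_mb, c0$ces_d, method = "spearman"), -1)
})

test_that("null effect links leave parameters unrelated to CES-D", {
  spec <- cohort_spec(n_subjects = 200, seed = 12,
                      eta_link = list(intercept = qlogis(0.2), slope = 0,
                                      center = 20, noise_sd = 0.3),
                      tau_mb_link = list(intercept = log(0.2), slope = 0,
                                         center = 20, noise_sd = 0.25))
  c0 <- sample_cohort(spec)
  expect_lt(abs(cor(c0$eta, c0$ces_d, method = "spearman")), 0.15)
  expect_lt(abs(cor(c0$tau_mb, c0$ces_d, method = "spearman")), 0.15)
})

test_that("simulated subjects emit structurally valid full-length logs", {
  sim <- simulate_subject(t3_par(), seed = 51)
  expect_equal(sum(sim$trials$is_pretraining), 100L)
  main <- sum(!sim$trials$is_pretraining)
  expect_gte(main, 320); expect_lte(main, 350)
  # every logged transition is consistent with the successor map
  expect_silent({
    p <- tempfile(fileext = ".csv")
    write_trial_log(sim$trials, p)
    read_trial_log(p, default_graph)
  })
  # pre-training is reward-free
  expect_true(all(sim$trials$reward[sim$trials$is_pretraining] == 0))
  # same seed reproduces the log; different seeds differ in choices
  sim2 <- simulate_subject(t3_par(), seed = 51)
  expect_identical(sim$trials, sim2$trials)
  sim3 <- simulate_subject(t3_par(), seed = 52)
  expect_false(identical(sim3$trials$a1, sim$trials$a1))
})

test_that("higher reliability learning rates destabilize chi_MF", {
  # the mechanism linking depression to arbitration: a larger eta makes
  # the MF reliability track each RPE, raising its trial-to-trial variance
  var_chi <- function(eta, seed) {
    par <- t3_par(eta = eta)
    sim <- simulate_subject(par, config = small_cfg, seed = seed)
    stats::var(diff(sim$latents$chi_mf[!sim$trials$is_pretraining]))
  }
  lows <- sapply(1:8, function(s) var_chi(0.05, seed = 700 + s))
  highs <- sapply(1:8, function(s) var_chi(0.7, seed = 700 + s))
  expect_true(all(highs > lows))
})

test_that("pure-MB agents beat pure-MF agents on choice optimality", {
  # specific-goal, low-uncertainty blocks; >= 50 paired seeded runs
  opt_in_cell <- function(par, p_mb_init, seed) {
    g <- default_graph
    ctl <- arb_control(g, p_mb_init = p_mb_init)
    sim <- simulate_subject(par, config = small_cfg, seed = seed,
                            control = ctl, graph = g)
    co <- choice_optimality(sim$trials, g)$by_condition
    co$optimality[co$goal_class == "specific" & co$uncertainty == "low"]
  }
  mb_par <- c(alpha_mb = 0.9, alpha_mf = 0.1, eta = 0.1, A_beta = 0,
              A_gamma = 0, tau_mb = 5, tau_mf = 5)
  mf_par <- c(alpha_mb = 0.9, alpha_mf = 0.5, eta = 0.1, A_beta = 0,
              A_gamma = 0, tau_mb = 5, tau_mf = 5)
  diffs <- sapply(1:15, function(s)
    opt_in_cell(mb_par, 1, 900 + s) - opt_in_cell(mf_par, 0, 900 + s))
  expect_gt(mean(diffs), 0.1)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("habitual agents repeat choices more than chance", {
  # high tau_MF, P_MB ~ 0: once a habit forms, first-stage choices repeat
  hab_par <- c(alpha_mb = 0.5, alpha_mf = 0.7, eta = 0.1, A_beta = 0,
               A_gamma = 0, tau_mb = 0, tau_mf = 2)
  g <- default_graph
  ctl0 <- arb_control(g, p_mb_init = 0)
  cons <- sapply(1:20, function(s) {
    sim <- simulate_subject(hab_par, config = small_cfg, seed = 400 + s,
                            control = ctl0, graph = g)
    choice_consistency(sim$trials)$overall
  })
  expect_gt(mean(cons), 0.6)  # a random agent sits at 0.5
})
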