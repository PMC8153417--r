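ctl <- arb_control(default_graph)

test_that("model-based reliability matches the conjugate closed forms", {
  # empty history, symmetric prior: chi0 = chi1 = 6, chi_MB = 0.5
  expect_equal(mb_reliability(numeric(0), ctl), 0.5)
  # four zero-SPE events: posteriors (5,1) and (1,5), chi = 42 / (42 + 8.4)
  expect_equal(mb_reliability(rep(0, 4), ctl), 42 / 50.4, tolerance = 1e-9)
  # swapping zero for non-zero events reflects chi about 0.5
  h <- c(0, 0, 0, 0.9, 0.9)
  h_swapped <- c(0.9, 0.9, 0.9, 0, 0)
  expect_equal(mb_reliability(h, ctl), 1 - mb_reliability(h_swapped, ctl),
               tolerance = 1e-12)
})

test_that("model-based reliability matches numerical posterior moments", {
  for (case in list(c(0, 0), c(4, 0), c(3, 7), c(15, 5), c(0, 20))) {
    h <- c(rep(0, case[1]), rep(0.9, case[2]))
    expect_equal(mb_reliability(h, ctl),
                 chi_numeric_oracle(case[1], case[2]), tolerance = 1e-6)
  }
})

test_that("Pearce-Hall reliability tracks the unsigned RPE", {
  # Omega 10, |RPE| 30, eta 0.5 -> Omega 20, chi_MF 0.5 at RPE_max 40
  u <- mf_reliability_update(10, 30, 0.5, ctl)
  expect_equal(u$omega, 20)
  expect_equal(u$chi_mf, 0.5)
  # eta = 1 overwrites Omega with |RPE|
  expect_equal(mf_reliability_update(10, 7, 1, ctl)$omega, 7)
  # perfect prediction forever keeps chi_MF at 1
  o <- 0
  for (i in 1:5) o <- mf_reliability_update(o, 0, 0.3, ctl)$omega
  expect_equal(mf_reliability_update(o, 0, 0.3, ctl)$chi_mf, 1)
  expect_error(mf_reliability_update(10, 5, 1.2, ctl), "eta")
})

test_that("transition rates are sigmoidal and decreasing in reliability", {
  r <- transition_rates(0.5, 0.5, 1, 1, B = 10)
  expect_equal(r$beta, 1 / (1 + exp(5)), tolerance = 1e-9)
  expect_equal(r$beta, r$gamma)
  # B = 0 flattens the rate at half the amplitude
  expect_equal(transition_rates(0.9, 0.1, 2, 2, B = 0)$beta, 1)
  # monotone decreasing in the reliability argument
  b <- sapply(seq(0, 1, 0.1), function(x)
    transition_rates(x, 0.5, 1, 1)$beta)
  expect_true(all(diff(b) < 0))
  expect_error(transition_rates(0.5, 0.5, -1, 1), "amplitudes")
})

test_that("model choice probability follows the two-state dynamics", {
  # analytic fixed point beta / (beta + gamma)
  p <- 0.9
  for (i in 1:300) p <- update_model_choice_prob(p, 0.2, 0.3)
  expect_equal(p, 0.4, tolerance = 1e-9)
  expect_equal(update_model_choice_prob(0.5, 0.1, 0.1), 0.5)
  expect_equal(update_model_choice_prob(0, 1, 0), 1)
  # stays in [0, 1] over a long random-rate trajectory
  set.seed(303)
  p <- 0.5
  for (i in 1:10000) {
    p <- update_model_choice_prob(p, runif(1, 0, 2.5), runif(1, 0, 2.5))
    if (p < 0 || p > 1) break
  }
  expect_gte(p, 0); expect_lte(p, 1)
})

test_that("value integration is the P_MB-weighted mixture", {
  expect_equal(integrate_values(c(10, 5), c(2, 1), 1), c(10, 5))
  expect_equal(integrate_values(c(10, 5), c(2, 1), 0), c(2, 1))
  expect_equal(integrate_values(10, 2, 0.25), 4)
  expect_error(integrate_values(c(1, 2), 1, 0.5), "same")
})

test_that("exploitation variants implement their stated forms", {
  w <- exploitation_spec("weighted", tau_mb = 3, tau_mf = 1)
  expect_equal(dynamic_exploitation(1, w), 3)
  expect_equal(dynamic_exploitation(0, w), 1)
  expect_equal(dynamic_exploitation(0.25, w), 0.25 * 3 + 0.75 * 1)
  # tau_mb = tau_mf reduces to the fixed-tau model for all P_MB
  w0 <- exploitation_spec("weighted", tau_mb = 2, tau_mf = 2)
  for (p in seq(0, 1, 0.2))
    expect_equal(dynamic_exploitation(p, w0), 2)
  lg <- exploitation_spec("logistic", c1 = 1, c2 = 5, c3 = 4, c4 = 0.5)
  expect_equal(dynamic_exploitation(0.5, lg), 1 + (5 - 1) / 2)
  expect_error(exploitation_spec("logistic", c1 = 5, c2 = 1, c3 = 4,
                                 c4 = 0.5), "c2 >= c1")
  ln <- exploitation_spec("linear", c = 4)
  expect_equal(dynamic_exploitation(0.25, ln), 1)
})

test_that("softmax policy is stable, normalized, and has the right limits", {
  expect_equal(softmax_policy(c(3, 3), 0), c(0.5, 0.5))
  p <- softmax_policy(c(1, 0), 1)
  expect_equal(p, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(sum(softmax_policy(c(1000, 999), 5)), 1)  # no overflow
  expect_gt(softmax_policy(c(10, 0), 50)[1], 1 - 1e-12)
  expect_error(softmax_policy(c(NaN, 1), 1), "non-finite")
  expect_error(softmax_policy(c(1, 0), -1), "tau")
})

test_that("agent trials are deterministic and structurally complete", {
  g <- default_graph
  ex <- expand_params("Arb_a_t3", t3_par())
  run <- function() {
    set.seed(77)
    agent <- init_agent_state(g, ctl)
    out <- list()
    for (t in 1:10)
      out[[t]] <- {
        res <- agent_trial(agent, g, ex, goal = "red", uncertainty = "low",
                           control = ctl)
        agent <<- res$agent
        res
      }
    out
  }
  a <- run(); b <- run()
  expect_identical(a, b)
  last <- a[[10]]
  expect_length(last$latents$spe, 2)     # two SPE events per trial
  expect_length(last$latents$rpe, 2)     # two RPE events per trial
  expect_length(last$latents$p_chosen, 2)  # two decisions per trial
  expect_true(all(dim(last$latents$action_probs) == c(2, 2)))
  expect_true(abs(sum(last$latents$action_probs[1, ]) - 1) < 1e-12)
})

test_that("a planted pure-MB agent exploits the true structure", {
  # P_MB pinned at 1 (A_gamma = 0, start at 1), kappa = 1, deterministic
  # transitions: after one exposure to each transition the agent's choices
  # maximize true expected reward
  g <- default_graph
  ctl1 <- arb_control(g, p_mb_init = 1)
  par <- c(alpha_mb = 1, alpha_mf = 0.1, eta = 0.1, A_beta = 0,
           A_gamma = 0, tau_mb = 50, tau_mf = 50)
  ex <- expand_params("Arb_a_t3", par)
  probs <- list(low = 1, high = 0.5)  # deterministic environment
  agent <- init_agent_state(g, ctl1)
  set.seed(9)
  for (t in 1:40) {
    res <- agent_trial(agent, g, ex, goal = "flexible", uncertainty = "low",
                       control = ctl1, transition_probs = probs)
    agent <- res$agent
  }
  # with p = 1 the best flexible-goal path is S1 -L-> S2 -L-> red coin (40)
  res <- agent_trial(agent, g, ex, goal = "flexible", uncertainty = "low",
                     control = ctl1, transition_probs = probs)
  expect_equal(res$record$a1, 1L)
  expect_equal(res$record$reward, 40)
})
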