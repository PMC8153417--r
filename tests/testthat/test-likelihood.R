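g <- default_graph

test_that("zero exploitation gives the uniform-policy closed form", {
  log5 <- quick_log(seed = 4, n_pre = 20, n_sessions = 1,
                    session_trials = 30)
  main_decisions <- 2 * sum(!log5$is_pretraining)
  par0 <- t3_par(tau_mb = 0, tau_mf = 0)
  expect_equal(session_nll("Arb_a_t3", par0, log5, g),
               main_decisions * log(2), tolerance = 1e-9)
})

test_that("compiled replay equals the pure-R component replay", {
  set.seed(55)
  for (rep in 1:15) {
    model <- sample(model_names(), 1)
    spec <- model_spec(model)
    gen_par <- t3_par(alpha_mb = runif(1, 0.1, 0.9),
                      alpha_mf = runif(1, 0.1, 0.9),
                      eta = runif(1, 0.05, 0.8),
                      A_beta = runif(1, 0.2, 2), A_gamma = runif(1, 0.2, 2),
                      tau_mb = runif(1, 0.05, 0.4),
                      tau_mf = runif(1, 0.05, 0.4))
    log_i <- quick_log(par = gen_par, seed = 1000 + rep, n_pre = 10,
                       n_sessions = 1, session_trials = 25)
    par <- setNames(runif(spec$k, 0.05, 0.9), spec$params)
    par[spec$params %in% c("tau", "tau_mb", "tau_mf", "c", "c1")] <-
      runif(sum(spec$params %in% c("tau", "tau_mb", "tau_mf", "c", "c1")),
            0.05, 0.5)
    if (model == "Arb_a_t1") {
      par["c2"] <- par["c1"] + runif(1, 0.05, 0.5)
      par["c3"] <- runif(1, 1, 10)
    }
    expect_equal(session_nll(model, par, log_i, g, engine = "cpp"),
                 session_nll(model, par, log_i, g, engine = "r"),
                 tolerance = 1e-9)
  }
})

test_that("appending trials never decreases the NLL", {
  log1 <- quick_log(seed = 6, n_pre = 10, n_sessions = 1,
                    session_trials = 30)
  par <- t3_par()
  main <- which(!log1$is_pretraining)
  n_all <- session_nll("Arb_a_t3", par, log1, g)
  n_fewer <- session_nll("Arb_a_t3", par,
                         log1[-main[length(main)], ], g)
  expect_gte(n_all, n_fewer)
})

test_that("replay and simulation assign identical choice probabilities", {
  par <- t3_par()
  cfg <- task_config(n_pretraining = 20, n_sessions = 1,
                     session_trials = 30)
  sim <- simulate_subject(par, config = cfg, seed = 31)
  rep <- session_nll("Arb_a_t3", par, sim$trials, g, details = TRUE)
  main <- !sim$trials$is_pretraining
  expect_equal(rep$latents$p_chosen1[main], sim$latents$p_chosen1[main],
               tolerance = 1e-12)
  expect_equal(rep$latents$p_chosen2[main], sim$latents$p_chosen2[main],
               tolerance = 1e-12)
})

test_that("BIC and group Bayes factors follow their definitions", {
  expect_equal(bic_score(100, 7, 640), 200 + 7 * log(640), tolerance = 1e-9)
  expect_equal(bic_score(50, 0, 10), 100)
  expect_equal(bic_score(100, 14, 640) - bic_score(100, 7, 640),
               7 * log(640))
  f <- function(id, bic) structure(list(subject_id = id, bic = bic),
                                   class = "fit_result")
  ref <- list(f("a", 100), f("b", 120))
  alt <- list(f("a", 99), f("b", 119))
  expect_equal(group_bayes_factor(ref, ref), 1)
  expect_equal(group_bayes_factor(ref, alt), exp(1))
  expect_equal(group_bayes_factor(ref, alt) * group_bayes_factor(alt, ref),
               1)
  expect_error(group_bayes_factor(ref, list(f("a", 1), f("c", 2))),
               "different subjects")
})

test_that("nested variants reproduce each other's likelihoods exactly", {
  log1 <- quick_log(seed = 8, n_pre = 10, n_sessions = 1,
                    session_trials = 30)
  set.seed(88)
  for (rep in 1:10) {
    a <- runif(1, 0.1, 0.9); eta <- runif(1, 0.1, 0.9)
    Ab <- runif(1, 0.2, 2); Ag <- runif(1, 0.2, 2)
    tau <- runif(1, 0.05, 0.5)
    nll_arb <- session_nll("Arb", c(alpha = a, eta = eta, A_beta = Ab,
                                    A_gamma = Ag, tau = tau), log1, g)
    nll_arb_a <- session_nll("Arb_a", c(alpha_mb = a, alpha_mf = a,
                                        eta = eta, A_beta = Ab,
                                        A_gamma = Ag, tau = tau), log1, g)
    nll_t3 <- session_nll("Arb_a_t3", c(alpha_mb = a, alpha_mf = a,
                                        eta = eta, A_beta = Ab,
                                        A_gamma = Ag, tau_mb = tau,
                                        tau_mf = tau), log1, g)
    expect_identical(nll_arb, nll_arb_a)
    expect_equal(nll_arb_a, nll_t3, tolerance = 1e-12)
  }
})

test_that("fitting is deterministic and cannot be beaten by its restart 0", {
  log1 <- quick_log(seed = 12, n_pre = 10, n_sessions = 1,
                    session_trials = 40)
  truth <- t3_par()
  f1 <- fit_subject("Arb_a_t3", log1, g, n_restarts = 3, seed = 5,
                    init_par = truth)
  f2 <- fit_subject("Arb_a_t3", log1, g, n_restarts = 3, seed = 5,
                    init_par = truth)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$restart_nll, f2$restart_nll)
  expect_lte(f1$nll, session_nll("Arb_a_t3", truth, log1, g))
  # stored BIC is consistent with its parts
  expect_equal(f1$bic, bic_score(f1$nll, f1$k, f1$n_obs))
  expect_equal(f1$nll, min(f1$restart_nll))
  expect_error(fit_subject("Arb_a_t3", log1, g, n_restarts = 0), "restarts")
})

test_that("richer parameter spaces never fit worse at matched seeds", {
  log1 <- quick_log(seed = 13, n_pre = 10, n_sessions = 1,
                    session_trials = 40)
  fa <- fit_subject("Arb_a", log1, g, n_restarts = 6, seed = 2)
  # slice of Arb_a_t3 at the Arb_a optimum, injected as restart 0
  slice <- c(fa$par[c("alpha_mb", "alpha_mf", "eta", "A_beta", "A_gamma")],
             tau_mb = unname(fa$par["tau"]), tau_mf = unname(fa$par["tau"]))
  ft3 <- fit_subject("Arb_a_t3", log1, g, n_restarts = 6, seed = 2,
                     init_par = slice)
  expect_lte(ft3$nll, fa$nll + 1e-9)
})

test_that("a single-model comparison degenerates to a unit Bayes factor", {
  logs <- quick_log(seed = 14, n_pre = 10, n_sessions = 1,
                    session_trials = 25)
  cmp <- compare_models(logs, models = "Arb", g, n_restarts = 2, seed = 3,
                        base = "Arb")
  expect_equal(nrow(cmp$table), 1L)
  expect_equal(cmp$table$bf_vs_base, 1)
  expect_equal(cmp$winner, "Arb")
})
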