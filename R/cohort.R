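#' Synthetic cohort specification
#'
#' Defines the statistical structure of a simulated cohort: the CES-D
#' depression-score distribution (uniform integers over `ces_d_range`,
#' populating both sides of the clinical cutoff at 16), per-parameter
#' priors, and the two effect links tying CES-D to model parameters -- the
#' model-free reliability learning rate `eta` (increasing, on the logit
#' scale) and the model-based exploitation parameter `tau_mb` (decreasing,
#' on the log scale), each with Gaussian noise on the transformed scale.
#' Setting both slopes to 0 yields a null cohort.
#'
#' @param n_subjects cohort size.
#' @param seed master seed; the whole pipeline is reproducible given it.
#' @param config a [task_config()].
#' @param ces_d_range integer range of CES-D scores (within 0-60).
#' @param eta_link,tau_mb_link lists `intercept`, `slope`, `center`,
#'   `noise_sd` on the transformed scale.
#' @return A list with class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 40L, seed = 1L, config = task_config(),
                        ces_d_range = c(0L, 40L),
                        eta_link = list(intercept = qlogis(0.2), slope = 0.06,
                                        center = 20, noise_sd = 0.3),
                        tau_mb_link = list(intercept = log(0.35),
                                           slope = -0.045, center = 20,
                                           noise_sd = 0.25)) {
  stopifnot(n_subjects >= 1, ces_d_range[1] >= 0, ces_d_range[2] <= 60,
            ces_d_range[1] <= ces_d_range[2])
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 config = config, ces_d_range = as.integer(ces_d_range),
                 eta_link = eta_link, tau_mb_link = tau_mb_link),
            class = "cohort_spec")
}

# CES-D -> parameter links on their transformed scales
apply_eta_link <- function(link, ces, noise) {
  plogis(link$intercept + link$slope * (ces - link$center) + noise)
}
apply_tau_mb_link <- function(link, ces, noise) {
  exp(link$intercept + link$slope * (ces - link$center) + noise)
}

#' Sample a synthetic cohort
#'
#' Draws per-subject CES-D scores and true generating parameters of the
#' reliability-weighted exploitation model (`Arb_a_t3`). `eta` and `tau_mb`
#' depend on CES-D through the spec's effect links; every other parameter
#' is drawn independently of CES-D. Draws falling outside the model bounds
#' are rejected and redrawn (up to 1000 attempts).
#'
#' @param spec a [cohort_spec()].
#' @return data.frame: `subject_id`, `ces_d`, and one column per model
#'   parameter.
#' @export
sample_cohort <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  ces <- sample(seq(spec$ces_d_range[1], spec$ces_d_range[2]), n,
                replace = TRUE)
  ms <- model_spec("Arb_a_t3")
  draw_linked <- function(fun, link, ces_i) {
    for (a in 1:1000) {
      x <- fun(link, ces_i, rnorm(1, 0, link$noise_sd))
      if (is.finite(x) && x > 0) return(x)
    }
    stop("effect-link prior produced out-of-bound values after 1000 rejections")
  }
  eta <- vapply(ces, function(ci) draw_linked(apply_eta_link,
                                              spec$eta_link, ci), 0)
  tau_mb <- vapply(ces, function(ci)
    min(draw_linked(apply_tau_mb_link, spec$tau_mb_link, ci),
        ms$upper["tau_mb"]), 0)
  out <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    ces_d = as.integer(ces),
    alpha_mb = rbeta(n, 4, 4),
    alpha_mf = rbeta(n, 4, 4),
    eta = eta,
    A_beta = runif(n, 1, 2.5),
    A_gamma = runif(n, 0.3, 1.2),
    tau_mb = tau_mb,
    tau_mf = rlnorm(n, log(0.1), 0.2),
    stringsAsFactors = FALSE)
  for (p in ms$params)
    out[[p]] <- pmin(pmax(out[[p]], 1e-6), ms$upper[p] - 1e-9)
  out
}

#' Generic parameter priors for recovery simulations
#'
#' Draws `n` plausible parameter vectors for any of the five model
#' variants, independent of any covariate. Used by model-recovery
#' experiments, where the generating regime should span the space in which
#' the variants are distinguishable.
#'
#' @param model a model name or spec.
#' @param n number of parameter vectors.
#' @return data.frame, one column per parameter.
#' @export
sample_model_params <- function(model, n) {
  spec <- model_spec(model)
  draw <- function(p) switch(p,
    alpha = , alpha_mb = , alpha_mf = rbeta(n, 2, 2),
    eta = runif(n, 0.5, 0.85),
    # asymmetric amplitudes keep the arbitration weight mid-range and
    # responsive, where the weighted-exploitation mechanism is expressed
    A_beta = runif(n, 3, 4.5),
    A_gamma = runif(n, 1, 2),
    tau = rlnorm(n, log(0.15), 0.5),
    tau_mb = NA_real_,  # filled jointly with tau_mf below
    tau_mf = NA_real_,
    c = rlnorm(n, log(0.25), 0.5),
    c1 = rlnorm(n, log(0.08), 0.4),
    c3 = runif(n, 2, 10),
    c4 = runif(n, 0.3, 0.7),
    stop("no prior for parameter ", p))
  out <- data.frame(row.names = seq_len(n))
  for (p in spec$params) {
    if (p == "c2") { # logistic upper bound: above c1 by a positive gap
      out[[p]] <- out[["c1"]] + rlnorm(n, log(0.2), 0.5)
    } else out[[p]] <- draw(p)
  }
  if (all(c("tau_mb", "tau_mf") %in% spec$params)) {
    # the weighted rule is only identifiable when the two exploitation
    # scales differ: draw a common scale and a well-separated log-ratio,
    # in either direction (MB-decisive or MF-decisive agents)
    gm <- rlnorm(n, log(0.2), 0.3)
    delta <- sample(c(-1, 1), n, replace = TRUE) * rnorm(n, 1.2, 0.25)
    out$tau_mb <- gm * exp(-delta / 2)
    out$tau_mf <- gm * exp(delta / 2)
  }
  for (p in spec$params)
    out[[p]] <- pmin(pmax(out[[p]], 1e-6), spec$upper[p] - 1e-9)
  out
}

#' Simulate one subject's full experiment
#'
#' Runs the arbitration agent through a reward-free pre-training session
#' (uniform random choices, transition-model learning only) and the main
#' sessions under a pseudo-random goal/uncertainty block schedule, emitting
#' the standard trial log plus the per-trial latent record.
#'
#' @param par named parameter vector.
#' @param model model variant generating behaviour (default `"Arb_a_t3"`).
#' @param config a [task_config()].
#' @param seed integer seed (plan and choices share one RNG stream).
#' @param subject_id identifier written into the log.
#' @param graph optionally a pre-built `"task_graph"` for `config`.
#' @param control an [arb_control()].
#' @return `list(trials, latents)`: the trial-log data.frame and a
#'   data.frame of per-trial latent variables.
#' @export
simulate_subject <- function(par, model = "Arb_a_t3", config = task_config(),
                             seed = 1L, subject_id = "sub001", graph = NULL,
                             control = NULL) {
  spec <- model_spec(model)
  validate_params(spec, par)
  ex <- expand_params(spec, par)
  if (is.null(graph)) graph <- build_task_graph(config)
  if (is.null(control)) control <- arb_control(graph)
  set.seed(seed)
  plan <- make_session_plan(config)
  n <- nrow(plan)
  agent <- init_agent_state(graph, control)
  rec <- matrix(0L, n, 5)  # s1 a1 s2 a2 s_out
  rew <- numeric(n)
  lat <- matrix(NA_real_, n, 13)
  for (t in seq_len(n)) {
    res <- agent_trial(agent, graph, ex, goal = plan$goal[t],
                       uncertainty = plan$uncertainty[t], control = control,
                       transition_probs = config$transition_probs,
                       pretraining = plan$is_pretraining[t])
    agent <- res$agent
    r <- res$record
    rec[t, ] <- c(r$s1, r$a1, r$s2, r$a2, r$s_outcome)
    rew[t] <- r$reward
    l <- res$latents
    lat[t, ] <- c(l$spe, l$rpe, l$chi_mb, l$chi_mf, l$p_mb, l$tau,
                  l$p_chosen, l$action_probs[1, 2], l$action_probs[2, 2])
  }
  trials <- data.frame(
    subject_id = subject_id, session = plan$session, trial = plan$trial,
    is_pretraining = plan$is_pretraining, goal = plan$goal,
    uncertainty = plan$uncertainty,
    s1 = graph$states[rec[, 1]], a1 = ACTIONS[rec[, 2]],
    s2 = graph$states[rec[, 3]], a2 = ACTIONS[rec[, 4]],
    s_outcome = graph$states[rec[, 5]], reward = rew,
    stringsAsFactors = FALSE)
  colnames(lat) <- c("spe1", "spe2", "rpe1", "rpe2", "chi_mb", "chi_mf",
                     "p_mb", "tau1", "tau2", "p_chosen1", "p_chosen2",
                     "p_right1", "p_right2")
  latents <- cbind(data.frame(subject_id = subject_id,
                              session = plan$session, trial = plan$trial),
                   as.data.frame(lat))
  list(trials = trials, latents = latents)
}

#' Simulate a whole cohort
#'
#' @param cohort data.frame from [sample_cohort()] (or any data.frame with
#'   `subject_id` plus the model's parameter columns).
#' @param model model variant generating behaviour.
#' @param config a [task_config()].
#' @param seed base seed; subject i uses `seed + 97 * i`.
#' @return `list(logs, latents)`: row-bound trial logs and latents.
#' @export
simulate_cohort <- function(cohort, model = "Arb_a_t3",
                            config = task_config(), seed = 1L) {
  spec <- model_spec(model)
  graph <- build_task_graph(config)
  control <- arb_control(graph)
  sims <- lapply(seq_len(nrow(cohort)), function(i) {
    par <- unlist(cohort[i, spec$params])
    simulate_subject(par, model = model, config = config,
                     seed = seed + 97L * i,
                     subject_id = cohort$subject_id[i], graph = graph,
                     control = control)
  })
  list(logs = do.call(rbind, lapply(sims, `[[`, "trials")),
       latents = do.call(rbind, lapply(sims, `[[`, "latents")))
}

# the three behavioural measures of one subject's log
measure_subject <- function(trials, graph, config) {
  list(accumulated_reward = accumulated_reward(trials),
       choice_optimality = choice_optimality(trials, graph,
                                             config$transition_probs)$overall,
       choice_consistency = choice_consistency(trials)$overall)
}

cohort_measures <- function(logs, graph, config) {
  ids <- unique(logs$subject_id)
  rows <- lapply(ids, function(id) {
    m <- measure_subject(logs[logs$subject_id == id, , drop = FALSE],
                         graph, config)
    data.frame(subject_id = id, accumulated_reward = m$accumulated_reward,
               choice_optimality = m$choice_optimality,
               choice_consistency = m$choice_consistency,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Parameter recovery experiment
#'
#' Simulates a cohort from known parameters, refits every subject, and
#' correlates true against fitted values per parameter. The report
#' emphasizes the two key parameters, `eta` and `tau_mb`. The generating
#' truth is injected as restart 0 of each fit (the optimizer can only
#' improve on it), so recovery failures reflect identifiability, not
#' optimization.
#'
#' @param spec a [cohort_spec()].
#' @param n_restarts,seed fitting settings.
#' @param inject_truth evaluate the generating parameters as restart 0.
#' @return A list with class `"recovery_report"`: `per_parameter`
#'   (param, r, p), `true`, `fitted`, `fits`.
#' @export
run_parameter_recovery <- function(spec, n_restarts = 16L, seed = 1L,
                                   inject_truth = TRUE) {
  ms <- model_spec("Arb_a_t3")
  cohort <- sample_cohort(spec)
  sims <- simulate_cohort(cohort, config = spec$config, seed = spec$seed)
  graph <- build_task_graph(spec$config)
  fits <- lapply(seq_len(nrow(cohort)), function(i) {
    sub <- sims$logs[sims$logs$subject_id == cohort$subject_id[i], ]
    truth <- unlist(cohort[i, ms$params])
    fit_subject("Arb_a_t3", sub, graph, n_restarts = n_restarts,
                seed = seed + i,
                init_par = if (inject_truth) truth else NULL,
                subject_id = cohort$subject_id[i])
  })
  fitted <- t(vapply(fits, `[[`, numeric(ms$k), "par"))
  true <- as.matrix(cohort[, ms$params])
  per_par <- do.call(rbind, lapply(ms$params, function(p) {
    ct <- correlate_with_score(fitted[, p], true[, p], "pearson")
    data.frame(param = p, r = ct$estimate, p = ct$p_value)
  }))
  structure(list(per_parameter = per_par, true = true, fitted = fitted,
                 cohort = cohort, fits = fits), class = "recovery_report")
}

#' Model recovery experiment
#'
#' For each repetition, simulates a cohort from the generating model and
#' lets [compare_models()] pick a winner among the candidates by group
#' Bayes factor; returns the generator-by-winner confusion counts.
#'
#' @param generating_model name of the data-generating variant.
#' @param n_reps repetitions.
#' @param n_subjects agents per repetition.
#' @param candidates candidate model names (must include the generator).
#' @param n_restarts,seed fitting settings.
#' @param config a [task_config()].
#' @return `list(confusion, winners)`; `confusion` is a named count vector
#'   over candidates summing to `n_reps`.
#' @export
run_model_recovery <- function(generating_model = "Arb_a_t3", n_reps = 5L,
                               n_subjects = 10L,
                               candidates = model_names(),
                               n_restarts = 8L, seed = 1L,
                               config = task_config()) {
  if (!generating_model %in% candidates)
    stop("generating model must be among the candidates")
  graph <- build_task_graph(config)
  winners <- character(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + 131L * r)
    pars <- sample_model_params(generating_model, n_subjects)
    pars$subject_id <- sprintf("rep%02d_sub%03d", r, seq_len(n_subjects))
    sims <- simulate_cohort(pars, model = generating_model, config = config,
                            seed = seed + 977L * r)
    cmp <- compare_models(sims$logs, candidates, graph,
                          n_restarts = n_restarts, seed = seed + 37L * r)
    winners[r] <- cmp$winner
  }
  confusion <- table(factor(winners, levels = candidates))
  list(confusion = confusion, winners = winners)
}

#' Behaviour recovery experiment
#'
#' Re-simulates each subject from their fitted parameters (`n_reps`
#' replications, default 100), averages the three behavioural measures over
#' replications, and correlates the simulated against the source measures
#' across subjects.
#'
#' @param fits list of `"fit_result"` objects (model `Arb_a_t3` or any
#'   other variant; each fit's own model is used to re-simulate).
#' @param source_measures data.frame from the source cohort with columns
#'   `subject_id`, `accumulated_reward`, `choice_optimality`,
#'   `choice_consistency`.
#' @param n_reps replications per subject (>= 1).
#' @param config a [task_config()].
#' @param seed base seed.
#' @return `list(correlations, simulated)`; correlations has one row per
#'   measure with `r` and `p` (`NA` when the source measure has zero
#'   variance across subjects, reported as such).
#' @export
run_behavior_recovery <- function(fits, source_measures, n_reps = 100L,
                                  config = task_config(), seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  graph <- build_task_graph(config)
  sim_rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    reps <- vapply(seq_len(n_reps), function(r) {
      sim <- simulate_subject(f$par, model = f$model, config = config,
                              seed = seed + 7919L * i + r,
                              subject_id = f$subject_id, graph = graph)
      m <- measure_subject(sim$trials, graph, config)
      c(m$accumulated_reward, m$choice_optimality, m$choice_consistency)
    }, numeric(3))
    data.frame(subject_id = f$subject_id,
               accumulated_reward = mean(reps[1, ]),
               choice_optimality = mean(reps[2, ]),
               choice_consistency = mean(reps[3, ]),
               stringsAsFactors = FALSE)
  })
  sim_m <- do.call(rbind, sim_rows)
  sim_m <- sim_m[match(source_measures$subject_id, sim_m$subject_id), ]
  cors <- do.call(rbind, lapply(
    c("accumulated_reward", "choice_optimality", "choice_consistency"),
    function(m) {
      ct <- tryCatch(correlate_with_score(sim_m[[m]], source_measures[[m]],
                                          "pearson"),
                     error = function(e) list(estimate = NA_real_,
                                              p_value = NA_real_))
      data.frame(measure = m, r = ct$estimate, p = ct$p_value)
    }))
  list(correlations = cors, simulated = sim_m)
}

#' End-to-end depression-effect report
#'
#' The full analysis pipeline on a synthetic cohort: sample (CES-D-linked
#' parameters), simulate, measure, fit, correlate. Reports Pearson
#' correlations of CES-D with the three behavioural measures (expected
#' negative under the default links), Spearman correlations of CES-D with
#' the fitted `eta` (expected positive) and `tau_mb` (expected negative),
#' and per-group measure means after the standard CES-D >= 16 split.
#'
#' @param spec a [cohort_spec()].
#' @param n_restarts,seed fitting settings (the truth is *not* injected
#'   here; fits only see the behaviour).
#' @return A list with class `"depression_report"`: `behavioral`,
#'   `parameters`, `group_means`, `measures`, `cohort`, `fits`.
#' @export
run_depression_effect_report <- function(spec, n_restarts = 16L, seed = 1L) {
  graph <- build_task_graph(spec$config)
  cohort <- sample_cohort(spec)
  if (all(cohort$ces_d < 16)) stop("subclinical group empty")
  if (all(cohort$ces_d >= 16)) stop("healthy group empty")
  sims <- simulate_cohort(cohort, config = spec$config, seed = spec$seed)
  meas <- cohort_measures(sims$logs, graph, spec$config)
  ms <- model_spec("Arb_a_t3")
  fits <- lapply(seq_len(nrow(cohort)), function(i) {
    sub <- sims$logs[sims$logs$subject_id == cohort$subject_id[i], ]
    fit_subject("Arb_a_t3", sub, graph, n_restarts = n_restarts,
                seed = seed + i, subject_id = cohort$subject_id[i])
  })
  fitted <- t(vapply(fits, `[[`, numeric(ms$k), "par"))
  behavioral <- do.call(rbind, lapply(
    c("accumulated_reward", "choice_optimality", "choice_consistency"),
    function(m) {
      ct <- correlate_with_score(meas[[m]], cohort$ces_d, "pearson")
      data.frame(measure = m, r = ct$estimate, p = ct$p_value)
    }))
  parameters <- do.call(rbind, lapply(c("eta", "tau_mb"), function(p) {
    ct <- correlate_with_score(fitted[, p], cohort$ces_d, "spearman")
    data.frame(param = p, rho = ct$estimate, p = ct$p_value)
  }))
  grp <- factor(ifelse(cohort$ces_d >= 16, "subclinical", "healthy"),
                levels = c("healthy", "subclinical"))
  group_means <- aggregate(meas[, -1], list(group = grp), mean)
  structure(list(behavioral = behavioral, parameters = parameters,
                 group_means = group_means, measures = meas,
                 cohort = cohort, fitted = fitted, fits = fits),
            class = "depression_report")
}

#' @export
print.depression_report <- function(x, ...) {
  cat("CES-D vs behavioural measures (Pearson):\n")
  print(x$behavioral, row.names = FALSE)
  cat("CES-D vs fitted parameters (Spearman):\n")
  print(x$parameters, row.names = FALSE)
  cat("group means (CES-D cutoff 16):\n")
  print(x$group_means, row.names = FALSE)
  invisible(x)
}
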