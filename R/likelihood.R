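# --- encodings shared by the likelihood engines ---------------------------

encode_graph <- function(graph) {
  list(pairs = as.matrix(graph$pairs[, c("state", "action", "succ1", "succ2")]),
       pair_id = graph$pair_id,
       reward_by_goal = reward_matrix(graph),
       stage = graph$stage)
}

encode_trials <- function(trials, graph) {
  goal <- match(trials$goal, GOAL_LEVELS)
  if (anyNA(goal)) stop("unknown goal label(s) in trial log")
  st <- function(x) if (is.character(x)) match(x, graph$states) else as.integer(x)
  ac <- function(x) if (is.character(x)) match(x, ACTIONS) else as.integer(x)
  enc <- list(goal = as.integer(goal),
              s1 = st(trials$s1), a1 = ac(trials$a1),
              s2 = st(trials$s2), a2 = ac(trials$a2),
              sout = st(trials$s_outcome),
              reward = as.numeric(trials$reward),
              is_pre = as.integer(trials$is_pretraining))
  if (anyNA(enc$s1) || anyNA(enc$s2) || anyNA(enc$sout))
    stop("trial log references states absent from the graph")
  if (anyNA(enc$a1) || anyNA(enc$a2)) stop("actions must be L or R")
  enc
}

#' Negative log-likelihood of a trial log under an arbitration model
#'
#' Replays the agent deterministically through the logged experience --
#' actions and transitions come from the log, never sampled -- accumulating
#' `-log P(logged action)` at every decision of the main sessions (and of
#' pre-training too when `control$fit_pretraining` is set; otherwise
#' pre-training trials update the transition model and SPE history but
#' contribute no likelihood terms).
#'
#' Two engines implement the same replay: a compiled one (`"cpp"`, used by
#' the fitting loop) and a pure-R one (`"r"`) built from the exported
#' component operations, kept as an independent cross-check.
#'
#' @param model a model name or `"model_spec"`.
#' @param par named parameter vector of that model.
#' @param trials one subject's trial log, ordered by session and trial.
#' @param graph a `"task_graph"`.
#' @param control an [arb_control()].
#' @param engine `"cpp"` or `"r"`.
#' @param details if `TRUE`, also return per-trial latents and the number
#'   of likelihood decisions.
#' @return The NLL in nats, or (with `details`) a list `nll`, `n_obs`,
#'   `latents`.
#' @export
session_nll <- function(model, par, trials, graph,
                        control = arb_control(graph),
                        engine = c("cpp", "r"), details = FALSE) {
  engine <- match.arg(engine)
  spec <- model_spec(model)
  validate_params(spec, par)
  if (engine == "cpp") {
    res <- cpp_nll_prepared(spec, make_nll_data(trials, graph, control),
                            par, keep_latents = details)
    if (!details) return(res$nll)
    return(list(nll = res$nll, n_obs = res$n_obs,
                latents = as.data.frame(res$latents)))
  }
  replay_session_r(spec, par, trials, graph, control, details = details)
}

# pre-encode a subject's log once so the optimizer's objective is cheap
make_nll_data <- function(trials, graph, control) {
  list(genc = encode_graph(graph), tenc = encode_trials(trials, graph),
       control = unclass(control))
}

# kept lean: this runs once per objective evaluation inside the optimizer
cpp_nll_prepared <- function(spec, data, par, keep_latents = FALSE) {
  if (spec$name == "Arb") {
    amb <- par[["alpha"]]; amf <- amb
  } else {
    amb <- par[["alpha_mb"]]; amf <- par[["alpha_mf"]]
  }
  tau_par <- switch(spec$variant,
                    fixed = par[["tau"]],
                    logistic = c(par[["c1"]], par[["c2"]], par[["c3"]],
                                 par[["c4"]]),
                    linear = par[["c"]],
                    weighted = c(par[["tau_mb"]], par[["tau_mf"]]))
  variant_code <- match(spec$variant,
                        c("fixed", "logistic", "linear", "weighted")) - 1L
  cpp_replay_session(
    c(amb, amf, par[["eta"]], par[["A_beta"]], par[["A_gamma"]]),
    variant_code, as.numeric(tau_par),
    data$genc$pairs, data$genc$pair_id, data$genc$reward_by_goal,
    data$genc$stage,
    data$tenc$goal, data$tenc$s1, data$tenc$a1, data$tenc$s2, data$tenc$a2,
    data$tenc$sout, data$tenc$reward, data$tenc$is_pre,
    data$control, keep_latents)
}

# pure-R replay: drives agent_trial() with forced actions/transitions
replay_session_r <- function(spec, par, trials, graph, control,
                             details = FALSE) {
  ex <- expand_params(spec, par)
  enc <- encode_trials(trials, graph)
  agent <- init_agent_state(graph, control)
  n <- nrow(trials)
  nll <- 0
  n_obs <- 0L
  lat <- if (details) vector("list", n)
  for (t in seq_len(n)) {
    forced <- list(a1 = enc$a1[t], s2 = enc$s2[t], a2 = enc$a2[t],
                   s_outcome = enc$sout[t], reward = enc$reward[t])
    res <- agent_trial(agent, graph, ex, goal = trials$goal[t],
                       uncertainty = trials$uncertainty[t],
                       control = control, forced = forced,
                       pretraining = enc$is_pre[t] == 1L)
    agent <- res$agent
    pc <- res$latents$p_chosen
    if (!anyNA(pc)) {
      nll <- nll - sum(log(pmax(pc, control$prob_floor)))
      n_obs <- n_obs + 2L
    }
    if (details) lat[[t]] <- res$latents
  }
  if (!details) return(nll)
  list(nll = nll, n_obs = n_obs, latents = lat)
}

#' Bayesian Information Criterion
#'
#' `BIC = 2 * NLL + k * log(n)`, penalizing each model for its number of
#' free parameters.
#'
#' @param nll negative log-likelihood (nats).
#' @param k number of free parameters (>= 0).
#' @param n number of observations (logged decisions) entering the
#'   likelihood (> 0).
#' @return The BIC.
#' @export
bic_score <- function(nll, k, n) {
  if (n <= 0) stop("n must be > 0")
  if (k < 0) stop("k must be >= 0")
  2 * nll + k * log(n)
}

#' Fit one subject by multi-start Nelder-Mead
#'
#' Minimizes the session NLL with the downhill-simplex method from
#' `n_restarts` random interior starting points (default 128, matching the
#' study protocol); box bounds are enforced by a logistic reparameterization
#' so the simplex search is unconstrained. When a candidate parameter vector
#' is supplied (`init_par`, e.g. the generating truth in recovery
#' experiments) it is evaluated as restart 0, so the returned NLL can never
#' exceed the NLL at that point.
#'
#' @inheritParams session_nll
#' @param n_restarts number of random restarts (>= 1).
#' @param seed integer seed making the restart draw reproducible.
#' @param init_par optional named parameter vector injected as restart 0.
#' @param subject_id identifier stored in the result.
#' @param maxit,reltol Nelder-Mead control settings.
#' @return A list with class `"fit_result"`: `subject_id`, `model`, `par`,
#'   `nll`, `k`, `n_obs`, `bic`, `restart_nll`, `seed`.
#' @export
fit_subject <- function(model, trials, graph, n_restarts = 128L, seed = 1L,
                        control = arb_control(graph), init_par = NULL,
                        subject_id = "subject", maxit = 1500L,
                        reltol = 1e-8) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  spec <- model_spec(model)
  data <- make_nll_data(trials, graph, control)
  obj <- function(z) {
    v <- cpp_nll_prepared(spec, data, transform_params(spec, z))$nll
    if (!is.finite(v)) 1e10 else v
  }
  set.seed(seed)
  starts <- draw_starts(spec, n_restarts)
  if (!is.null(init_par)) {
    validate_params(spec, init_par)
    starts <- rbind(untransform_params(spec, init_par), starts)
  }
  restart_nll <- rep(NA_real_, nrow(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
    restart_nll[i] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (all(!is.finite(restart_nll) | restart_nll >= 1e10))
    stop("all restarts produced non-finite likelihoods")
  par <- transform_params(spec, best$par)
  n_obs <- cpp_nll_prepared(spec, data, par)$n_obs
  structure(list(subject_id = subject_id, model = spec$name, par = par,
                 nll = best$value, k = spec$k, n_obs = n_obs,
                 bic = bic_score(best$value, spec$k, n_obs),
                 restart_nll = restart_nll, n_restarts = n_restarts,
                 seed = seed), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$subject_id, "model", x$model,
      sprintf("NLL %.3f BIC %.3f (k = %d, n = %d)\n",
              x$nll, x$bic, x$k, x$n_obs))
  print(round(x$par, 4))
  invisible(x)
}

#' Group Bayes factor from summed BICs
#'
#' `BF = exp((sum BIC_ref - sum BIC_alt) / 2)` over the common subject set;
#' `BF > 1` favors the alternative model. Summing BIC differences across
#' subjects is what produces the very large Bayes-factor magnitudes typical
#' of group-level comparisons.
#'
#' @param fits_ref,fits_alt lists of `"fit_result"` objects for the same
#'   subjects under the reference and alternative model.
#' @return The Bayes factor (possibly `Inf` for overwhelming evidence).
#' @export
group_bayes_factor <- function(fits_ref, fits_alt) {
  ids_ref <- sort(vapply(fits_ref, `[[`, "", "subject_id"))
  ids_alt <- sort(vapply(fits_alt, `[[`, "", "subject_id"))
  if (!identical(ids_ref, ids_alt))
    stop("reference and alternative fits cover different subjects")
  d <- sum(vapply(fits_ref, `[[`, 0, "bic")) -
    sum(vapply(fits_alt, `[[`, 0, "bic"))
  exp(d / 2)
}

# embed a fitted simpler model's optimum into a richer variant's parameter
# space, to warm-start the richer fit (the embeddings are exact for Arb ->
# Arb_a, Arb_a -> Arb_a_t1 with c1 = c2 = tau, and Arb_a -> Arb_a_t3 with
# tau_mb = tau_mf = tau; the linear variant gets a heuristic start)
embed_params <- function(from_model, par, to_model) {
  widen <- function(p) {
    if (from_model == "Arb")
      c(alpha_mb = unname(p["alpha"]), alpha_mf = unname(p["alpha"]),
        p[c("eta", "A_beta", "A_gamma", "tau")])
    else p
  }
  p <- widen(par)
  tau <- unname(p["tau"])
  base <- p[c("alpha_mb", "alpha_mf", "eta", "A_beta", "A_gamma")]
  out <- switch(to_model,
    Arb_a = p[c("alpha_mb", "alpha_mf", "eta", "A_beta", "A_gamma", "tau")],
    Arb_a_t1 = c(base, c1 = tau, c2 = tau + 1e-6, c3 = 1, c4 = 0.5),
    Arb_a_t2 = c(base, c = min(2 * tau, 49)),
    Arb_a_t3 = c(base, tau_mb = tau, tau_mf = tau),
    NULL)
  if (!is.null(out)) {
    spec <- model_spec(to_model)
    out <- pmin(pmax(out[spec$params], 1e-8), spec$upper - 1e-8)
  }
  out
}

#' Fit and compare arbitration model variants over a cohort
#'
#' Fits every (subject, model) combination, reports per-model summed BIC
#' and the Bayes factor against the base model, selects the winner (lowest
#' summed BIC), and runs a paired per-subject NLL comparison (t-test)
#' between the two best models.
#'
#' Models are fitted in increasing complexity; every variant that nests an
#' already-fitted simpler model receives that model's optimum (embedded in
#' its own parameter space) as an additional warm start, which enforces the
#' nesting inequalities in practice and makes the BIC comparison reflect
#' model structure rather than optimizer luck.
#'
#' @param logs trial log data.frame for one or more subjects (column
#'   `subject_id`).
#' @param models character vector of model names (>= 1).
#' @param graph a `"task_graph"`.
#' @param n_restarts,seed,control passed to [fit_subject()]; each
#'   (subject, model) pair gets a distinct seed derived from `seed`.
#' @param base name of the reference model for the Bayes-factor column.
#' @return A list with class `"model_comparison"`: `table` (model, k,
#'   sum_bic, bf_vs_base), `winner`, `paired_test`, `fits` (nested list).
#' @export
compare_models <- function(logs, models = model_names(), graph,
                           n_restarts = 16L, seed = 1L,
                           control = arb_control(graph), base = "Arb") {
  subjects <- unique(logs$subject_id)
  if (length(subjects) < 1) stop("need at least one subject")
  complexity <- order(vapply(models, function(m) model_spec(m)$k, 0L))
  donor_of <- function(m) {
    cand <- switch(m, Arb_a = "Arb",
                   Arb_a_t1 = , Arb_a_t2 = , Arb_a_t3 = c("Arb_a", "Arb"),
                   character(0))
    cand[cand %in% names(fits)][1]
  }
  fits <- list()
  for (mi in complexity) {
    m <- models[mi]
    donor <- donor_of(m)
    fits[[m]] <- lapply(seq_along(subjects), function(si) {
      sub <- logs[logs$subject_id == subjects[si], , drop = FALSE]
      init <- if (!is.na(donor) && length(donor))
        embed_params(donor, fits[[donor]][[si]]$par, m)
      fit_subject(m, sub, graph, n_restarts = n_restarts,
                  seed = seed + 1000L * mi + si, control = control,
                  init_par = init, subject_id = subjects[si])
    })
  }
  fits <- fits[models]
  sum_bic <- vapply(fits, function(f) sum(vapply(f, `[[`, 0, "bic")), 0)
  k <- vapply(models, function(m) model_spec(m)$k, 0L)
  bf <- if (base %in% models)
    vapply(models, function(m) group_bayes_factor(fits[[base]], fits[[m]]), 0)
  else rep(NA_real_, length(models))
  tab <- data.frame(model = models, k = k, sum_bic = unname(sum_bic),
                    bf_vs_base = unname(bf), row.names = NULL,
                    stringsAsFactors = FALSE)
  winner <- models[which.min(sum_bic)]
  paired <- NULL
  if (length(models) >= 2 && length(subjects) >= 2) {
    ord <- order(sum_bic)
    n1 <- models[ord[1]]; n2 <- models[ord[2]]
    d <- vapply(seq_along(subjects), function(si)
      fits[[n2]][[si]]$nll - fits[[n1]][[si]]$nll, 0)
    tt <- t.test(d)
    paired <- list(best = n1, second = n2, mean_nll_gain = mean(d),
                   t = unname(tt$statistic), p_value = tt$p.value)
  }
  structure(list(table = tab, winner = winner, paired_test = paired,
                 fits = fits), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table)
  cat("winner:", x$winner, "\n")
  invisible(x)
}
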