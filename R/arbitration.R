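#' Arbitration control constants
#'
#' Fixed (non-fitted) constants of the arbitration scheme. `rpe_max`
#' defaults to the maximum coin value of the task graph, so that the
#' Pearce-Hall reliability stays a probability-like quantity.
#'
#' @param graph optional `"task_graph"` used to default `rpe_max`.
#' @param rate_steepness steepness B of the transition-rate sigmoid
#'   `A / (1 + exp(B * chi))`.
#' @param spe_zero_threshold SPE magnitude at or below which an event counts
#'   as a "zero SPE" for the model-based reliability estimator.
#' @param spe_window length of the bounded SPE history.
#' @param prior conjugate Beta prior counts `(a0, b0)` of the zero-SPE
#'   probability.
#' @param rpe_max normalization bound of the Pearce-Hall estimator (points).
#' @param prob_floor floor applied to action probabilities before taking
#'   logs in the likelihood.
#' @param p_mb_init initial model choice probability.
#' @param fit_pretraining if `TRUE`, pre-training trials are replayed with
#'   full value/arbitration updates and contribute likelihood terms; by
#'   default they only update the transition model and SPE history.
#' @param p_mb_step `"decision"` (default) integrates the model choice
#'   probability with one Euler step after every prediction-error event
#'   (twice per trial), so arbitration tracks the reliabilities within a
#'   trial; `"trial"` applies a single step after the outcome.
#' @return A list with class `"arb_control"`.
#' @export
arb_control <- function(graph = NULL, rate_steepness = 5,
                        spe_zero_threshold = 0.2, spe_window = 6L,
                        prior = c(1, 1), rpe_max = NULL,
                        prob_floor = 1e-12, p_mb_init = 0.5,
                        fit_pretraining = FALSE,
                        p_mb_step = c("decision", "trial")) {
  p_mb_step <- match.arg(p_mb_step)
  if (is.null(rpe_max))
    rpe_max <- if (!is.null(graph)) max(graph$coin_values) else 40
  stopifnot(rpe_max > 0, all(prior > 0), spe_zero_threshold >= 0,
            spe_window >= 1, p_mb_init >= 0, p_mb_init <= 1)
  structure(list(rate_steepness = rate_steepness,
                 spe_zero_threshold = spe_zero_threshold,
                 spe_window = as.integer(spe_window),
                 prior = as.numeric(prior),
                 rpe_max = rpe_max,
                 prob_floor = prob_floor,
                 p_mb_init = p_mb_init,
                 fit_pretraining = isTRUE(fit_pretraining),
                 p_mb_per_decision = p_mb_step == "decision"),
            class = "arb_control")
}

# inverse index of dispersion (posterior mean / posterior variance) of a
# Beta(a, b) posterior: (a+b)(a+b+1)/b
beta_inv_dispersion <- function(a, b) (a + b) * (a + b + 1) / b

#' Model-based reliability from the SPE history
#'
#' Empirical-Bayes estimate: events in the bounded SPE history are
#' classified as "zero SPE" (SPE <= threshold) or non-zero; the
#' probabilities of the two event types get conjugate Beta posteriors, and
#' each system reliability index is the inverse index of dispersion
#' (posterior mean over posterior variance). The model-based reliability is
#' `chi_0 / (chi_0 + chi_1)`, in (0, 1), and equals 0.5 under the symmetric
#' prior with an empty history.
#'
#' @param spe_history numeric vector of recent SPE values (at most
#'   `control$spe_window` of them).
#' @param control an [arb_control()].
#' @return `chi_MB` in (0, 1).
#' @export
mb_reliability <- function(spe_history, control = arb_control()) {
  n0 <- sum(spe_history <= control$spe_zero_threshold)
  n1 <- length(spe_history) - n0
  a0 <- control$prior[1]; b0 <- control$prior[2]
  chi0 <- beta_inv_dispersion(a0 + n0, b0 + n1)
  chi1 <- beta_inv_dispersion(a0 + n1, b0 + n0)
  chi0 / (chi0 + chi1)
}

# bounded queue of SPE events (most recent last)
push_spe <- function(spe_history, spe, window) {
  h <- c(spe_history, spe)
  if (length(h) > window) h <- h[(length(h) - window + 1L):length(h)]
  h
}

#' Pearce-Hall update of model-free reliability
#'
#' The absolute-RPE estimator follows `Omega <- Omega + eta * (|RPE| -
#' Omega)` (clipped to `[0, rpe_max]`), and the model-free reliability is
#' its normalized complement `chi_MF = (rpe_max - Omega) / rpe_max`.
#'
#' @param omega current absolute-RPE estimator (points).
#' @param abs_rpe unsigned reward prediction error (>= 0).
#' @param eta associability learning rate in `[0, 1]`.
#' @param control an [arb_control()] supplying `rpe_max`.
#' @return `list(omega = updated estimator, chi_mf = reliability)`.
#' @export
mf_reliability_update <- function(omega, abs_rpe, eta,
                                  control = arb_control()) {
  if (!is.numeric(eta) || eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  if (abs_rpe < 0) stop("abs_rpe must be >= 0")
  omega <- omega + eta * (abs_rpe - omega)
  omega <- min(max(omega, 0), control$rpe_max)
  list(omega = omega, chi_mf = (control$rpe_max - omega) / control$rpe_max)
}

#' Transition rates of the two-state arbitration dynamic
#'
#' `beta = A_beta / (1 + exp(B * chi_MF))` is the MF-to-MB rate and
#' `gamma = A_gamma / (1 + exp(B * chi_MB))` the MB-to-MF rate: each rate is
#' strictly positive and decreasing in the reliability of the system it
#' would leave *to* -- a reliable system retains control. The amplitudes are
#' free per-subject parameters; the steepness B is a fixed constant.
#'
#' @param chi_mf,chi_mb reliabilities in `[0, 1]`.
#' @param A_beta,A_gamma non-negative rate amplitudes.
#' @param B sigmoid steepness.
#' @return `list(beta, gamma)`.
#' @export
transition_rates <- function(chi_mf, chi_mb, A_beta, A_gamma, B = 5) {
  if (A_beta < 0 || A_gamma < 0) stop("rate amplitudes must be >= 0")
  list(beta = A_beta / (1 + exp(B * chi_mf)),
       gamma = A_gamma / (1 + exp(B * chi_mb)))
}

#' One Euler step of the model choice probability
#'
#' `dP_MB/dt = beta (1 - P_MB) - gamma P_MB`, integrated with one explicit
#' Euler step (dt = 1) per decision event and clipped to `[0, 1]`. The fixed
#' point at constant rates is `beta / (beta + gamma)`.
#'
#' @param p_mb current model choice probability.
#' @param beta,gamma transition rates from [transition_rates()].
#' @return Updated `P_MB` in `[0, 1]`.
#' @export
update_model_choice_prob <- function(p_mb, beta, gamma) {
  if (p_mb < 0 || p_mb > 1) stop("p_mb must be in [0, 1]")
  clip01(p_mb + beta * (1 - p_mb) - gamma * p_mb)
}

#' Reliability-weighted value integration
#'
#' `Q_arb = P_MB * Q_MB + (1 - P_MB) * Q_MF`, elementwise over matching
#' (state, action) pairs.
#'
#' @param q_mb,q_mf value vectors over the same (state, action) pairs.
#' @param p_mb model choice probability.
#' @return Integrated value vector.
#' @export
integrate_values <- function(q_mb, q_mf, p_mb) {
  if (length(q_mb) != length(q_mf))
    stop("q_mb and q_mf must cover the same (state, action) pairs")
  p_mb * q_mb + (1 - p_mb) * q_mf
}

#' Exploitation (softmax inverse temperature) specification
#'
#' The four variants of the value-action conversion rule:
#' * `fixed`: constant `tau`;
#' * `logistic`: `c1 + (c2 - c1) / (1 + exp(-c3 (P_MB - c4)))`;
#' * `linear`: `P_MB * c`;
#' * `weighted`: `P_MB * tau_mb + (1 - P_MB) * tau_mf`.
#'
#' All parameters are non-negative; the logistic variant requires
#' `c2 >= c1`.
#'
#' @param variant one of `"fixed"`, `"logistic"`, `"linear"`, `"weighted"`.
#' @param ... the variant's parameters (`tau`; `c1, c2, c3, c4`; `c`;
#'   `tau_mb, tau_mf`).
#' @return A list with class `"exploitation_spec"`.
#' @export
exploitation_spec <- function(variant = c("fixed", "logistic", "linear",
                                          "weighted"), ...) {
  variant <- match.arg(variant)
  pars <- list(...)
  need <- switch(variant,
                 fixed = "tau",
                 logistic = c("c1", "c2", "c3", "c4"),
                 linear = "c",
                 weighted = c("tau_mb", "tau_mf"))
  if (!setequal(names(pars), need))
    stop("variant '", variant, "' needs parameters: ",
         paste(need, collapse = ", "))
  if (any(unlist(pars) < 0)) stop("exploitation parameters must be >= 0")
  if (variant == "logistic" && pars$c2 < pars$c1)
    stop("logistic exploitation requires c2 >= c1")
  structure(c(list(variant = variant), pars), class = "exploitation_spec")
}

#' Dynamic degree of exploitation
#'
#' Maps the model choice probability to the softmax inverse temperature
#' under the given exploitation rule. In the weighted variant with
#' `tau_mb = tau_mf` this reduces exactly to the fixed-tau model.
#'
#' @param p_mb model choice probability in `[0, 1]`.
#' @param spec an [exploitation_spec()].
#' @return `tau >= 0`.
#' @export
dynamic_exploitation <- function(p_mb, spec) {
  if (p_mb < 0 || p_mb > 1) stop("p_mb must be in [0, 1]")
  switch(spec$variant,
         fixed = spec$tau,
         logistic = spec$c1 + (spec$c2 - spec$c1) /
           (1 + exp(-spec$c3 * (p_mb - spec$c4))),
         linear = p_mb * spec$c,
         weighted = p_mb * spec$tau_mb + (1 - p_mb) * spec$tau_mf,
         stop("unknown exploitation variant"))
}

#' Softmax action-selection policy
#'
#' `P(a) = exp(tau * Q(a)) / sum_b exp(tau * Q(b))`, computed with the
#' max-subtraction trick for numerical stability. `tau = 0` gives the
#' uniform policy.
#'
#' @param q action values.
#' @param tau degree of exploitation (inverse temperature, >= 0).
#' @return Probability vector over the actions (sums to 1).
#' @export
softmax_policy <- function(q, tau) {
  if (tau < 0) stop("tau must be >= 0")
  if (any(!is.finite(q))) stop("non-finite action values")
  z <- exp(tau * (q - max(q)))
  z / sum(z)
}

#' Initialize an arbitration agent
#'
#' Latent state before any experience: uniform transition rows, zero
#' model-free values, empty SPE history (so `chi_MB = 0.5` under the
#' symmetric prior), `Omega = rpe_max / 2` (so `chi_MF = 0.5`), and
#' `P_MB` at its configured starting value (default 0.5, maximal
#' ignorance).
#'
#' @param graph a `"task_graph"`.
#' @param control an [arb_control()].
#' @return A list with class `"agent_state"`.
#' @export
init_agent_state <- function(graph, control = arb_control(graph)) {
  omega <- control$rpe_max / 2
  structure(list(
    T = new_transition_model(graph),
    q_mf = numeric(nrow(graph$pairs)),
    spe_history = numeric(0),
    omega = omega,
    chi_mb = mb_reliability(numeric(0), control),
    chi_mf = (control$rpe_max - omega) / control$rpe_max,
    p_mb = control$p_mb_init
  ), class = "agent_state")
}

# observe one transition: SPE, history push, T update, chi_MB refresh
observe_transition <- function(agent, graph, s, a, s_next, kappa, control) {
  spe <- state_prediction_error(agent$T, graph, s, a, s_next)
  agent$spe_history <- push_spe(agent$spe_history, spe, control$spe_window)
  agent$T <- update_transition_model(agent$T, graph, s, a, s_next, kappa)
  agent$chi_mb <- mb_reliability(agent$spe_history, control)
  list(agent = agent, spe = spe)
}

#' Run one trial of the arbitration agent
#'
#' Composes the full per-trial cycle: for each of the two decisions the
#' model-based values are re-planned under the current goal, integrated with
#' the model-free values by `P_MB`, converted through the exploitation rule,
#' and an action is drawn from (or forced onto) the softmax policy; each
#' observed transition updates the transition model and the model-based
#' reliability; after the outcome the two SARSA steps update the model-free
#' values and reliability; finally the transition rates move `P_MB` by one
#' Euler step.
#'
#' Pre-training trials (no rewards delivered, the agent only learns the
#' state space) take uniformly random actions and perform only
#' transition-model and SPE-history updates, unless
#' `control$fit_pretraining` is set.
#'
#' @param agent an [init_agent_state()] object.
#' @param graph a `"task_graph"`.
#' @param params expanded parameter list (see [expand_params()]):
#'   `alpha_mb`, `alpha_mf`, `eta`, `A_beta`, `A_gamma`, and an
#'   `exploitation_spec` under `expl`.
#' @param goal,uncertainty the trial's conditions.
#' @param control an [arb_control()].
#' @param transition_probs successor probabilities per uncertainty level
#'   (used only when transitions are sampled).
#' @param forced optional list `(a1, s2, a2, s_outcome, reward)` replaying a
#'   logged trial instead of sampling.
#' @param pretraining logical flag for pre-training trials.
#' @return `list(agent, record, latents)`: the updated agent, the trial
#'   record (states, actions, reward), and the per-trial latent variables
#'   (SPEs, RPEs, reliabilities, `P_MB`, `tau`, action probabilities).
#' @export
agent_trial <- function(agent, graph, params, goal, uncertainty,
                        control = arb_control(graph),
                        transition_probs = list(low = 0.9, high = 0.5),
                        forced = NULL, pretraining = FALSE) {
  s1 <- graph$first_stage
  draw <- function(pr) sample.int(2L, 1L, prob = pr)
  step_transition <- function(s, a, forced_next) {
    if (!is.null(forced_next)) forced_next
    else sample_transition(graph, s, a, uncertainty, transition_probs)
  }
  reduced <- pretraining && !control$fit_pretraining

  if (reduced) {
    a1 <- forced$a1 %||% draw(c(0.5, 0.5))
    s2 <- step_transition(s1, a1, forced$s2)
    o1 <- observe_transition(agent, graph, s1, a1, s2, params$alpha_mb, control)
    agent <- o1$agent
    a2 <- forced$a2 %||% draw(c(0.5, 0.5))
    s_out <- step_transition(s2, a2, forced$s_outcome)
    o2 <- observe_transition(agent, graph, s2, a2, s_out, params$alpha_mb,
                             control)
    agent <- o2$agent
    record <- list(s1 = s1, a1 = a1, s2 = s2, a2 = a2, s_outcome = s_out,
                   reward = 0)
    latents <- list(spe = c(o1$spe, o2$spe), rpe = c(NA_real_, NA_real_),
                    chi_mb = agent$chi_mb, chi_mf = agent$chi_mf,
                    p_mb = agent$p_mb, tau = c(NA_real_, NA_real_),
                    action_probs = matrix(0.5, 2, 2),
                    p_chosen = c(NA_real_, NA_real_))
    return(list(agent = agent, record = record, latents = latents))
  }

  action_probs <- matrix(NA_real_, 2, 2)
  tau_used <- numeric(2)

  # decision 1
  q_mb <- plan_mb_values(agent$T, graph, goal)
  tau_used[1] <- dynamic_exploitation(agent$p_mb, params$expl)
  pid1 <- graph$pair_id[s1, ]
  pr1 <- softmax_policy(integrate_values(q_mb[pid1], agent$q_mf[pid1],
                                         agent$p_mb), tau_used[1])
  action_probs[1, ] <- pr1
  a1 <- forced$a1 %||% draw(pr1)
  s2 <- step_transition(s1, a1, forced$s2)
  o1 <- observe_transition(agent, graph, s1, a1, s2, params$alpha_mb, control)
  agent <- o1$agent
  if (control$p_mb_per_decision) {
    r1 <- transition_rates(agent$chi_mf, agent$chi_mb, params$A_beta,
                           params$A_gamma, control$rate_steepness)
    agent$p_mb <- update_model_choice_prob(agent$p_mb, r1$beta, r1$gamma)
  }

  # decision 2 (values re-planned: the transition model just changed)
  q_mb <- plan_mb_values(agent$T, graph, goal)
  tau_used[2] <- dynamic_exploitation(agent$p_mb, params$expl)
  pid2 <- graph$pair_id[s2, ]
  pr2 <- softmax_policy(integrate_values(q_mb[pid2], agent$q_mf[pid2],
                                         agent$p_mb), tau_used[2])
  action_probs[2, ] <- pr2
  a2 <- forced$a2 %||% draw(pr2)
  s_out <- step_transition(s2, a2, forced$s_outcome)
  o2 <- observe_transition(agent, graph, s2, a2, s_out, params$alpha_mb,
                           control)
  agent <- o2$agent

  reward <- forced$reward %||% goal_reward(s_out, goal, graph)
  if (pretraining && is.null(forced)) reward <- 0

  # SARSA on both steps, Pearce-Hall reliability after each RPE
  u1 <- sarsa_update(agent$q_mf, graph, s1, a1, r = 0, s_next = s2,
                     a_next = a2, alpha = params$alpha_mf)
  agent$q_mf <- u1$Q
  m1 <- mf_reliability_update(agent$omega, abs(u1$rpe), params$eta, control)
  agent$omega <- m1$omega; agent$chi_mf <- m1$chi_mf
  u2 <- sarsa_update(agent$q_mf, graph, s2, a2, r = reward,
                     s_next = s_out, alpha = params$alpha_mf)
  agent$q_mf <- u2$Q
  m2 <- mf_reliability_update(agent$omega, abs(u2$rpe), params$eta, control)
  agent$omega <- m2$omega; agent$chi_mf <- m2$chi_mf

  # arbitration: one Euler step per trial
  rates <- transition_rates(agent$chi_mf, agent$chi_mb,
                            params$A_beta, params$A_gamma,
                            control$rate_steepness)
  agent$p_mb <- update_model_choice_prob(agent$p_mb, rates$beta, rates$gamma)

  record <- list(s1 = s1, a1 = a1, s2 = s2, a2 = a2, s_outcome = s_out,
                 reward = reward)
  latents <- list(spe = c(o1$spe, o2$spe), rpe = c(u1$rpe, u2$rpe),
                  chi_mb = agent$chi_mb, chi_mf = agent$chi_mf,
                  p_mb = agent$p_mb, tau = tau_used,
                  action_probs = action_probs,
                  p_chosen = c(pr1[a1], pr2[a2]))
  list(agent = agent, record = record, latents = latents)
}
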