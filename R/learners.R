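#' Initial transition model
#'
#' Returns the FORWARD learner's state-action-state transition matrix `T`,
#' one row per (state, action) pair of the graph, initialized uniform over
#' the pair's two successors (an uninformative start before pre-training).
#'
#' @param graph a `"task_graph"`.
#' @return Numeric matrix `n_pairs x 2`; column j is the probability of the
#'   j-th listed successor.
#' @export
new_transition_model <- function(graph) {
  matrix(0.5, nrow(graph$pairs), 2L)
}

# index (1 or 2) of s_next among the successors of (s, a), or error
successor_index <- function(graph, s, a, s_next) {
  pid <- graph$pair_id[s, a]
  if (pid == 0L) stop("unknown (state, action) pair: (", s, ", ", a, ")")
  if (s_next == graph$pairs$succ1[pid]) 1L
  else if (s_next == graph$pairs$succ2[pid]) 2L
  else stop("state ", s_next, " is not a successor of (", s, ", ", a, ")")
}

#' State prediction error
#'
#' SPE = 1 - expected probability of the observed transition. Drives both
#' the transition-model update and the model-based reliability estimate.
#'
#' @param T transition matrix from [new_transition_model()].
#' @param graph a `"task_graph"`.
#' @param s,a,s_next state, action, and observed successor (integer ids).
#' @return SPE in `[0, 1]`.
#' @export
state_prediction_error <- function(T, graph, s, a, s_next) {
  j <- successor_index(graph, s, a, s_next)
  1 - T[graph$pair_id[s, a], j]
}

#' FORWARD transition-model update
#'
#' Moves the observed successor's probability toward 1 by
#' `kappa * (1 - T(s,a,s'))` and the unobserved successor toward 0 by
#' `kappa * (0 - T)`, which keeps each row normalized.
#'
#' @inheritParams state_prediction_error
#' @param s_observed observed successor id.
#' @param kappa model-based learning rate in `[0, 1]`.
#' @return The updated transition matrix.
#' @export
update_transition_model <- function(T, graph, s, a, s_observed, kappa) {
  if (!is.numeric(kappa) || kappa < 0 || kappa > 1)
    stop("kappa must be in [0, 1]")
  j <- successor_index(graph, s, a, s_observed)
  pid <- graph$pair_id[s, a]
  T[pid, j] <- T[pid, j] + kappa * (1 - T[pid, j])
  T[pid, 3L - j] <- (1 - kappa) * T[pid, 3L - j]
  T
}

#' Model-based action values by backward induction
#'
#' Computes `Q_MB(s, a) = sum_s' T(s,a,s') * (r(s') + max_a' Q_MB(s', a'))`
#' over the two-stage graph, with goal-conditional outcome rewards `r(s')`
#' and terminal value 0. Recomputed whenever the goal changes; this is what
#' makes the model-based system goal-sensitive.
#'
#' @inheritParams state_prediction_error
#' @param goal `"flexible"` or a coin colour.
#' @return Numeric vector of values, one per (state, action) pair, in the
#'   row order of `graph$pairs`.
#' @export
plan_mb_values <- function(T, graph, goal) {
  r <- goal_reward_vector(graph, goal)
  q <- numeric(nrow(graph$pairs))
  st <- graph$pairs$state
  s2_rows <- which(graph$stage[st] == 2L)
  for (i in s2_rows)
    q[i] <- T[i, 1] * r[graph$pairs$succ1[i]] + T[i, 2] * r[graph$pairs$succ2[i]]
  v <- numeric(graph$n_states)
  for (s in graph$stage2_states)
    v[s] <- max(q[graph$pair_id[s, ]])
  for (i in which(graph$stage[st] == 1L)) {
    k1 <- graph$pairs$succ1[i]; k2 <- graph$pairs$succ2[i]
    q[i] <- T[i, 1] * (r[k1] + v[k1]) + T[i, 2] * (r[k2] + v[k2])
  }
  q
}

#' SARSA update of model-free values
#'
#' Computes the reward prediction error
#' `RPE = r + Q(s', a') - Q(s, a)` (with `Q(s', a') = 0` at terminal
#' states) and increments `Q(s, a)` by `alpha * RPE`. No other entry
#' changes; the learner is insensitive to goal changes, the reward entering
#' the update is the realized goal-conditional reward.
#'
#' @param Q numeric vector of model-free values, one per (state, action)
#'   pair of the graph.
#' @param graph a `"task_graph"`.
#' @param s,a current state and action.
#' @param r realized reward (points).
#' @param s_next,a_next successor state and its action; both `NULL` when
#'   `s_next` is terminal.
#' @param alpha model-free learning rate in `[0, 1]`.
#' @return `list(Q = updated values, rpe = reward prediction error)`.
#' @export
sarsa_update <- function(Q, graph, s, a, r, s_next = NULL, a_next = NULL,
                         alpha) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]")
  pid <- graph$pair_id[s, a]
  if (pid == 0L) stop("unknown (state, action) pair: (", s, ", ", a, ")")
  q_next <- 0
  if (!is.null(s_next) && graph$stage[s_next] != 3L) {
    if (is.null(a_next)) stop("a_next required for a non-terminal successor")
    q_next <- Q[graph$pair_id[s_next, a_next]]
  }
  rpe <- r + q_next - Q[pid]
  Q[pid] <- Q[pid] + alpha * rpe
  list(Q = Q, rpe = rpe)
}
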