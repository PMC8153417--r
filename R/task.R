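#' Default task configuration
#'
#' Returns the configuration of the two-stage Markov decision task: coin
#' colours and values, transition probabilities per uncertainty condition,
#' block-length ranges, and session structure (one reward-free pre-training
#' session followed by four main sessions). All downstream computation reads
#' these values from the configuration; nothing is hard-coded.
#'
#' The default layout has one first-stage state, four second-stage states and
#' eight outcome slots. Coin point values (red 40, blue 20, yellow 10) and
#' the colour assignment of the outcome slots are package defaults, not task
#' constants, and can be overridden.
#'
#' @param ... named overrides of the default entries.
#' @return A list with class `"task_config"`.
#' @examples
#' cfg <- task_config()
#' cfg$transition_probs
#' @export
task_config <- function(...) {
  cfg <- list(
    coin_values = c(red = 40, blue = 20, yellow = 10),
    outcome_colors = c("red", "yellow", "blue", "red",
                       "yellow", "blue", "red", "yellow"),
    # probability of reaching the *first* listed successor of a (state,
    # action) pair; low uncertainty (0.9, 0.1), high uncertainty (0.5, 0.5)
    transition_probs = list(low = 0.9, high = 0.5),
    block_lengths = list(low = c(3L, 5L), high = c(5L, 7L)),
    n_pretraining = 100L,
    n_sessions = 4L,
    session_trials = 80L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown task_config entries: ",
                          paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  validate_task_config(cfg)
  class(cfg) <- "task_config"
  cfg
}

validate_task_config <- function(cfg) {
  for (u in c("low", "high")) {
    p <- cfg$transition_probs[[u]]
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("transition probability for '", u, "' must be in [0, 1]")
  }
  if (any(cfg$coin_values < 0)) stop("coin values must be >= 0")
  missing_cols <- setdiff(unique(cfg$outcome_colors), names(cfg$coin_values))
  if (length(missing_cols))
    stop("missing coin value for referenced color(s): ",
         paste(missing_cols, collapse = ", "))
  invisible(cfg)
}

#' Construct a task graph
#'
#' Low-level constructor for the two-stage state/action/outcome structure.
#' States are integer ids `1..n`; each non-terminal state has two actions
#' (`L` = 1, `R` = 2), and each (state, action) pair maps to an ordered pair
#' of distinct successor states. Stages are inferred: the unique state that
#' is never a successor is first-stage; its successors are second-stage; all
#' remaining states are outcome states and must carry a coin colour.
#'
#' @param pairs data.frame with integer columns `state`, `action` (1 or 2),
#'   `succ1`, `succ2`.
#' @param outcome_colors character vector, one colour per outcome state, in
#'   increasing order of outcome-state id.
#' @param coin_values named numeric vector of non-negative point values, one
#'   per colour referenced in `outcome_colors`.
#' @param states optional character labels, one per state id.
#' @return A list with class `"task_graph"`.
#' @seealso [build_task_graph()] for the default layout.
#' @export
task_graph <- function(pairs, outcome_colors, coin_values, states = NULL) {
  pairs <- as.data.frame(pairs)
  req <- c("state", "action", "succ1", "succ2")
  if (!all(req %in% names(pairs))) stop("pairs needs columns: ",
                                        paste(req, collapse = ", "))
  pairs[req] <- lapply(pairs[req], as.integer)
  if (any(pairs$succ1 == pairs$succ2))
    stop("each (state, action) pair must map to exactly 2 distinct successors")
  n_states <- max(pairs$state, pairs$succ1, pairs$succ2)

  succs <- unique(c(pairs$succ1, pairs$succ2))
  first <- setdiff(unique(pairs$state), succs)
  if (length(first) != 1L) stop("graph must have exactly one first-stage state")
  stage <- integer(n_states)
  stage[first] <- 1L
  s1_rows <- pairs$state == first
  stage2 <- sort(unique(c(pairs$succ1[s1_rows], pairs$succ2[s1_rows])))
  stage[stage2] <- 2L
  outcomes <- sort(setdiff(seq_len(n_states), c(first, stage2)))
  stage[outcomes] <- 3L
  if (any(stage[pairs$state] == 3L)) stop("outcome states cannot have actions")
  if (any(stage[c(pairs$succ1[s1_rows], pairs$succ2[s1_rows])] != 2L) ||
      any(stage[c(pairs$succ1[!s1_rows], pairs$succ2[!s1_rows])] != 3L))
    stop("graph is not a two-stage structure")
  for (s in c(first, stage2)) {
    acts <- sort(pairs$action[pairs$state == s])
    if (!identical(acts, c(1L, 2L)))
      stop("state ", s, " must have exactly actions 1 (L) and 2 (R)")
  }

  if (length(outcome_colors) != length(outcomes))
    stop("need exactly one coin color per outcome state (",
         length(outcomes), " outcomes, ", length(outcome_colors), " colors)")
  missing_cols <- setdiff(unique(outcome_colors), names(coin_values))
  if (length(missing_cols))
    stop("missing coin value for referenced color(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(coin_values < 0)) stop("coin values must be >= 0")

  pairs <- pairs[order(pairs$state, pairs$action), , drop = FALSE]
  rownames(pairs) <- NULL
  pair_id <- matrix(0L, n_states, 2L)
  for (i in seq_len(nrow(pairs)))
    pair_id[pairs$state[i], pairs$action[i]] <- i

  if (is.null(states)) {
    states <- character(n_states)
    states[stage != 3L] <- paste0("S", seq_len(sum(stage != 3L)))
    states[outcomes] <- paste0("O", seq_along(outcomes))
  }
  color_by_state <- rep(NA_character_, n_states)
  color_by_state[outcomes] <- outcome_colors

  structure(list(
    n_states = n_states,
    states = states,
    stage = stage,
    first_stage = first,
    stage2_states = stage2,
    outcome_states = outcomes,
    pairs = pairs,
    pair_id = pair_id,
    outcome_color = color_by_state,
    coin_values = coin_values
  ), class = "task_graph")
}

#' Build the default two-stage task graph
#'
#' The default layout follows the task: from the first-stage state `S1` a
#' left choice leads to `S2` or `S3` and a right choice to `S4` or `S5`.
#' Each second-stage state has its own pair of outcome slots; the two
#' actions reach the same pair in opposite order, so the layout has eight
#' outcome slots in total. Under low uncertainty (p = 0.9) each action
#' therefore mostly reaches "its" outcome, while under high uncertainty
#' (p = 0.5) the two actions are equivalent.
#'
#' @param config a [task_config()] (coin values, outcome colours).
#' @return A `"task_graph"`.
#' @examples
#' g <- build_task_graph()
#' g$states
#' @export
build_task_graph <- function(config = task_config()) {
  validate_task_config(config)
  s2 <- 2:5
  out0 <- 5L  # outcomes start at id 6
  rows <- list(data.frame(state = 1L, action = 1:2,
                          succ1 = c(2L, 4L), succ2 = c(3L, 5L)))
  for (k in seq_along(s2)) {
    o1 <- out0 + 2L * (k - 1L) + 1L
    o2 <- o1 + 1L
    rows[[k + 1L]] <- data.frame(state = s2[k], action = 1:2,
                                 succ1 = c(o1, o2), succ2 = c(o2, o1))
  }
  task_graph(do.call(rbind, rows), config$outcome_colors, config$coin_values)
}

#' Goal-conditional reward of an outcome state
#'
#' Under a specific goal the coin is redeemable only if its colour matches
#' the goal colour; under the flexible goal every coin is redeemable.
#'
#' @param outcome_state integer state id (or character label) of an outcome.
#' @param goal `"flexible"` or a coin colour.
#' @param graph a `"task_graph"`.
#' @return Reward in points (>= 0).
#' @export
goal_reward <- function(outcome_state, goal, graph) {
  s <- resolve_state(outcome_state, graph)
  if (graph$stage[s] != 3L)
    stop("state ", outcome_state, " is not an outcome state")
  col <- graph$outcome_color[s]
  v <- unname(graph$coin_values[col])
  if (identical(goal, "flexible")) return(v)
  if (!goal %in% names(graph$coin_values))
    stop("unknown goal: ", goal)
  if (identical(goal, col)) v else 0
}

# reward of every state under a goal (0 for non-outcome states)
goal_reward_vector <- function(graph, goal) {
  r <- numeric(graph$n_states)
  for (s in graph$outcome_states) r[s] <- goal_reward(s, goal, graph)
  r
}

# n_states x 4 matrix of rewards, columns in GOAL_LEVELS order
reward_matrix <- function(graph) {
  vapply(GOAL_LEVELS, function(g) goal_reward_vector(graph, g),
         numeric(graph$n_states))
}

resolve_state <- function(s, graph) {
  if (is.character(s)) {
    i <- match(s, graph$states)
    if (is.na(i)) stop("unknown state label: ", s)
    return(i)
  }
  s <- as.integer(s)
  if (s < 1L || s > graph$n_states) stop("state id out of range: ", s)
  s
}

#' Sample a state transition
#'
#' Returns the first listed successor of `(state, action)` with probability
#' `p` and the second with probability `1 - p`, where `p` is the setting for
#' the trial's uncertainty condition. Uses R's RNG, so results are
#' reproducible under [set.seed()].
#'
#' @param graph a `"task_graph"`.
#' @param state,action non-terminal state id and action (1 = L, 2 = R).
#' @param uncertainty `"low"` or `"high"`.
#' @param transition_probs named list giving, per uncertainty condition, the
#'   probability of the first successor.
#' @return Integer id of the sampled successor.
#' @export
sample_transition <- function(graph, state, action,
                              uncertainty = c("low", "high"),
                              transition_probs = list(low = 0.9, high = 0.5)) {
  uncertainty <- match.arg(uncertainty)
  s <- resolve_state(state, graph)
  if (graph$stage[s] == 3L) stop("cannot transition from a terminal state")
  pid <- graph$pair_id[s, action]
  if (pid == 0L) stop("unknown (state, action) pair")
  p <- transition_probs[[uncertainty]]
  if (stats::runif(1) <= p) graph$pairs$succ1[pid] else graph$pairs$succ2[pid]
}

#' Pseudo-random block schedule
#'
#' Draws blocks of the four condition types (2 goal classes x 2 uncertainty
#' levels) until the requested trial total is reached. Block lengths are
#' uniform on 3-5 trials for low-uncertainty blocks and 5-7 for
#' high-uncertainty blocks; the same condition type never repeats more than
#' twice in a row, and every schedule contains all four types. Specific-goal
#' blocks are assigned a coin colour uniformly at random.
#'
#' @param n_trials_target minimum number of trials (>= 20); the schedule may
#'   overshoot by at most one block.
#' @param seed optional integer seed (calls [set.seed()]).
#' @param config a [task_config()] supplying block-length ranges and colours.
#' @return data.frame with columns `block`, `goal_class`, `goal`,
#'   `uncertainty`, `n_trials`.
#' @export
make_block_schedule <- function(n_trials_target, seed = NULL,
                                config = task_config()) {
  if (!is.numeric(n_trials_target) || n_trials_target < 20)
    stop("n_trials_target must be >= 20")
  if (!is.null(seed)) set.seed(seed)
  colors <- names(config$coin_values)
  types <- expand.grid(goal_class = c("flexible", "specific"),
                       uncertainty = c("low", "high"),
                       stringsAsFactors = FALSE)
  repeat {
    type_seq <- integer(0)
    total <- 0L
    lens <- integer(0)
    while (total < n_trials_target) {
      allowed <- 1:4
      k <- length(type_seq)
      if (k >= 2 && type_seq[k] == type_seq[k - 1])
        allowed <- setdiff(allowed, type_seq[k])
      t_i <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
      rng <- config$block_lengths[[types$uncertainty[t_i]]]
      len <- sample(seq(rng[1], rng[2]), 1L)
      type_seq <- c(type_seq, t_i)
      lens <- c(lens, len)
      total <- total + len
    }
    if (length(unique(type_seq)) == 4L) break
  }
  goal_class <- types$goal_class[type_seq]
  goal <- ifelse(goal_class == "flexible", "flexible",
                 sample(colors, length(type_seq), replace = TRUE))
  data.frame(block = seq_along(type_seq),
             goal_class = goal_class,
             goal = goal,
             uncertainty = types$uncertainty[type_seq],
             n_trials = lens,
             stringsAsFactors = FALSE)
}

#' Trial-level session plan
#'
#' Expands block schedules into one row per trial for the full experiment:
#' a pre-training session (session 0) followed by the main sessions, per the
#' session structure in the task configuration (default 100 + 4 x ~80
#' trials).
#'
#' @param config a [task_config()].
#' @param seed optional integer seed.
#' @return data.frame with columns `session`, `trial`, `is_pretraining`,
#'   `goal_class`, `goal`, `uncertainty`.
#' @export
make_session_plan <- function(config = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one_session <- function(session, target, is_pre) {
    sched <- make_block_schedule(max(target, 20L), seed = NULL,
                                 config = config)
    idx <- rep(seq_len(nrow(sched)), sched$n_trials)
    # pre-training has a fixed length; main sessions keep whole blocks
    if (is_pre) idx <- idx[seq_len(target)]
    data.frame(session = session,
               trial = seq_along(idx),
               is_pretraining = is_pre,
               goal_class = sched$goal_class[idx],
               goal = sched$goal[idx],
               uncertainty = sched$uncertainty[idx],
               stringsAsFactors = FALSE)
  }
  out <- list(one_session(0L, config$n_pretraining, TRUE))
  for (s in seq_len(config$n_sessions))
    out[[s + 1L]] <- one_session(s, config$session_trials, FALSE)
  do.call(rbind, out)
}
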