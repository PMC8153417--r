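#' Accumulated reward
#'
#' Total points earned over the main sessions (pre-training is reward-free
#' and excluded).
#'
#' @param trials a trial log data.frame for one subject.
#' @return Total points.
#' @export
accumulated_reward <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0) stop("empty trial log")
  sum(trials$reward[!trials$is_pretraining])
}

#' Ideal-agent policy at a state
#'
#' The ideal agent has full, immediate access to the environmental
#' structure: the true transition probabilities of the trial's uncertainty
#' condition and the current goal. Its policy is greedy over true expected
#' reward, with ties split uniformly over the argmax set (the correction
#' for the number of available options, making chance level 0.5 at binary
#' states).
#'
#' @param graph a `"task_graph"`.
#' @param state a first- or second-stage state id.
#' @param goal,uncertainty the trial's conditions.
#' @param transition_probs true successor probabilities per uncertainty
#'   level.
#' @param tol values within `tol` of the maximum count as tied.
#' @return Probability vector over the two actions.
#' @export
ideal_policy <- function(graph, state, goal, uncertainty,
                         transition_probs = list(low = 0.9, high = 0.5),
                         tol = 1e-9) {
  p <- transition_probs[[uncertainty]]
  T_true <- matrix(c(p, 1 - p), nrow(graph$pairs), 2, byrow = TRUE)
  q <- plan_mb_values(T_true, graph, goal)
  qs <- q[graph$pair_id[state, ]]
  best <- qs >= max(qs) - tol
  best / sum(best)
}

#' Choice optimality
#'
#' Mean likelihood the ideal agent assigns to the subject's actual choices:
#' per decision, 1 for the unique greedy action, 1/2 under a two-way tie,
#' 0 otherwise; averaged over all main-session decisions (both stages) and
#' broken down by goal-class x uncertainty condition. A behavioural
#' read-out of model-based control.
#'
#' @inheritParams accumulated_reward
#' @param graph a `"task_graph"`.
#' @param transition_probs the true generating transition probabilities.
#' @return `list(overall, by_condition, per_decision)`.
#' @export
choice_optimality <- function(trials, graph,
                              transition_probs = list(low = 0.9, high = 0.5)) {
  main <- trials[!trials$is_pretraining, , drop = FALSE]
  if (nrow(main) == 0) stop("no main-session trials")
  if (anyNA(main$goal)) stop("goal missing for some trials")
  enc <- encode_trials(main, graph)
  score <- matrix(NA_real_, nrow(main), 2)
  for (t in seq_len(nrow(main))) {
    pi1 <- ideal_policy(graph, enc$s1[t], main$goal[t], main$uncertainty[t],
                        transition_probs)
    pi2 <- ideal_policy(graph, enc$s2[t], main$goal[t], main$uncertainty[t],
                        transition_probs)
    score[t, 1] <- pi1[enc$a1[t]]
    score[t, 2] <- pi2[enc$a2[t]]
  }
  per_trial <- rowMeans(score)
  gc <- ifelse(main$goal == "flexible", "flexible", "specific")
  by_cond <- aggregate(list(optimality = per_trial),
                       list(goal_class = gc, uncertainty = main$uncertainty),
                       mean)
  list(overall = mean(score), by_condition = by_cond,
       per_decision = score)
}

#' First-stage choice consistency
#'
#' Proportion of main-session trials whose first-stage choice repeats the
#' previous trial's, computed within sessions (no carry-over across session
#' boundaries) and broken down by the condition of the current trial. A
#' behavioural read-out of model-free/habitual control.
#'
#' @inheritParams accumulated_reward
#' @return `list(overall, by_condition, per_trial)` where `per_trial` has
#'   one row per evaluable trial (t >= 2 within a session).
#' @export
choice_consistency <- function(trials) {
  main <- trials[!trials$is_pretraining, , drop = FALSE]
  if (nrow(main) < 2) stop("need at least 2 main trials")
  rows <- list()
  for (s in unique(main$session)) {
    ses <- main[main$session == s, , drop = FALSE]
    if (nrow(ses) < 2) next
    t2 <- 2:nrow(ses)
    rows[[as.character(s)]] <- data.frame(
      session = s,
      same = ses$a1[t2] == ses$a1[t2 - 1],
      goal_class = ifelse(ses$goal[t2] == "flexible", "flexible", "specific"),
      uncertainty = ses$uncertainty[t2],
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  if (is.null(per)) stop("need at least 2 main trials within a session")
  by_cond <- aggregate(list(consistency = as.numeric(per$same)),
                       list(goal_class = per$goal_class,
                            uncertainty = per$uncertainty), mean)
  list(overall = mean(per$same), by_condition = by_cond, per_trial = per)
}

#' Choice-probability calibration curve
#'
#' Bins decisions by the model's predicted probability of choosing right
#' and reports, per bin, the empirical proportion of right choices. For a
#' well-calibrated model the empirical proportions track the predicted
#' probabilities.
#'
#' @param p_right model probabilities of the right action, in `[0, 1]`.
#' @param chose_right logical (or 0/1) vector of the same length.
#' @param n_bins number of equal-width bins (>= 2).
#' @return data.frame `bin`, `lower`, `upper`, `mean_p`, `prop_right`, `n`;
#'   empty bins carry `NA` and `n = 0`.
#' @export
calibration_curve <- function(p_right, chose_right, n_bins = 10L) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (any(p_right < 0 | p_right > 1)) stop("probabilities must be in [0, 1]")
  chose_right <- as.numeric(chose_right)
  br <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(p_right, br, rightmost.closed = TRUE)
  out <- data.frame(bin = seq_len(n_bins), lower = br[-length(br)],
                    upper = br[-1], mean_p = NA_real_,
                    prop_right = NA_real_, n = 0L)
  for (b in seq_len(n_bins)) {
    sel <- idx == b
    out$n[b] <- sum(sel)
    if (out$n[b] > 0) {
      out$mean_p[b] <- mean(p_right[sel])
      out$prop_right[b] <- mean(chose_right[sel])
    }
  }
  out
}

#' Condition breakdown with a 2 x 2 factorial test
#'
#' Cell means of a trial-level measure over goal-class x uncertainty, with
#' main-effect and interaction F statistics from the standard two-way
#' analysis-of-variance decomposition.
#'
#' @param values numeric trial-level measure.
#' @param goal_class,uncertainty factors of the same length as `values`.
#' @return `list(cell_means, anova)` where `anova` has one row per term
#'   (`goal_class`, `uncertainty`, `goal_class:uncertainty`) with `df`,
#'   `F`, `p`.
#' @export
condition_breakdown <- function(values, goal_class, uncertainty) {
  goal_class <- factor(goal_class)
  uncertainty <- factor(uncertainty)
  if (nlevels(goal_class) < 2 || nlevels(uncertainty) < 2 ||
      any(table(goal_class, uncertainty) == 0))
    stop("every goal-class x uncertainty cell must be occupied")
  cells <- tapply(values, list(goal_class, uncertainty), mean)
  fit <- aov(values ~ goal_class * uncertainty)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  list(cell_means = cells,
       anova = data.frame(term = terms[keep], df = s$Df[keep],
                          F = s$`F value`[keep], p = s$`Pr(>F)`[keep],
                          row.names = NULL))
}

#' Correlate per-subject values with a covariate score
#'
#' Pearson correlation for behavioural measures; Spearman for fitted model
#' parameters (right-skewed by their lower bound at 0).
#'
#' @param values,scores numeric vectors, one entry per subject (n >= 4).
#' @param method `"pearson"` or `"spearman"`.
#' @return `list(estimate, p_value, method, n)`.
#' @export
correlate_with_score <- function(values, scores,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(values) != length(scores)) stop("length mismatch")
  if (length(values) < 4) stop("need at least 4 subjects")
  if (stats::sd(values) == 0 || stats::sd(scores) == 0)
    stop("zero variance in values or scores")
  ct <- cor.test(values, scores, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(values))
}
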