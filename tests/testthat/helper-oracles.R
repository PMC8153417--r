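# Shared fixtures and independent oracles for the test suite.

default_graph <- build_task_graph()
default_config <- task_config()

t3_par <- function(alpha_mb = 0.5, alpha_mf = 0.4, eta = 0.2, A_beta = 1,
                   A_gamma = 1, tau_mb = 0.3, tau_mf = 0.1) {
  c(alpha_mb = alpha_mb, alpha_mf = alpha_mf, eta = eta, A_beta = A_beta,
    A_gamma = A_gamma, tau_mb = tau_mb, tau_mf = tau_mf)
}

# random small two-stage graph: 2-4 second-stage states, private outcome
# pairs, random colours and coin values
random_small_graph <- function() {
  n2 <- sample(2:4, 1)
  s2 <- 1 + seq_len(n2)
  # stage-1 successor pairs: distinct states per action, jointly covering
  # every second-stage state (otherwise the graph is not two-stage)
  p1 <- sample(s2, 2)
  rest <- setdiff(s2, p1)
  p2 <- switch(as.character(n2),
               "2" = sample(s2, 2),
               "3" = sample(c(rest, sample(p1, 1))),
               "4" = sample(rest))
  out0 <- 1 + n2
  rows <- list(data.frame(state = 1L, action = 1:2,
                          succ1 = c(p1[1], p2[1]), succ2 = c(p1[2], p2[2])))
  for (k in seq_len(n2)) {
    o1 <- out0 + 2L * (k - 1L) + 1L
    rows[[k + 1L]] <- data.frame(state = s2[k], action = 1:2,
                                 succ1 = c(o1, o1 + 1L),
                                 succ2 = c(o1 + 1L, o1))
  }
  colors <- sample(c("red", "blue", "yellow"), 2L * n2, replace = TRUE)
  vals <- c(red = runif(1, 5, 50), blue = runif(1, 5, 50),
            yellow = runif(1, 5, 50))
  task_graph(do.call(rbind, rows), colors, vals)
}

random_T <- function(graph) {
  p <- runif(nrow(graph$pairs))
  cbind(p, 1 - p)
}

# brute-force oracle for plan_mb_values: enumerate every deterministic
# second-stage policy, score it by explicit path enumeration, take the max
mb_path_oracle <- function(T, graph, goal) {
  r <- numeric(graph$n_states)
  for (s in graph$outcome_states) r[s] <- goal_reward(s, goal, graph)
  s2 <- graph$stage2_states
  policies <- as.matrix(expand.grid(rep(list(1:2), length(s2))))
  q <- numeric(nrow(graph$pairs))
  # stage-2 values by direct expectation
  for (i in which(graph$stage[graph$pairs$state] == 2L))
    q[i] <- T[i, 1] * r[graph$pairs$succ1[i]] + T[i, 2] * r[graph$pairs$succ2[i]]
  for (a in 1:2) {
    pid <- graph$pair_id[graph$first_stage, a]
    best <- -Inf
    for (row in seq_len(nrow(policies))) {
      ev <- 0
      for (j in 1:2) {
        s <- graph$pairs[[paste0("succ", j)]][pid]
        a2 <- policies[row, match(s, s2)]
        pid2 <- graph$pair_id[s, a2]
        for (k in 1:2)
          ev <- ev + T[pid, j] * T[pid2, k] *
            r[graph$pairs[[paste0("succ", k)]][pid2]]
      }
      best <- max(best, ev)
    }
    q[pid] <- best
  }
  q
}

# posterior mean/variance of Beta(a, b) by numerical integration of the
# unnormalized density (no closed-form moments used)
chi_numeric_oracle <- function(n0, n1, prior = c(1, 1)) {
  moments <- function(a, b) {
    dens <- function(th) th^(a - 1) * (1 - th)^(b - 1)
    z <- integrate(dens, 0, 1)$value
    m <- integrate(function(th) th * dens(th), 0, 1)$value / z
    m2 <- integrate(function(th) th^2 * dens(th), 0, 1)$value / z
    c(mean = m, var = m2 - m^2)
  }
  m0 <- moments(prior[1] + n0, prior[2] + n1)
  m1 <- moments(prior[1] + n1, prior[2] + n0)
  chi0 <- m0["mean"] / m0["var"]
  chi1 <- m1["mean"] / m1["var"]
  unname(chi0 / (chi0 + chi1))
}

# quick simulated log for likelihood tests (short sessions)
quick_log <- function(par = t3_par(), seed = 1, model = "Arb_a_t3",
                      n_pre = 20L, n_sessions = 2L, session_trials = 30L) {
  cfg <- task_config(n_pretraining = n_pre, n_sessions = n_sessions,
                     session_trials = session_trials)
  simulate_subject(par, model = model, config = cfg, seed = seed)$trials
}

# sequential (type-I) sums-of-squares F statistics for a balanced 2x2
# design, computed from first principles
anova_ss_oracle <- function(values, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  n <- length(values)
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  m1 <- tapply(values, f1, mean)
  ss1 <- sum(table(f1) * (m1 - gm)^2)
  m2 <- tapply(values, f2, mean)
  ss2 <- sum(table(f2) * (m2 - gm)^2)
  m12 <- tapply(values, list(f1, f2), mean)
  ss_cells <- sum(table(f1, f2) * (m12 - gm)^2)
  ss_int <- ss_cells - ss1 - ss2
  ss_res <- ss_total - ss_cells
  df_res <- n - nlevels(f1) * nlevels(f2)
  data.frame(term = c("f1", "f2", "int"),
             F = c(ss1 / (nlevels(f1) - 1), ss2 / (nlevels(f2) - 1),
                   ss_int / ((nlevels(f1) - 1) * (nlevels(f2) - 1))) /
               (ss_res / df_res))
}
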