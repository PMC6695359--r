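# Small protocols for structural tests; acceptance tests use full-size runs.
tiny_protocol <- function(...) {
  protocol(n_sessions = 2, trials_per_session = 10, ...)
}

# Independent brute-force Bellman fixed-point iteration over explicit
# (state, action) tables, written against task_edges() only (different loop
# order and data layout than the package solver).
brute_force_q <- function(model, gamma, n_iter = 300) {
  edges <- task_edges(model$task)
  q <- stats::setNames(numeric(nrow(edges)), paste(edges$state, edges$action))
  for (it in seq_len(n_iter)) {
    q_old <- q
    for (i in sample(nrow(edges))) { # deliberate scrambled update order
      s_next <- edges$next_state[i]
      cont <- 0
      if (!is.na(s_next)) {
        rows <- which(edges$state == s_next)
        cont <- max(q_old[rows])
      }
      t_i <- mb_transition(model, edges$state[i], edges$action[i], s_next)
      q[i] <- mb_reward(model, edges$state[i], edges$action[i]) +
        gamma * t_i * cont
    }
  }
  q
}

# Force an FMF learner through one complete trial path of a task, applying
# the prediction-error and value updates at every transition and the ITI
# revision at the end. Used for closed-form learning-curve checks.
force_fmf_path <- function(values, task, actions_by_state, gamma, alpha,
                           u_iti) {
  state <- task$start
  repeat {
    action <- actions_by_state[[state]]
    step <- task_step(task, state, action)
    next_features <- if (is.na(step$next_state)) {
      NULL
    } else {
      task_edges(task)$feature[task_edges(task)$state == step$next_state]
    }
    delta <- fmf_rpe(values, step$reward, step$feature, next_features, gamma)
    values <- fmf_update(values, step$feature, delta, alpha)
    if (is.na(step$next_state)) break
    state <- step$next_state
  }
  fmf_iti_revision(values, u_iti)
}

sign_path_policy <- list(
  s0 = "goE", s1 = "goL", s2 = "eng", s5 = "goM", s7 = "eat"
)
goal_path_policy <- list(s0 = "goE", s1 = "goM", s4 = "eng", s7 = "eat")
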