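#' World model of the Model-Based system
#'
#' The Model-Based (MB) learner estimates the structure of the task: a
#' transition function `T(s, a, s')` and a reward function `R(s, a)`, both
#' initialized at 0 and updated incrementally from observed transitions.
#' Because the task is deterministic, each state-action pair has a unique
#' successor, so only the observed triple of a pair ever acquires
#' probability mass; `T` converges to 1 on every repeatedly visited possible
#' transition and stays 0 on impossible ones. The model is stored per
#' state-action edge of the task graph, which is exactly the set of triples
#' that can ever be observed.
#'
#' @param task An [stgt_task][task_standard].
#' @return An object of class `stgt_world_model`: the task plus numeric
#'   vectors `t` and `r` aligned with `task_edges(task)`.
#' @examples
#' m <- world_model(task_standard())
#' m <- mb_update_transition(m, "s0", "goE", "s1", alpha = 0.03)
#' mb_transition(m, "s0", "goE", "s1")
#' @export
world_model <- function(task) {
  stopifnot(inherits(task, "stgt_task"))
  structure(
    list(task = task, t = numeric(nrow(task$edges)), r = numeric(nrow(task$edges))),
    class = "stgt_world_model"
  )
}

edge_index <- function(model, state, action) {
  i <- which(model$task$edges$state == state & model$task$edges$action == action)
  if (length(i) != 1L) {
    stop(sprintf("action '%s' is not available in state '%s'", action, state),
      call. = FALSE
    )
  }
  i
}

#' Update the learned transition function
#'
#' Applies `T(s, a, s') <- (1 - alpha) * T(s, a, s') + alpha` to the
#' observed triple only; no other triple is touched and rows are not
#' renormalized. After `n` consecutive observations from 0 the estimate is
#' `1 - (1 - alpha)^n`.
#'
#' @param model An [world_model] object.
#' @param state,action The state-action pair taken.
#' @param next_state The observed successor state (`NA` for trial end).
#' @param alpha Learning rate in `[0, 1]`.
#' @return The updated model.
#' @export
mb_update_transition <- function(model, state, action, next_state, alpha) {
  stopifnot(inherits(model, "stgt_world_model"), alpha >= 0, alpha <= 1)
  i <- edge_index(model, state, action)
  expected <- model$task$edges$next_state[i]
  if (!identical(next_state, expected) && !(is.na(next_state) && is.na(expected))) {
    stop(sprintf(
      "observed successor '%s' is impossible: (%s, %s) leads to '%s'",
      next_state, state, action, expected
    ), call. = FALSE)
  }
  model$t[i] <- (1 - alpha) * model$t[i] + alpha
  model
}

#' Update the learned reward function
#'
#' Applies `R(s, a) <- R(s, a) + alpha * (r - R(s, a))`. Since the eat
#' action is the only rewarded one and occurs exactly once per trial,
#' `R(s7, eat)` after `n` trials equals `1 - (1 - alpha)^n`.
#'
#' @inheritParams mb_update_transition
#' @param reward Observed reward, 0 or 1.
#' @return The updated model.
#' @export
mb_update_reward <- function(model, state, action, reward, alpha) {
  stopifnot(inherits(model, "stgt_world_model"), alpha >= 0, alpha <= 1)
  i <- edge_index(model, state, action)
  model$r[i] <- model$r[i] + alpha * (reward - model$r[i])
  model
}

#' Transition- and reward-function accessors
#'
#' `mb_transition()` returns the learned probability of a triple
#' `(state, action, next_state)`; triples that cannot occur in the
#' deterministic graph are never updated and report 0. `mb_reward()` returns
#' the learned reward of a state-action pair.
#'
#' @inheritParams mb_update_transition
#' @return A scalar estimate.
#' @export
mb_transition <- function(model, state, action, next_state) {
  stopifnot(inherits(model, "stgt_world_model"))
  i <- which(model$task$edges$state == state & model$task$edges$action == action)
  if (length(i) != 1L) {
    return(0)
  }
  expected <- model$task$edges$next_state[i]
  same <- identical(next_state, expected) || (is.na(next_state) && is.na(expected))
  if (same) model$t[i] else 0
}

#' @rdname mb_transition
#' @export
mb_reward <- function(model, state, action) {
  stopifnot(inherits(model, "stgt_world_model"))
  model$r[edge_index(model, state, action)]
}

#' Ideal (fully learned) world model
#'
#' Convenience constructor of the asymptotic model: `T = 1` on every edge of
#' the graph and `R = 1` on the eat action, 0 elsewhere. Useful for
#' analysing the structural preferences of the MB system independently of
#' learning transients.
#'
#' @param task An [stgt_task][task_standard].
#' @return An `stgt_world_model`.
#' @export
world_model_ideal <- function(task) {
  model <- world_model(task)
  model$t[] <- 1
  model$r[task$compiled$eat_edge] <- 1
  model
}

#' Solve the Bellman action values of a world model
#'
#' Computes the fixed point of
#' \deqn{Q(s, a) = R(s, a) + \gamma \sum_{s'} T(s, a, s') \max_k Q(s', a_k)}
#' by synchronous value iteration until the largest absolute change falls
#' below `tol`, and derives the advantage
#' `A(s, a) = Q(s, a) - max_j Q(s, a_j)`, the relative worth of each action
#' within its state: 0 for the best action, negative otherwise. A trial-end
#' transition contributes no continuation value, so `Q(s7, eat)` converges
#' to `R(s7, eat)` exactly. On this acyclic graph value iteration reaches
#' the exact fixed point after at most depth-many sweeps; the iteration cap
#' is a safety net.
#'
#' @param model An [world_model] object.
#' @param gamma Discount factor in `[0, 1)`.
#' @param tol Convergence tolerance on the sup-norm change (default 1e-9).
#' @param max_iter Iteration cap (default 10000).
#' @return A tibble of class `stgt_qtable` with columns `state`, `action`,
#'   `q` and `advantage`.
#' @examples
#' q <- mb_solve_q(world_model_ideal(task_standard()), gamma = 0.8)
#' subset(q, state == "s1")
#' @export
mb_solve_q <- function(model, gamma, tol = 1e-9, max_iter = 10000L) {
  stopifnot(inherits(model, "stgt_world_model"), gamma >= 0, gamma < 1, tol > 0)
  ct <- model$task$compiled
  q <- solve_q_compiled(ct, model$t, model$r, gamma, tol, max_iter)
  adv <- q - state_max(q, ct)[ct$from_i]
  out <- tibble::tibble(
    state = model$task$edges$state,
    action = model$task$edges$action,
    q = q,
    advantage = adv
  )
  class(out) <- c("stgt_qtable", class(out))
  out
}

#' Advantage of each action in a state
#'
#' @param q An `stgt_qtable` from [mb_solve_q()].
#' @param state A state identifier.
#' @return Named numeric vector of advantages over the actions of `state`.
#' @export
mb_advantage <- function(q, state) {
  stopifnot(inherits(q, "stgt_qtable"))
  rows <- q$state == state
  if (!any(rows)) stop(sprintf("unknown or terminal state '%s'", state), call. = FALSE)
  stats::setNames(q$advantage[rows], q$action[rows])
}

# max_a Q(s, a) per state (0 for states without actions, unused here since
# every state in the edge table has at least one action)
state_max <- function(q, ct) {
  vapply(ct$state_edges, function(es) if (length(es)) max(q[es]) else 0, numeric(1))
}

# Synchronous value iteration on the compiled edge representation. In the
# deterministic graph T has a single successor per edge, so the Bellman sum
# collapses to one term.
solve_q_compiled <- function(ct, t, r, gamma, tol, max_iter, q = NULL) {
  if (is.null(q)) q <- numeric(length(t))
  nonterm <- ct$to_i > 0L
  to_nt <- ct$to_i[nonterm]
  for (iter in seq_len(max_iter)) {
    vs <- state_max(q, ct)
    cont <- numeric(length(q))
    cont[nonterm] <- vs[to_nt]
    q_new <- r + gamma * t * cont
    if (max(abs(q_new - q)) < tol) {
      return(q_new)
    }
    q <- q_new
  }
  stop("value iteration did not converge within the iteration cap",
    call. = FALSE
  )
}

#' @export
print.stgt_world_model <- function(x, ...) {
  cat(sprintf(
    "<stgt_world_model> over %s task (%d state-action pairs)\n",
    x$task$variant, length(x$t)
  ))
  print(tibble::tibble(
    state = x$task$edges$state, action = x$task$edges$action,
    next_state = x$task$edges$next_state, t = x$t, r = x$r
  ), n = length(x$t))
  invisible(x)
}
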