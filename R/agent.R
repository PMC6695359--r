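#' Agent parameters
#'
#' Bundles and validates the five parameters of the hybrid agent. The
#' defaults are the canonical values used throughout the simulations:
#' shared learning rate `alpha = 0.03` and discount `gamma = 0.8` for both
#' learning systems, softmax temperature `tau = 0.15`, and an ITI update
#' factor of 0.01 (short ITI) or 0.1 (long ITI). `omega` weighs the two
#' systems in behaviour: 1 is a pure Feature-Model-Free (sign-tracking
#' prone) controller, 0 a pure Model-Based (goal-tracking prone) one. Both
#' systems always learn from every observed transition; `omega` only gates
#' which system drives choice.
#'
#' @param alpha Learning rate in `[0, 1]`, shared by both systems.
#' @param gamma Discount factor in `[0, 1)`, shared by both systems.
#' @param tau Softmax temperature, > 0; larger values flatten choice
#'   probabilities towards uniform.
#' @param u_iti ITI update factor in `[0, 1]`; 0.01 encodes a short ITI,
#'   0.1 a long one.
#' @param omega Integration weight in `[0, 1]`, fixed per individual.
#' @return A list of class `stgt_params`.
#' @examples
#' agent_params(omega = 1, u_iti = 0.1) # FMF-only agent, long ITI
#' @export
agent_params <- function(alpha = 0.03, gamma = 0.8, tau = 0.15,
                         u_iti = 0.1, omega = 0.5) {
  check_range <- function(x, nm, lo, hi, hi_open = FALSE) {
    bad <- !is.numeric(x) || length(x) != 1L || is.na(x) || x < lo ||
      (if (hi_open) x >= hi else x > hi)
    if (bad) {
      stop(sprintf(
        "'%s' must be a single number in [%s, %s%s", nm, lo, hi,
        if (hi_open) ")" else "]"
      ), call. = FALSE)
    }
  }
  check_range(alpha, "alpha", 0, 1)
  check_range(gamma, "gamma", 0, 1, hi_open = TRUE)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("'tau' must be a single positive number", call. = FALSE)
  }
  check_range(u_iti, "u_iti", 0, 1)
  check_range(omega, "omega", 0, 1)
  structure(
    list(alpha = alpha, gamma = gamma, tau = tau, u_iti = u_iti, omega = omega),
    class = "stgt_params"
  )
}

#' @export
print.stgt_params <- function(x, ...) {
  cat(sprintf(
    "<stgt_params> alpha=%g gamma=%g tau=%g u_iti=%g omega=%g\n",
    x$alpha, x$gamma, x$tau, x$u_iti, x$omega
  ))
  invisible(x)
}

#' Integrate the two systems' action preferences
#'
#' Weighted sum `P(s, a) = (1 - omega) * A(s, a) + omega * V(f(s, a))` of
#' the MB advantages and the FMF values of the features each action is
#' directed at.
#'
#' @param advantages Named numeric vector of MB advantages per action.
#' @param feature_values Named numeric vector of FMF values of each
#'   action's feature, over the same action set.
#' @param omega Integration weight in `[0, 1]`.
#' @return Named numeric vector of integrated preferences.
#' @export
integrate_values <- function(advantages, feature_values, omega) {
  stopifnot(omega >= 0, omega <= 1)
  if (is.null(names(advantages)) || is.null(names(feature_values)) ||
    !setequal(names(advantages), names(feature_values))) {
    stop("'advantages' and 'feature_values' must be named over the same actions",
      call. = FALSE
    )
  }
  feature_values <- feature_values[names(advantages)]
  (1 - omega) * advantages + omega * feature_values
}

#' Softmax choice probabilities
#'
#' `p(a_i) = exp(P_i / tau) / sum_j exp(P_j / tau)`, computed with
#' max-subtraction for overflow safety.
#'
#' @param x Numeric vector of integrated action preferences.
#' @param tau Temperature, > 0.
#' @return Probability vector of the same length and names as `x`; strictly
#'   positive, summing to 1.
#' @export
softmax_probs <- function(x, tau) {
  stopifnot(is.numeric(x), length(x) >= 1L, tau > 0)
  z <- (x - max(x)) / tau
  p <- exp(z)
  p / sum(p)
}

#' Create a hybrid agent
#'
#' Binds a task, a parameter set and a fresh learning state (zero feature
#' values except the pinned food value, zero world model). The agent is an
#' immutable value: [run_trial()] returns an updated copy.
#'
#' @param task An [stgt_task][task_standard].
#' @param params An [agent_params] object.
#' @return A list of class `stgt_agent` with elements `task`, `params` and
#'   `state` (feature values `V`, transition `t` and reward `r` estimates,
#'   and the current Bellman solution `q`).
#' @export
stgt_agent <- function(task, params = agent_params()) {
  stopifnot(inherits(task, "stgt_task"), inherits(params, "stgt_params"))
  n_edges <- nrow(task$edges)
  list_state <- list(
    V = c(E = 0, L = 0, M = 0, F = 1),
    t = numeric(n_edges),
    r = numeric(n_edges),
    q = numeric(n_edges)
  )
  structure(list(task = task, params = params, state = list_state),
    class = "stgt_agent"
  )
}

#' Run one trial of a hybrid agent
#'
#' Executes one complete trial: at each visited state the agent solves the
#' Bellman values of its current world model, computes advantages, reads the
#' FMF values of the available actions' features, integrates them by
#' `omega`, samples an action from the softmax, steps the task, computes the
#' prediction error, and updates the feature values, the transition function
#' and the reward function (decisions always use the estimates from before
#' that transition's updates). After the trial ends, the ITI revision of
#' magazine and environment values is applied once.
#'
#' Uses R's global random number generator; seed it with [set.seed()] for
#' reproducibility.
#'
#' @param agent An [stgt_agent].
#' @return A list with `agent` (updated) and `record`, a one-row tibble in
#'   the trial-log format (see [run_subject()]).
#' @examples
#' set.seed(1)
#' a <- stgt_agent(task_standard(), agent_params(omega = 1))
#' out <- run_trial(a)
#' out$record$cs_choice
#' @export
run_trial <- function(agent) {
  stopifnot(inherits(agent, "stgt_agent"))
  rec <- trial_record_buffer(1L)
  st <- sim_one_trial(
    agent$task$compiled, agent$params, agent$state,
    agent$task$edges$action, rec, 1L
  )
  agent$state <- st
  rec$session <- 1L
  rec$trial <- 1L
  list(agent = agent, record = finish_records(rec, agent$task, agent$params))
}

# ---- internal simulation engine -------------------------------------------
# Plain-vector trial loop shared by run_trial() and run_subject(). `rec` is
# an environment of preallocated per-trial vectors filled at slot `i`.

trial_record_buffer <- function(n) {
  e <- new.env(parent = emptyenv())
  e$cs_choice <- character(n)
  e$second_choice <- rep(NA_character_, n)
  e$path <- character(n)
  e$delta_cs <- rep(NA_real_, n)
  e$delta_us <- rep(NA_real_, n)
  e$delta_eat <- rep(NA_real_, n)
  e$p_goL <- rep(NA_real_, n)
  e$p_goM <- rep(NA_real_, n)
  e$p_goE <- rep(NA_real_, n)
  e$a_goL <- rep(NA_real_, n)
  e$a_goM <- rep(NA_real_, n)
  e$a_goE <- rep(NA_real_, n)
  e$v_E <- numeric(n)
  e$v_L <- numeric(n)
  e$v_M <- numeric(n)
  e
}

sim_one_trial <- function(ct, params, st, edge_actions, rec, i) {
  alpha <- params$alpha
  gamma <- params$gamma
  tau <- params$tau
  omega <- params$omega
  s <- ct$start_i
  first_step <- TRUE
  repeat {
    st$q <- solve_q_compiled(ct, st$t, st$r, gamma, 1e-9, 10000L, st$q)
    es <- ct$state_edges[[s]]
    if (length(es) > 1L) {
      qs <- st$q[es]
      adv <- qs - max(qs)
      vf <- st$V[ct$feat_i[es]]
      pref <- (1 - omega) * adv + omega * vf
      z <- (pref - max(pref)) / tau
      pr <- exp(z)
      pr <- pr / sum(pr)
      k <- sample.int(length(es), 1L, prob = pr)
    } else {
      adv <- 0
      pr <- 1
      k <- 1L
    }
    e <- es[k]
    if (s == ct$cs_state_i) {
      acts <- edge_actions[es]
      rec$cs_choice[i] <- acts[k]
      pm <- match(c("goL", "goM", "goE"), acts)
      rec$p_goL[i] <- pr[pm[1L]]
      rec$p_goM[i] <- pr[pm[2L]]
      rec$p_goE[i] <- pr[pm[3L]]
      rec$a_goL[i] <- adv[pm[1L]]
      rec$a_goM[i] <- adv[pm[2L]]
      rec$a_goE[i] <- adv[pm[3L]]
      # decision feature labels the path on the standard task
      rec$path[i] <- c("sign", "goal", "explore", "")[match(
        ct$feat_i[e], c(2L, 3L, 1L, 4L)
      )]
    } else if (s %in% ct$mid_cs_i) {
      rec$second_choice[i] <- edge_actions[e]
      # on the split-CS task the mid-CS choice decides the second-half
      # engagement, which labels the path
      rec$path[i] <- if (ct$feat_i[e] == 3L) "goal" else "sign"
    }
    s2 <- ct$to_i[e]
    rew <- ct$reward[e]
    next_max <- if (s2 > 0L) {
      max(st$V[ct$feat_i[ct$state_edges[[s2]]]])
    } else {
      0
    }
    fe <- ct$feat_i[e]
    delta <- rew + gamma * next_max - st$V[fe]
    if (fe != 4L) st$V[fe] <- st$V[fe] + alpha * delta
    st$t[e] <- (1 - alpha) * st$t[e] + alpha
    st$r[e] <- st$r[e] + alpha * (rew - st$r[e])
    if (first_step) {
      rec$delta_cs[i] <- delta
      first_step <- FALSE
    }
    if (ct$us_delivery[e]) rec$delta_us[i] <- delta
    if (s2 == 0L) {
      rec$delta_eat[i] <- delta
      break
    }
    s <- s2
  }
  st$V["M"] <- (1 - params$u_iti) * st$V["M"]
  st$V["E"] <- (1 - params$u_iti) * st$V["E"]
  rec$v_E[i] <- st$V[["E"]]
  rec$v_L[i] <- st$V[["L"]]
  rec$v_M[i] <- st$V[["M"]]
  st
}

finish_records <- function(rec, task, params) {
  tibble::tibble(
    session = rec$session,
    trial = rec$trial,
    cs_choice = rec$cs_choice,
    second_choice = rec$second_choice,
    path = rec$path,
    delta_cs = rec$delta_cs,
    delta_us = rec$delta_us,
    delta_eat = rec$delta_eat,
    p_goL = rec$p_goL,
    p_goM = rec$p_goM,
    p_goE = rec$p_goE,
    a_goL = rec$a_goL,
    a_goM = rec$a_goM,
    a_goE = rec$a_goE,
    v_E = rec$v_E,
    v_L = rec$v_L,
    v_M = rec$v_M,
    task_variant = task$variant,
    feature_variant = task$feature_variant,
    omega = params$omega,
    u_iti = params$u_iti
  )
}
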