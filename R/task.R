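#' Autoshaping task graphs
#'
#' The autoshaping trial is modelled as a small deterministic Markov decision
#' process. Each trial starts in a pre-CS state, the lever (conditioned
#' stimulus, CS) is then presented, the agent chooses what to approach and
#' engage, food (unconditioned stimulus, US) is delivered into the magazine,
#' and the trial ends when the reward is eaten. Every state-action pair is
#' mapped by the feature function to the environmental feature the action is
#' directed at: the environment `E`, the lever `L`, the magazine `M`, or the
#' food `F`.
#'
#' `task_standard()` builds the canonical eight-state graph with a single
#' decision point at CS onset and three trial paths: sign-tracking
#' (approach and engage the lever), goal-tracking (approach and engage the
#' magazine), and exploration of the environment.
#'
#' `task_split_cs()` builds the split-CS variant in which the 8-s CS period
#' contains two sequential decision points (first and last 4 s). At CS onset
#' the agent chooses between lever and magazine only (exploration is
#' removed); at the mid-CS decision the agent can stay with the stimulus it
#' is engaging or switch to the other one. The post-US structure is
#' unchanged: an agent at the lever when food drops must still travel to the
#' magazine before eating, so the goal path remains one step shorter.
#'
#' The `feature_variant` argument controls the feature assigned to the final
#' eat action: `"food"` is the original convention (eating is directed at the
#' food itself, whose value is pinned at 1, so the eat-transition prediction
#' error is always 0), while `"magazine"` assigns the magazine feature to
#' eating, which lets magazine value be updated even on sign-tracking trials
#' and produces a non-trivial prediction error at reward consumption. The
#' magazine variant is the one used for dopamine-like prediction-error
#' analyses.
#'
#' @param feature_variant Feature assigned to the eat action: `"food"`
#'   (original) or `"magazine"` (corrected, used for prediction-error
#'   analyses).
#'
#' @return An object of class `stgt_task`: a list with elements
#'   \describe{
#'     \item{edges}{tibble with one row per state-action pair: `state`,
#'       `action`, `next_state` (`NA` for trial end), `reward`, `feature`.}
#'     \item{start}{the trial-start state.}
#'     \item{cs_state}{the CS-onset decision state used for approach
#'       scoring.}
#'     \item{variant, feature_variant}{the construction arguments.}
#'   }
#' @examples
#' task <- task_standard("food")
#' task_edges(task)
#' task_step(task, "s1", "goL")
#' @export
task_standard <- function(feature_variant = c("food", "magazine")) {
  feature_variant <- match.arg(feature_variant)
  eat_feature <- if (feature_variant == "food") "F" else "M"
  edges <- tibble::tribble(
    ~state, ~action, ~next_state, ~reward, ~feature, ~us_delivery,
    "s0",   "goE",   "s1",        0,       "E",      FALSE,
    "s1",   "goL",   "s2",        0,       "L",      FALSE,
    "s1",   "goE",   "s3",        0,       "E",      FALSE,
    "s1",   "goM",   "s4",        0,       "M",      FALSE,
    "s2",   "eng",   "s5",        0,       "L",      TRUE,
    "s3",   "wait",  "s6",        0,       "E",      TRUE,
    "s4",   "eng",   "s7",        0,       "M",      TRUE,
    "s5",   "goM",   "s7",        0,       "F",      FALSE,
    "s6",   "goM",   "s7",        0,       "F",      FALSE,
    "s7",   "eat",   NA,          1,       eat_feature, FALSE
  )
  new_stgt_task(edges,
    start = "s0", cs_state = "s1",
    variant = "standard", feature_variant = feature_variant
  )
}

#' @rdname task_standard
#' @export
task_split_cs <- function(feature_variant = c("food", "magazine")) {
  feature_variant <- match.arg(feature_variant)
  eat_feature <- if (feature_variant == "food") "F" else "M"
  # c0: CS onset (first 4 s choice); cL1/cM1: engaging lever/magazine during
  # the first half, where the mid-CS choice is made; cL2/cM2: position during
  # the second half. US delivery ends the CS: a lever-engaged agent (cL2)
  # sees food drop (uL) and must approach the magazine, a magazine-engaged
  # agent receives it directly in s7, keeping the goal route one step shorter.
  edges <- tibble::tribble(
    ~state, ~action,   ~next_state, ~reward, ~feature, ~us_delivery,
    "c0",   "goL",     "cL1",       0,       "L",      FALSE,
    "c0",   "goM",     "cM1",       0,       "M",      FALSE,
    "cL1",  "engL",    "cL2",       0,       "L",      FALSE,
    "cL1",  "switchM", "cM2",       0,       "M",      FALSE,
    "cM1",  "engM",    "cM2",       0,       "M",      FALSE,
    "cM1",  "switchL", "cL2",       0,       "L",      FALSE,
    "cL2",  "eng",     "uL",        0,       "L",      TRUE,
    "cM2",  "eng",     "s7",        0,       "M",      TRUE,
    "uL",   "goM",     "s7",        0,       "F",      FALSE,
    "s7",   "eat",     NA,          1,       eat_feature, FALSE
  )
  new_stgt_task(edges,
    start = "c0", cs_state = "c0",
    variant = "split_cs", feature_variant = feature_variant
  )
}

# Constructor: validates the graph and precompiles integer-indexed lookup
# tables used by the simulation loop.
new_stgt_task <- function(edges, start, cs_state, variant, feature_variant) {
  stopifnot(all(edges$feature %in% c("E", "L", "M", "F")))
  if (anyDuplicated(edges[c("state", "action")]) > 0) {
    stop("each (state, action) pair must appear exactly once", call. = FALSE)
  }
  states <- unique(edges$state)
  from_i <- match(edges$state, states)
  to_i <- match(edges$next_state, states)
  to_i[is.na(to_i)] <- 0L # 0 marks trial end
  feat_i <- match(edges$feature, c("E", "L", "M", "F"))
  state_edges <- lapply(seq_along(states), function(s) which(from_i == s))
  # mid-CS decision states: successors of the CS-onset state that offer a
  # further choice (non-empty only on the split-CS variant)
  cs_succ <- to_i[from_i == match(cs_state, states)]
  cs_succ <- cs_succ[cs_succ > 0L]
  mid_cs_i <- cs_succ[vapply(
    cs_succ, function(s) length(which(from_i == s)) > 1L, logical(1)
  )]
  task <- structure(
    list(
      edges = edges,
      states = states,
      start = start,
      cs_state = cs_state,
      variant = variant,
      feature_variant = feature_variant,
      compiled = list(
        from_i = from_i,
        to_i = to_i,
        feat_i = feat_i,
        reward = edges$reward,
        us_delivery = edges$us_delivery,
        eat_edge = which(to_i == 0L),
        state_edges = state_edges,
        start_i = match(start, states),
        cs_state_i = match(cs_state, states),
        mid_cs_i = mid_cs_i
      )
    ),
    class = "stgt_task"
  )
  validate_stgt_task(task)
  task
}

validate_stgt_task <- function(task) {
  cc <- task$compiled
  if (length(cc$eat_edge) != 1L || task$edges$reward[cc$eat_edge] != 1) {
    stop("the task must end with a single rewarded eat transition",
      call. = FALSE
    )
  }
  if (any(task$edges$reward[-cc$eat_edge] != 0)) {
    stop("reward must be 0 everywhere except the eat transition",
      call. = FALSE
    )
  }
  paths <- task_paths(task)
  total_reward <- vapply(paths, function(p) sum(p$reward), numeric(1))
  if (any(total_reward != 1)) {
    stop("every complete trial path must collect exactly one reward",
      call. = FALSE
    )
  }
  invisible(task)
}

#' Deterministic one-step transition
#'
#' Looks up the successor state and reward of taking `action` in `state`.
#'
#' @param task An `stgt_task`.
#' @param state A state identifier of `task`.
#' @param action An action available in `state`.
#' @return A list with `next_state` (`NA` if the trial ends), `reward`
#'   (0 or 1) and `feature` (the feature the action is directed at).
#' @export
task_step <- function(task, state, action) {
  stopifnot(inherits(task, "stgt_task"))
  i <- which(task$edges$state == state & task$edges$action == action)
  if (length(i) != 1L) {
    stop(sprintf("action '%s' is not available in state '%s'", action, state),
      call. = FALSE
    )
  }
  list(
    next_state = task$edges$next_state[i],
    reward = task$edges$reward[i],
    feature = task$edges$feature[i]
  )
}

#' Actions available in a state
#'
#' @inheritParams task_step
#' @return Character vector of action names, in the task's canonical order.
#' @export
task_actions <- function(task, state) {
  stopifnot(inherits(task, "stgt_task"))
  out <- task$edges$action[task$edges$state == state]
  if (length(out) == 0L) {
    stop(sprintf("unknown or terminal state '%s'", state), call. = FALSE)
  }
  out
}

#' Feature function lookup
#'
#' @inheritParams task_step
#' @return The feature label (`"E"`, `"L"`, `"M"` or `"F"`) that `action`
#'   in `state` is directed at.
#' @export
task_feature <- function(task, state, action) {
  task_step(task, state, action)$feature
}

#' Task graph as a tidy edge table
#'
#' Serializes the full graph (states, actions, transitions, rewards and
#' feature assignments) for audit or export.
#'
#' @param task An `stgt_task`.
#' @return A tibble with columns `state`, `action`, `next_state`, `reward`,
#'   `feature` and `us_delivery` (whether food appears on that transition).
#' @export
task_edges <- function(task) {
  stopifnot(inherits(task, "stgt_task"))
  task$edges
}

#' Enumerate all complete trial paths
#'
#' Depth-first enumeration of every path from the trial-start state to the
#' end of the trial. The standard task has exactly three (sign, goal,
#' explore); the split-CS task has four (stay-lever, stay-magazine, and the
#' two switch routes).
#'
#' @param task An `stgt_task`.
#' @return A list of tibbles, one per path, each with the visited `state`,
#'   `action`, `reward` and `feature` sequence.
#' @export
task_paths <- function(task) {
  stopifnot(inherits(task, "stgt_task"))
  edges <- task$edges
  out <- list()
  walk <- function(state, acc) {
    rows <- which(edges$state == state)
    if (length(rows) == 0L) {
      stop(sprintf("state '%s' has no actions and is not terminal", state),
        call. = FALSE
      )
    }
    for (i in rows) {
      acc2 <- rbind(acc, edges[i, c("state", "action", "reward", "feature")])
      if (is.na(edges$next_state[i])) {
        out[[length(out) + 1L]] <<- tibble::as_tibble(acc2)
      } else {
        walk(edges$next_state[i], acc2)
      }
    }
  }
  walk(task$start, edges[0, c("state", "action", "reward", "feature")])
  out
}

#' @export
print.stgt_task <- function(x, ...) {
  cat(sprintf(
    "<stgt_task> %s variant, eat feature: %s\n", x$variant,
    x$feature_variant
  ))
  cat(sprintf(
    "  %d states, %d state-action pairs, start: %s, CS-onset state: %s\n",
    length(x$states), nrow(x$edges), x$start, x$cs_state
  ))
  print(x$edges, n = nrow(x$edges))
  invisible(x)
}
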