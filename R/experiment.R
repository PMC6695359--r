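#' Simulation protocol
#'
#' Describes one training protocol: how many sessions and trials, which ITI
#' condition, which task variant, and which eat-action feature convention.
#' The defaults reproduce the canonical acquisition protocol of ten
#' sessions of fifty trials. Sessions are contiguous training: the agent's
#' state carries over between sessions, and the ITI revision is the only
#' between-trial event.
#'
#' @param n_sessions Number of sessions (default 10).
#' @param trials_per_session Trials per session (default 50).
#' @param iti ITI condition, `"short"` (`u_iti = 0.01`) or `"long"`
#'   (`u_iti = 0.1`).
#' @param task_variant `"standard"` (single decision per CS period) or
#'   `"split_cs"` (two decision points per CS period).
#' @param feature_variant Feature of the eat action, `"food"` or
#'   `"magazine"` (see [task_standard()]).
#' @param seed Integer seed for the simulation, or `NULL` to use the
#'   current state of R's random number generator.
#' @param u_iti Optional explicit ITI update factor overriding the value
#'   implied by `iti`.
#' @return A list of class `stgt_protocol`.
#' @export
protocol <- function(n_sessions = 10, trials_per_session = 50,
                     iti = c("long", "short"),
                     task_variant = c("standard", "split_cs"),
                     feature_variant = c("food", "magazine"),
                     seed = NULL, u_iti = NULL) {
  iti <- match.arg(iti)
  task_variant <- match.arg(task_variant)
  feature_variant <- match.arg(feature_variant)
  stopifnot(
    n_sessions >= 1, trials_per_session >= 1,
    is.null(seed) || (is.numeric(seed) && length(seed) == 1L)
  )
  if (is.null(u_iti)) u_iti <- if (iti == "short") 0.01 else 0.1
  stopifnot(u_iti >= 0, u_iti <= 1)
  structure(
    list(
      n_sessions = as.integer(n_sessions),
      trials_per_session = as.integer(trials_per_session),
      iti = iti, u_iti = u_iti,
      task_variant = task_variant, feature_variant = feature_variant,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "stgt_protocol"
  )
}

protocol_task <- function(proto) {
  if (proto$task_variant == "standard") {
    task_standard(proto$feature_variant)
  } else {
    task_split_cs(proto$feature_variant)
  }
}

#' Simulate one subject through a protocol
#'
#' Runs a single hybrid agent through every trial of the protocol, with the
#' ITI condition of the protocol overriding `params$u_iti`, and returns a
#' tidy per-trial log. Learning persists across sessions; nothing is reset
#' between them.
#'
#' @param params An [agent_params] object (its `omega` defines the
#'   subject's model-based/model-free balance).
#' @param proto An [protocol] object.
#' @param subject_id Identifier stored in the log (default 1).
#' @return A tibble of class `stgt_log` with one row per trial:
#'   \describe{
#'     \item{subject_id, condition, session, trial}{indexing; `condition`
#'       is the protocol's ITI label.}
#'     \item{cs_choice}{action chosen at the CS-onset state.}
#'     \item{second_choice}{mid-CS action (split-CS task only, else `NA`).}
#'     \item{path}{trial path: `"sign"`, `"goal"` or `"explore"`.}
#'     \item{delta_cs, delta_us, delta_eat}{prediction errors tagged at CS
#'       onset, at food delivery, and at the eat action.}
#'     \item{p_goL, p_goM, p_goE}{softmax probabilities at the CS-onset
#'       state.}
#'     \item{a_goL, a_goM, a_goE}{MB advantages at the CS-onset state.}
#'     \item{v_E, v_L, v_M}{feature values after the trial (post ITI
#'       revision).}
#'     \item{task_variant, feature_variant, omega, u_iti}{run metadata.}
#'   }
#' @examples
#' log <- run_subject(agent_params(omega = 1), protocol(seed = 1))
#' dplyr::count(log, cs_choice)
#' @export
run_subject <- function(params, proto, subject_id = 1L) {
  stopifnot(inherits(params, "stgt_params"), inherits(proto, "stgt_protocol"))
  params$u_iti <- proto$u_iti
  if (!is.null(proto$seed)) set.seed(proto$seed)
  task <- protocol_task(proto)
  ct <- task$compiled
  n <- proto$n_sessions * proto$trials_per_session
  rec <- trial_record_buffer(n)
  st <- stgt_agent(task, params)$state
  for (i in seq_len(n)) {
    st <- sim_one_trial(ct, params, st, task$edges$action, rec, i)
  }
  rec$session <- rep(seq_len(proto$n_sessions), each = proto$trials_per_session)
  rec$trial <- rep(seq_len(proto$trials_per_session), times = proto$n_sessions)
  out <- finish_records(rec, task, params)
  out <- tibble::add_column(out,
    subject_id = subject_id, condition = proto$iti, .before = 1L
  )
  class(out) <- c("stgt_log", class(out))
  attr(out, "agent") <- structure(
    list(task = task, params = params, state = st),
    class = "stgt_agent"
  )
  out
}

#' Final agent of a single-subject run
#'
#' Returns the trained agent left behind by [run_subject()] (its feature
#' values and learned world model), for inspecting what was learned, e.g.
#' `final_agent(log)$state$V` or [mb_solve_q()] on the learned model.
#'
#' @param log An `stgt_log` returned by `run_subject()`.
#' @return The `stgt_agent` after the last trial.
#' @export
final_agent <- function(log) {
  agent <- attr(log, "agent")
  if (is.null(agent)) {
    stop("no stored agent: only run_subject() logs carry the final agent",
      call. = FALSE
    )
  }
  agent
}

#' Learned world model of a trained agent
#'
#' Repackages the transition and reward estimates accumulated by an agent
#' into an [world_model] object, so they can be queried with
#' [mb_transition()] / [mb_reward()] or solved with [mb_solve_q()].
#'
#' @param agent An `stgt_agent`, e.g. from [final_agent()].
#' @return An `stgt_world_model`.
#' @export
agent_world_model <- function(agent) {
  stopifnot(inherits(agent, "stgt_agent"))
  model <- world_model(agent$task)
  model$t <- agent$state$t
  model$r <- agent$state$r
  model
}

#' Sample a population of integration weights
#'
#' Draws the per-subject `omega` values that define a simulated population's
#' mix of sign- and goal-tracking tendencies. The default is a beta(2, 1)
#' distribution, the simplest density increasing towards 1, reflecting the
#' reported prevalence of sign-trackers; a uniform alternative and a
#' degenerate fixed value (for single-system populations) are available.
#'
#' @param n Number of subjects (default 20).
#' @param dist `"beta"`, `"uniform"` or `"fixed"`.
#' @param shape1,shape2 Beta shape parameters (default 2 and 1).
#' @param value The common value when `dist = "fixed"`.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return Numeric vector of `n` values in `[0, 1]`.
#' @examples
#' sample_omegas(5, seed = 1)
#' sample_omegas(3, dist = "fixed", value = 1)
#' @export
sample_omegas <- function(n = 20, dist = c("beta", "uniform", "fixed"),
                          shape1 = 2, shape2 = 1, value = NULL, seed = NULL) {
  dist <- match.arg(dist)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- switch(dist,
    beta = {
      if (shape1 <= 0 || shape2 <= 0) {
        stop("beta shape parameters must be positive", call. = FALSE)
      }
      stats::rbeta(n, shape1, shape2)
    },
    uniform = stats::runif(n),
    fixed = {
      if (is.null(value) || value < 0 || value > 1) {
        stop("'value' must be supplied in [0, 1] when dist = 'fixed'",
          call. = FALSE
        )
      }
      rep(value, n)
    }
  )
  out
}

#' Simulate a population under one protocol
#'
#' Runs one subject per `omega`, each with its own reproducible choice
#' stream derived from the protocol seed.
#'
#' @param omegas Numeric vector of per-subject integration weights, e.g.
#'   from [sample_omegas()].
#' @param proto An [protocol] object; its `seed` drives the per-subject
#'   seeds.
#' @param params Base [agent_params] shared by all subjects (its `omega`
#'   and `u_iti` are overridden per subject and by the protocol).
#' @return An `stgt_log` tibble covering all subjects.
#' @export
run_population <- function(omegas, proto, params = agent_params()) {
  stopifnot(is.numeric(omegas), all(omegas >= 0 & omegas <= 1))
  if (!is.null(proto$seed)) set.seed(proto$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, length(omegas))
  logs <- purrr::map(seq_along(omegas), function(i) {
    p_i <- params
    p_i$omega <- omegas[i]
    proto_i <- proto
    proto_i$seed <- subject_seeds[i]
    run_subject(p_i, proto_i, subject_id = i)
  })
  out <- dplyr::bind_rows(logs)
  class(out) <- c("stgt_log", setdiff(class(out), "stgt_log"))
  out
}

#' Simulate a population under paired ITI conditions
#'
#' Runs every subject under both the short (`u_iti = 0.01`) and long
#' (`u_iti = 0.1`) ITI conditions with the same `omega` values, so the ITI
#' effect can be analysed within subjects. Choice streams are drawn per
#' subject and condition; set `share_choice_streams = TRUE` to reuse the
#' identical stream in both conditions of a subject.
#'
#' @inheritParams run_population
#' @param share_choice_streams Reuse each subject's choice-noise stream in
#'   both conditions (default `FALSE`).
#' @return An `stgt_log` tibble with `condition` equal to `"short"` or
#'   `"long"`; subjects are aligned by `subject_id` across conditions.
#' @examples
#' log <- run_paired_population(
#'   sample_omegas(3, seed = 1),
#'   protocol(n_sessions = 2, trials_per_session = 10, seed = 1)
#' )
#' dplyr::count(log, condition)
#' @export
run_paired_population <- function(omegas, proto, params = agent_params(),
                                  share_choice_streams = FALSE) {
  stopifnot(is.numeric(omegas), all(omegas >= 0 & omegas <= 1))
  if (!is.null(proto$seed)) set.seed(proto$seed)
  n <- length(omegas)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n), ncol = 2L)
  if (share_choice_streams) seeds[, 2L] <- seeds[, 1L]
  conditions <- c("short", "long")
  logs <- purrr::map(seq_len(n), function(i) {
    p_i <- params
    p_i$omega <- omegas[i]
    per_cond <- purrr::map(1:2, function(j) {
      proto_ij <- proto
      proto_ij$iti <- conditions[j]
      proto_ij$u_iti <- if (conditions[j] == "short") 0.01 else 0.1
      proto_ij$seed <- seeds[i, j]
      run_subject(p_i, proto_ij, subject_id = i)
    })
    dplyr::bind_rows(per_cond)
  })
  out <- dplyr::bind_rows(logs)
  class(out) <- c("stgt_log", setdiff(class(out), "stgt_log"))
  out
}

#' Experiment presets
#'
#' `preset()` returns the fully bound configuration of one of the stock
#' simulation experiments; `run_preset()` executes it. Available presets:
#' \describe{
#'   \item{fig3_fmf_only}{20 pure-FMF agents (`omega = 1`) under both ITI
#'     conditions; the ITI-sensitivity of the feature-based system.}
#'   \item{fig3_mb_only}{20 pure-MB agents (`omega = 0`); the
#'     ITI-insensitivity of the model-based system.}
#'   \item{fig4_population}{20 subjects with beta(2, 1) `omega`, paired ITI
#'     conditions, original (food) eat feature; the behavioural
#'     replication.}
#'   \item{fig5_rpe}{as `fig4_population` but with the magazine eat
#'     feature, for prediction-error (dopamine-like) analyses.}
#'   \item{fig6_split_cs}{the split-CS task with the magazine eat feature;
#'     within-CS-period dynamics.}
#'   \item{supp_uniform}{as `fig4_population` with uniform `omega`.}
#'   \item{supp_extended_sessions}{as `fig5_rpe` with 30 sessions, to show
#'     the slow catch-up of the lever value under short ITIs.}
#' }
#'
#' @param name Preset name.
#' @param n_sessions,trials_per_session,n_subjects Optional overrides of
#'   the preset's protocol sizes (e.g. to scale a run down).
#' @return `preset()`: a list of class `stgt_preset` with the population
#'   spec and protocol; `run_preset()`: the paired `stgt_log`.
#' @examples
#' preset("fig3_fmf_only")
#' @export
preset <- function(name = c(
                     "fig3_fmf_only", "fig3_mb_only", "fig4_population",
                     "fig5_rpe", "fig6_split_cs", "supp_uniform",
                     "supp_extended_sessions"
                   ),
                   n_sessions = NULL, trials_per_session = NULL,
                   n_subjects = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    fig3_fmf_only = list(
      omega_dist = list(dist = "fixed", value = 1),
      feature_variant = "magazine", task_variant = "standard", n_sessions = 10,
      share_choice_streams = TRUE
    ),
    fig3_mb_only = list(
      omega_dist = list(dist = "fixed", value = 0),
      feature_variant = "magazine", task_variant = "standard", n_sessions = 10,
      share_choice_streams = TRUE
    ),
    fig4_population = list(
      omega_dist = list(dist = "beta", shape1 = 2, shape2 = 1),
      feature_variant = "magazine", task_variant = "standard", n_sessions = 10
    ),
    fig5_rpe = list(
      omega_dist = list(dist = "beta", shape1 = 2, shape2 = 1),
      feature_variant = "magazine", task_variant = "standard", n_sessions = 10
    ),
    fig6_split_cs = list(
      omega_dist = list(dist = "beta", shape1 = 2, shape2 = 1),
      feature_variant = "magazine", task_variant = "split_cs", n_sessions = 10
    ),
    supp_uniform = list(
      omega_dist = list(dist = "uniform"),
      feature_variant = "magazine", task_variant = "standard", n_sessions = 10
    ),
    supp_extended_sessions = list(
      omega_dist = list(dist = "beta", shape1 = 2, shape2 = 1),
      feature_variant = "magazine", task_variant = "standard", n_sessions = 30
    )
  )
  structure(
    list(
      name = name,
      n_subjects = if (is.null(n_subjects)) 20L else as.integer(n_subjects),
      omega_dist = cfg$omega_dist,
      task_variant = cfg$task_variant,
      feature_variant = cfg$feature_variant,
      n_sessions = if (is.null(n_sessions)) cfg$n_sessions else as.integer(n_sessions),
      trials_per_session = if (is.null(trials_per_session)) {
        50L
      } else {
        as.integer(trials_per_session)
      },
      share_choice_streams = isTRUE(cfg$share_choice_streams)
    ),
    class = "stgt_preset"
  )
}

#' @rdname preset
#' @param x An `stgt_preset` (or a preset name, which is passed to
#'   `preset()`).
#' @param seed Integer master seed for the omega sample and all choice
#'   streams.
#' @param params Base [agent_params].
#' @export
run_preset <- function(x, seed = 1L, params = agent_params()) {
  if (is.character(x)) x <- preset(x)
  stopifnot(inherits(x, "stgt_preset"))
  set.seed(seed)
  od <- x$omega_dist
  omegas <- sample_omegas(
    n = x$n_subjects, dist = od$dist,
    shape1 = od$shape1 %||% 2, shape2 = od$shape2 %||% 1,
    value = od$value
  )
  proto <- protocol(
    n_sessions = x$n_sessions, trials_per_session = x$trials_per_session,
    task_variant = x$task_variant, feature_variant = x$feature_variant,
    seed = sample.int(.Machine$integer.max - 1L, 1L)
  )
  run_paired_population(omegas, proto,
    params = params,
    share_choice_streams = x$share_choice_streams
  )
}

#' @export
print.stgt_preset <- function(x, ...) {
  od <- x$omega_dist
  od_lab <- switch(od$dist,
    fixed = sprintf("fixed(%g)", od$value),
    beta = sprintf("beta(%g, %g)", od$shape1, od$shape2),
    uniform = "uniform(0, 1)"
  )
  cat(sprintf(
    "<stgt_preset> %s: %d subjects, omega ~ %s, %s task (%s eat feature), %d x %d trials, paired short/long ITI\n",
    x$name, x$n_subjects, od_lab, x$task_variant, x$feature_variant,
    x$n_sessions, x$trials_per_session
  ))
  invisible(x)
}
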