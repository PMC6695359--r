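#' Per-session approach counts and probabilities
#'
#' Summarizes the choices made at the CS-onset state: how often each
#' subject approached the lever (`goL`, sign-tracking), the magazine
#' (`goM`, goal-tracking) or explored (`goE`), per session, together with
#' the mean softmax probabilities of the two approaches.
#'
#' @param log An `stgt_log` tibble from [run_subject()] or the population
#'   runners.
#' @return A tibble with one row per subject x condition x session:
#'   `n_goL`, `n_goM`, `n_goE`, `n_trials`, `p_goL`, `p_goM`.
#' @export
approach_summary <- function(log) {
  check_log(log)
  log |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$session) |>
    dplyr::summarise(
      n_goL = sum(.data$cs_choice == "goL"),
      n_goM = sum(.data$cs_choice == "goM"),
      n_goE = sum(.data$cs_choice == "goE"),
      n_trials = dplyr::n(),
      p_goL = mean(.data$p_goL),
      p_goM = mean(.data$p_goM),
      .groups = "drop"
    )
}

#' Normalized approach score
#'
#' The normalized difference between lever and magazine approach,
#' `(p_L - p_M) / (p_L + p_M)`: +1 for pure sign-tracking (no magazine
#' approach), -1 for pure goal-tracking (no lever approach), 0 for
#' indifference. The normalization accounts for the possibility of
#' exploring instead of approaching either cue. Inputs may be softmax
#' probabilities or choice frequencies; if both are 0 (possible only for
#' frequencies) the score is undefined and `NA` is returned with a warning.
#'
#' @param p_lever,p_magazine Non-negative probabilities or frequencies of
#'   approaching the lever and the magazine (vectorized).
#' @return Numeric vector of scores in `[-1, 1]`.
#' @examples
#' normalized_approach_score(0.6, 0.2)
#' @export
normalized_approach_score <- function(p_lever, p_magazine) {
  stopifnot(
    is.numeric(p_lever), is.numeric(p_magazine),
    length(p_lever) == length(p_magazine),
    all(p_lever >= 0, na.rm = TRUE), all(p_magazine >= 0, na.rm = TRUE)
  )
  tot <- p_lever + p_magazine
  undef <- !is.na(tot) & tot == 0
  if (any(undef)) {
    warning("both approach measures are zero; score undefined, returning NA",
      call. = FALSE
    )
  }
  out <- (p_lever - p_magazine) / tot
  out[undef] <- NA_real_
  out
}

#' Behavioural score table
#'
#' Computes the normalized approach score per subject (optionally per
#' session) in two ways: from the softmax probabilities of approach
#' (`score_prob`, the model's direct readout) and from realized choice
#' frequencies (`score_freq`, closer to how behaviour is scored
#' experimentally).
#'
#' @param log An `stgt_log` tibble.
#' @param by `"subject"` (scores aggregate over all sessions) or
#'   `"subject_session"`.
#' @return A tibble keyed by subject, condition (and session), with
#'   `score_prob` and `score_freq` in `[-1, 1]`.
#' @export
approach_scores <- function(log, by = c("subject", "subject_session")) {
  by <- match.arg(by)
  check_log(log)
  keys <- c("subject_id", "condition", if (by == "subject_session") "session")
  log |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      score_prob = normalized_approach_score(
        mean(.data$p_goL), mean(.data$p_goM)
      ),
      score_freq = normalized_approach_score(
        sum(.data$cs_choice == "goL"), sum(.data$cs_choice == "goM")
      ),
      .groups = "drop"
    )
}

#' Prediction-error summaries and contrasts
#'
#' Summarizes the CS- and US-locked prediction errors (the model's proxy
#' for phasic dopamine) by condition and training phase, and runs the
#' corresponding comparisons: a Welch two-sample test of the long versus
#' short ITI condition on per-subject all-session means, and paired early
#' versus late tests within each condition. The US measure follows the
#' active feature convention: under the original food eat-feature it is the
#' error on the food-delivery transition; under the magazine eat-feature it
#' is the error at reward consumption (both are always present in the log).
#'
#' @param log A paired `stgt_log` (both ITI conditions, aligned subjects).
#' @param early_sessions Sessions forming the early phase (default 1:3);
#'   all later sessions form the late phase.
#' @return An object of class `stgt_rpe_contrasts`: a list with
#'   `summary` (condition x phase x event means and s.e.m.), `by_subject`
#'   (the per-subject means the tests run on) and `tests` (a tidy table of
#'   test results). Supports [generics::tidy()].
#' @export
rpe_contrasts <- function(log, early_sessions = 1:3) {
  check_log(log, paired = TRUE)
  if (!any(log$session %in% early_sessions) ||
    all(log$session %in% early_sessions)) {
    stop("'early_sessions' must split the sessions into two non-empty phases",
      call. = FALSE
    )
  }
  us_col <- if (unique(log$feature_variant) == "magazine") {
    "delta_eat"
  } else {
    "delta_us"
  }
  by_subject <- log |>
    dplyr::mutate(
      phase = ifelse(.data$session %in% early_sessions, "early", "late")
    ) |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$phase) |>
    dplyr::summarise(
      cs = mean(.data$delta_cs),
      us = mean(.data[[us_col]]),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("cs", "us"), names_to = "event", values_to = "delta")

  summary <- by_subject |>
    dplyr::group_by(.data$condition, .data$phase, .data$event) |>
    dplyr::summarise(
      mean = mean(.data$delta),
      sem = stats::sd(.data$delta) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )

  all_session <- log |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(
      cs = mean(.data$delta_cs), us = mean(.data[[us_col]]),
      .groups = "drop"
    )

  welch_row <- function(event) {
    x <- all_session[[event]][all_session$condition == "long"]
    y <- all_session[[event]][all_session$condition == "short"]
    tt <- safe_t_test(x, y)
    tibble::tibble(
      test = "welch_long_vs_short", condition = NA_character_,
      event = toupper(event), estimate = mean(x) - mean(y),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value
    )
  }
  paired_row <- function(cond, ev) {
    w <- by_subject |>
      dplyr::filter(.data$condition == cond, .data$event == ev) |>
      tidyr::pivot_wider(names_from = "phase", values_from = "delta") |>
      dplyr::arrange(.data$subject_id)
    tt <- safe_t_test(w$late, w$early, paired = TRUE)
    tibble::tibble(
      test = "paired_late_vs_early", condition = cond,
      event = toupper(ev), estimate = mean(w$late - w$early),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value
    )
  }
  tests <- dplyr::bind_rows(
    welch_row("cs"), welch_row("us"),
    paired_row("long", "cs"), paired_row("long", "us"),
    paired_row("short", "cs"), paired_row("short", "us")
  )
  structure(
    list(
      summary = summary, by_subject = by_subject, tests = tests,
      us_measure = us_col, early_sessions = early_sessions
    ),
    class = "stgt_rpe_contrasts"
  )
}

#' Feature-value learning trajectories
#'
#' Session-by-session population means of the learned feature values
#' (lever, magazine, environment) per condition, for visualizing how the
#' two ITI conditions shape the value landscape (plateau with a wide
#' lever-magazine gap under long ITIs versus a slowly rising lever value
#' under short ITIs).
#'
#' @param log An `stgt_log` tibble.
#' @return A tibble with columns `condition`, `session`, `feature`
#'   (`"E"`, `"L"`, `"M"`), `value` (mean) and `sem`.
#' @export
feature_value_trajectories <- function(log) {
  check_log(log)
  log |>
    tidyr::pivot_longer(c("v_E", "v_L", "v_M"),
      names_to = "feature", names_prefix = "v_", values_to = "v"
    ) |>
    dplyr::group_by(.data$condition, .data$session, .data$feature) |>
    dplyr::summarise(
      value = mean(.data$v),
      sem = stats::sd(.data$v) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Within-CS-period contrast of magazine approach
#'
#' For split-CS-task logs, compares each subject's probability of being at
#' the magazine during the first half of the CS period (the choice at CS
#' onset) with the probability of being there during the second half
#' (after the mid-CS stay/switch decision), over the requested sessions,
#' and tests the difference with a paired Wilcoxon signed-rank test.
#'
#' @param log An `stgt_log` from a split-CS run.
#' @param condition ITI condition to analyse (default `"short"`, where the
#'   within-CS switch is expected).
#' @param sessions Sessions to include; default session 4 onwards (the
#'   post-acquisition phase).
#' @return An object of class `stgt_split_contrast`: a list with
#'   `by_subject` (paired first/second-half probabilities) and `test`.
#'   Supports [generics::tidy()].
#' @export
split_cs_contrast <- function(log, condition = "short", sessions = NULL) {
  check_log(log)
  if (unique(log$task_variant) != "split_cs") {
    stop("split_cs_contrast() requires a log from the split-CS task",
      call. = FALSE
    )
  }
  if (is.null(sessions)) sessions <- 4:max(log$session)
  sub <- log |>
    dplyr::filter(.data$condition == !!condition, .data$session %in% sessions)
  if (nrow(sub) == 0L) {
    stop("no trials in the requested condition and session window",
      call. = FALSE
    )
  }
  by_subject <- sub |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      p_first_half = mean(.data$cs_choice == "goM"),
      p_second_half = mean(.data$path == "goal"),
      .groups = "drop"
    )
  wt <- tryCatch(
    suppressWarnings(
      stats::wilcox.test(by_subject$p_second_half, by_subject$p_first_half,
        paired = TRUE
      )
    ),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_)
  )
  structure(
    list(
      by_subject = by_subject,
      test = tibble::tibble(
        test = "wilcoxon_second_vs_first_half",
        estimate = mean(by_subject$p_second_half - by_subject$p_first_half),
        statistic = unname(wt$statistic),
        p.value = wt$p.value
      ),
      condition = condition, sessions = sessions
    ),
    class = "stgt_split_contrast"
  )
}

# t.test that degrades gracefully on degenerate (zero-variance or tiny)
# samples instead of erroring: the statistic is then 0/NaN and p is NA.
safe_t_test <- function(x, y, paired = FALSE) {
  tryCatch(
    stats::t.test(x, y, paired = paired),
    error = function(e) {
      est <- if (paired) mean(x - y) else mean(x) - mean(y)
      list(
        statistic = c(t = if (!is.na(est) && est == 0) 0 else NaN),
        parameter = c(df = NA_real_), p.value = NA_real_
      )
    }
  )
}

check_log <- function(log, paired = FALSE) {
  needed <- c(
    "subject_id", "condition", "session", "trial", "cs_choice",
    "p_goL", "p_goM", "delta_cs", "delta_us", "delta_eat",
    "v_E", "v_L", "v_M", "task_variant", "feature_variant"
  )
  missing <- setdiff(needed, names(log))
  if (length(missing)) {
    stop(
      "not a trial log: missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (paired) {
    conds <- sort(unique(log$condition))
    if (!identical(conds, c("long", "short"))) {
      stop("a paired log with both 'short' and 'long' conditions is required",
        call. = FALSE
      )
    }
    subj <- split(log$subject_id, log$condition)
    if (!setequal(unique(subj$short), unique(subj$long))) {
      stop("subjects are not aligned across the two conditions", call. = FALSE)
    }
  }
  invisible(log)
}

#' @export
print.stgt_rpe_contrasts <- function(x, ...) {
  cat("<stgt_rpe_contrasts> CS- and US-locked prediction errors\n")
  cat(sprintf(
    "US measured on the %s transition; early sessions: %s\n",
    if (x$us_measure == "delta_eat") "eat" else "food-delivery",
    paste(range(x$early_sessions), collapse = "-")
  ))
  print(x$summary)
  cat("\nTests:\n")
  print(x$tests)
  invisible(x)
}

#' @export
print.stgt_split_contrast <- function(x, ...) {
  cat(sprintf(
    "<stgt_split_contrast> magazine approach, first vs second CS half (%s ITI, sessions %s)\n",
    x$condition, paste(range(x$sessions), collapse = "-")
  ))
  print(x$test)
  invisible(x)
}
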