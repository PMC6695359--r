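#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the result objects
#'
#' `tidy()` methods return one row per test (or per summary cell) as a
#' tibble; `glance()` methods return a one-row overview.
#'
#' @param x A result object (`stgt_battery`, `stgt_rpe_contrasts`,
#'   `stgt_split_contrast`) or an `stgt_log`.
#' @param ... Unused.
#' @return A tibble.
#' @name stgt-tidiers
NULL

#' @rdname stgt-tidiers
#' @export
tidy.stgt_battery <- function(x, ...) {
  x$results
}

#' @rdname stgt-tidiers
#' @export
glance.stgt_battery <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$results),
    n_significant_05 = sum(x$results$p.value < 0.05, na.rm = TRUE)
  )
}

#' @rdname stgt-tidiers
#' @export
tidy.stgt_rpe_contrasts <- function(x, ...) {
  x$tests
}

#' @rdname stgt-tidiers
#' @export
tidy.stgt_split_contrast <- function(x, ...) {
  x$test
}

#' @rdname stgt-tidiers
#' @export
glance.stgt_log <- function(x, ...) {
  scores <- approach_scores(x, by = "subject") |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(score_freq = mean(.data$score_freq), .groups = "drop")
  out <- tibble::tibble(
    n_subjects = dplyr::n_distinct(x$subject_id),
    n_trials = nrow(x),
    n_sessions = max(x$session),
    task_variant = unique(x$task_variant)[1],
    feature_variant = unique(x$feature_variant)[1],
    conditions = paste(sort(unique(x$condition)), collapse = "+")
  )
  for (i in seq_len(nrow(scores))) {
    out[[paste0("mean_score_", scores$condition[i])]] <- scores$score_freq[i]
  }
  out
}
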