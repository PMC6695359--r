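#' Statistical battery for paired-condition simulations
#'
#' Runs the standard battery of tests on a paired short/long-ITI population
#' log, mirroring how such simulated experiments are reported:
#' \itemize{
#'   \item a repeated-measures ANOVA with two within factors (session and
#'     ITI condition) on the proportion of lever-approach trials and on the
#'     proportion of magazine-approach trials (no sphericity correction is
#'     applied);
#'   \item one-sample Wilcoxon signed-rank tests of the per-subject
#'     normalized approach scores against 0, per condition, for both the
#'     probability- and frequency-based scores;
#'   \item paired Wilcoxon signed-rank tests of the long minus short
#'     condition difference in both scores;
#'   \item Welch two-sample tests of the per-subject mean softmax
#'     probabilities of approaching the lever and the magazine between
#'     conditions.
#' }
#'
#' @param log A paired `stgt_log` (both ITI conditions, aligned subjects,
#'   balanced sessions).
#' @return An object of class `stgt_battery`: a list with `results` (one
#'   tidy row per test: `test`, `measure`, `condition`, `term`, `estimate`,
#'   `statistic`, `df`, `df2`, `p.value`) and `anova` (the fitted `aov`
#'   objects). Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' \donttest{
#' log <- run_paired_population(
#'   sample_omegas(6, seed = 1),
#'   protocol(n_sessions = 3, trials_per_session = 20, seed = 1)
#' )
#' tidy(stat_battery(log))
#' }
#' @export
stat_battery <- function(log) {
  check_log(log, paired = TRUE)
  counts <- approach_summary(log)
  n_per_cell <- dplyr::count(counts, .data$subject_id, .data$condition,
    name = "k"
  )
  if (length(unique(n_per_cell$k)) != 1L ||
    length(unique(counts$n_trials)) != 1L) {
    stop("stat_battery() requires a balanced within-subject design",
      call. = FALSE
    )
  }

  rm_df <- counts |>
    dplyr::mutate(
      subject = factor(.data$subject_id),
      session = factor(.data$session),
      condition = factor(.data$condition),
      prop_goL = .data$n_goL / .data$n_trials,
      prop_goM = .data$n_goM / .data$n_trials
    )
  aov_goL <- stats::aov(
    prop_goL ~ session * condition + Error(subject / (session * condition)),
    data = rm_df
  )
  aov_goM <- stats::aov(
    prop_goM ~ session * condition + Error(subject / (session * condition)),
    data = rm_df
  )
  anova_rows <- dplyr::bind_rows(
    tidy_rm_aov(aov_goL, "prop_goL"),
    tidy_rm_aov(aov_goM, "prop_goM")
  )

  scores <- approach_scores(log, by = "subject")
  wide <- scores |>
    tidyr::pivot_longer(c("score_prob", "score_freq"),
      names_to = "measure", values_to = "score"
    )
  signed_rank_rows <- wide |>
    dplyr::group_by(.data$condition, .data$measure) |>
    dplyr::summarise(
      test = "wilcoxon_vs_zero",
      estimate = mean(.data$score),
      statistic = safe_wilcox(.data$score)$statistic,
      p.value = safe_wilcox(.data$score)$p.value,
      .groups = "drop"
    )

  paired_rows <- wide |>
    tidyr::pivot_wider(names_from = "condition", values_from = "score") |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(
      test = "wilcoxon_long_vs_short",
      estimate = mean(.data$long - .data$short),
      statistic = safe_wilcox(.data$long, .data$short, paired = TRUE)$statistic,
      p.value = safe_wilcox(.data$long, .data$short, paired = TRUE)$p.value,
      .groups = "drop"
    )

  probs <- log |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(
      p_goL = mean(.data$p_goL), p_goM = mean(.data$p_goM),
      .groups = "drop"
    )
  welch_one <- function(col) {
    x <- probs[[col]][probs$condition == "long"]
    y <- probs[[col]][probs$condition == "short"]
    tt <- stats::t.test(x, y)
    tibble::tibble(
      test = "welch_long_vs_short", measure = col,
      estimate = mean(x) - mean(y), statistic = unname(tt$statistic),
      df = unname(tt$parameter), p.value = tt$p.value
    )
  }
  welch_rows <- dplyr::bind_rows(welch_one("p_goL"), welch_one("p_goM"))

  results <- dplyr::bind_rows(
    anova_rows, signed_rank_rows, paired_rows, welch_rows
  ) |>
    dplyr::select(dplyr::any_of(c(
      "test", "measure", "condition", "term", "estimate",
      "statistic", "df", "df2", "p.value"
    )))
  structure(
    list(results = results, anova = list(prop_goL = aov_goL, prop_goM = aov_goM)),
    class = "stgt_battery"
  )
}

# wilcox.test that tolerates degenerate samples (e.g. all-zero paired
# differences, where the signed-rank statistic is undefined).
safe_wilcox <- function(x, y = NULL, paired = FALSE) {
  out <- tryCatch(
    suppressWarnings(stats::wilcox.test(x, y, paired = paired)),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_)
  )
  list(statistic = unname(out$statistic), p.value = out$p.value)
}

# Flatten the within-stratum F tests of a two-within-factor aov fit.
tidy_rm_aov <- function(fit, measure) {
  strata <- summary(fit)
  rows <- list()
  for (stratum in strata) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals" || is.na(tab[i, "F value"])) next
      resid_i <- which(terms == "Residuals")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        test = "rm_anova", measure = measure, term = terms[i],
        statistic = tab[i, "F value"], df = tab[i, "Df"],
        df2 = tab[resid_i, "Df"], p.value = tab[i, "Pr(>F)"]
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.stgt_battery <- function(x, ...) {
  cat("<stgt_battery> statistical battery on a paired-condition log\n")
  print(x$results, n = nrow(x$results))
  invisible(x)
}
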