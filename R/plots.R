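#' Plot approach curves
#'
#' Session-by-session population mean (± s.e.m.) number of lever and
#' magazine approaches per condition — the standard acquisition-curve view
#' of sign- versus goal-tracking.
#'
#' @param log An `stgt_log` tibble.
#' @return A ggplot object.
#' @export
plot_approach <- function(log) {
  dat <- approach_summary(log) |>
    tidyr::pivot_longer(c("n_goL", "n_goM"),
      names_to = "approach", values_to = "n"
    ) |>
    dplyr::mutate(
      approach = dplyr::recode(.data$approach,
        n_goL = "lever", n_goM = "magazine"
      )
    ) |>
    dplyr::group_by(.data$condition, .data$session, .data$approach) |>
    dplyr::summarise(
      mean = mean(.data$n), sem = stats::sd(.data$n) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(dat, ggplot2::aes(
    .data$session, .data$mean,
    colour = .data$condition, linetype = .data$approach
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      size = 0.2
    ) +
    ggplot2::scale_x_continuous(breaks = unique(dat$session)) +
    ggplot2::labs(
      x = "session", y = "approaches per session",
      colour = "ITI", linetype = "approach target"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_approach
#' @param object An `stgt_log`.
#' @param ... Unused.
#' @export
autoplot.stgt_log <- function(object, ...) {
  plot_approach(object)
}

#' Plot prediction-error contrasts
#'
#' Bar chart of mean (± s.e.m.) CS- and US-locked prediction errors by
#' condition and training phase.
#'
#' @param x An `stgt_rpe_contrasts` object from [rpe_contrasts()].
#' @return A ggplot object.
#' @export
plot_rpe <- function(x) {
  stopifnot(inherits(x, "stgt_rpe_contrasts"))
  ggplot2::ggplot(x$summary, ggplot2::aes(
    .data$event, .data$mean,
    fill = .data$phase
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.2
    ) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "event", y = "mean prediction error", fill = "phase") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rpe
#' @param object An `stgt_rpe_contrasts`.
#' @param ... Unused.
#' @export
autoplot.stgt_rpe_contrasts <- function(object, ...) {
  plot_rpe(object)
}

#' Plot feature-value trajectories
#'
#' Session-by-session mean learned values of the lever, magazine and
#' environment features per condition.
#'
#' @param log An `stgt_log` tibble.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(log) {
  dat <- feature_value_trajectories(log)
  ggplot2::ggplot(dat, ggplot2::aes(
    .data$session, .data$value,
    colour = .data$feature
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$value - .data$sem, ymax = .data$value + .data$sem,
        fill = .data$feature
      ),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "session", y = "feature value") +
    ggplot2::theme_minimal()
}

#' Plot the within-CS-period contrast
#'
#' Mean magazine-approach probability in the first versus second half of
#' the CS period, with individual subjects as grey lines.
#'
#' @param x An `stgt_split_contrast` object from [split_cs_contrast()].
#' @return A ggplot object.
#' @export
plot_split_cs <- function(x) {
  stopifnot(inherits(x, "stgt_split_contrast"))
  dat <- x$by_subject |>
    tidyr::pivot_longer(c("p_first_half", "p_second_half"),
      names_to = "half", values_to = "p"
    ) |>
    dplyr::mutate(half = ifelse(.data$half == "p_first_half", "first 4 s", "last 4 s"))
  means <- dat |>
    dplyr::group_by(.data$half) |>
    dplyr::summarise(p = mean(.data$p), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$half, .data$p)) +
    ggplot2::geom_col(data = means, fill = "steelblue", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id), colour = "grey40") +
    ggplot2::labs(x = NULL, y = "P(approach magazine)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_split_cs
#' @param object An `stgt_split_contrast`.
#' @param ... Unused.
#' @export
autoplot.stgt_split_contrast <- function(object, ...) {
  plot_split_cs(object)
}
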