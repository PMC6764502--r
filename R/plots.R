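# Quick-look figures. These mirror the standard displays for this task
# (binned psychometric curve; proportion correct by intensity bin) and are
# diagnostics, not part of the numeric analysis surface.

#' Plot group-averaged binned psychometric curves
#'
#' Mean signed response per signed-target bin, averaged over participants
#' within each group; the diagonal marks perfect report.
#'
#' @param trials A validated trial tibble.
#' @param task Which task to plot.
#' @return A ggplot object.
#' @export
plot_psychometric_curve <- function(trials, task = "wm") {
  trials <- validate_trials(trials)
  trials <- trials[trials$task == task, ]
  keys <- unique(trials[, c("participant_id", "group")])
  curves <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- dplyr::semi_join(trials, keys[i, 1], by = "participant_id")
    dplyr::bind_cols(keys[i, ], bin_psychometric_curve(sub))
  }) |> dplyr::bind_rows()
  summ <- curves |>
    dplyr::mutate(center = (.data$lo + .data$hi) / 2) |>
    dplyr::group_by(.data$group, .data$center) |>
    dplyr::summarise(
      mean_response = mean(.data$mean_response, na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(
    summ,
    ggplot2::aes(.data$center, .data$mean_response, colour = .data$group)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "binned signed target intensity (%)",
      y = "mean signed response (%)",
      colour = "age group"
    ) +
    ggplot2::theme_minimal()
}

#' Plot proportion correct by intensity bin
#'
#' @param valence Output of [valence_scores()].
#' @param task Which task to plot.
#' @return A ggplot object.
#' @export
plot_proportion_correct <- function(valence, task = "wm") {
  long <- valence[valence$task == task, ] |>
    tidyr::pivot_longer(
      dplyr::starts_with("bin"),
      names_to = "bin", names_prefix = "bin", values_to = "prop_correct"
    ) |>
    dplyr::group_by(.data$group, .data$target_emotion, .data$bin) |>
    dplyr::summarise(
      prop_correct = mean(.data$prop_correct, na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$bin, .data$prop_correct,
      colour = .data$group, group = .data$group
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~target_emotion) +
    ggplot2::labs(
      x = "intensity bin", y = "proportion correct", colour = "age group"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
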