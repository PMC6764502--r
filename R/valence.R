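# Categorical valence judgments: was the reported emotion type the target's?
# Proportion correct is summarized in five intensity bins and its linear
# trend across bins (the "ambiguity slope") is the per-participant statistic.

#' Categorize a trial's valence report
#'
#' Correct when the response has the target's emotion type (same sign),
#' incorrect when it has the opposite type, `neutral_report` when the
#' response is exactly 0 (no emotion type reported). Neutral targets have no
#' correct valence and are not accepted.
#'
#' @param signed_target Signed target intensities, nonzero.
#' @param signed_response Signed responses.
#' @return Character vector in `c("correct", "incorrect", "neutral_report")`.
#' @export
categorize_trial <- function(signed_target, signed_response) {
  check_signed(signed_target, "signed_target")
  check_signed(signed_response, "signed_response")
  if (any(signed_target == 0)) {
    stop("neutral targets have no correct valence", call. = FALSE)
  }
  dplyr::case_when(
    signed_response == 0 ~ "neutral_report",
    sign(signed_response) == sign(signed_target) ~ "correct",
    .default = "incorrect"
  )
}

#' Intensity bins for the valence analysis
#'
#' Five equal bins of absolute target intensity: 1-20, 21-40, 41-60, 61-80,
#' 81-100. Neutral (0%) targets fall in no bin.
#'
#' @return Tibble with `bin` (1..5), `lo`, `hi`.
#' @export
valence_bins <- function() {
  tibble::tibble(
    bin = 1:5,
    lo = c(1L, 21L, 41L, 61L, 81L),
    hi = c(20L, 40L, 60L, 80L, 100L)
  )
}

#' Proportion correct per emotion and intensity bin
#'
#' For one participant and task: trials with emotional targets are
#' categorized with [categorize_trial()]; neutral-report trials are excluded
#' from numerator and denominator; the proportion correct is
#' `correct / (correct + incorrect)` per target emotion x intensity bin.
#' Empty bins are reported with `n = 0` and a missing proportion.
#'
#' @param trials Trials of one participant x task.
#' @return Tibble with `target_emotion`, `bin`, `lo`, `hi`, `n`,
#'   `prop_correct`.
#' @export
bin_proportion_correct <- function(trials) {
  one_participant_task(trials)
  trials <- trials[trials$target_emotion != "neutral", , drop = FALSE]
  bins <- valence_bins()
  cat <- categorize_trial(trials$signed_target, trials$signed_response)
  keep <- cat != "neutral_report"
  trials <- trials[keep, , drop = FALSE]
  cat <- cat[keep]
  per <- trials |>
    dplyr::mutate(
      bin = bins$bin[findInterval(abs(.data$signed_target), bins$lo)],
      correct = cat == "correct"
    ) |>
    dplyr::group_by(.data$target_emotion, .data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      prop_correct = mean(.data$correct), .groups = "drop"
    )
  tidyr::expand_grid(target_emotion = c("fear", "happy"), bins) |>
    dplyr::left_join(per, by = c("target_emotion", "bin")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Linear slope of proportion correct across intensity bins
#'
#' Ordinary least-squares slope of the bin proportions against the bin index
#' 1..5, in units of proportion per bin step; missing bins are omitted. A
#' positive slope means categorization improves with emotional intensity.
#'
#' @param prop_correct Proportions for bins 1..5 (NA allowed).
#' @param bin Bin indices matching `prop_correct`.
#' @return Slope (proportion per bin step).
#' @export
proportion_slope <- function(prop_correct, bin = seq_along(prop_correct)) {
  ok <- is.finite(prop_correct)
  if (sum(ok) < 2L) {
    stop("need at least two populated bins for a slope", call. = FALSE)
  }
  x <- bin[ok]
  y <- prop_correct[ok]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Valence summary for every participant and task
#'
#' One row per participant x task x emotion: overall proportion of
#' wrong-emotion reports, proportion correct in each of the five intensity
#' bins, and the OLS slope across bins; plus the happy-minus-fear slope
#' difference repeated on both rows for convenience.
#'
#' @param trials A validated trial tibble.
#' @return Tidy tibble with columns `participant_id`, `group`, `gender`,
#'   `trait_anxiety`, `task`, `target_emotion`, `prop_wrong`, `bin1`..`bin5`,
#'   `slope`, `slope_diff`.
#' @export
valence_scores <- function(trials) {
  trials <- validate_trials(trials)
  meta_cols <- intersect(
    c("participant_id", participant_cols, "task"), names(trials)
  )
  keys <- unique(trials[, c("participant_id", "task")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- dplyr::semi_join(trials, keys[i, ], by = c("participant_id", "task"))
    props <- bin_proportion_correct(sub)
    per_emo <- props |>
      dplyr::group_by(.data$target_emotion) |>
      dplyr::summarise(
        prop_wrong = 1 - sum(.data$prop_correct * .data$n, na.rm = TRUE) /
          sum(.data$n[is.finite(.data$prop_correct)]),
        slope = proportion_slope(.data$prop_correct, .data$bin),
        .groups = "drop"
      )
    wide <- props |>
      dplyr::mutate(bin = paste0("bin", .data$bin)) |>
      tidyr::pivot_wider(
        id_cols = "target_emotion", names_from = "bin",
        values_from = "prop_correct"
      )
    out <- dplyr::left_join(per_emo, wide, by = "target_emotion")
    out$slope_diff <- out$slope[out$target_emotion == "happy"] -
      out$slope[out$target_emotion == "fear"]
    dplyr::bind_cols(sub[1L, meta_cols], out)
  })
  dplyr::bind_rows(rows)
}
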