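# Core derived measures on the signed bipolar valence scale: absolute trial
# error, signed trial bias, block feedback, per-participant error and bias,
# and the binned psychometric curve.

check_signed <- function(x, what) {
  if (any(abs(x) > 100, na.rm = TRUE)) {
    stop(what, " outside -100..100", call. = FALSE)
  }
  invisible(x)
}

#' Absolute trial error on the signed scale
#'
#' Targets and responses carry sign (fear negative, happy positive); the error
#' is the absolute difference, so reporting the wrong emotion type compounds
#' the error. A 20% fearful target reported as 15% fearful scores
#' `|-20 - (-15)| = 5`; reported as 15% happy it scores `|-20 - 15| = 35`.
#' The largest possible error is 200 (opposite emotion at full intensity).
#'
#' @param signed_target,signed_response Signed intensities, -100..100.
#' @return Non-negative error, same length as the inputs.
#' @export
trial_error <- function(signed_target, signed_response) {
  check_signed(signed_target, "signed_target")
  check_signed(signed_response, "signed_response")
  abs(signed_target - signed_response)
}

#' Signed trial bias on the signed scale
#'
#' Response minus target: positive values mean the face was reported happier
#' (or less fearful) than it was.
#'
#' @inheritParams trial_error
#' @return Signed bias in -200..200.
#' @export
trial_bias <- function(signed_target, signed_response) {
  check_signed(signed_target, "signed_target")
  check_signed(signed_response, "signed_response")
  signed_response - signed_target
}

one_participant_task <- function(trials) {
  key <- unique(trials[, c("participant_id", "task")])
  if (nrow(key) > 1L) {
    stop("trials must belong to one participant and one task", call. = FALSE)
  }
  invisible(trials)
}

#' Mean absolute error for one participant and task
#'
#' @param trials Trials of one participant x task.
#' @param variant Exclusion variant applied first (see [apply_exclusions()]).
#' @return Mean of [trial_error()] over retained trials.
#' @export
participant_error <- function(trials, variant = "all_trials") {
  one_participant_task(trials)
  trials <- apply_exclusions(trials, variant)
  if (nrow(trials) == 0L) {
    stop("no retained trials; error undefined", call. = FALSE)
  }
  mean(trial_error(trials$signed_target, trials$signed_response))
}

condition_means <- function(trials) {
  trials |>
    dplyr::group_by(.data$signed_target) |>
    dplyr::summarise(
      mean_response = mean(.data$signed_response), .groups = "drop"
    )
}

#' Overall emotional bias: the mean of the psychometric curve
#'
#' The psychometric curve is the mean signed response at each signed target
#' intensity (-100..100, including the neutral 0 condition). The overall bias
#' is the mean of that curve; zero for an unbiased responder on the symmetric
#' design, positive when faces are reported happier / less fearful than they
#' are. By default each intensity condition contributes equally
#' (`weights = "condition"`); `weights = "trial"` averages raw trials instead,
#' which matters only after exclusions unbalance the design.
#'
#' @inheritParams participant_error
#' @param weights `"condition"` (mean of condition means, default) or
#'   `"trial"` (plain trial mean).
#' @return Signed bias in -200..200.
#' @export
participant_bias_overall <- function(trials, variant = "all_trials",
                                     weights = c("condition", "trial")) {
  weights <- match.arg(weights)
  one_participant_task(trials)
  trials <- apply_exclusions(trials, variant)
  if (nrow(trials) == 0L) {
    stop("no retained trials; bias undefined", call. = FALSE)
  }
  if (weights == "trial") {
    return(mean(trials$signed_response))
  }
  mean(condition_means(trials)$mean_response)
}

#' Design-exact normalizer for the per-emotion bias
#'
#' Mean of the 19 nonzero intensity levels (5..45, 55..100); the conventional
#' normalizer rounds this to 50, leaving a +1000/19 - 50 = +2.63 residual for
#' a perfectly unbiased responder.
#'
#' @return 1000/19.
#' @export
emotion_bias_normalizer_exact <- function() {
  mean(setdiff(wm_intensity_levels(), 0L))
}

#' Per-emotion bias with sign-flip normalization
#'
#' Neutral-target trials are always excluded. Responses on fearful-target
#' trials are flipped (multiplied by -1) so both emotions live on a common
#' positive scale; the mean response over the 19 nonzero intensity conditions
#' is then normalized by subtracting 50 (`normalizer = "conventional"`,
#' default) so values match the overall bias measure. Because the design-grid
#' mean is 1000/19, an exactly unbiased responder scores +2.63 under the
#' conventional normalizer; `normalizer = "exact"` subtracts 1000/19 so that
#' responder scores 0.
#'
#' @inheritParams participant_bias_overall
#' @param normalizer `"conventional"` (subtract 50) or `"exact"`
#'   (subtract 1000/19).
#' @return Named numeric vector `c(fear = ..., happy = ...)`, positive =
#'   toward happy on fear trials after the flip (less fearful) and toward
#'   more intense happiness on happy trials.
#' @export
participant_bias_by_emotion <- function(trials, variant = "all_trials",
                                        weights = c("condition", "trial"),
                                        normalizer = c("conventional", "exact")) {
  weights <- match.arg(weights)
  normalizer <- match.arg(normalizer)
  one_participant_task(trials)
  trials <- apply_exclusions(trials, variant)
  trials <- trials[trials$target_emotion != "neutral", , drop = FALSE]
  norm <- switch(normalizer,
    conventional = 50,
    exact = emotion_bias_normalizer_exact()
  )
  vapply(c(fear = "fear", happy = "happy"), function(emo) {
    sub <- trials[trials$target_emotion == emo, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no retained ", emo, " trials; per-emotion bias undefined",
        call. = FALSE
      )
    }
    flip <- if (emo == "fear") -1 else 1
    sub$signed_response <- flip * sub$signed_response
    sub$signed_target <- flip * sub$signed_target
    m <- if (weights == "trial") {
      mean(sub$signed_response)
    } else {
      mean(condition_means(sub)$mean_response)
    }
    m - norm
  }, numeric(1))
}

#' Block feedback score
#'
#' The feedback shown after each block: 100 minus the block's mean absolute
#' error ("percent correct"); can go negative for extreme error and is
#' reported as-is.
#'
#' @param trials Trials of one block (nonempty).
#' @return Feedback value.
#' @export
block_feedback <- function(trials) {
  if (nrow(trials) == 0L) stop("empty block", call. = FALSE)
  100 - mean(trial_error(trials$signed_target, trials$signed_response))
}

#' Feedback for every block of one participant and task
#'
#' @inheritParams participant_error
#' @return Tibble with `block` and `feedback`.
#' @export
feedback_by_block <- function(trials) {
  one_participant_task(trials)
  trials |>
    dplyr::group_by(block = .data$block) |>
    dplyr::summarise(
      feedback = 100 - mean(trial_error(.data$signed_target, .data$signed_response)),
      .groups = "drop"
    )
}

#' Bin definitions for the visual psychometric curve
#'
#' Eleven bins over the signed target: five fear bins of width 20 from -100
#' to -1 (the -20 bin covering -20..-1), a neutral 0 bin, and five mirrored
#' happy bins from 1 to 100.
#'
#' @return Tibble with `bin` (index -5..5), `lo`, `hi`.
#' @export
psychometric_bins <- function() {
  fear <- tibble::tibble(
    bin = -5:-1,
    lo = c(-100L, -80L, -60L, -40L, -20L),
    hi = c(-81L, -61L, -41L, -21L, -1L)
  )
  happy <- tibble::tibble(bin = 1:5, lo = -rev(fear$hi), hi = -rev(fear$lo))
  dplyr::bind_rows(fear, tibble::tibble(bin = 0L, lo = 0L, hi = 0L), happy)
}

#' Binned psychometric curve for one participant and task
#'
#' Mean signed response per signed-target bin (see [psychometric_bins()]);
#' empty bins are reported with `n = 0` and a missing mean.
#'
#' @inheritParams participant_error
#' @return Tibble with `bin`, `lo`, `hi`, `n`, `mean_response`.
#' @export
bin_psychometric_curve <- function(trials, variant = "all_trials") {
  one_participant_task(trials)
  trials <- apply_exclusions(trials, variant)
  bins <- psychometric_bins()
  idx <- findInterval(trials$signed_target, bins$lo)
  stopifnot(all(trials$signed_target <= bins$hi[idx]))
  per <- trials |>
    dplyr::mutate(bin = bins$bin[idx]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_response = mean(.data$signed_response), .groups = "drop"
    )
  bins |>
    dplyr::left_join(per, by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Score every participant and task in a trial table
#'
#' Tidy wrapper producing one row per participant x task x exclusion variant
#' with the derived measures used by the group-level analyses.
#'
#' @param trials A validated trial tibble (any number of participants).
#' @param variants Exclusion variants to compute.
#' @inheritParams participant_bias_overall
#' @inheritParams participant_bias_by_emotion
#' @return Tibble with columns `participant_id`, `group`, `gender`,
#'   `trait_anxiety`, `task`, `variant`, `mean_error`, `error_fear`,
#'   `error_happy`, `bias_overall`, `bias_fear`, `bias_happy`.
#' @export
score_trials <- function(trials,
                         variants = "all_trials",
                         weights = "condition",
                         normalizer = "conventional") {
  trials <- validate_trials(trials)
  meta_cols <- intersect(
    c("participant_id", participant_cols, "task"), names(trials)
  )
  keys <- unique(trials[, c("participant_id", "task")])
  combos <- tidyr::expand_grid(k = seq_len(nrow(keys)), variant = variants)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    key <- keys[combos$k[i], ]
    v <- combos$variant[i]
    sub <- dplyr::semi_join(trials, key, by = c("participant_id", "task"))
    excl <- apply_exclusions(sub, v)
    per_emo_err <- vapply(c(fear = "fear", happy = "happy"), function(emo) {
      s <- excl[excl$target_emotion == emo, ]
      if (nrow(s) == 0L) {
        return(NA_real_)
      }
      mean(trial_error(s$signed_target, s$signed_response))
    }, numeric(1))
    be <- participant_bias_by_emotion(sub, v,
      weights = weights, normalizer = normalizer
    )
    meta <- sub[1L, meta_cols]
    dplyr::bind_cols(
      meta,
      tibble::tibble(
        variant = v,
        mean_error = participant_error(sub, v),
        error_fear = per_emo_err[["fear"]],
        error_happy = per_emo_err[["happy"]],
        bias_overall = participant_bias_overall(sub, v, weights = weights),
        bias_fear = be[["fear"]],
        bias_happy = be[["happy"]]
      )
    )
  })
  dplyr::bind_rows(rows)
}
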