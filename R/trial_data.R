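# Canonical trial-level data model: validation, delimited I/O, exclusion
# filters. All emotional intensities live on the signed bipolar scale:
# fearful = -100..-1, neutral = 0, happy = +1..+100.

#: maximum response time in seconds; at timeout the on-screen intensity is
#: recorded as the response
WM_MAX_RT <- 11

#' Admissible target intensities for the working-memory and matching tasks
#'
#' Targets are morph intensities from 0% to 45% and 55% to 100% in 5% steps;
#' 50% is never shown so that every emotional target has a majority emotion.
#'
#' @return Integer vector of the 20 admissible intensity levels.
#' @export
wm_intensity_levels <- function() {
  c(seq(0L, 45L, by = 5L), seq(55L, 100L, by = 5L))
}

required_trial_cols <- c(
  "participant_id", "task", "block", "trial_index",
  "target_emotion", "target_intensity", "identity_id",
  "signed_response", "response_time", "timed_out"
)

participant_cols <- c("group", "gender", "trait_anxiety")

optional_covariate_cols <- c(
  "state_anxiety", "bdi", "panas_pos", "panas_neg", "scroll_mapping"
)

#' Signed target intensity from emotion type and unsigned intensity
#'
#' @param target_emotion Character vector in `c("fear", "happy", "neutral")`.
#' @param target_intensity Integer intensities in 0..100.
#' @return Integer vector on the signed scale (fear negative, happy positive,
#'   neutral 0).
#' @export
signed_target <- function(target_emotion, target_intensity) {
  sgn <- dplyr::case_match(
    target_emotion,
    "fear" ~ -1L,
    "happy" ~ 1L,
    "neutral" ~ 0L
  )
  sgn * as.integer(target_intensity)
}

fail_rows <- function(bad, msg, lenient) {
  rows <- which(bad)
  if (length(rows) == 0L) {
    return(integer(0))
  }
  shown <- paste(utils::head(rows, 5L), collapse = ", ")
  text <- sprintf(
    "%s [%d row(s); e.g. row %s]", msg, length(rows), shown
  )
  if (lenient) {
    warning(text, call. = FALSE)
    rows
  } else {
    stop(text, call. = FALSE)
  }
}

#' Validate a trial table
#'
#' Checks column presence, ranges, and internal consistency: the sign of the
#' target matches the emotion type, neutral targets have intensity 0,
#' working-memory targets sit on the 5%-step grid that omits 50%, timed-out
#' trials carry the maximum response time, and block/trial indices are unique
#' within participant and task. A `signed_target` column is (re)computed from
#' emotion and intensity; if one was stored it is cross-checked first.
#'
#' @param trials A data frame of trials (see [read_trials()] for columns).
#' @param lenient If `TRUE`, rows that fail a check are dropped with a warning
#'   instead of aborting.
#' @return A validated tibble with a `signed_target` column.
#' @export
validate_trials <- function(trials, lenient = FALSE) {
  trials <- tibble::as_tibble(trials)
  missing <- setdiff(required_trial_cols, names(trials))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(trials) == 0L) {
    trials$signed_target <- integer(0)
    return(trials)
  }
  for (col in c(
    "block", "trial_index", "target_intensity", "identity_id",
    "signed_response", "response_time"
  )) {
    if (!is.numeric(trials[[col]])) {
      stop("column `", col, "` must be numeric", call. = FALSE)
    }
  }
  if (is.character(trials$timed_out)) {
    trials$timed_out <- toupper(trials$timed_out) %in% c("TRUE", "T", "1")
  }
  trials$timed_out <- as.logical(trials$timed_out)

  drop <- integer(0)
  chk <- function(bad, msg) {
    drop <<- union(drop, fail_rows(bad & !is.na(bad), msg, lenient))
  }

  chk(
    !trials$target_emotion %in% c("fear", "happy", "neutral"),
    "target_emotion outside {fear, happy, neutral}"
  )
  chk(
    trials$target_intensity < 0 | trials$target_intensity > 100,
    "target_intensity outside 0..100"
  )
  chk(
    abs(trials$signed_response) > 100,
    "signed_response outside -100..100"
  )
  chk(
    trials$target_emotion == "neutral" & trials$target_intensity != 0,
    "neutral target with nonzero intensity"
  )
  chk(
    trials$target_emotion != "neutral" & trials$target_intensity == 0,
    "zero-intensity target not labelled neutral"
  )
  chk(
    trials$task == "wm" &
      !trials$target_intensity %in% wm_intensity_levels(),
    "WM target_intensity off the admissible grid (5% steps, 50% excluded)"
  )
  chk(
    !trials$identity_id %in% 1:10,
    "identity_id outside 1..10"
  )
  chk(
    trials$response_time < 0,
    "negative response_time"
  )
  chk(
    trials$timed_out & trials$response_time != WM_MAX_RT,
    sprintf("timed_out trial with response_time != %d s", WM_MAX_RT)
  )
  chk(
    trials$block < 1 | trials$trial_index < 1,
    "block/trial_index must be >= 1"
  )

  expected_signed <- signed_target(trials$target_emotion, trials$target_intensity)
  if ("signed_target" %in% names(trials)) {
    chk(
      trials$signed_target != expected_signed,
      "stored signed_target disagrees with target_emotion/target_intensity"
    )
  }
  trials$signed_target <- expected_signed

  if (length(drop) > 0L) {
    trials <- trials[-drop, , drop = FALSE]
  }

  dup <- duplicated(trials[, c("participant_id", "task", "block", "trial_index")])
  if (any(dup)) {
    fail_rows(dup, "duplicate (participant, task, block, trial) index", FALSE)
  }
  trials
}

#' Read a trial table from delimited text
#'
#' Expects a header row naming the trial fields; column order is free.
#' Required columns: `participant_id`, `task`, `block`, `trial_index`,
#' `target_emotion`, `target_intensity`, `identity_id`, `signed_response`,
#' `response_time`, `timed_out`; participant attributes (`group`, `gender`,
#' `trait_anxiety`) and further covariates ride along when present.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter, comma by default.
#' @param lenient Passed to [validate_trials()].
#' @return A validated trial tibble.
#' @export
read_trials <- function(path, delim = ",", lenient = FALSE) {
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0L) {
    stop(
      "unparseable cell(s), e.g. row ", prob$row[1], " column ", prob$col[1],
      call. = FALSE
    )
  }
  validate_trials(raw, lenient = lenient)
}

#' Write a trial table to delimited text
#'
#' Columns are written in canonical order; optional covariate columns are
#' included only when present, so [read_trials()] round-trips the table
#' field-for-field.
#'
#' @param trials A validated trial tibble.
#' @param path Destination file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, delim = ",") {
  trials <- validate_trials(trials)
  order <- c(
    "participant_id", intersect(participant_cols, names(trials)),
    intersect(optional_covariate_cols, names(trials)),
    "task", "block", "trial_index", "target_emotion", "target_intensity",
    "signed_target", "identity_id", "signed_response", "response_time",
    "timed_out"
  )
  out <- trials[, c(order, setdiff(names(trials), order)), drop = FALSE]
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

exclusion_variants <- c(
  "all_trials", "drop_wrong_emotion", "drop_wrong_emotion_and_neutral",
  "drop_timeouts"
)

#' Flag wrong-emotion-type trials
#'
#' A trial is a wrong-emotion report when the response lies on the opposite
#' side of neutral from the target (e.g. a fearful target adjusted to a happy
#' expression). Neutral targets and exactly-neutral responses carry no emotion
#' type and are never flagged.
#'
#' @param signed_target,signed_response Signed intensities in -100..100.
#' @return Logical vector.
#' @export
is_wrong_emotion <- function(signed_target, signed_response) {
  signed_target != 0 & signed_response != 0 &
    sign(signed_target) != sign(signed_response)
}

#' Apply a trial-exclusion variant
#'
#' The analysis variants are: `all_trials` (identity); `drop_wrong_emotion`
#' (remove trials reported as the incorrect emotion type);
#' `drop_wrong_emotion_and_neutral` (additionally remove neutral-target
#' trials); `drop_timeouts` (remove trials that used the full response
#' window). Per-participant counts of removed trials are attached as the
#' `"exclusion_counts"` attribute for reporting.
#'
#' @param trials A validated trial tibble.
#' @param variant One of the exclusion variants above.
#' @return The filtered tibble (possibly empty), with removal counts attached.
#' @export
apply_exclusions <- function(trials, variant = exclusion_variants) {
  variant <- match.arg(variant)
  trials <- validate_trials(trials)
  keep <- switch(variant,
    all_trials = rep(TRUE, nrow(trials)),
    drop_wrong_emotion =
      !is_wrong_emotion(trials$signed_target, trials$signed_response),
    drop_wrong_emotion_and_neutral =
      !is_wrong_emotion(trials$signed_target, trials$signed_response) &
        trials$target_emotion != "neutral",
    drop_timeouts = !trials$timed_out
  )
  removed <- trials[!keep, , drop = FALSE] |>
    dplyr::count(.data$participant_id, .data$task, name = "n_removed")
  out <- trials[keep, , drop = FALSE]
  attr(out, "exclusion_counts") <- removed
  attr(out, "exclusion_variant") <- variant
  out
}
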