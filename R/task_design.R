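# Balanced trial schedules for the working-memory and perceptual
# emotion-matching tasks. A schedule fixes, per trial, the emotion condition
# (which morph continuum the target comes from), the target intensity, and
# the facial identity; responses are filled in later (by a participant or by
# the simulator).

N_IDENTITIES <- 10L
WM_BLOCKS <- 8L
TRIALS_PER_BLOCK <- 20L
MATCHING_BLOCKS <- 2L

#' Build a working-memory task schedule
#'
#' The WM design is 8 blocks of 20 trials. Each emotion condition (fearful,
#' happy) contributes one trial at each of the 20 intensity levels (0-45% and
#' 55-100% in 5% steps), four times over, for 80 trials per condition. Each of
#' the 10 facial identities appears exactly 16 times and in both emotion
#' conditions; identities are otherwise allocated pseudorandomly over
#' intensity conditions. Emotion conditions are intermixed within every block.
#'
#' Note that the 0%-intensity trials of both conditions are physically neutral
#' faces; the condition label records which response continuum they were
#' scheduled under, while [schedule_trials()] labels their `target_emotion`
#' as `"neutral"`.
#'
#' @param seed Integer seed; the same seed always yields the same schedule.
#' @return A tibble with columns `task`, `block`, `trial_index`,
#'   `emotion_condition`, `target_intensity`, `identity_id`, carrying the seed
#'   as an attribute.
#' @export
build_wm_schedule <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  grid <- tidyr::expand_grid(
    emotion_condition = c("fear", "happy"),
    target_intensity = wm_intensity_levels(),
    rep = 1:4
  )
  n <- nrow(grid) # 160
  sched <- withr::with_seed(as.integer(seed), {
    repeat {
      ids <- sample(rep(seq_len(N_IDENTITIES), n / N_IDENTITIES))
      both <- all(vapply(
        split(grid$emotion_condition, ids),
        function(e) length(unique(e)) == 2L, logical(1)
      ))
      if (both) break
    }
    grid$identity_id <- ids
    grid[sample.int(n), ] |> enforce_block_mixing(WM_BLOCKS)
  })
  out <- tibble::tibble(
    task = "wm",
    block = rep(seq_len(WM_BLOCKS), each = TRIALS_PER_BLOCK),
    trial_index = rep(seq_len(TRIALS_PER_BLOCK), WM_BLOCKS),
    emotion_condition = sched$emotion_condition,
    target_intensity = sched$target_intensity,
    identity_id = sched$identity_id
  )
  attr(out, "seed") <- as.integer(seed)
  out
}

# reshuffle until no block is single-emotion (essentially never triggers)
enforce_block_mixing <- function(rows, n_blocks) {
  repeat {
    blocks <- rep(seq_len(n_blocks), each = nrow(rows) / n_blocks)
    mixed <- all(vapply(
      split(rows$emotion_condition, blocks),
      function(e) length(unique(e)) == 2L, logical(1)
    ))
    if (mixed) {
      return(rows)
    }
    rows <- rows[sample.int(nrow(rows)), ]
  }
}

#' Build a perceptual emotion-matching schedule
#'
#' The matching design is 2 blocks of 20 trials: each of the 20 intensity
#' levels appears once per emotion condition (20 trials per condition).
#' For every (emotion condition, intensity) cell, the identity assigned here
#' must differ from every identity the participant's WM schedule used in the
#' same cell, so the identity-intensity pairing is new in this task.
#'
#' @param seed Integer seed.
#' @param wm_schedule The same participant's WM schedule from
#'   [build_wm_schedule()], which supplies the pairing-difference constraint.
#' @return A tibble in the same layout as [build_wm_schedule()].
#' @export
build_matching_schedule <- function(seed, wm_schedule) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  grid <- tidyr::expand_grid(
    emotion_condition = c("fear", "happy"),
    target_intensity = wm_intensity_levels()
  )
  used <- wm_schedule |>
    dplyr::group_by(.data$emotion_condition, .data$target_intensity) |>
    dplyr::summarise(
      used = list(unique(.data$identity_id)), .groups = "drop"
    )
  grid <- dplyr::left_join(
    grid, used,
    by = c("emotion_condition", "target_intensity")
  )
  sched <- withr::with_seed(as.integer(seed), {
    grid$identity_id <- vapply(grid$used, function(u) {
      allowed <- setdiff(seq_len(N_IDENTITIES), u)
      if (length(allowed) == 0L) {
        stop(
          "infeasible matching schedule: a WM condition uses all identities",
          call. = FALSE
        )
      }
      allowed[sample.int(length(allowed), 1L)]
    }, integer(1))
    grid$used <- NULL
    grid[sample.int(nrow(grid)), ] |> enforce_block_mixing(MATCHING_BLOCKS)
  })
  out <- tibble::tibble(
    task = "matching",
    block = rep(seq_len(MATCHING_BLOCKS), each = TRIALS_PER_BLOCK),
    trial_index = rep(seq_len(TRIALS_PER_BLOCK), MATCHING_BLOCKS),
    emotion_condition = sched$emotion_condition,
    target_intensity = sched$target_intensity,
    identity_id = sched$identity_id
  )
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Expand a schedule into trial rows
#'
#' Adds `target_emotion` (the condition label, or `"neutral"` for 0%
#' intensity) and the signed target, with empty response fields ready for a
#' participant or the simulator.
#'
#' @param schedule A schedule from [build_wm_schedule()] or
#'   [build_matching_schedule()].
#' @return A tibble of trial skeletons.
#' @export
schedule_trials <- function(schedule) {
  schedule |>
    dplyr::mutate(
      target_emotion = dplyr::if_else(
        .data$target_intensity == 0L, "neutral", .data$emotion_condition
      ),
      signed_target = signed_target(.data$target_emotion, .data$target_intensity),
      signed_response = NA_integer_,
      response_time = NA_real_,
      timed_out = NA
    )
}
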