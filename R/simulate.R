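# Generative response model. The simulator exists to exercise the scoring and
# inference pipeline end to end and to support parameter recovery; it is a
# convention of this package, not a fitted model. On each emotional trial the
# simulated participant either miscategorizes the valence (probability
# decaying exponentially with target intensity) and reports a low-to-moderate
# intensity of the opposite emotion, or reports the target plus a signed bias
# shift plus Gaussian report noise, rounded to the 1% morph steps of the
# response dial and clipped to the scale.

#' Generative parameters for one participant group
#'
#' @param noise_sd Report noise SD per emotion condition, in intensity-percent
#'   units, named `fear` and `happy`; neutral targets use their mean.
#' @param bias_shift Signed shift per emotion condition on the bipolar scale
#'   (positive = toward happy), intensity-percent units.
#' @param flip_base_rate Probability of a valence miscategorization at zero
#'   intensity, per target emotion.
#' @param flip_decay Exponential decay scale (intensity %) of the flip
#'   probability: `p_flip(i) = flip_base_rate * exp(-i / flip_decay)`.
#'   `Inf` gives an intensity-independent flip rate.
#' @param flip_magnitude_mean,flip_magnitude_sd Parameters of the folded
#'   normal from which the reported magnitude of a flipped response is drawn
#'   (clipped to 1..100).
#' @param timeout_rate Probability a trial uses the full response window.
#' @param anxiety_mean,anxiety_sd Normal distribution of the group's trait
#'   anxiety scores (clipped to the 20..80 instrument range).
#' @return A list of class `emowm_params`.
#' @export
generative_params <- function(noise_sd = c(fear = 12, happy = 12),
                              bias_shift = c(fear = 0, happy = 0),
                              flip_base_rate = c(fear = 0.2, happy = 0.5),
                              flip_decay = 30,
                              flip_magnitude_mean = 15,
                              flip_magnitude_sd = 10,
                              timeout_rate = 0.01,
                              anxiety_mean = 35,
                              anxiety_sd = 9) {
  p <- list(
    noise_sd = noise_sd[c("fear", "happy")],
    bias_shift = bias_shift[c("fear", "happy")],
    flip_base_rate = flip_base_rate[c("fear", "happy")],
    flip_decay = flip_decay,
    flip_magnitude_mean = flip_magnitude_mean,
    flip_magnitude_sd = flip_magnitude_sd,
    timeout_rate = timeout_rate,
    anxiety_mean = anxiety_mean,
    anxiety_sd = anxiety_sd
  )
  if (anyNA(p$noise_sd) || any(p$noise_sd <= 0)) {
    stop("noise_sd must name fear and happy and be > 0", call. = FALSE)
  }
  if (anyNA(p$bias_shift)) {
    stop("bias_shift must name fear and happy", call. = FALSE)
  }
  if (anyNA(p$flip_base_rate) || any(p$flip_base_rate < 0) ||
    any(p$flip_base_rate > 1)) {
    stop("flip_base_rate must name fear and happy and lie in [0, 1]",
      call. = FALSE
    )
  }
  if (p$flip_decay <= 0) stop("flip_decay must be > 0", call. = FALSE)
  if (p$timeout_rate < 0 || p$timeout_rate > 1) {
    stop("timeout_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "emowm_params")
}

#' Default generative parameters for the two age groups
#'
#' The defaults emulate the qualitative structure the task is designed to
#' expose: older adults report more noisily, carry a positive shift on
#' fearful targets (fearful faces remembered as less fearful), and flip
#' low-intensity fearful faces to happy more often than younger adults,
#' while both groups miscategorize low-intensity happy faces at a high rate.
#'
#' @return Named list with elements `young` and `old`.
#' @export
default_cohort_params <- function() {
  list(
    young = generative_params(
      noise_sd = c(fear = 12, happy = 11),
      bias_shift = c(fear = 0, happy = 0),
      flip_base_rate = c(fear = 0.2, happy = 0.5)
    ),
    old = generative_params(
      noise_sd = c(fear = 14, happy = 13),
      bias_shift = c(fear = 4, happy = 0),
      flip_base_rate = c(fear = 0.3, happy = 0.45)
    )
  )
}

#' Valence-flip probability at a given target intensity
#'
#' @param intensity Absolute target intensity, 0..100.
#' @param base_rate Flip probability at zero intensity.
#' @param decay Exponential decay scale; `Inf` for a flat rate.
#' @return Probability vector, non-increasing in intensity.
#' @export
flip_probability <- function(intensity, base_rate, decay) {
  if (is.infinite(decay)) {
    return(base_rate + 0 * intensity)
  }
  base_rate * exp(-abs(intensity) / decay)
}

#' Simulate responses for a table of trial skeletons
#'
#' Vectorized over trials; draws from the current RNG state, so wrap in a
#' seed for reproducibility (as [simulate_participant()] does).
#'
#' @param trials Trial skeletons from [schedule_trials()].
#' @param params An `emowm_params` object.
#' @return `trials` with `signed_response`, `response_time`, `timed_out`
#'   filled in.
#' @export
simulate_responses <- function(trials, params) {
  stopifnot(inherits(params, "emowm_params"))
  n <- nrow(trials)
  tgt <- trials$signed_target
  emo <- trials$target_emotion

  base <- ifelse(emo == "fear", params$flip_base_rate[["fear"]],
    ifelse(emo == "happy", params$flip_base_rate[["happy"]], 0)
  )
  p_flip <- flip_probability(abs(tgt), base, params$flip_decay)
  flipped <- stats::runif(n) < p_flip

  flip_mag <- round(pmin(100, pmax(1, abs(
    stats::rnorm(n, params$flip_magnitude_mean, params$flip_magnitude_sd)
  ))))
  flip_resp <- -sign(tgt) * flip_mag

  sd_vec <- ifelse(emo == "fear", params$noise_sd[["fear"]],
    ifelse(emo == "happy", params$noise_sd[["happy"]],
      mean(params$noise_sd)
    )
  )
  shift <- ifelse(emo == "fear", params$bias_shift[["fear"]],
    ifelse(emo == "happy", params$bias_shift[["happy"]], 0)
  )
  plain_resp <- round(tgt + shift + stats::rnorm(n, 0, sd_vec))
  plain_resp <- pmin(100, pmax(-100, plain_resp))

  trials$signed_response <- as.integer(ifelse(flipped, flip_resp, plain_resp))
  trials$timed_out <- stats::runif(n) < params$timeout_rate
  rt <- pmin(stats::rlnorm(n, meanlog = log(2.5), sdlog = 0.4), WM_MAX_RT - 0.1)
  trials$response_time <- ifelse(trials$timed_out, WM_MAX_RT, round(rt, 3))
  trials
}

#' Simulate one participant (WM + matching tasks)
#'
#' Builds the participant's WM and matching schedules, simulates every
#' response, and attaches participant attributes. All randomness for the
#' participant comes from one substream derived from `seed`, so adding or
#' removing other participants from a cohort never perturbs this one's data.
#'
#' @param participant_id Identifier string.
#' @param group `"young"` or `"old"`.
#' @param params An `emowm_params` object.
#' @param seed Integer substream seed for this participant.
#' @return A trial tibble for 160 WM + 40 matching trials.
#' @export
simulate_participant <- function(participant_id, group, params, seed) {
  seed <- as.integer(seed %% .Machine$integer.max)
  wm_sched <- build_wm_schedule(seed)
  match_sched <- build_matching_schedule(seed + 1L, wm_sched)
  withr::with_seed(seed + 2L, {
    trials <- dplyr::bind_rows(
      simulate_responses(schedule_trials(wm_sched), params),
      simulate_responses(schedule_trials(match_sched), params)
    )
    anx <- pmin(80, pmax(20, round(
      stats::rnorm(1, params$anxiety_mean, params$anxiety_sd), 1
    )))
    gender <- sample(c("female", "male"), 1L)
    scroll <- sample(c("happy_right", "happy_left"), 1L)
    tibble::tibble(
      participant_id = participant_id,
      group = group,
      gender = gender,
      trait_anxiety = anx,
      scroll_mapping = scroll,
      trials |> dplyr::select(-"emotion_condition")
    )
  })
}

#' Simulate a two-group cohort
#'
#' @param n_young,n_old Number of participants per age group.
#' @param params_young,params_old `emowm_params` per group; defaults are
#'   [default_cohort_params()].
#' @param seed Master seed; per-participant substream seeds are derived from
#'   it, so the whole table is reproducible.
#' @return A validated trial tibble, `(n_young + n_old) * 200` rows.
#' @export
simulate_cohort <- function(n_young, n_old,
                            params_young = default_cohort_params()$young,
                            params_old = default_cohort_params()$old,
                            seed = 1L) {
  stopifnot(n_young >= 1L, n_old >= 1L)
  groups <- c(rep("young", n_young), rep("old", n_old))
  ids <- sprintf("P%03d", seq_along(groups))
  tabs <- lapply(seq_along(groups), function(k) {
    p <- if (groups[k] == "young") params_young else params_old
    simulate_participant(
      ids[k], groups[k], p,
      seed = (as.integer(seed) + 7919L * k) %% .Machine$integer.max
    )
  })
  validate_trials(dplyr::bind_rows(tabs))
}
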