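# Fixtures are built in code. `make_trials()` wraps arbitrary signed
# target/response pairs in a valid trial table (matching task, so targets
# need not sit on the WM 5%-step grid); `perfect_participant()` returns a
# full WM design answered without error.

make_trials <- function(signed_target, signed_response,
                        task = "matching",
                        participant_id = "P1",
                        response_time = 2,
                        timed_out = FALSE,
                        block = 1L) {
  n <- length(signed_target)
  tibble::tibble(
    participant_id = participant_id,
    group = "young",
    gender = "female",
    trait_anxiety = 35,
    task = task,
    block = block,
    trial_index = stats::ave(seq_len(n), block, FUN = seq_along),
    target_emotion = dplyr::case_when(
      signed_target < 0 ~ "fear",
      signed_target > 0 ~ "happy",
      .default = "neutral"
    ),
    target_intensity = abs(signed_target),
    identity_id = rep_len(1:10, n),
    signed_response = as.integer(signed_response),
    response_time = response_time,
    timed_out = timed_out
  )
}

# full WM schedule answered with a deterministic response rule
responder_trials <- function(seed = 101, rule = identity) {
  sk <- schedule_trials(build_wm_schedule(seed))
  tibble::tibble(
    participant_id = "P1", group = "young", gender = "female",
    trait_anxiety = 35,
    sk |> dplyr::select(-"emotion_condition")
  ) |>
    dplyr::mutate(
      signed_response = as.integer(pmin(100, pmax(-100, rule(.data$signed_target)))),
      response_time = 2, timed_out = FALSE
    )
}

perfect_participant <- function(seed = 101) {
  responder_trials(seed, identity)
}

# noiseless-ish parameter set: effectively deterministic reports
quiet_params <- function(...) {
  generative_params(
    noise_sd = c(fear = 1e-9, happy = 1e-9),
    flip_base_rate = c(fear = 0, happy = 0),
    timeout_rate = 0,
    ...
  )
}
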