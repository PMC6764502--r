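test_that("trial error and bias reproduce the worked examples", {
  # error: happy 50 reported 60 -> 10; fear 20 reported 15 fear -> 5;
  # fear 20 reported 15 happy -> 35
  expect_equal(trial_error(50L, 60L), 10)
  expect_equal(trial_error(50L, 40L), 10)
  expect_equal(trial_error(-20L, -15L), 5)
  expect_equal(trial_error(-20L, 15L), 35)
  expect_equal(trial_error(37L, 37L), 0)
  # bias: signed response minus signed target
  expect_equal(trial_bias(50L, 60L), 10)
  expect_equal(trial_bias(50L, 40L), -10)
  expect_equal(trial_bias(-20L, 15L), 35)
  expect_equal(trial_bias(15L, -20L), -35)
  expect_error(trial_error(150L, 0L), "outside")
  expect_error(trial_bias(0L, -101L), "outside")
})

test_that("error equals |bias| and extremes are exact on the exhaustive grid", {
  grid <- expand.grid(t = -100:100, r = -100:100)
  err <- trial_error(grid$t, grid$r)
  expect_equal(err, abs(trial_bias(grid$t, grid$r)))
  expect_equal(max(err), 200)
  expect_equal(min(trial_bias(grid$t, grid$r)), -200)
  expect_equal(max(trial_bias(grid$t, grid$r)), 200)
  # for a fixed target of magnitude m the maximum error is m + 100
  for (m in c(0L, 35L, 50L, 100L)) {
    expect_equal(max(trial_error(-m, -100:100)), m + 100)
  }
})

test_that("participant error averages absolute errors and honors exclusions", {
  tr <- make_trials(c(50L, -20L), c(60L, 15L))
  expect_equal(participant_error(tr), (10 + 35) / 2)
  expect_equal(participant_error(tr, "drop_wrong_emotion"), 10)
  expect_equal(participant_error(perfect_participant()), 0)
  expect_error(
    participant_error(make_trials(-20L, 15L), "drop_wrong_emotion"),
    "no retained trials"
  )
})

test_that("perfect and mirrored responders bracket the overall bias at zero", {
  perfect <- perfect_participant()
  expect_equal(participant_bias_overall(perfect), 0)
  expect_equal(participant_bias_overall(perfect, weights = "trial"), 0)
  mirror <- responder_trials(rule = function(t) -t)
  expect_equal(participant_bias_overall(mirror), 0)
})

test_that("overall bias responds linearly to a uniform shift", {
  shifted <- responder_trials(rule = function(t) t + 7L)
  # +7 on every trial, clipped at +100: the two top happy conditions clip
  cm <- 7 - (7 + 2) / 39 # conditions 95->100 (lose 2) and 100->100 (lose 7)
  expect_equal(participant_bias_overall(shifted), cm)
  expect_equal(
    participant_bias_overall(shifted, weights = "trial"),
    mean(pmin(validate_trials(shifted)$signed_target + 7, 100) -
      validate_trials(shifted)$signed_target) + 0,
    tolerance = 1e-12
  )
})

test_that("per-emotion bias carries the conventional subtract-50 residual", {
  perfect <- perfect_participant()
  be <- participant_bias_by_emotion(perfect)
  expect_equal(unname(be["fear"]), 1000 / 19 - 50, tolerance = 1e-12)
  expect_equal(unname(be["happy"]), 1000 / 19 - 50, tolerance = 1e-12)
  # the exact normalizer zeroes an unbiased responder
  be0 <- participant_bias_by_emotion(perfect, normalizer = "exact")
  expect_equal(unname(be0), c(0, 0), tolerance = 1e-12)
  # linearity: reporting target - 10 on happy trials only
  dimmed <- responder_trials(rule = identity) |>
    dplyr::mutate(signed_response = as.integer(
      .data$signed_response - 10L * (.data$signed_target > 0)
    ))
  bd <- participant_bias_by_emotion(dimmed)
  expect_equal(unname(bd["happy"]), 1000 / 19 - 50 - 10, tolerance = 1e-12)
  expect_equal(unname(bd["fear"]), 1000 / 19 - 50, tolerance = 1e-12)
})

test_that("block feedback is 100 minus block mean error", {
  perfect <- perfect_participant()
  fb <- feedback_by_block(perfect[perfect$task == "wm", ])
  expect_equal(fb$feedback, rep(100, 8))
  one <- make_trials(-20L, 15L) # single trial, error 35
  expect_equal(block_feedback(validate_trials(one)), 65)
  three <- make_trials(c(10L, 20L, 30L), c(25L, 35L, 45L)) # errors all 15
  expect_equal(block_feedback(validate_trials(three)), 85)
  expect_error(block_feedback(three[0, ]), "empty block")
})

test_that("psychometric binning follows the eleven-bin convention", {
  bins <- psychometric_bins()
  expect_equal(nrow(bins), 11L)
  expect_equal(bins$lo[bins$bin == -1], -20L) # the -20 bin covers -20..-1
  expect_equal(bins$hi[bins$bin == -1], -1L)

  perfect <- perfect_participant()
  curve <- bin_psychometric_curve(perfect)
  tgt <- validate_trials(perfect)$signed_target
  for (i in seq_len(nrow(curve))) {
    inbin <- tgt >= curve$lo[i] & tgt <= curve$hi[i]
    expect_equal(curve$n[i], sum(inbin))
    expect_equal(curve$mean_response[i], mean(tgt[inbin]))
  }

  lone <- make_trials(c(-100L, -100L), c(-100L, -100L))
  lc <- bin_psychometric_curve(validate_trials(lone))
  expect_equal(lc$n[lc$bin == -5], 2L)
  expect_equal(lc$mean_response[lc$bin == -5], -100)
  expect_true(all(lc$n[lc$bin != -5] == 0L))
  # a -20 target lands in the innermost fear bin
  expect_equal(
    bin_psychometric_curve(make_trials(-20L, -5L))$n[
      psychometric_bins()$bin == -1
    ], 1L
  )
})

test_that("vectorized scoring matches naive loop oracles to 1e-12", {
  tr <- simulate_participant("P1", "old", default_cohort_params()$old, 17)
  tr <- validate_trials(tr)
  wm <- tr[tr$task == "wm", ]

  naive_error <- mean(vapply(
    seq_len(nrow(wm)),
    function(i) abs(wm$signed_target[i] - wm$signed_response[i]),
    numeric(1)
  ))
  expect_equal(participant_error(wm), naive_error, tolerance = 1e-12)

  conds <- sort(unique(wm$signed_target))
  naive_bias <- mean(vapply(conds, function(cc) {
    mean(wm$signed_response[wm$signed_target == cc])
  }, numeric(1)))
  expect_equal(participant_bias_overall(wm), naive_bias, tolerance = 1e-12)

  sc <- score_trials(tr)
  expect_equal(
    sc$mean_error[sc$task == "wm"], participant_error(wm),
    tolerance = 1e-12
  )
  expect_equal(
    sc$bias_fear[sc$task == "wm"],
    unname(participant_bias_by_emotion(wm)["fear"]),
    tolerance = 1e-12
  )
})
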