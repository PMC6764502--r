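welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

test_that("Welch t matches the brute-force formula and its special cases", {
  set.seed(1)
  a <- rnorm(11, 1, 2)
  b <- rnorm(17, 0, 0.5)
  got <- welch_t(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$statistic, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(
    got$effect_size,
    (mean(a) - mean(b)) /
      sqrt((10 * var(a) + 16 * var(b)) / 26),
    tolerance = 1e-10
  )

  # identical groups: t = 0, d = 0
  x <- c(1, 2, 3)
  same <- welch_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)

  # equal variance, equal n: Welch df = 2n - 2 and t equals the pooled t
  a2 <- c(1, 2, 3)
  b2 <- c(4, 5, 6)
  eq <- welch_t(a2, b2)
  expect_equal(eq$df, 4)
  sp <- sqrt(var(a2)) # equal variances
  expect_equal(eq$statistic, (mean(a2) - mean(b2)) / (sp * sqrt(2 / 3)),
    tolerance = 1e-12
  )
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("paired and one-sample t match their formula oracles", {
  set.seed(2)
  a <- rnorm(15)
  b <- a + rnorm(15, 0.3)
  got <- paired_t(a, b)
  d <- a - b
  expect_equal(got$statistic, mean(d) / (sd(d) / sqrt(15)), tolerance = 1e-10)
  expect_equal(got$df, 14)
  expect_equal(got$effect_size, mean(d) / sd(d), tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(-abs(got$statistic), 14), tolerance = 1e-10)

  # mean difference zero -> t = 0
  expect_equal(paired_t(c(1, 3), c(2, 2))$statistic, 0)
  expect_error(paired_t(c(1, 2), c(2, 3)), "zero variance")

  one <- one_sample_t(c(1, 2, 3), mu0 = 2)
  expect_equal(one$statistic, 0)
  set.seed(3)
  x <- rnorm(9, 1)
  got1 <- one_sample_t(x, mu0 = 0.5)
  expect_equal(got1$statistic, (mean(x) - 0.5) / (sd(x) / 3), tolerance = 1e-10)
})

test_that("Cohen's d CIs invert the noncentral t consistently", {
  # symmetric about zero for a null effect with equal n
  ci0 <- cohens_d_ci(0, 12, 12)
  expect_equal(ci0[1], -ci0[2], tolerance = 1e-7)

  ci <- cohens_d_ci(0.8, 20, 25, level = 95)
  expect_true(ci[1] < 0.8 && 0.8 < ci[2])
  # the bounds put the observed t at the 97.5th / 2.5th noncentral percentile
  mult <- sqrt(20 * 25 / 45)
  expect_equal(pt(0.8 * mult, 43, ncp = ci[1] * mult), 0.975, tolerance = 1e-6)
  expect_equal(pt(0.8 * mult, 43, ncp = ci[2] * mult), 0.025, tolerance = 1e-6)
  # intervals shrink with n
  wide <- cohens_d_ci(0.5, 10, 10)
  narrow <- cohens_d_ci(0.5, 100, 100)
  expect_lt(diff(narrow), diff(wide))
  # one-sample scaling
  ci1 <- cohens_d_ci(0.5, 30)
  expect_equal(pt(0.5 * sqrt(30), 29, ncp = ci1[1] * sqrt(30)), 0.975,
    tolerance = 1e-6
  )
})

test_that("partial eta squared CIs invert the noncentral F with a zero floor", {
  expect_equal(eta_sq_ci(0, 1, 50)[1], 0)
  expect_equal(eta_sq_ci(0.5, 1, 100)[1], 0) # small F: interval anchored at 0

  ci <- eta_sq_ci(14.1, 1, 101, level = 90)
  expect_true(ci[1] > 0 && ci[2] < 1 && ci[1] < ci[2])
  to_lambda <- function(eta) eta * (1 + 101 + 1) / (1 - eta)
  expect_equal(pf(14.1, 1, 101, ncp = to_lambda(ci[1])), 0.95, tolerance = 1e-6)
  expect_equal(pf(14.1, 1, 101, ncp = to_lambda(ci[2])), 0.05, tolerance = 1e-6)
})

sim_long <- function(n_per_group, k_within = 2, effects = c(0, 0, 0),
                     seed = 1) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      participant_id = sprintf("S%02d", seq_len(2 * n_per_group)),
      emotion = paste0("w", seq_len(k_within))
    )
    grid$group <- rep(c("young", "old"),
      each = k_within * n_per_group
    )
    subj <- stats::rnorm(2 * n_per_group, sd = 1)
    grid$value <- stats::rnorm(nrow(grid)) +
      subj[as.integer(factor(grid$participant_id))] +
      effects[1] * (grid$group == "old") +
      effects[2] * (grid$emotion == "w1") +
      effects[3] * (grid$group == "old") * (grid$emotion == "w1")
    grid$trait_anxiety <- stats::rnorm(2 * n_per_group)[
      as.integer(factor(grid$participant_id))
    ]
    grid$gender <- rep(
      sample(c("f", "m"), 2 * n_per_group, replace = TRUE),
      each = k_within
    )
    grid
  })
}

test_that("mixed ANCOVA matches the classical aov decomposition when balanced", {
  d <- sim_long(10, effects = c(0.8, 0.5, 0.4), seed = 42)
  got <- mixed_ancova(d,
    dv = "value", id = "participant_id",
    within = "emotion", between = "group"
  )
  oracle <- summary(stats::aov(
    value ~ group * emotion + Error(participant_id / emotion),
    data = d
  ))
  f_between <- oracle[["Error: participant_id"]][[1]]
  f_within <- oracle[["Error: participant_id:emotion"]][[1]]
  expect_equal(
    got$statistic[got$effect == "group"],
    f_between["group", "F value"],
    tolerance = 1e-10
  )
  expect_equal(
    got$statistic[got$effect == "emotion"],
    f_within["emotion", "F value"],
    tolerance = 1e-10
  )
  expect_equal(
    got$statistic[got$effect == "group:emotion"],
    f_within["group:emotion", "F value"],
    tolerance = 1e-10
  )
  expect_equal(
    got$p[got$effect == "group"],
    f_between["group", "Pr(>F)"],
    tolerance = 1e-10
  )
  # partial eta^2 against the SS decomposition
  ss_g <- f_between["group", "Sum Sq"]
  ss_ge <- f_between["Residuals", "Sum Sq"]
  expect_equal(
    got$partial_eta_sq[got$effect == "group"],
    ss_g / (ss_g + ss_ge),
    tolerance = 1e-10
  )
  # a 2-level within factor gets no sphericity correction
  expect_true(all(is.na(got$gg_epsilon)))
  expect_false(any(got$gg_applied))
})

test_that("GG correction applies to >=3-level within factors and never lowers p", {
  d <- sim_long(12, k_within = 5, seed = 7)
  # induce a sphericity violation: inflate one cell's variance
  d$value[d$emotion == "w1"] <- d$value[d$emotion == "w1"] * 3
  got <- mixed_ancova(d,
    dv = "value", id = "participant_id",
    within = "emotion", between = "group", gg = "always"
  )
  w <- got[got$effect == "emotion", ]
  expect_true(is.finite(w$gg_epsilon))
  expect_true(w$gg_epsilon > 1 / 4 && w$gg_epsilon <= 1)
  expect_true(w$gg_applied)
  expect_equal(w$df_num, w$gg_epsilon * w$df_num_unadj)
  expect_gte(w$p, w$p_unadj)
  # with gg = "never" the uncorrected dfs are reported
  raw <- mixed_ancova(d,
    dv = "value", id = "participant_id",
    within = "emotion", between = "group", gg = "never"
  )
  expect_equal(raw$df_num[raw$effect == "emotion"], 4)
})

test_that("constant covariates drop so the ANCOVA reduces to the ANOVA", {
  d <- sim_long(8, seed = 3)
  d$const <- 1
  expect_message(
    with_cov <- mixed_ancova(d,
      dv = "value", id = "participant_id",
      within = "emotion", between = "group", covariates = "const"
    ),
    "constant covariate"
  )
  plain <- mixed_ancova(d,
    dv = "value", id = "participant_id",
    within = "emotion", between = "group"
  )
  expect_equal(with_cov$statistic, plain$statistic, tolerance = 1e-12)
})

test_that("incomplete designs and collinear covariates are explicit errors", {
  d <- sim_long(6, seed = 4)
  expect_error(
    mixed_ancova(d[-1, ],
      dv = "value", id = "participant_id",
      within = "emotion", between = "group"
    ),
    "incomplete design"
  )
  d$dup <- d$trait_anxiety
  expect_error(
    mixed_ancova(d,
      dv = "value", id = "participant_id",
      within = "emotion", between = "group",
      covariates = c("trait_anxiety", "dup")
    ),
    "collinear"
  )
})

test_that("a pure between-subjects ANCOVA is supported", {
  d <- sim_long(10, seed = 9)
  one <- d[d$emotion == "w1", ]
  got <- mixed_ancova(one,
    dv = "value", id = "participant_id",
    between = "group", covariates = "trait_anxiety"
  )
  expect_setequal(got$effect, c("group", "trait_anxiety"))
  fit <- stats::lm(
    value ~ group + trait_anxiety,
    data = transform(one,
      group = factor(group),
      trait_anxiety = trait_anxiety - mean(trait_anxiety)
    ),
    contrasts = list(group = "contr.sum")
  )
  oracle <- car::Anova(fit, type = 3)
  expect_equal(
    got$statistic[got$effect == "group"],
    oracle["group", "F value"],
    tolerance = 1e-10
  )
})
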