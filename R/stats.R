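# Group-level inference: t tests with Cohen's d, effect-size confidence
# intervals by noncentral-distribution inversion, and mixed repeated-measures
# ANCOVA (Type III, effects coding) with Greenhouse-Geisser correction.

#' @importFrom rlang .data
NULL

new_test_result <- function(statistic, df, p, effect_size, effect_ci,
                            ci_level, method, extra = list()) {
  structure(
    c(
      list(
        statistic = statistic, df = df, p = p,
        effect_size = effect_size, effect_ci = effect_ci,
        ci_level = ci_level, method = method
      ),
      extra
    ),
    class = "emowm_test"
  )
}

#' @export
print.emowm_test <- function(x, ...) {
  cat(sprintf(
    "%s: t(%.2f) = %.3f, p = %.4g, d = %.3f, %g%% CI [%.3f, %.3f]\n",
    x$method, x$df, x$statistic, x$p, x$effect_size,
    x$ci_level, x$effect_ci[1], x$effect_ci[2]
  ))
  invisible(x)
}

# Two-sided CI for a noncentrality parameter given an observed statistic:
# bounds are the ncp values under which the observed value sits at the
# (1 - alpha/2) and (alpha/2) quantiles.
invert_ncp <- function(obs, pfun, lower_bound, level) {
  alpha <- 1 - level / 100
  solve_for <- function(target) {
    # pt/pf emit a "full precision" warning at extreme ncp; harmless here
    f <- function(ncp) suppressWarnings(pfun(obs, ncp)) - target
    if (f(lower_bound) < 0) {
      return(lower_bound)
    }
    hi <- max(abs(obs), 1)
    while (f(hi) > 0) hi <- hi * 2
    lo <- lower_bound
    if (is.infinite(lo)) {
      lo <- -max(abs(obs), 1)
      while (f(lo) < 0) lo <- lo * 2
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  }
  c(solve_for(1 - alpha / 2), solve_for(alpha / 2))
}

#' Confidence interval for Cohen's d via the noncentral t distribution
#'
#' The observed d is converted to a t statistic, a two-sided CI for the
#' noncentrality parameter is found by inverting the noncentral t CDF, and
#' the bounds are mapped back to the d scale. For two samples, d is the
#' pooled-SD standardized mean difference with `df = n_a + n_b - 2`; with
#' `n_b = NULL`, d is a one-sample (or paired, d_z) effect with `df = n - 1`.
#'
#' @param d Observed Cohen's d.
#' @param n_a,n_b Group sizes (`n_b = NULL` for one-sample/paired).
#' @param level Confidence level in percent.
#' @return `c(low, high)` on the d scale.
#' @export
cohens_d_ci <- function(d, n_a, n_b = NULL, level = 95) {
  stopifnot(is.finite(d), level > 0, level < 100)
  if (is.null(n_b)) {
    mult <- sqrt(n_a)
    df <- n_a - 1
  } else {
    mult <- sqrt(n_a * n_b / (n_a + n_b))
    df <- n_a + n_b - 2
  }
  t_obs <- d * mult
  ncp <- invert_ncp(
    t_obs,
    function(q, ncp) stats::pt(q, df = df, ncp = ncp),
    lower_bound = -Inf, level = level
  )
  ncp / mult
}

#' Confidence interval for partial eta squared via the noncentral F
#'
#' Inverts the noncentral F CDF for the noncentrality parameter lambda at the
#' observed F, then maps bounds to the partial eta squared scale with
#' `eta2 = lambda / (lambda + df_num + df_den + 1)`. Lambda cannot be
#' negative, so the lower bound is floored at 0 (an F near its null
#' expectation yields an interval anchored at zero).
#'
#' @param f Observed F statistic.
#' @param df_num,df_den Numerator and denominator degrees of freedom
#'   (fractional allowed).
#' @param level Confidence level in percent (90 is conventional for
#'   partial eta squared, matching a two-sided test at alpha = .05).
#' @return `c(low, high)` on the partial eta squared scale.
#' @export
eta_sq_ci <- function(f, df_num, df_den, level = 90) {
  stopifnot(is.finite(f), f >= 0, df_num > 0, df_den > 0, level > 0, level < 100)
  lambda <- invert_ncp(
    f,
    function(q, ncp) stats::pf(q, df1 = df_num, df2 = df_den, ncp = ncp),
    lower_bound = 0, level = level
  )
  lambda / (lambda + df_num + df_den + 1)
}

pooled_sd <- function(a, b) {
  sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2))
}

#' Welch two-sample t test with Cohen's d
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom;
#' Cohen's d uses the pooled SD, with a CI by noncentral-t inversion.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param ci_level Confidence level (percent) for the d CI.
#' @return An `emowm_test` with `statistic`, `df`, `p`, `effect_size` (d),
#'   `effect_ci`, and the group means.
#' @export
welch_t <- function(group_a, group_b, ci_level = 95) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  sp <- pooled_sd(group_a, group_b)
  if (sp == 0) stop("zero variance in both groups", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  d <- (mean(group_a) - mean(group_b)) / sp
  new_test_result(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, effect_size = d,
    effect_ci = cohens_d_ci(d, length(group_a), length(group_b), ci_level),
    ci_level = ci_level, method = "Welch two-sample t",
    extra = list(mean_a = mean(group_a), mean_b = mean(group_b))
  )
}

#' Paired t test with d_z (and pooled d) effect sizes
#'
#' The primary effect size is d_z, the mean paired difference divided by the
#' SD of the differences, with a noncentral-t CI; the pooled-SD standardized
#' difference is also reported as `d_pooled`.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2.
#' @inheritParams welch_t
#' @return An `emowm_test`.
#' @export
paired_t <- function(values_a, values_b, ci_level = 95) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  diffs <- values_a - values_b
  if (stats::sd(diffs) == 0) {
    stop("zero variance of paired differences", call. = FALSE)
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  dz <- mean(diffs) / stats::sd(diffs)
  new_test_result(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, effect_size = dz,
    effect_ci = cohens_d_ci(dz, length(diffs), NULL, ci_level),
    ci_level = ci_level, method = "Paired t (d_z)",
    extra = list(d_pooled = mean(diffs) / pooled_sd(values_a, values_b))
  )
}

#' One-sample t test against a reference value
#'
#' Used e.g. to test whether categorization slopes (or slope differences)
#' differ from zero. Effect size is `(mean - mu0) / sd`.
#'
#' @param values Numeric vector, length >= 2.
#' @param mu0 Null value.
#' @inheritParams welch_t
#' @return An `emowm_test`.
#' @export
one_sample_t <- function(values, mu0 = 0, ci_level = 95) {
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0) stop("zero variance", call. = FALSE)
  ht <- stats::t.test(values, mu = mu0)
  d <- (mean(values) - mu0) / stats::sd(values)
  new_test_result(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, effect_size = d,
    effect_ci = cohens_d_ci(d, length(values), NULL, ci_level),
    ci_level = ci_level, method = "One-sample t"
  )
}

#' Mixed repeated-measures ANCOVA with Greenhouse-Geisser correction
#'
#' Fits the classical univariate mixed model via a multivariate linear model
#' on the wide (one column per within-subject cell) data with Type III sums
#' of squares and effects-coded factors, the convention of the repeated-
#' measures ANOVA packages in this field. Between-subject factors are fully
#' crossed with each other and with the within factors; covariates enter
#' additively (numeric covariates centered first, so main effects are
#' evaluated at the covariate mean). Sphericity of within effects with three
#' or more levels is assessed by Mauchly's test; when rejected at
#' `sphericity_alpha` (and `gg = "auto"`), Greenhouse-Geisser-corrected
#' degrees of freedom and p values are reported for those effects. Partial
#' eta squared is `SS_effect / (SS_effect + SS_error)` with a CI from
#' [eta_sq_ci()].
#'
#' @param data Long-format data frame: one row per participant x within-cell.
#' @param dv Name of the dependent-variable column.
#' @param id Name of the participant identifier column.
#' @param within Character vector of within-subject factor columns (may be
#'   empty/NULL for a pure between-subjects ANCOVA).
#' @param between Character vector of between-subject factor columns.
#' @param covariates Character vector of covariate columns (continuous or
#'   categorical) entered additively; constant covariates are dropped with a
#'   message, so the model degrades gracefully to an ANOVA.
#' @param gg `"auto"` (apply GG when Mauchly rejects), `"never"`, or
#'   `"always"` (apply to every eligible within effect).
#' @param sphericity_alpha Mauchly test level used by `gg = "auto"`.
#' @param ci_level Level (percent) of the partial eta squared CI.
#' @return A tibble of class `emowm_ancova`: one row per effect with
#'   `effect`, `df_num`, `df_den`, `statistic` (F), `p`, `partial_eta_sq`,
#'   `eta_ci_low`, `eta_ci_high`, `gg_epsilon`, `gg_applied`,
#'   `mauchly_p`, and the uncorrected `df_num_unadj`, `df_den_unadj`,
#'   `p_unadj`.
#' @export
mixed_ancova <- function(data, dv, id, within = NULL, between = NULL,
                         covariates = NULL, gg = c("auto", "never", "always"),
                         sphericity_alpha = 0.05, ci_level = 90) {
  gg <- match.arg(gg)
  data <- tibble::as_tibble(data)
  for (col in c(dv, id, within, between, covariates)) {
    if (!col %in% names(data)) {
      stop("column `", col, "` not found", call. = FALSE)
    }
  }
  within <- as.character(within %||% character(0))
  between <- as.character(between %||% character(0))
  covariates <- as.character(covariates %||% character(0))

  # drop constant covariates so the model reduces to a plain (mixed) ANOVA
  keep <- vapply(covariates, function(cv) {
    length(unique(data[[cv]])) > 1L
  }, logical(1))
  if (any(!keep)) {
    message(
      "dropping constant covariate(s): ",
      paste(covariates[!keep], collapse = ", ")
    )
    covariates <- covariates[keep]
  }

  for (col in between) data[[col]] <- factor(data[[col]])
  for (col in covariates) {
    if (is.numeric(data[[col]])) {
      data[[col]] <- data[[col]] - mean(data[[col]])
    } else {
      data[[col]] <- factor(data[[col]])
    }
  }

  rhs <- c(
    if (length(between) > 0) paste(between, collapse = " * "),
    covariates
  )
  rhs <- if (length(rhs) == 0) "1" else paste(rhs, collapse = " + ")

  withr::local_options(contrasts = c("contr.sum", "contr.poly"))

  if (length(within) == 0L) {
    return(between_ancova(data, dv, rhs, ci_level))
  }

  for (col in within) data[[col]] <- factor(data[[col]])
  cells <- do.call(interaction, c(data[within], list(sep = ".", drop = FALSE)))
  data$.cell <- factor(cells, levels = levels(cells))
  wide <- data |>
    dplyr::select(dplyr::all_of(c(id, between, covariates)), ".cell",
      dplyr::all_of(dv)
    ) |>
    tidyr::pivot_wider(names_from = ".cell", values_from = dplyr::all_of(dv))
  cell_names <- levels(data$.cell)
  if (anyNA(wide[, cell_names]) ||
    nrow(wide) * length(cell_names) != nrow(data)) {
    stop(
      "incomplete design: every participant needs exactly one row per ",
      "within-subject cell", call. = FALSE
    )
  }
  idata <- do.call(
    tidyr::expand_grid,
    rev(lapply(data[within], function(x) factor(levels(x), levels(x))))
  )[, within, drop = FALSE]
  as_df <- as.data.frame(idata)
  stopifnot(identical(
    cell_names,
    do.call(paste, c(as_df, list(sep = ".")))
  ))
  resp <- as.matrix(wide[, cell_names])
  fit <- stats::lm(
    stats::as.formula(paste("resp ~", rhs)),
    data = wide
  )
  if (anyNA(stats::coef(fit))) {
    stop("collinear predictors in the between-subjects model", call. = FALSE)
  }
  idesign <- stats::as.formula(paste("~", paste(within, collapse = " * ")))
  av <- car::Anova(fit, idata = as_df, idesign = idesign, type = 3)
  s <- summary(av, multivariate = FALSE)
  build_ancova_table(s, within, gg, sphericity_alpha, ci_level)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

between_ancova <- function(data, dv, rhs, ci_level) {
  fit <- stats::lm(
    stats::as.formula(paste(dv, "~", rhs)),
    data = data
  )
  if (anyNA(stats::coef(fit))) {
    stop("collinear predictors in the between-subjects model", call. = FALSE)
  }
  av <- car::Anova(fit, type = 3)
  ss_err <- av["Residuals", "Sum Sq"]
  df_err <- av["Residuals", "Df"]
  effects <- setdiff(rownames(av), c("(Intercept)", "Residuals"))
  rows <- lapply(effects, function(e) {
    ss <- av[e, "Sum Sq"]
    f <- av[e, "F value"]
    df1 <- av[e, "Df"]
    ci <- eta_sq_ci(f, df1, df_err, ci_level)
    tibble::tibble(
      effect = e, df_num = df1, df_den = df_err, statistic = f,
      p = av[e, "Pr(>F)"],
      partial_eta_sq = ss / (ss + ss_err),
      eta_ci_low = ci[1], eta_ci_high = ci[2],
      gg_epsilon = NA_real_, gg_applied = FALSE, mauchly_p = NA_real_,
      df_num_unadj = df1, df_den_unadj = df_err, p_unadj = av[e, "Pr(>F)"]
    )
  })
  structure(dplyr::bind_rows(rows),
    class = c("emowm_ancova", class(tibble::tibble()))
  )
}

build_ancova_table <- function(s, within, gg, sphericity_alpha, ci_level) {
  ut <- s$univariate.tests
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  effects <- setdiff(rownames(ut), "(Intercept)")
  rows <- lapply(effects, function(e) {
    ss <- ut[e, "Sum Sq"]
    ss_err <- ut[e, "Error SS"]
    f <- ut[e, "F value"]
    df1 <- ut[e, "num Df"]
    df2 <- ut[e, "den Df"]
    p <- ut[e, "Pr(>F)"]
    eps <- NA_real_
    mau_p <- NA_real_
    applied <- FALSE
    if (!is.null(sph) && e %in% rownames(sph)) {
      mau_p <- sph[e, "p-value"]
      eps <- adj[e, "GG eps"]
      applied <- switch(gg,
        never = FALSE,
        always = TRUE,
        auto = is.finite(mau_p) && mau_p < sphericity_alpha
      )
    }
    df1_adj <- if (applied) eps * df1 else df1
    df2_adj <- if (applied) eps * df2 else df2
    p_adj <- if (applied) adj[e, "Pr(>F[GG])"] else p
    ci <- eta_sq_ci(f, df1_adj, df2_adj, ci_level)
    tibble::tibble(
      effect = e, df_num = df1_adj, df_den = df2_adj, statistic = f,
      p = p_adj,
      partial_eta_sq = ss / (ss + ss_err),
      eta_ci_low = ci[1], eta_ci_high = ci[2],
      gg_epsilon = eps, gg_applied = applied, mauchly_p = mau_p,
      df_num_unadj = df1, df_den_unadj = df2, p_unadj = p
    )
  })
  structure(dplyr::bind_rows(rows),
    class = c("emowm_ancova", class(tibble::tibble()))
  )
}
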