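#' Linear mixed-effects session/run trend model
#'
#' Fits the learning-trend model for one group and one outcome measure:
#' fixed linear effects of session (1..10) and run (1..7, baseline run
#' coded 1) and their interaction, with a subject random intercept and
#' uncorrelated subject random slopes for session and run. F tests are
#' sequential (Type I) with Satterthwaite denominator degrees of freedom.
#' A two-stage estimator (per-subject OLS, then a one-sample t test of the
#' per-subject slopes) is always computed alongside as an internal
#' cross-check; on balanced data its session-slope estimate coincides with
#' the mixed model's. If the mixed model fails or is singular the result is
#' flagged and the two-stage estimates stand in.
#'
#' @param data Data frame with columns `subject`, `session`, `run` and the
#'   outcome. `session` and `run` are used as numeric covariates.
#' @param outcome Name of the outcome column (default `"band_imcoh"`).
#' @return An object of class `trend_result`: `anova` (tibble with effect,
#'   F, df, MSE, p), `slopes` (fixed-effect estimates with SEs),
#'   `two_stage` (see [two_stage_trend()]), `singular`, `converged`,
#'   `model` (the `lmerModLmerTest` fit or `NULL`).
#' @export
fit_trend <- function(data, outcome = "band_imcoh") {
  data <- as.data.frame(data)
  stopifnot(all(c("subject", "session", "run", outcome) %in% names(data)))
  if (length(unique(data$subject)) < 2) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  data$.y <- data[[outcome]]
  two_stage <- two_stage_trend(data, outcome)

  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(.y ~ session + run + session:run + (1 | subject) +
                       (0 + session | subject) + (0 + run | subject),
                     data = data, REML = TRUE)
    )),
    error = function(e) NULL)

  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-4)
  av <- NULL
  slopes <- NULL
  if (!is.null(fit)) {
    at <- tryCatch(
      suppressMessages(suppressWarnings(stats::anova(fit, type = 1))),
      error = function(e) NULL)
    if (!is.null(at)) {
      av <- tibble::tibble(effect = rownames(at),
                           F = at[["F value"]],
                           df1 = at[["NumDF"]], df2 = at[["DenDF"]],
                           MSE = at[["Mean Sq"]],
                           p = at[["Pr(>F)"]])
    }
    cf <- summary(fit)$coefficients
    slopes <- tibble::tibble(term = rownames(cf),
                             estimate = unname(cf[, "Estimate"]),
                             se = unname(cf[, "Std. Error"]))
  }
  structure(list(anova = av, slopes = slopes, two_stage = two_stage,
                 singular = singular, converged = !is.null(fit) && !is.null(av),
                 outcome = outcome, model = fit),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result for '%s'%s>\n", x$outcome,
              if (x$singular) " (singular/failed fit; see $two_stage)" else ""))
  if (!is.null(x$anova)) print(as.data.frame(x$anova), digits = 4)
  cat(sprintf("two-stage session slope: %.5f (t = %.3f, df = %d, p = %.4f)\n",
              x$two_stage$session$mean_slope, x$two_stage$session$t,
              x$two_stage$session$df, x$two_stage$session$p))
  invisible(x)
}

#' Two-stage trend estimator
#'
#' Stage 1: per subject, an OLS fit of `outcome ~ session + run +
#' session:run`. Stage 2: one-sample t tests (df = n_subjects - 1) of the
#' per-subject coefficients against zero. Serves as a distribution-free
#' cross-check of the mixed model; on balanced designs the mean per-subject
#' OLS slope equals the mixed model's fixed-effect estimate.
#'
#' @inheritParams fit_trend
#' @return List with per-term components (`session`, `run`, `interaction`),
#'   each holding `per_subject`, `mean_slope`, `se`, `t`, `df`, `p`.
#' @export
two_stage_trend <- function(data, outcome = "band_imcoh") {
  data <- as.data.frame(data)
  data$.y <- data[[outcome]]
  subs <- split(data, data$subject)
  coefs <- t(vapply(subs, function(d) {
    stats::coef(stats::lm(.y ~ session + run + session:run, data = d))
  }, numeric(4)))
  one_sample <- function(v) {
    n <- length(v)
    m <- mean(v)
    s <- stats::sd(v)
    if (s <= 1e-12 + 1e-10 * abs(m)) {
      list(per_subject = v, mean_slope = m, se = 0, t = NA_real_,
           df = n - 1L, p = if (m == 0) 1 else 0, degenerate = TRUE)
    } else {
      tt <- m / (s / sqrt(n))
      list(per_subject = v, mean_slope = m, se = s / sqrt(n), t = tt,
           df = n - 1L, p = 2 * stats::pt(-abs(tt), n - 1), degenerate = FALSE)
    }
  }
  list(session = one_sample(coefs[, "session"]),
       run = one_sample(coefs[, "run"]),
       interaction = one_sample(coefs[, "session:run"]),
       n_subjects = nrow(coefs))
}

#' Cousineau-Morey within-subject standard errors
#'
#' For a complete subjects x conditions matrix: each subject's values are
#' recentred by replacing the subject mean with the grand mean
#' (\eqn{y'_{ij} = y_{ij} - \bar y_{i.} + \bar y_{..}}), the per-condition
#' standard error of the recentred values is taken across subjects, and the
#' result is inflated by \eqn{\sqrt{C/(C-1)}} with C the number of
#' conditions (Morey bias correction). The resulting error bars reflect
#' within-subject variability only: adding any constant to a subject's whole
#' row leaves them unchanged.
#'
#' @param m Numeric matrix, subjects in rows, conditions in columns; no
#'   missing values.
#' @return Numeric vector of per-condition standard errors.
#' @export
cousineau_morey_se <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2 || ncol(m) < 2) {
    stop("need a subjects x conditions matrix with >= 2 rows and columns",
         call. = FALSE)
  }
  if (anyNA(m)) stop("matrix contains missing cells", call. = FALSE)
  C <- ncol(m)
  norm <- m - rowMeans(m) + mean(m)
  apply(norm, 2, stats::sd) / sqrt(nrow(m)) * sqrt(C / (C - 1))
}

#' Paired pre/post comparison with Bonferroni correction
#'
#' Paired t test on post - pre differences (df = n - 1), with the raw p
#' value multiplied by the family size and capped at 1. When the
#' differences have zero variance the test statistic is undefined; the
#' result is flagged degenerate and p is reported as `NA`.
#'
#' @param pre,post Paired per-subject values, equal length n >= 2.
#' @param family_size Number of tests in the Bonferroni family (default 1).
#' @return A tibble with pre/post means and SEs, `t`, `df`, `p_raw`,
#'   `p_adjusted`, `family_size`, `degenerate`.
#' @export
prepost_tests <- function(pre, post, family_size = 1) {
  n <- length(pre)
  if (length(post) != n || n < 2) {
    stop("pre and post must be paired vectors of length >= 2", call. = FALSE)
  }
  d <- post - pre
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    t_stat <- NA_real_
    p_raw <- NA_real_
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p_raw <- tt$p.value
  }
  tibble::tibble(
    pre_mean = mean(pre), pre_se = stats::sd(pre) / sqrt(n),
    post_mean = mean(post), post_se = stats::sd(post) / sqrt(n),
    t = t_stat, df = n - 1L, p_raw = p_raw,
    p_adjusted = if (is.na(p_raw)) NA_real_ else min(1, p_raw * family_size),
    family_size = family_size, degenerate = degenerate)
}

#' Mean within-session slope per strategy label
#'
#' For each (subject, session) with labels, the OLS slope of the outcome on
#' run number is computed; each label's mean slope averages the slopes of
#' all (subject, session) cells carrying that label (a cell with k labels
#' contributes to k label means).
#'
#' @param data Data frame with columns `subject`, `session`, `run`, the
#'   outcome, and `labels` (list-column of character vectors, or a plain
#'   character column).
#' @param outcome Outcome column name (default `"band_imcoh"`).
#' @return Tibble with `label`, `mean_slope`, `n_cells`.
#' @export
slopes_by_label <- function(data, outcome = "band_imcoh") {
  data <- as.data.frame(data)
  stopifnot(all(c("subject", "session", "run", "labels", outcome) %in% names(data)))
  data$.y <- data[[outcome]]
  cells <- split(data, interaction(data$subject, data$session, drop = TRUE))
  rows <- lapply(cells, function(d) {
    if (nrow(d) < 3) stop("each (subject, session) needs >= 3 runs", call. = FALSE)
    slope <- unname(stats::coef(stats::lm(.y ~ run, data = d))["run"])
    labs <- unique(unlist(d$labels))
    data.frame(label = labs, slope = slope)
  })
  all_rows <- do.call(rbind, rows)
  out <- stats::aggregate(slope ~ label, data = all_rows, FUN = mean)
  counts <- stats::aggregate(slope ~ label, data = all_rows, FUN = length)
  tibble::tibble(label = out$label, mean_slope = out$slope,
                 n_cells = counts$slope)
}

#' Simulate a training dataset at the summary level
#'
#' Generates long-format (subject, session, run) outcome values directly
#' from the linear trend model the statistics target: outcome =
#' `c0 + b0_i + (beta_session + u_i) (session-1) + (beta_run + v_i) (run-1)
#' + noise`, with subject-level random intercepts and slopes. This is the
#' generator used for Monte-Carlo calibration of the trend tests, where
#' simulating full EEG for hundreds of cohorts would add nothing.
#'
#' @param n_subjects,n_sessions,n_runs Design size (defaults 10, 10, 7).
#' @param c0 Grand intercept (default 0.1).
#' @param beta_session,beta_run Fixed linear slopes per step.
#' @param subject_sd SD of random intercepts (default 0.05).
#' @param slope_sd_session,slope_sd_run SDs of the random slopes.
#' @param resid_sd Residual SD (default 0.03).
#' @param seed Optional integer seed.
#' @return Tibble with columns `subject`, `session`, `run`, `value`.
#' @export
simulate_trend_dataset <- function(n_subjects = 10, n_sessions = 10,
                                   n_runs = 7, c0 = 0.1,
                                   beta_session = 0, beta_run = 0,
                                   subject_sd = 0.05,
                                   slope_sd_session = 0.005,
                                   slope_sd_run = 0.005,
                                   resid_sd = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(run = seq_len(n_runs), session = seq_len(n_sessions),
                      subject = sprintf("S%02d", seq_len(n_subjects)))
  b0 <- stats::rnorm(n_subjects, 0, subject_sd)
  u <- stats::rnorm(n_subjects, 0, slope_sd_session)
  v <- stats::rnorm(n_subjects, 0, slope_sd_run)
  i <- as.integer(factor(grid$subject))
  grid$value <- c0 + b0[i] +
    (beta_session + u[i]) * (grid$session - 1) +
    (beta_run + v[i]) * (grid$run - 1) +
    stats::rnorm(nrow(grid), 0, resid_sd)
  tibble::as_tibble(grid[, c("subject", "session", "run", "value")])
}
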