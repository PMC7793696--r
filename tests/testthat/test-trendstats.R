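test_that("noise-free linear data is recovered exactly", {
  d <- exact_trend_data(4, 10, 7, b_session = 0.1, b_run = 0,
                        offsets = c(0, 1, 2, 3))
  r <- fit_trend(d, "value")
  expect_equal(r$two_stage$session$mean_slope, 0.1, tolerance = 1e-12)
  expect_equal(r$two_stage$run$mean_slope, 0, tolerance = 1e-12)
  expect_equal(r$two_stage$interaction$mean_slope, 0, tolerance = 1e-12)
  expect_true(r$two_stage$session$degenerate)  # zero between-subject variance
})

test_that("mixed-model and two-stage session slopes agree on balanced data", {
  d <- simulate_trend_dataset(8, 10, 7, beta_session = 0.02, beta_run = 0.003,
                              seed = 5)
  r <- fit_trend(d, "value")
  expect_true(r$converged)
  mm <- unname(r$slopes$estimate[r$slopes$term == "session"])
  expect_equal(mm, r$two_stage$session$mean_slope, tolerance = 1e-6)
  mm_run <- unname(r$slopes$estimate[r$slopes$term == "run"])
  expect_equal(mm_run, r$two_stage$run$mean_slope, tolerance = 1e-6)
  # sequential ANOVA table has the three effects with positive dfs
  expect_equal(r$anova$effect, c("session", "run", "session:run"))
  expect_true(all(r$anova$F >= 0))
  expect_true(all(r$anova$df2 > 0))
  expect_true(all(r$anova$p >= 0 & r$anova$p <= 1))
})

test_that("fixed-slope estimates recover the generating slope", {
  for (beta in c(0, 0.01, 0.03)) {
    est <- vapply(1:20, function(i) {
      d <- simulate_trend_dataset(10, 10, 7, beta_session = beta,
                                  seed = 7000 + 100 * beta * 1000 + i)
      fit_trend(d, "value")$two_stage$session$mean_slope
    }, numeric(1))
    mc_se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - beta), 2 * mc_se + 1e-4)
  }
})

test_that("Cousineau-Morey SEs remove between-subject offsets", {
  # identical condition profiles shifted per subject -> all SEs zero
  base <- matrix(rep(c(1, 3, 2, 5), each = 6), nrow = 6)
  m <- base + c(0, 10, -5, 2, 7, 100)
  expect_equal(cousineau_morey_se(m), rep(0, 4), tolerance = 1e-12)
  expect_equal(cousineau_morey_se(rbind(c(1, 2), c(3, 4))), c(0, 0),
               tolerance = 1e-12)

  # random matrix: equals the direct two-step formula
  set.seed(11)
  m2 <- matrix(rnorm(70), nrow = 10)
  direct <- {
    norm <- m2 - rowMeans(m2) + mean(m2)
    apply(norm, 2, sd) / sqrt(10) * sqrt(7 / 6)
  }
  expect_equal(cousineau_morey_se(m2), direct, tolerance = 1e-12)

  # invariance to per-subject additive constants
  expect_equal(cousineau_morey_se(m2 + rnorm(10) * 100),
               cousineau_morey_se(m2), tolerance = 1e-9)

  expect_error(cousineau_morey_se(matrix(c(1, NA, 2, 3), 2)), "missing")
  expect_error(cousineau_morey_se(matrix(1:3, 3)), "matrix")
})

test_that("paired pre/post tests follow the paired-t conventions", {
  set.seed(12)
  pre <- rnorm(10)
  post <- pre + 0.5 + rnorm(10, sd = 0.3)
  r <- prepost_tests(pre, post, family_size = 3)
  expect_equal(r$df, 9)
  ref <- t.test(post, pre, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p_raw, ref$p.value)
  expect_equal(r$p_adjusted, min(1, ref$p.value * 3))
  expect_gte(r$p_adjusted, r$p_raw)

  # constant shift with no noise: degenerate, p undefined
  rd <- prepost_tests(pre, pre + 1)
  expect_true(rd$degenerate)
  expect_true(is.na(rd$p_raw))

  expect_error(prepost_tests(1:3, 1:4), "paired")
})

test_that("pre/post power matches the noncentral-t benchmark", {
  # shift of 0.5 SD of the paired differences, n = 10
  n <- 10; shift <- 0.5
  set.seed(13)
  hits <- vapply(1:1000, function(i) {
    d <- rnorm(n, mean = shift, sd = 1)
    prepost_tests(rep(0, n), d)$p_raw < 0.05
  }, logical(1))
  ncp <- shift * sqrt(n)
  tc <- qt(0.975, n - 1)
  analytic <- 1 - pt(tc, n - 1, ncp) + pt(-tc, n - 1, ncp)
  expect_lt(abs(mean(hits) - analytic), 0.03)
})

test_that("per-label slope means match hand-computed values", {
  mk <- function(subject, slope, labels) {
    d <- data.frame(subject = subject, session = 1, run = 1:3,
                    band_imcoh = 0.1 + slope * (1:3))
    d$labels <- rep(list(labels), 3)
    d
  }
  d <- rbind(mk("S1", 0.01, c("A", "B")), mk("S2", 0.03, "A"),
             mk("S3", -0.01, "B"))
  out <- slopes_by_label(d)
  expect_equal(out$mean_slope[out$label == "A"], mean(c(0.01, 0.03)))
  expect_equal(out$mean_slope[out$label == "B"], mean(c(0.01, -0.01)))
  expect_equal(out$n_cells[out$label == "A"], 2)

  # exact common slope: every label reports it
  d2 <- rbind(mk("S1", 0.02, "X"), mk("S2", 0.02, "Y"))
  out2 <- slopes_by_label(d2)
  expect_equal(out2$mean_slope, c(0.02, 0.02), tolerance = 1e-12)

  expect_error(slopes_by_label(mk("S1", 0.01, "A")[1:2, ]), "3 runs")
})

test_that("summary-level trend generator has the declared moments", {
  d <- simulate_trend_dataset(6, 4, 3, c0 = 0.2, beta_session = 0.05,
                              subject_sd = 0, slope_sd_session = 0,
                              slope_sd_run = 0, resid_sd = 0, seed = 21)
  expect_equal(nrow(d), 6 * 4 * 3)
  # exact linear structure without noise
  expect_equal(unique(d$value[d$session == 1]), 0.2)
  expect_equal(unique(d$value[d$session == 4]), 0.2 + 3 * 0.05)
  expect_identical(d, simulate_trend_dataset(6, 4, 3, c0 = 0.2,
                                             beta_session = 0.05,
                                             subject_sd = 0,
                                             slope_sd_session = 0,
                                             slope_sd_run = 0, resid_sd = 0,
                                             seed = 21))
})
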