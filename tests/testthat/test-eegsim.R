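test_that("background generator calibrates variance and is reproducible", {
  x <- make_background(300, alpha = 1, sd = 10, seed = 42)
  expect_equal(mean(x), 0, tolerance = 1e-10)
  expect_gt(sd(x), 9.5)
  expect_lt(sd(x), 10.5)
  expect_identical(x, make_background(300, alpha = 1, sd = 10, seed = 42))

  # white-noise case: flat spectrum, negligible lag-1 autocorrelation
  w <- make_background(60, alpha = 0, sd = 5, seed = 7)
  expect_lt(abs(cor(w[-1], w[-length(w)])), 0.05)

  expect_error(make_background(-1), "positive")
  expect_error(make_background(10, alpha = 3), "alpha")
})

test_that("1/f background has log-log spectral slope near -alpha", {
  # oracle: periodogram regression over 1-40 Hz, averaged over 10 seeds
  slopes <- vapply(1:10, function(s) {
    x <- make_background(300, alpha = 1, sd = 10, seed = s)
    sp <- stats::spec.pgram(stats::ts(x, frequency = 256), plot = FALSE,
                            taper = 0)
    sel <- sp$freq >= 1 & sp$freq <= 40
    unname(coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
  }, numeric(1))
  expect_gt(mean(slopes), -1.3)
  expect_lt(mean(slopes), -0.7)
})

test_that("coupled pair attains its closed-form band coherence", {
  # perfect dependence, zero lag: identical band components
  p1 <- make_coupled_pair(smr_band(), 1, lag_ms = 0, duration_s = 180, seed = 1)
  expect_equal(p1$x, p1$y, tolerance = 1e-9)
  co1 <- band_coherence(eeg_recording(rbind(Cz = p1$x, CPz = p1$y)))
  expect_gt(co1$band_msc, 0.98)

  # independence: MSC near the 1/n_epochs bias floor
  p0 <- make_coupled_pair(smr_band(), 0, duration_s = 180, seed = 2)
  co0 <- band_coherence(eeg_recording(rbind(Cz = p0$x, CPz = p0$y)))
  expect_lt(co0$band_msc, 1 / 180 + 0.05)

  # intermediate coupling with quarter-period lag: ImCoh near its oracle,
  # the same estimator on a much longer realization
  co <- band_coherence(pair_recording(0.7, 180, lag_ms = 18, seed = 3))
  oracle <- band_coherence(pair_recording(0.7, 3600, lag_ms = 18, seed = 4))
  expect_lt(abs(co$band_imcoh - oracle$band_imcoh), 0.1)
  expect_equal(p1$true_msc, 1)
  expect_equal(make_coupled_pair(smr_band(), 0.7, duration_s = 5,
                                 seed = 1)$true_msc, 0.49)

  expect_error(make_coupled_pair(smr_band(), 1.4, duration_s = 5), "coupling")
  expect_error(make_coupled_pair(smr_band(), 0.5, lag_ms = 6000,
                                 duration_s = 5), "lag")
})

test_that("coupling calibration is monotone in the coupling parameter", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  msc <- vapply(grid, function(cpl) {
    mean(vapply(1:3, function(s) {
      band_coherence(pair_recording(cpl, 60, seed = 100 + s))$band_msc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(msc) > 0))
})

test_that("zero-lag mixtures have high MSC but null imaginary coherence", {
  co <- band_coherence(eeg_recording(rbind(
    Cz = (v <- make_volume_conduction_pair(smr_band(), rbind(1, 0.8), 180,
                                           seed = 5))$x, CPz = v$y)))
  expect_gt(co$band_msc, 0.5)
  expect_lt(abs(co$band_imcoh), 0.05)

  # disconnected second channel: MSC at the bias floor
  v0 <- make_volume_conduction_pair(smr_band(), rbind(1, 0), 180, seed = 6)
  co0 <- band_coherence(eeg_recording(rbind(Cz = v0$x, CPz = v0$y)))
  expect_lt(co0$band_msc, 1 / 180 + 0.05)

  # two sources, random weights: long-run mean ImCoh stays near zero
  imcohs <- vapply(1:10, function(s) {
    set.seed(s)
    W <- matrix(runif(4, 0.3, 1), 2)
    v <- make_volume_conduction_pair(smr_band(), W, 60, seed = 1000 + s)
    band_coherence(eeg_recording(rbind(Cz = v$x, CPz = v$y)))$band_imcoh
  }, numeric(1))
  expect_lt(abs(mean(imcohs)), 0.05)

  expect_error(make_volume_conduction_pair(smr_band(), rbind(0, 0), 10),
               "nonzero")
})

test_that("artifact injection marks truth and respects rates", {
  rec <- eeg_recording(rbind(Cz = rnorm(256 * 180, sd = 5),
                             CPz = rnorm(256 * 180, sd = 5),
                             EOG = rnorm(256 * 180, sd = 10)))
  # zero rates: identity, empty mask
  r0 <- inject_artifacts(rec, blink_rate = 0, muscle_rate = 0, seed = 1)
  expect_identical(r0$data, rec$data)
  expect_false(any(r0$artifact_truth))

  # blinks exceed the EOG rejection bound by construction
  rb <- inject_artifacts(rec, blink_rate = 4, muscle_rate = 0,
                         blink_amp_uV = 300, seed = 2)
  n_events <- length(rb$meta$artifact_events$blink_onsets)
  expect_gt(n_events, qpois(0.001, 12))
  expect_lt(n_events, qpois(0.999, 12))
  for (t0 in rb$meta$artifact_events$blink_onsets) {
    expect_gt(max(abs(rb$data["EOG", t0:(t0 + 102)])), 120)
  }

  # muscle bursts at least double the beta-band power of affected epochs
  rm_ <- inject_artifacts(rec, blink_rate = 0, muscle_rate = 2, seed = 3)
  es <- epoch_recording(rm_)
  bp <- complex_demod_power(channel(rm_, "Cz"), beta_band(), 256)$epoch_power
  hit <- es$artifact_truth[, "muscle"]
  expect_gte(median(bp[hit]), 2 * median(bp[!hit]))
})

test_that("simulated runs follow the linear coupling rule deterministically", {
  lp0 <- learner_params(c0 = 0.3, beta_session = 0, beta_run = 0, noise_sd = 0)
  r1 <- simulate_run(lp0, 1, 1, duration_s = 4, seed = 1)
  r2 <- simulate_run(lp0, 10, 7, duration_s = 4, seed = 1)
  expect_equal(r1$meta$coupling_true, r2$meta$coupling_true)
  expect_identical(r1$data, simulate_run(lp0, 1, 1, duration_s = 4,
                                         seed = 1)$data)

  lp <- learner_params(c0 = 0.3, beta_session = 0.04, noise_sd = 0)
  expect_equal(simulate_run(lp, 10, 1, duration_s = 4,
                            seed = 1)$meta$coupling_true, 0.3 + 0.36)
  # clipping
  lph <- learner_params(c0 = 0.9, beta_session = 0.04, noise_sd = 0)
  expect_equal(simulate_run(lph, 10, 1, duration_s = 4,
                            seed = 1)$meta$coupling_true, 0.95)

  expect_error(simulate_run(lp, 11, 1, duration_s = 4), "session")
  expect_error(simulate_run(lp, 1, 8, duration_s = 4), "run")
})

test_that("a cohort with positive session slope shows rising coherence", {
  # recovery at reduced scale: 4 subjects, 3 sessions, one 60-s run each
  msc_by_session <- sapply(c(1, 2, 3), function(s) {
    mean(vapply(1:4, function(subj) {
      lp <- learner_params(c0 = 0.2, beta_session = 0.15, noise_sd = 0)
      rec <- simulate_run(lp, s, 1, duration_s = 60, seed = 50 + 10 * subj + s)
      es <- reject_epochs(epoch_recording(rec))
      coherence(epoch_spectra(es), smr_band())$band_msc
    }, numeric(1)))
  })
  expect_true(all(diff(msc_by_session) > 0))
})
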