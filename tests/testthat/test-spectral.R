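test_that("taper window matches its split-cosine-bell definition", {
  expect_equal(taper_window(64, 0), rep(1, 64))
  # full taper reduces to the Hann window
  n <- 256
  hann <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  expect_equal(taper_window(n, 1), hann, tolerance = 1e-12)
  # 10% taper: ramps at the ends, flat middle
  w <- taper_window(256, 0.10)
  t <- (0:255) / 255
  ramp <- t < 0.05 | t > 0.95
  expect_true(all(w[!ramp] == 1))
  expect_true(all(w[ramp] < 1 | abs(t[ramp] - 0.05) < 1e-12 |
                    abs(t[ramp] - 0.95) < 1e-12))
  # direct evaluation of the split-cosine formula on the first ramp
  k <- which(t < 0.05)
  expect_equal(w[k], 0.5 * (1 + cos(pi * (2 * t[k] / 0.10 - 1))),
               tolerance = 1e-12)
  expect_error(taper_window(3), "n_samples")
})

test_that("epoch spectra satisfy Parseval and basic identities", {
  # white noise: recovered total power close to the signal variance
  set.seed(1)
  x <- rnorm(256 * 60)
  rec <- eeg_recording(rbind(Cz = x, CPz = rnorm(256 * 60)), fs = 256)
  est <- epoch_spectra(epoch_recording(rec), taper_fraction = 0.10)
  expect_equal(sum(est$sxx), 1, tolerance = 0.03)
  # flat spectrum: per-bin level near 1/128 uV^2
  inner <- est$sxx[2:128]
  expect_lt(max(abs(inner - 1 / 128)) / (1 / 128), 0.6)

  # x = y: cross-spectrum real, equal to the auto-spectrum
  rec2 <- eeg_recording(rbind(Cz = x, CPz = x), fs = 256)
  est2 <- epoch_spectra(epoch_recording(rec2))
  expect_equal(Im(est2$sxy), rep(0, length(est2$freqs)), tolerance = 1e-12)
  expect_equal(Re(est2$sxy), est2$sxx, tolerance = 1e-12)

  # Cauchy-Schwarz at every bin
  expect_true(all(Mod(est$sxy)^2 <= est$sxx * est$syy * (1 + 1e-12)))

  # sinusoid with rectangular window: all power in its bin, variance A^2/2
  rec3 <- sine_recording(13, amp = 1, duration_s = 10)
  est3 <- epoch_spectra(epoch_recording(rec3), taper_fraction = 0)
  expect_equal(est3$sxx[est3$freqs == 13], 0.5, tolerance = 0.005)
  expect_equal(sum(est3$sxx), 0.5, tolerance = 0.005)

  # single kept epoch is refused (its MSC would be identically 1)
  rec4 <- eeg_recording(rbind(Cz = rnorm(256), CPz = rnorm(256)), fs = 256)
  expect_error(epoch_spectra(epoch_recording(rec4)), "2 kept epochs")
})

test_that("coherence identities hold and band averaging uses inclusive bins", {
  set.seed(2)
  x <- rnorm(256 * 60)
  rec <- eeg_recording(rbind(Cz = x, CPz = x), fs = 256)
  co <- band_coherence(rec)
  expect_equal(co$band_msc, 1, tolerance = 1e-10)
  expect_equal(co$band_imcoh, 0, tolerance = 1e-10)
  expect_equal(co$freqs[co$bins], c(12, 13, 14, 15))

  # quadrature pair: coherent but purely imaginary coherency
  p <- make_coupled_pair(smr_band(), 1, lag_ms = 0, duration_s = 60, seed = 3)
  y90 <- Re(fft(fft(p$y) * complex(imaginary =
    -sign(smrcoh:::fft_freqs(length(p$y), 256))), inverse = TRUE)) / length(p$y)
  recq <- eeg_recording(rbind(Cz = p$x, CPz = y90), fs = 256)
  coq <- band_coherence(recq)
  expect_gt(coq$band_msc, 0.95)
  expect_gt(abs(coq$band_imcoh), 0.95)

  # zero-lag coupled pair: MSC near coupling^2, ImCoh near zero
  co0 <- band_coherence(pair_recording(0.7, 180, lag_ms = 0, seed = 4))
  expect_lt(abs(co0$band_msc - 0.49), 0.1)
  expect_lt(abs(co0$band_imcoh), 0.05)

  # degenerate signal errors
  recz <- eeg_recording(rbind(Cz = rep(0, 256 * 4),
                              CPz = rnorm(256 * 4)), fs = 256)
  esz <- epoch_recording(recz)
  expect_error(coherence(epoch_spectra(esz), smr_band()), "degenerate")
})

test_that("MSC and ImCoh respect their bounds on random signals", {
  for (s in 1:20) {
    set.seed(s)
    n <- 256 * 8
    a <- rnorm(n); b <- 0.5 * a + rnorm(n) * runif(1, 0.1, 2)
    co <- band_coherence(eeg_recording(rbind(Cz = a, CPz = b), fs = 256))
    expect_true(all(co$msc >= 0 & co$msc <= 1))
    expect_true(all(co$imcoh >= -1 & co$imcoh <= 1))
  }
})

test_that("MSC is scale-invariant; channel swap flips ImCoh's sign", {
  p <- make_coupled_pair(smr_band(), 0.6, duration_s = 30, seed = 5)
  co <- band_coherence(eeg_recording(rbind(Cz = p$x, CPz = p$y), fs = 256))
  co_scaled <- band_coherence(eeg_recording(rbind(Cz = 7 * p$x,
                                                  CPz = 0.2 * p$y), fs = 256))
  expect_equal(co$band_msc, co_scaled$band_msc, tolerance = 1e-10)
  co_swap <- band_coherence(eeg_recording(rbind(Cz = p$y, CPz = p$x),
                                          fs = 256))
  expect_equal(co_swap$band_imcoh, -co$band_imcoh, tolerance = 1e-10)
})

test_that("independence bias of MSC shrinks like 1/n_epochs", {
  msc_at <- function(n_ep) {
    mean(vapply(1:3, function(s) {
      p <- make_coupled_pair(smr_band(), 0, duration_s = n_ep, seed = 600 + s)
      band_coherence(eeg_recording(rbind(Cz = p$x, CPz = p$y)))$band_msc
    }, numeric(1)))
  }
  b10 <- msc_at(10); b60 <- msc_at(60); b180 <- msc_at(180)
  expect_gt(b10, b60)
  expect_gt(b60, b180)
  expect_lt(abs(b10 - 1 / 10), 0.08)
  expect_lt(abs(b180 - 1 / 180), 0.02)
})

test_that("volume-conduction ImCoh shrinks with more epochs", {
  im_at <- function(dur, seed) {
    v <- make_volume_conduction_pair(smr_band(), rbind(1, 0.8), dur, seed = seed)
    abs(band_coherence(eeg_recording(rbind(Cz = v$x, CPz = v$y)))$band_imcoh)
  }
  short <- mean(vapply(1:3, function(s) im_at(60, s), numeric(1)))
  long <- mean(vapply(1:3, function(s) im_at(600, 100 + s), numeric(1)))
  expect_lt(long, short)
})

test_that("complex demodulation is calibrated and band-selective", {
  t <- (0:(256 * 20 - 1)) / 256
  # amplitude-2 sinusoid at band centre -> power 2 within 2%
  x <- 2 * cos(2 * pi * 13.5 * t)
  dp <- complex_demod_power(x, smr_band(), 256)
  mid <- dp$epoch_power[5:16]
  expect_true(all(abs(mid - 2) / 2 < 0.02))
  # out-of-band tone suppressed below 1%
  x30 <- 2 * cos(2 * pi * 30 * t)
  dp30 <- complex_demod_power(x30, smr_band(), 256)
  expect_lt(mean(dp30$epoch_power[5:16]), 0.01 * 2)
  # amplitude step x2 -> epoch power ratio ~4 away from the transition
  amp <- ifelse(t < 10, 1, 2)
  dps <- complex_demod_power(amp * cos(2 * pi * 13.5 * t), smr_band(), 256)
  expect_equal(mean(dps$epoch_power[13:18]) / mean(dps$epoch_power[3:8]), 4,
               tolerance = 0.1)
  expect_error(complex_demod_power(x, band_spec("bad", 100, 140), 256),
               "Nyquist")
  expect_error(complex_demod_power(x[1:100], smr_band(), 256), "2 s")
})

test_that("FFT and demodulation band power agree on narrowband noise", {
  # noise sits inside the band: at the band edges the two conventions differ
  # (bin leakage vs low-pass half-gain), which is not what is under test
  set.seed(8)
  x <- smrcoh:::band_limited_noise(256 * 120, 256, 12.75, 14.25) * 3
  rec <- eeg_recording(rbind(Cz = x, CPz = rnorm(length(x))), fs = 256)
  est <- epoch_spectra(epoch_recording(rec), taper_fraction = 0.10)
  p_fft <- band_power_fft(est, smr_band(), "x")
  p_dem <- mean(complex_demod_power(x, smr_band(), 256)$epoch_power)
  expect_lt(abs(p_fft - p_dem) / p_dem, 0.10)

  # sinusoid calibration A^2/2 and additivity over disjoint bands
  rec13 <- sine_recording(13, amp = 3, duration_s = 10)
  est13 <- epoch_spectra(epoch_recording(rec13), taper_fraction = 0)
  expect_equal(band_power_fft(est13, smr_band(), "x"), 9 / 2,
               tolerance = 0.01 * 9 / 2)
  set.seed(9)
  w <- rnorm(256 * 30)
  estw <- epoch_spectra(epoch_recording(eeg_recording(
    rbind(Cz = w, CPz = w), fs = 256)), taper_fraction = 0)
  p_lo <- band_power_fft(estw, band_spec("lo", 10, 20), "x")
  p_hi <- band_power_fft(estw, band_spec("hi", 21, 30), "x")
  p_all <- band_power_fft(estw, band_spec("all", 10, 30), "x")
  expect_equal(p_lo + p_hi, p_all, tolerance = 1e-12)
})

test_that("per-epoch coherency normalization is available as a variant", {
  p <- make_coupled_pair(smr_band(), 0.7, duration_s = 60, seed = 10)
  es <- epoch_recording(eeg_recording(rbind(Cz = p$x, CPz = p$y), fs = 256))
  est <- epoch_spectra(es, keep_epochs = TRUE)
  co_avg <- coherence(est, smr_band(), method = "average")
  co_ep <- coherence(est, smr_band(), method = "per_epoch")
  # both see the same coupling, not identical numerically
  expect_lt(abs(co_avg$band_imcoh - co_ep$band_imcoh), 0.15)
  est2 <- epoch_spectra(es)
  expect_error(coherence(est2, smr_band(), method = "per_epoch"), "keep_epochs")
})
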