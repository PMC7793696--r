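# Shared fixture builders. Everything is generated in code at test time.

# A two-channel recording from a coupled pair (unit-variance channels).
pair_recording <- function(coupling, duration_s = 180, lag_ms = 18, seed = 1,
                           band = smr_band(), fs = 256) {
  p <- make_coupled_pair(band, coupling, lag_ms, duration_s, fs, seed = seed)
  eeg_recording(rbind(Cz = p$x, CPz = p$y), fs = fs)
}

# Band MSC / ImCoh of a plain two-channel recording (no rejection).
band_coherence <- function(rec, band = smr_band(), taper = 0.10) {
  coherence(epoch_spectra(epoch_recording(rec), taper_fraction = taper), band)
}

# A sinusoidal recording on both channels.
sine_recording <- function(freq, amp = 1, duration_s = 10, fs = 256,
                           phase2 = 0) {
  t <- (seq_len(duration_s * fs) - 1) / fs
  eeg_recording(rbind(Cz = amp * cos(2 * pi * freq * t),
                      CPz = amp * cos(2 * pi * freq * t + phase2)), fs = fs)
}

# A scripted 20-update bar trajectory with hand-enumerated reward counts
# (up: green at t = 2,5,9,11,12,14,17,20 -> 7 entries; down: 5 entries).
scripted_bars <- function() {
  tibble::tibble(
    t = 1:20,
    coh = c(NA, .6, .6, .4, .7, .7, .7, .3, .6, .4,
            .8, .8, .2, .9, .6, .4, .7, .7, .5, .9),
    theta = c(5, 5, 12, 5, 5, 5, 12, 5, 5, 5, 5, 5, 5, 5, 12, 5, 5, 12, 5, 5),
    beta = c(1, 1, 1, 1, 1, 6, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
}
scripted_thr <- structure(list(coh_thr = 0.5, theta_thr = 10, beta_thr = 5),
                          class = "nf_thresholds")

# Session/run long data with exact linear structure (no noise).
exact_trend_data <- function(n_subjects = 4, n_sessions = 10, n_runs = 7,
                             b_session = 0.1, b_run = 0, offsets = NULL) {
  g <- expand.grid(run = seq_len(n_runs), session = seq_len(n_sessions),
                   subject = sprintf("S%02d", seq_len(n_subjects)))
  if (is.null(offsets)) offsets <- rep(0, n_subjects)
  i <- as.integer(factor(g$subject))
  g$value <- offsets[i] + b_session * g$session + b_run * g$run
  g
}
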