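# ---- internal signal primitives ---------------------------------------------

# Band-limited unit-variance Gaussian noise via brick-wall FFT masking of a
# white-noise realization. Draws from the current RNG stream.
band_limited_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- fft_freqs(n, fs)
  keep <- abs(f) >= f_lo & abs(f) <= f_hi
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate band (no FFT bins in range)", call. = FALSE)
  x / s
}

# Signed two-sided frequency grid matching stats::fft ordering.
fft_freqs <- function(n, fs) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

# Delay a real signal by tau seconds with a frequency-domain phase ramp
# (circular, supports fractional-sample delays).
delay_signal <- function(x, tau_s, fs) {
  if (tau_s == 0) return(x)
  n <- length(x)
  f <- fft_freqs(n, fs)
  X <- stats::fft(x) * exp(-2i * pi * f * tau_s)
  if (n %% 2 == 0) X[n / 2 + 1] <- Re(X[n / 2 + 1])  # keep Nyquist bin real
  Re(stats::fft(X, inverse = TRUE)) / n
}

# ---- background -------------------------------------------------------------

#' Generate 1/f^alpha background EEG
#'
#' Spectrally shaped Gaussian noise emulating the broadband EEG background:
#' a white-noise realization is FFT-filtered so that its power spectrum falls
#' off as \eqn{f^{-\alpha}}, then rescaled to the requested standard
#' deviation. `alpha = 0` gives white noise; `alpha = 1` (the default used by
#' the run simulator) gives the pink, approximately 1/f spectrum typical of
#' resting EEG.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling rate in Hz (default 256).
#' @param alpha Spectral exponent in `[0, 2]`.
#' @param sd Target sample standard deviation in microvolts.
#' @param seed Optional integer seed; when given the output is reproducible.
#' @return Numeric vector of `duration_s * fs` samples, zero mean, SD `sd`.
#' @examples
#' x <- make_background(10, alpha = 1, sd = 10, seed = 1)
#' sd(x)
#' @export
make_background <- function(duration_s, fs = 256, alpha = 1, sd = 10,
                            seed = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0 || fs <= 0) {
    stop("duration_s and fs must be positive", call. = FALSE)
  }
  if (alpha < 0 || alpha > 2) stop("alpha must lie in [0, 2]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  w <- stats::rnorm(n)
  if (alpha == 0) {
    x <- w
  } else {
    X <- stats::fft(w)
    f <- abs(fft_freqs(n, fs))
    scale <- ifelse(f > 0, f^(-alpha / 2), 0)
    x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  }
  x <- x - mean(x)
  x * (sd / stats::sd(x))
}

# ---- coupled pair -----------------------------------------------------------

#' Generate a pair of band-limited coupled signals
#'
#' Both channels share a band-limited Gaussian source; channel 2 receives it
#' delayed by `lag_ms`. Each channel adds its own independent band-limited
#' noise with the complementary weight, so that the magnitude-squared
#' coherence between the channels equals `coupling^2` at every in-band
#' frequency: with source weight \eqn{\sqrt{c}} and noise weight
#' \eqn{\sqrt{1-c}}, the cross-spectrum is \eqn{c\,S(f)} while both
#' auto-spectra are \eqn{S(f)}.
#'
#' A nonzero lag makes the coupling visible to the imaginary part of
#' coherency; the default 18 ms is approximately a quarter period at the
#' 13.5 Hz SMR band centre, which maximizes |Im coherency| for given MSC.
#'
#' @param band A [band_spec()].
#' @param coupling Coupling strength in `[0, 1]`.
#' @param lag_ms Delay of the shared source on channel 2, in milliseconds
#'   (>= 0).
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @return List with unit-variance signals `x`, `y` and the analytically
#'   implied band magnitude-squared coherence `true_msc = coupling^2`.
#' @examples
#' p <- make_coupled_pair(smr_band(), coupling = 0.7, duration_s = 10, seed = 1)
#' p$true_msc
#' @export
make_coupled_pair <- function(band, coupling, lag_ms = 18, duration_s,
                              fs = 256, seed = NULL) {
  stopifnot(inherits(band, "band_spec"))
  if (!is.numeric(coupling) || coupling < 0 || coupling > 1) {
    stop("coupling must lie in [0, 1]", call. = FALSE)
  }
  if (lag_ms < 0) stop("lag_ms must be >= 0", call. = FALSE)
  if (lag_ms / 1000 >= duration_s) {
    stop("lag_ms must be shorter than the signal", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  s  <- band_limited_noise(n, fs, band$f_lo, band$f_hi)
  n1 <- band_limited_noise(n, fs, band$f_lo, band$f_hi)
  n2 <- band_limited_noise(n, fs, band$f_lo, band$f_hi)
  a <- sqrt(coupling)
  b <- sqrt(1 - coupling)
  x <- a * s + b * n1
  y <- a * delay_signal(s, lag_ms / 1000, fs) + b * n2
  list(x = x, y = y, true_msc = coupling^2)
}

#' Generate a zero-lag (volume-conducted) channel pair
#'
#' Both channels are instantaneous linear mixtures of the same `k` shared
#' band-limited sources plus independent in-band noise. Because the mixing is
#' strictly zero-lag, the cross-spectrum is real: the channels can have large
#' magnitude-squared coherence while the imaginary part of coherency is zero
#' in expectation — the situation volume conduction creates between adjacent
#' scalp electrodes.
#'
#' @param source_band A [band_spec()] (shared by all sources), or a list of
#'   `k` band specs, one per source.
#' @param mixing Numeric 2 x k matrix of real mixing weights.
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param noise_scale SD of each channel's independent in-band noise relative
#'   to a unit-variance source (default 0.3).
#' @param seed Optional integer seed.
#' @return List with signals `x` and `y`.
#' @export
make_volume_conduction_pair <- function(source_band, mixing, duration_s,
                                        fs = 256, noise_scale = 0.3,
                                        seed = NULL) {
  if (!is.matrix(mixing) || nrow(mixing) != 2L) {
    stop("mixing must be a 2 x k matrix", call. = FALSE)
  }
  if (all(mixing == 0)) stop("mixing matrix must be nonzero", call. = FALSE)
  k <- ncol(mixing)
  bands <- if (inherits(source_band, "band_spec")) {
    rep(list(source_band), k)
  } else {
    stopifnot(length(source_band) == k)
    source_band
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  S <- vapply(bands, function(b) band_limited_noise(n, fs, b$f_lo, b$f_hi),
              numeric(n))
  nb <- bands[[1]]
  x <- drop(S %*% mixing[1, ]) + noise_scale * band_limited_noise(n, fs, nb$f_lo, nb$f_hi)
  y <- drop(S %*% mixing[2, ]) + noise_scale * band_limited_noise(n, fs, nb$f_lo, nb$f_hi)
  list(x = x, y = y)
}

# ---- artifacts --------------------------------------------------------------

#' Inject ocular and muscle artifacts into a recording
#'
#' Blinks are modelled as 400 ms raised-cosine transients, dominant on the
#' EOG channel with attenuated copies on the EEG channels (default amplitude
#' ratio EOG:Cz:CPz = 1:0.4:0.2, reflecting the frontal dominance of ocular
#' potentials). Muscle artifacts are 500 ms bursts of 30--100 Hz band noise
#' on the EEG channels. Event onsets are Poisson in time. Affected samples
#' are recorded in a per-class ground-truth mask so downstream rejection can
#' be validated against it.
#'
#' @param rec An [eeg_recording()] with channels Cz, CPz and (for blinks) EOG.
#' @param blink_rate,muscle_rate Event rates in events per minute (>= 0).
#' @param blink_amp_uV Peak blink amplitude on the EOG channel (microvolts).
#' @param blink_ratio Named attenuation factors for the blink template per
#'   channel.
#' @param muscle_sd_uV SD of the muscle-burst noise on each EEG channel.
#' @param seed Optional integer seed.
#' @return The recording with artifacts added and `artifact_truth` set
#'   (logical rows `blink` and `muscle`).
#' @export
inject_artifacts <- function(rec, blink_rate = 3, muscle_rate = 1,
                             blink_amp_uV = 300,
                             blink_ratio = c(EOG = 1, Cz = 0.4, CPz = 0.2),
                             muscle_sd_uV = 40, seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (blink_rate < 0 || muscle_rate < 0) {
    stop("artifact rates must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples(rec)
  fs <- rec$fs
  mask <- matrix(FALSE, nrow = 2, ncol = n, dimnames = list(c("blink", "muscle"), NULL))
  dur_min <- n / fs / 60

  blink_len <- round(0.4 * fs)
  blink_tpl <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = blink_len)))
  # the truth mask marks the samples where the transient is substantial
  # (> 40% of peak); the gentle cosine flanks are not counted as affected
  blink_core <- blink_tpl > 0.4
  n_blink <- stats::rpois(1, blink_rate * dur_min)
  blink_onsets <- integer(0)
  if (n_blink > 0 && n > blink_len) {
    blink_onsets <- sort(sample.int(n - blink_len, n_blink, replace = TRUE))
    for (t0 in blink_onsets) {
      idx <- t0:(t0 + blink_len - 1L)
      for (lab in intersect(names(blink_ratio), rec$labels)) {
        rec$data[lab, idx] <- rec$data[lab, idx] +
          blink_amp_uV * blink_ratio[[lab]] * blink_tpl
      }
      mask["blink", idx[blink_core]] <- TRUE
    }
  }

  burst_len <- round(0.5 * fs)
  n_burst <- stats::rpois(1, muscle_rate * dur_min)
  burst_onsets <- integer(0)
  if (n_burst > 0 && n > burst_len) {
    burst_onsets <- sort(sample.int(n - burst_len, n_burst, replace = TRUE))
    env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = burst_len)))
    env_core <- env > 0.4
    eeg_ch <- setdiff(rec$labels, "EOG")
    for (t0 in burst_onsets) {
      idx <- t0:(t0 + burst_len - 1L)
      for (lab in eeg_ch) {
        burst <- band_limited_noise(burst_len, fs, 30, min(100, fs / 2 - 1)) *
          muscle_sd_uV * env
        rec$data[lab, idx] <- rec$data[lab, idx] + burst
      }
      mask["muscle", idx[env_core]] <- TRUE
    }
  }

  rec$artifact_truth <- mask
  rec$meta$artifact_events <- list(blink_onsets = blink_onsets,
                                   muscle_onsets = burst_onsets)
  rec
}

# ---- learner and run simulation ---------------------------------------------

#' Generative parameters of a simulated neurofeedback learner
#'
#' Describes one simulated subject: baseline Cz-CPz coupling, linear
#' per-session and per-run coupling changes (the learning trends the trend
#' statistics are meant to recover), coupling lag, per-band amplitude trends,
#' run-to-run coupling jitter and artifact rates.
#'
#' @param c0 Baseline coupling in `[0, 1]`.
#' @param beta_session Coupling change per session (coupling units/session).
#' @param beta_run Coupling change per run within a session.
#' @param lag_ms Lag of the shared SMR source between Cz and CPz in ms (>= 0).
#' @param power_trends Named list with elements `smr`, `theta`, `beta`, each a
#'   numeric vector `c(session = ..., run = ...)` of relative amplitude
#'   slopes per step.
#' @param noise_sd SD of run-level coupling jitter.
#' @param artifact_rates Named numeric vector `c(blink = ..., muscle = ...)`
#'   in events per minute.
#' @return An object of class `learner_params`.
#' @examples
#' learner_params(c0 = 0.3, beta_session = 0.03)
#' @export
learner_params <- function(c0 = 0.3, beta_session = 0, beta_run = 0,
                           lag_ms = 18,
                           power_trends = list(smr = c(session = 0, run = 0),
                                               theta = c(session = 0, run = 0),
                                               beta = c(session = 0, run = 0)),
                           noise_sd = 0.02,
                           artifact_rates = c(blink = 3, muscle = 1)) {
  if (c0 < 0 || c0 > 1) stop("c0 must lie in [0, 1]", call. = FALSE)
  if (lag_ms < 0) stop("lag_ms must be >= 0", call. = FALSE)
  structure(list(c0 = c0, beta_session = beta_session, beta_run = beta_run,
                 lag_ms = lag_ms, power_trends = power_trends,
                 noise_sd = noise_sd, artifact_rates = artifact_rates),
            class = "learner_params")
}

# Ground-truth coupling for a given (session, run), before jitter, clipped.
true_coupling <- function(learner, session_idx, run_idx, jitter = 0) {
  c_raw <- learner$c0 +
    learner$beta_session * (session_idx - 1) +
    learner$beta_run * (run_idx - 1) + jitter
  min(max(c_raw, 0), 0.95)
}

#' Simulate one 3-minute neurofeedback run
#'
#' Composes a three-channel recording (Cz, CPz, EOG) for one run of the
#' training protocol: 1/f background on every channel, a shared lagged SMR
#' band component on Cz/CPz whose coupling follows the learner's linear
#' session/run trend (plus jitter, clipped to `[0, 0.95]`), independent theta
#' and beta band components with their own amplitude trends, and injected
#' blink/muscle artifacts. The coupling actually used is stored in
#' `meta$coupling_true`.
#'
#' @param learner A [learner_params()].
#' @param session_idx Session number 1..10.
#' @param run_idx Run number 1..7 (1 = baseline run).
#' @param duration_s Run length in seconds (default 180).
#' @param fs Sampling rate in Hz (default 256).
#' @param seed Optional integer seed; fixed seed gives a bit-identical run.
#' @param amplitudes Named list of component scales in microvolts RMS:
#'   `background_sd`, `smr_rms`, `theta_rms`, `beta_rms`, `eog_sd`.
#' @return An [eeg_recording()] with channels Cz, CPz, EOG, artifact truth
#'   mask, and metadata (`coupling_true`, `session`, `run`).
#' @export
simulate_run <- function(learner, session_idx, run_idx, duration_s = 180,
                         fs = 256, seed = NULL,
                         amplitudes = list(background_sd = 8, smr_rms = 4,
                                           theta_rms = 3, beta_rms = 2,
                                           eog_sd = 15)) {
  stopifnot(inherits(learner, "learner_params"))
  if (!(session_idx %in% 1:10)) stop("session_idx must be in 1..10", call. = FALSE)
  if (!(run_idx %in% 1:7)) stop("run_idx must be in 1..7", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)

  jitter <- if (learner$noise_sd > 0) stats::rnorm(1, 0, learner$noise_sd) else 0
  cpl <- true_coupling(learner, session_idx, run_idx, jitter)

  amp <- function(base, band_name) {
    tr <- learner$power_trends[[band_name]]
    base * max(0, 1 + tr[["session"]] * (session_idx - 1) +
                  tr[["run"]] * (run_idx - 1))
  }

  pair <- make_coupled_pair(smr_band(), cpl, learner$lag_ms, duration_s, fs)
  smr_amp <- amp(amplitudes$smr_rms, "smr")
  th <- theta_band(); be <- beta_band()
  cz <- make_background(duration_s, fs, alpha = 1, sd = amplitudes$background_sd) +
    smr_amp * pair$x +
    amp(amplitudes$theta_rms, "theta") * band_limited_noise(n, fs, th$f_lo, th$f_hi) +
    amp(amplitudes$beta_rms, "beta") * band_limited_noise(n, fs, be$f_lo, be$f_hi)
  cpz <- make_background(duration_s, fs, alpha = 1, sd = amplitudes$background_sd) +
    smr_amp * pair$y +
    amp(amplitudes$theta_rms, "theta") * band_limited_noise(n, fs, th$f_lo, th$f_hi) +
    amp(amplitudes$beta_rms, "beta") * band_limited_noise(n, fs, be$f_lo, be$f_hi)
  eog <- make_background(duration_s, fs, alpha = 1, sd = amplitudes$eog_sd)

  rec <- eeg_recording(rbind(Cz = cz, CPz = cpz, EOG = eog), fs = fs,
                       meta = list(coupling_true = cpl,
                                   session = session_idx, run = run_idx,
                                   seed = seed))
  inject_artifacts(rec,
                   blink_rate = learner$artifact_rates[["blink"]],
                   muscle_rate = learner$artifact_rates[["muscle"]])
}
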