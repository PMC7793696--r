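#' Training-protocol configuration
#'
#' Describes the closed-loop protocol: 10 sessions of 7 runs (1 baseline +
#' 6 feedback), 3 minutes per run; the SMR feedback band and the theta/beta
#' control bands (control bars are computed over Cz); regulation direction;
#' and the online estimator settings (trailing window length in 1-s epochs
#' and bar update rate).
#'
#' @param n_sessions Number of training sessions (default 10).
#' @param runs_per_session Runs per session including the baseline run
#'   (default 7, >= 2).
#' @param run_s Run length in seconds (default 180).
#' @param fs Sampling rate in Hz (default 256).
#' @param feedback_band,theta_band_,beta_band_ [band_spec()]s for the
#'   feedback and control bars.
#' @param direction `"up"` (reward coherence above threshold) or `"down"`.
#' @param online_window_epochs Trailing window of the online coherence
#'   estimator, in 1-s epochs (default 8, >= 2).
#' @param taper_fraction Taper used by both online and offline spectra.
#' @param reward_mode `"entry"`: the counter increments once per entry into
#'   the all-bars-green state; `"per_update"`: increments every green update.
#' @param criteria A [rejection_criteria()] for the offline pipeline.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_sessions = 10, runs_per_session = 7,
                            run_s = 180, fs = 256,
                            feedback_band = smr_band(),
                            theta_band_ = theta_band(),
                            beta_band_ = beta_band(),
                            direction = c("up", "down"),
                            online_window_epochs = 8,
                            taper_fraction = 0.10,
                            reward_mode = c("entry", "per_update"),
                            criteria = rejection_criteria()) {
  direction <- match.arg(direction)
  reward_mode <- match.arg(reward_mode)
  if (runs_per_session < 2) stop("runs_per_session must be >= 2", call. = FALSE)
  if (online_window_epochs < 2) {
    stop("online_window_epochs must be >= 2", call. = FALSE)
  }
  structure(list(n_sessions = n_sessions, runs_per_session = runs_per_session,
                 run_s = run_s, fs = fs, feedback_band = feedback_band,
                 theta_band = theta_band_, beta_band = beta_band_,
                 direction = direction,
                 online_window_epochs = online_window_epochs,
                 taper_fraction = taper_fraction, reward_mode = reward_mode,
                 criteria = criteria),
            class = "protocol_config")
}

#' Online feedback-bar time series for one run
#'
#' Emulates the real-time display at a 1 Hz update rate: at each 1-s update
#' the coherence bar shows the band magnitude-squared coherence over the
#' trailing `online_window_epochs` 1-s epochs (earlier updates use all epochs
#' available so far, minimum 2, so the first bar value appears at t = 2 s);
#' the theta and beta control bars show the current epoch's
#' complex-demodulation band power on Cz. No artifact rejection is applied
#' online.
#'
#' @param rec An [eeg_recording()] with channels Cz and CPz.
#' @param config A [protocol_config()].
#' @return A tibble with columns `t` (s), `coh`, `theta`, `beta`; `coh` is
#'   `NA` at t = 1.
#' @export
online_bars <- function(rec, config = protocol_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  es <- epoch_recording(rec, epoch_s = 1)
  n_ep <- dim(es$epochs)[1]
  len <- dim(es$epochs)[3]
  w <- taper_window(len, config$taper_fraction)
  X <- epoch_ffts(es$epochs[, "Cz", , drop = TRUE], w)
  Y <- epoch_ffts(es$epochs[, "CPz", , drop = TRUE], w)
  freqs <- (seq_len(len %/% 2 + 1L) - 1L) * rec$fs / len
  bins <- band_bins(freqs, config$feedback_band)

  cs_xy <- apply(X[bins, , drop = FALSE] * Conj(Y[bins, , drop = FALSE]), 1, cumsum)
  cs_xx <- apply(Mod(X[bins, , drop = FALSE])^2, 1, cumsum)
  cs_yy <- apply(Mod(Y[bins, , drop = FALSE])^2, 1, cumsum)
  # rows = epochs, cols = band bins; trailing-window sums via cumsum diffs
  win <- config$online_window_epochs
  coh_bar <- rep(NA_real_, n_ep)
  for (t in 2:n_ep) {
    lo <- max(0L, t - win)  # sum over epochs (lo+1):t
    sxy <- cs_xy[t, ] - if (lo > 0) cs_xy[lo, ] else 0
    sxx <- cs_xx[t, ] - if (lo > 0) cs_xx[lo, ] else 0
    syy <- cs_yy[t, ] - if (lo > 0) cs_yy[lo, ] else 0
    coh_bar[t] <- mean(Mod(sxy)^2 / (sxx * syy))
  }

  cz <- channel(rec, "Cz")
  th <- complex_demod_power(cz, config$theta_band, rec$fs)$epoch_power
  be <- complex_demod_power(cz, config$beta_band, rec$fs)$epoch_power
  tibble::tibble(t = seq_len(n_ep), coh = coh_bar,
                 theta = th[seq_len(n_ep)], beta = be[seq_len(n_ep)])
}

#' Baseline-derived feedback thresholds
#'
#' From the baseline run's bar series: the coherence threshold is the mean
#' online coherence; the theta and beta thresholds are mean + 1 sample SD
#' (n-1 denominator) of the respective control-bar power.
#'
#' @param bars A bar tibble from [online_bars()].
#' @return An object of class `nf_thresholds` with `coh_thr`, `theta_thr`,
#'   `beta_thr`.
#' @export
compute_thresholds <- function(bars) {
  coh <- bars$coh[!is.na(bars$coh)]
  if (length(coh) < 2) stop("insufficient baseline epochs", call. = FALSE)
  structure(list(coh_thr = mean(coh),
                 theta_thr = mean(bars$theta) + stats::sd(bars$theta),
                 beta_thr = mean(bars$beta) + stats::sd(bars$beta)),
            class = "nf_thresholds")
}

#' Adapt the coherence threshold after a feedback run
#'
#' The coherence threshold is reset to the just-completed run's mean online
#' coherence; the theta and beta control thresholds are never changed within
#' a session.
#'
#' @param bars Bar series of the completed run.
#' @param thresholds Current [compute_thresholds()] result.
#' @return Updated `nf_thresholds`.
#' @export
adapt_threshold <- function(bars, thresholds) {
  stopifnot(inherits(thresholds, "nf_thresholds"))
  thresholds$coh_thr <- mean(bars$coh, na.rm = TRUE)
  thresholds
}

#' Count rewards over a feedback run
#'
#' An update is "green" when all three bars are in their desired state:
#' theta below its threshold, beta below its threshold, and coherence above
#' (up-regulation) or below (down-regulation) the feedback threshold.
#' Updates with no coherence estimate yet are never green. In `"entry"` mode
#' (default) the counter increments once per transition into the green
#' state; `"per_update"` counts every green update.
#'
#' @param bars Bar series from [online_bars()].
#' @param thresholds An `nf_thresholds`.
#' @param direction `"up"` or `"down"`.
#' @param mode `"entry"` or `"per_update"`.
#' @return Integer reward count.
#' @export
score_rewards <- function(bars, thresholds, direction = c("up", "down"),
                          mode = c("entry", "per_update")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  coh_ok <- if (direction == "up") bars$coh > thresholds$coh_thr
            else bars$coh < thresholds$coh_thr
  green <- !is.na(coh_ok) & coh_ok &
    bars$theta < thresholds$theta_thr & bars$beta < thresholds$beta_thr
  if (mode == "per_update") return(sum(green))
  entries <- green & !c(FALSE, green[-length(green)])
  sum(entries)
}

#' Offline per-run summary
#'
#' Applies the offline pipeline to one run: 1-s epoching, artifact
#' rejection, epoch-averaged coherence (MSC and signed imaginary part) in
#' the feedback band, and complex-demodulation band powers for the SMR,
#' theta and beta bands on both channels averaged over the kept epochs.
#'
#' @param rec An [eeg_recording()].
#' @param config A [protocol_config()].
#' @return A one-row tibble of summaries.
#' @export
process_run <- function(rec, config = protocol_config()) {
  es <- reject_epochs(epoch_recording(rec, 1), config$criteria)
  est <- epoch_spectra(es, "Cz", "CPz", config$taper_fraction)
  co <- coherence(est, config$feedback_band)
  kept <- es$keep
  demod_mean <- function(ch, band) {
    ep <- complex_demod_power(channel(rec, ch), band, rec$fs)$epoch_power
    mean(ep[seq_along(kept)][kept])
  }
  tibble::tibble(
    n_epochs = length(kept), n_epochs_kept = sum(kept),
    rejection_rate = rejection_rate(es),
    band_msc = co$band_msc, band_imcoh = co$band_imcoh,
    power_smr_cz = demod_mean("Cz", config$feedback_band),
    power_smr_cpz = demod_mean("CPz", config$feedback_band),
    power_theta_cz = demod_mean("Cz", config$theta_band),
    power_theta_cpz = demod_mean("CPz", config$theta_band),
    power_beta_cz = demod_mean("Cz", config$beta_band),
    power_beta_cpz = demod_mean("CPz", config$beta_band),
    coupling_true = rec$meta$coupling_true %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full training for a cohort
#'
#' For each subject and session: simulate the baseline run, derive
#' thresholds, then simulate the six feedback runs with reward scoring and
#' per-run coherence-threshold adaptation; every run is also pushed through
#' the offline pipeline ([process_run()]). All randomness derives from
#' `seed` (per-run sub-seeds are drawn once up front), so a rerun with the
#' same cohort, config and seed is identical.
#'
#' @param cohort List of [learner_params()], one per subject; names are used
#'   as subject ids when present.
#' @param config A [protocol_config()] (its `direction` labels the group).
#' @param seed Integer master seed.
#' @param group Group label stored in the dataset (defaults to
#'   `config$direction`).
#' @return List with `dataset` (long tibble: group, subject, session, run,
#'   offline summaries, reward count on feedback runs) and `sessions`
#'   (list of per-session records: thresholds per run, rewards).
#' @export
run_training <- function(cohort, config = protocol_config(), seed = 1,
                         group = config$direction) {
  stopifnot(length(cohort) > 0)
  ids <- names(cohort) %||% sprintf("S%02d", seq_along(cohort))
  if (is.null(names(cohort))) names(cohort) <- ids
  set.seed(seed)
  n_runs <- config$runs_per_session
  seeds <- array(sample.int(2^31 - 1, length(cohort) * config$n_sessions * n_runs),
                 dim = c(length(cohort), config$n_sessions, n_runs))

  rows <- list()
  sessions <- list()
  for (si in seq_along(cohort)) {
    learner <- cohort[[si]]
    for (s in seq_len(config$n_sessions)) {
      base_rec <- simulate_run(learner, s, 1, config$run_s, config$fs,
                               seed = seeds[si, s, 1])
      base_bars <- online_bars(base_rec, config)
      thr <- compute_thresholds(base_bars)
      thr_log <- list(thr)
      rewards <- integer(n_runs - 1)
      run_rows <- list(cbind(run = 1, process_run(base_rec, config),
                             reward_count = NA_integer_))
      for (r in 2:n_runs) {
        rec <- simulate_run(learner, s, r, config$run_s, config$fs,
                            seed = seeds[si, s, r])
        bars <- online_bars(rec, config)
        rewards[r - 1] <- score_rewards(bars, thr, config$direction,
                                        config$reward_mode)
        run_rows[[r]] <- cbind(run = r, process_run(rec, config),
                               reward_count = rewards[r - 1])
        thr <- adapt_threshold(bars, thr)
        thr_log[[r]] <- thr
      }
      sess <- do.call(rbind, run_rows)
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = group, subject = ids[si], session = s, sess)
      sessions[[length(sessions) + 1]] <- list(
        subject = ids[si], group = group, session = s,
        thresholds = thr_log, reward_count = sum(rewards),
        rewards_per_run = rewards)
    }
  }
  dataset <- dplyr::bind_rows(rows)
  list(dataset = tibble::as_tibble(dataset), sessions = sessions)
}
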