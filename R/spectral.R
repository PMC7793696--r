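#' Split-cosine-bell taper window
#'
#' A Tukey-type window: raised-cosine ramps covering `taper_fraction` of the
#' total length (half at each end), flat 1.0 elsewhere. `taper_fraction = 0`
#' gives a rectangular window; `taper_fraction = 1` reduces to the full Hann
#' window. The default 10% taper is the convention of common EEG analysis
#' software when a "Hanning window, 10%" is requested.
#'
#' @param n_samples Window length (>= 4).
#' @param taper_fraction Fraction of the window covered by the two
#'   cosine ramps combined, in `[0, 1]`.
#' @return Numeric vector of `n_samples` weights in `[0, 1]`.
#' @examples
#' w <- taper_window(256, 0.10)
#' sum(w == 1)
#' @export
taper_window <- function(n_samples, taper_fraction = 0.10) {
  if (n_samples < 4) stop("n_samples must be >= 4", call. = FALSE)
  if (taper_fraction < 0 || taper_fraction > 1) {
    stop("taper_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (taper_fraction == 0) return(rep(1, n_samples))
  t <- (seq_len(n_samples) - 1) / (n_samples - 1)
  r <- taper_fraction
  w <- rep(1, n_samples)
  lo <- t < r / 2
  hi <- t > 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / r - 1)))
  w
}

# FFT of demeaned, windowed epochs. M: n_ep x len matrix; returns complex
# matrix (len x n_ep), unnormalized.
epoch_ffts <- function(M, window) {
  M <- M - rowMeans(M)
  stats::mvfft(t(M) * window)
}

#' Epoch-averaged auto- and cross-spectra of a channel pair
#'
#' Per kept epoch: demean, apply the taper window, FFT. The spectra are
#' averaged over epochs: `sxy = mean(X * Conj(Y))`, `sxx`, `syy` analogous.
#' One-sided spectra are returned on the natural frequency grid of the epoch
#' length (1 Hz resolution for 1-s epochs at 256 Hz), normalized by the
#' window power so that the spectrum integrates to the unwindowed signal
#' variance (Parseval within 1% on white noise).
#'
#' At least two kept epochs are required: the coherence of a single epoch is
#' identically 1 and carries no information.
#'
#' @param es An [epoch_recording()] result (after [reject_epochs()] if
#'   rejection is wanted).
#' @param ch_x,ch_y Channel labels of the pair (defaults Cz, CPz).
#' @param taper_fraction Passed to [taper_window()].
#' @param keep_epochs If `TRUE`, per-epoch complex spectra are retained in
#'   the result (`x_epochs`, `y_epochs`), enabling the per-epoch
#'   normalization variant of [coherence()].
#' @return An object of class `spectral_estimate` with fields `freqs` (Hz),
#'   `sxx`, `syy` (one-sided, microvolt^2 per bin), complex `sxy`,
#'   `n_epochs`, `fs`.
#' @export
epoch_spectra <- function(es, ch_x = "Cz", ch_y = "CPz",
                          taper_fraction = 0.10, keep_epochs = FALSE) {
  stopifnot(inherits(es, "epoch_set"))
  kept <- which(es$keep)
  if (length(kept) < 2) {
    stop("need at least 2 kept epochs for spectral estimation", call. = FALSE)
  }
  len <- dim(es$epochs)[3]
  w <- taper_window(len, taper_fraction)
  X <- epoch_ffts(es$epochs[kept, ch_x, , drop = TRUE], w)
  Y <- epoch_ffts(es$epochs[kept, ch_y, , drop = TRUE], w)
  build_spectral_estimate(X, Y, es$fs, len, w, keep_epochs)
}

# Shared by epoch_spectra and the online estimator: average FFT products and
# fold to one-sided spectra.
build_spectral_estimate <- function(X, Y, fs, len, window, keep_epochs = FALSE) {
  n_ep <- ncol(X)
  norm <- 1 / (len * sum(window^2))
  sxx2 <- rowMeans(Mod(X)^2) * norm
  syy2 <- rowMeans(Mod(Y)^2) * norm
  sxy2 <- rowMeans(X * Conj(Y)) * norm
  nb <- len %/% 2 + 1L
  fold <- c(1, rep(2, nb - 2L), if (len %% 2 == 0) 1 else 2)
  est <- structure(
    list(freqs = (seq_len(nb) - 1L) * fs / len,
         sxx = sxx2[seq_len(nb)] * fold,
         syy = syy2[seq_len(nb)] * fold,
         sxy = sxy2[seq_len(nb)] * fold,
         n_epochs = n_ep, fs = fs),
    class = "spectral_estimate")
  if (keep_epochs) {
    est$x_epochs <- X[seq_len(nb), , drop = FALSE]
    est$y_epochs <- Y[seq_len(nb), , drop = FALSE]
  }
  est
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate: %d bins (0-%g Hz), %d epochs>\n",
              length(x$freqs), max(x$freqs), x$n_epochs))
  invisible(x)
}

#' Magnitude-squared and imaginary coherence
#'
#' Coherency \eqn{C(f) = S_{xy}(f) / \sqrt{S_{xx}(f) S_{yy}(f)}} from
#' epoch-averaged spectra; magnitude-squared coherence \eqn{|C(f)|^2} in
#' `[0, 1]` and the signed imaginary part \eqn{\mathrm{Im}\,C(f)} in
#' `[-1, 1]`. Band summaries are arithmetic means over the bins whose centre
#' frequency falls in `[f_lo, f_hi]` inclusive (at 1 Hz resolution the
#' 12--15 Hz band comprises the 12, 13, 14 and 15 Hz bins).
#'
#' The imaginary part is insensitive to zero-lag dependence: an instantaneous
#' (volume-conducted) mixture has a real cross-spectrum, so its MSC can be
#' large while Im C stays at zero. It is reported signed, not rectified.
#'
#' @param est A [epoch_spectra()] result.
#' @param band A [band_spec()] within the frequency range.
#' @param method `"average"` (default): normalize the epoch-averaged spectra,
#'   the standard coherency definition. `"per_epoch"`: normalize each epoch's
#'   cross-spectrum before averaging (requires `keep_epochs = TRUE` in
#'   [epoch_spectra()]); available for sensitivity analysis.
#' @return An object of class `coherence_result` with per-bin `msc`,
#'   `imcoh`, the included `bins`, and scalars `band_msc`, `band_imcoh`.
#' @export
coherence <- function(est, band, method = c("average", "per_epoch")) {
  stopifnot(inherits(est, "spectral_estimate"), inherits(band, "band_spec"))
  method <- match.arg(method)
  bins <- band_bins(est$freqs, band)
  if (length(bins) == 0) stop("band outside the frequency range", call. = FALSE)
  if (method == "average") {
    if (any(est$sxx[bins] <= 0) || any(est$syy[bins] <= 0)) {
      stop("zero auto-spectrum in band: degenerate signal", call. = FALSE)
    }
    C <- est$sxy / sqrt(est$sxx * est$syy)
  } else {
    if (is.null(est$x_epochs)) {
      stop("per-epoch method needs epoch_spectra(..., keep_epochs = TRUE)",
           call. = FALSE)
    }
    Cx <- est$x_epochs * Conj(est$y_epochs)
    denom <- Mod(est$x_epochs) * Mod(est$y_epochs)
    C <- rowMeans(Cx / ifelse(denom == 0, NA_real_, denom))
  }
  msc <- pmin(Mod(C)^2, 1)
  imcoh <- Im(C)
  structure(list(freqs = est$freqs, msc = msc, imcoh = imcoh, bins = bins,
                 band_msc = mean(msc[bins]), band_imcoh = mean(imcoh[bins]),
                 band = band, n_epochs = est$n_epochs),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence %s (%g-%g Hz): MSC %.3f, ImCoh %+.3f over %d epochs>\n",
              x$band$name, x$band$f_lo, x$band$f_hi,
              x$band_msc, x$band_imcoh, x$n_epochs))
  invisible(x)
}

#' Band power from the epoch-averaged auto-spectrum
#'
#' Sum of one-sided auto-spectral power over the band's bins; serves as a
#' direct FFT cross-check for the complex-demodulation band power.
#'
#' @param est A [epoch_spectra()] result.
#' @param band A [band_spec()].
#' @param channel `"x"` or `"y"`.
#' @return Band power in microvolt^2.
#' @export
band_power_fft <- function(est, band, channel = c("x", "y")) {
  stopifnot(inherits(est, "spectral_estimate"))
  channel <- match.arg(channel)
  bins <- band_bins(est$freqs, band)
  if (length(bins) == 0) stop("band outside the frequency range", call. = FALSE)
  s <- if (channel == "x") est$sxx else est$syy
  sum(s[bins])
}

#' Band power by complex demodulation
#'
#' The signal is shifted to baseband by multiplication with a complex
#' exponential at the band centre \eqn{f_c = (f_{lo}+f_{hi})/2}, low-pass
#' filtered at half the bandwidth with a zero-phase 4th-order Butterworth
#' filter, and converted to instantaneous power scaled so that a pure
#' amplitude-\eqn{A} sinusoid at \eqn{f_c} yields \eqn{A^2/2} (the variance
#' of that sinusoid). Instantaneous power is then averaged within each
#' consecutive `epoch_s` segment; pass `keep` to average only over kept
#' (artifact-free) epochs downstream.
#'
#' @param x Numeric signal (microvolts), at least 2 s long.
#' @param band A [band_spec()]; must fit below the Nyquist frequency.
#' @param fs Sampling rate in Hz.
#' @param epoch_s Epoch length for the per-epoch averages (default 1 s).
#' @return List with `epoch_power` (microvolt^2 per epoch),
#'   `instantaneous` (per sample), and `fc`.
#' @export
complex_demod_power <- function(x, band, fs = 256, epoch_s = 1) {
  stopifnot(inherits(band, "band_spec"))
  assert_band_in_range(band, fs)
  if (length(x) < 2 * fs) stop("signal must be at least 2 s long", call. = FALSE)
  fc <- band_centre(band)
  half_bw <- (band$f_hi - band$f_lo) / 2
  n <- length(x)
  # demodulate in the frequency domain: multiplying by exp(-2i*pi*fc*t) is a
  # circular shift of the spectrum when fc falls on the FFT grid
  shift <- fc * n / fs
  if (abs(shift - round(shift)) < 1e-9) {
    Z <- fft(x)
    Z <- c(Z[(round(shift) + 1):n], Z[seq_len(round(shift))])
  } else {
    t <- (seq_len(n) - 1) / fs
    Z <- stats::fft(x * exp(-2i * pi * fc * t))
  }
  # zero-phase (forward-backward) 4th-order Butterworth low-pass: gain |H|^2
  f <- abs(fft_freqs(n, fs))
  H2 <- 1 / (1 + (f / half_bw)^8)
  zf <- stats::fft(Z * H2, inverse = TRUE) / n
  inst <- 2 * Mod(zf)^2
  len <- round(epoch_s * fs)
  n_ep <- floor(length(x) / len)
  ep <- rowMeans(matrix(inst[seq_len(n_ep * len)], nrow = n_ep, byrow = TRUE))
  list(epoch_power = ep, instantaneous = inst, fc = fc)
}
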