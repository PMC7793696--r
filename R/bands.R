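#' Frequency band specification
#'
#' A band is a named closed frequency interval \eqn{[f_{lo}, f_{hi}]} in Hz.
#' The three bands of the training protocol are provided as constructors:
#' the SMR feedback band (12--15 Hz) and the theta (4--7 Hz) and beta
#' (21--35 Hz) control bands.
#'
#' @param name Band label.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return An object of class `band_spec` with fields `name`, `f_lo`, `f_hi`.
#' @examples
#' band_spec("smr", 12, 15)
#' smr_band()
#' @export
band_spec <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || length(f_lo) != 1L ||
      length(f_hi) != 1L || !(0 < f_lo) || !(f_lo < f_hi)) {
    stop("invalid band: need 0 < f_lo < f_hi", call. = FALSE)
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' @rdname band_spec
#' @export
smr_band <- function() band_spec("smr", 12, 15)

#' @rdname band_spec
#' @export
theta_band <- function() band_spec("theta", 4, 7)

#' @rdname band_spec
#' @export
beta_band <- function() band_spec("beta", 21, 35)

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

# Centre frequency of a band (Hz).
band_centre <- function(band) (band$f_lo + band$f_hi) / 2

# Indices of frequency-grid bins whose centre lies in [f_lo, f_hi] inclusive.
band_bins <- function(freqs, band) {
  which(freqs >= band$f_lo - 1e-9 & freqs <= band$f_hi + 1e-9)
}

assert_band_in_range <- function(band, fs) {
  if (band$f_hi >= fs / 2) {
    stop(sprintf("band '%s' exceeds the Nyquist frequency %g Hz",
                 band$name, fs / 2), call. = FALSE)
  }
  invisible(TRUE)
}
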