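#' Multichannel EEG recording container
#'
#' A lightweight container for a continuous multichannel recording:
#' a channels-by-samples matrix in microvolts, a sampling rate, channel
#' labels, an optional per-sample artifact truth mask (one logical row per
#' artifact class), and free-form metadata (ground-truth coupling, seeds).
#'
#' @param data Numeric matrix, channels x samples, in microvolts. Row names
#'   are used as labels when `labels` is missing.
#' @param fs Sampling rate in Hz (default 256).
#' @param labels Character vector of channel names, one per row.
#' @param artifact_truth Optional logical matrix (artifact classes x samples)
#'   with row names naming each class (e.g. `"blink"`, `"muscle"`), or `NULL`.
#' @param meta Named list of metadata carried along unchanged.
#' @return An object of class `eeg_recording`.
#' @examples
#' x <- matrix(rnorm(2 * 256), nrow = 2)
#' rec <- eeg_recording(x, fs = 256, labels = c("Cz", "CPz"))
#' n_samples(rec)
#' @export
eeg_recording <- function(data, fs = 256, labels = rownames(data),
                          artifact_truth = NULL, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    stop("labels must have one entry per channel", call. = FALSE)
  }
  if (!is.null(artifact_truth)) {
    if (!is.matrix(artifact_truth) || !is.logical(artifact_truth) ||
        ncol(artifact_truth) != ncol(data)) {
      stop("artifact_truth must be a logical matrix with one column per sample",
           call. = FALSE)
    }
  }
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels,
         artifact_truth = artifact_truth, meta = meta),
    class = "eeg_recording"
  )
}

#' @rdname eeg_recording
#' @param rec An `eeg_recording`.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname eeg_recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Extract one channel of a recording
#'
#' @param rec An `eeg_recording`.
#' @param label Channel name.
#' @return Numeric vector of samples (microvolts).
#' @export
channel <- function(rec, label) {
  if (!label %in% rec$labels) {
    stop(sprintf("channel '%s' not present (have: %s)",
                 label, paste(rec$labels, collapse = ", ")), call. = FALSE)
  }
  rec$data[label, ]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channel(s) [%s], %.1f s @ %g Hz>\n",
              nrow(x$data), paste(x$labels, collapse = ", "),
              duration_s(x), x$fs))
  invisible(x)
}
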