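#' Artifact-rejection criteria
#'
#' Thresholds for automated epoch rejection, mirroring standard gradient /
#' amplitude / low-activity checks plus an EOG amplitude proxy for manual
#' ocular rejection:
#' * `max_step_uV`: maximum allowed voltage step between consecutive samples
#'   (default 50 microvolts);
#' * `max_abs_uV`: maximum allowed absolute voltage (default 120 microvolts);
#' * `min_activity_uV`: minimum allowed peak-to-peak range within any sliding
#'   window of `activity_window_ms` (defaults 0.5 microvolts in 100 ms) —
#'   a flatline check;
#' * `eog_abs_uV`: any EOG sample beyond this magnitude rejects the epoch
#'   (default 100 microvolts). This automates what is often done by visual
#'   inspection of the EOG trace.
#'
#' The first three criteria apply to every EEG channel; the EOG criterion
#' applies to the EOG channel only.
#'
#' @param max_step_uV,max_abs_uV,min_activity_uV,activity_window_ms,eog_abs_uV
#'   Positive scalars, see above.
#' @return An object of class `rejection_criteria`.
#' @export
rejection_criteria <- function(max_step_uV = 50, max_abs_uV = 120,
                               min_activity_uV = 0.5,
                               activity_window_ms = 100,
                               eog_abs_uV = 100) {
  vals <- c(max_step_uV, max_abs_uV, min_activity_uV, activity_window_ms,
            eog_abs_uV)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all rejection criteria must be positive", call. = FALSE)
  }
  structure(list(max_step_uV = max_step_uV, max_abs_uV = max_abs_uV,
                 min_activity_uV = min_activity_uV,
                 activity_window_ms = activity_window_ms,
                 eog_abs_uV = eog_abs_uV),
            class = "rejection_criteria")
}

#' Cut a continuous recording into fixed-length epochs
#'
#' Splits the recording into consecutive non-overlapping epochs of
#' `epoch_s` seconds (default 1 s); a trailing partial epoch is discarded.
#' All epochs start out kept; [reject_epochs()] fills the keep mask.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_s Epoch length in seconds.
#' @return An object of class `epoch_set`: a 3-d array `epochs`
#'   (epoch x channel x sample), `fs`, `labels`, logical `keep`,
#'   list-column `reasons` (character vector per epoch), and the source
#'   recording's `artifact_truth` cut to the same epochs (per-epoch logical,
#'   TRUE if any sample of the epoch is marked).
#' @export
epoch_recording <- function(rec, epoch_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_s * rec$fs)
  n_ep <- floor(n_samples(rec) / len)
  if (n_ep < 1) {
    stop("recording shorter than one epoch", call. = FALSE)
  }
  used <- n_ep * len
  a <- array(NA_real_, dim = c(n_ep, nrow(rec$data), len),
             dimnames = list(NULL, rec$labels, NULL))
  for (ch in seq_len(nrow(rec$data))) {
    a[, ch, ] <- matrix(rec$data[ch, seq_len(used)], nrow = n_ep, byrow = TRUE)
  }
  truth <- NULL
  if (!is.null(rec$artifact_truth)) {
    truth <- t(vapply(seq_len(n_ep), function(i) {
      idx <- ((i - 1) * len + 1):(i * len)
      apply(rec$artifact_truth[, idx, drop = FALSE], 1, any)
    }, logical(nrow(rec$artifact_truth))))
    colnames(truth) <- rownames(rec$artifact_truth)
  }
  structure(list(epochs = a, fs = rec$fs, labels = rec$labels,
                 keep = rep(TRUE, n_ep),
                 reasons = rep(list(character(0)), n_ep),
                 artifact_truth = truth),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set: %d epochs x %d channel(s) x %d samples, %d kept>\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              sum(x$keep)))
  invisible(x)
}

#' Reject artifact-contaminated epochs
#'
#' Marks an epoch rejected if, on any EEG channel (every channel except
#' `eog_label`): (a) any consecutive-sample voltage step exceeds
#' `max_step_uV`; (b) any absolute value exceeds `max_abs_uV`; (c) any
#' sliding `activity_window_ms` window has peak-to-peak range below
#' `min_activity_uV`; or (d) any EOG sample exceeds `eog_abs_uV` in
#' magnitude. Reasons (`"step"`, `"amplitude"`, `"flatline"`, `"eog"`) are
#' recorded per epoch; a rejected epoch always carries at least one reason.
#'
#' @param es An [epoch_recording()] result.
#' @param criteria A [rejection_criteria()].
#' @param eog_label Name of the EOG channel (ignored if absent).
#' @return The `epoch_set` with `keep` and `reasons` updated.
#' @export
reject_epochs <- function(es, criteria = rejection_criteria(),
                          eog_label = "EOG") {
  stopifnot(inherits(es, "epoch_set"), inherits(criteria, "rejection_criteria"))
  n_ep <- dim(es$epochs)[1]
  if (n_ep == 0) stop("no epochs present", call. = FALSE)
  len <- dim(es$epochs)[3]
  win <- max(2L, round(criteria$activity_window_ms / 1000 * es$fs))
  eeg_ch <- setdiff(es$labels, eog_label)

  step_hit <- amp_hit <- flat_hit <- rep(FALSE, n_ep)
  for (lab in eeg_ch) {
    M <- es$epochs[, lab, , drop = TRUE]
    if (n_ep == 1) M <- matrix(M, nrow = 1)
    D <- abs(M[, -1, drop = FALSE] - M[, -len, drop = FALSE])
    step_hit <- step_hit | row_max(D) > criteria$max_step_uV
    amp_hit <- amp_hit | row_max(abs(M)) > criteria$max_abs_uV
    flat_hit <- flat_hit | min_sliding_range(M, win) < criteria$min_activity_uV
  }
  eog_hit <- rep(FALSE, n_ep)
  if (eog_label %in% es$labels) {
    E <- es$epochs[, eog_label, , drop = TRUE]
    if (n_ep == 1) E <- matrix(E, nrow = 1)
    eog_hit <- row_max(abs(E)) > criteria$eog_abs_uV
  }

  es$reasons <- lapply(seq_len(n_ep), function(i) {
    c("step", "amplitude", "flatline", "eog")[c(step_hit[i], amp_hit[i],
                                                flat_hit[i], eog_hit[i])]
  })
  es$keep <- !(step_hit | amp_hit | flat_hit | eog_hit)
  es
}

row_max <- function(m) do.call(pmax, as.data.frame(m))

row_min <- function(m) do.call(pmin, as.data.frame(m))

# Per-epoch minimum peak-to-peak range over all sliding windows of `win`
# samples (stride 1), vectorized across epochs via shifted pmax/pmin.
min_sliding_range <- function(M, win) {
  len <- ncol(M)
  if (len <= win) return(row_max(M) - row_min(M))
  n1 <- len - win + 1L
  rmax <- M[, 1:n1, drop = FALSE]
  rmin <- rmax
  for (k in seq_len(win - 1L)) {
    shifted <- M[, (1L + k):(n1 + k), drop = FALSE]
    rmax <- pmax(rmax, shifted)
    rmin <- pmin(rmin, shifted)
  }
  row_min(rmax - rmin)
}

#' Overall epoch-rejection rate
#'
#' Fraction of epochs rejected across one or more epoch sets (e.g. all runs
#' of a session or a whole training).
#'
#' @param epoch_sets A single `epoch_set` or a list of them.
#' @return Rejected / total, in `[0, 1]`.
#' @export
rejection_rate <- function(epoch_sets) {
  if (inherits(epoch_sets, "epoch_set")) epoch_sets <- list(epoch_sets)
  if (length(epoch_sets) == 0) stop("no epoch sets supplied", call. = FALSE)
  total <- sum(vapply(epoch_sets, function(e) length(e$keep), integer(1)))
  if (total == 0) stop("no epochs present", call. = FALSE)
  kept <- sum(vapply(epoch_sets, function(e) sum(e$keep), integer(1)))
  (total - kept) / total
}
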