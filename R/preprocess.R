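#' Re-reference to the scalp average
#'
#' Subtracts, at every sample, the mean over scalp channels from every scalp
#' channel, so the scalp mean is exactly zero afterwards. Ocular channels
#' are left untouched: they monitor eye activity and must not be mixed into
#' the reference.
#'
#' @param rec a [recording()].
#' @return the re-referenced recording.
#' @export
apply_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  sc <- scalp_channels(rec$montage)
  if (length(sc) < 2)
    stop("average reference needs at least 2 scalp channels")
  ref <- colMeans(rec$data[sc, , drop = FALSE])
  rec$data[sc, ] <- sweep(rec$data[sc, , drop = FALSE], 2, ref)
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a digital Butterworth band-pass (default 1--30 Hz, order 4)
#' forward and backward (`signal::filtfilt`), so ERP peak latencies are not
#' shifted by group delay.
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param order filter order.
#' @return the filtered recording.
#' @export
bandpass_filter <- function(rec, low = 1, high = 30, order = 4) {
  stopifnot(inherits(rec, "recording"))
  if (low <= 0 || high <= low) stop("band must satisfy 0 < low < high")
  if (high >= rec$fs / 2)
    stop(sprintf("high edge %g Hz must be below the Nyquist rate %g Hz",
                 high, rec$fs / 2))
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rownames(rec$data) <- rec$montage$channels
  rec
}

#' Segment a recording into stimulus-locked epochs
#'
#' Cuts one epoch per event over the half-open window `[tmin, tmax)` ms
#' relative to stimulus onset (onset = 0 ms). At 500 Hz the default window
#' -100..700 ms yields 400 samples per epoch.
#'
#' @param rec a [recording()] with at least one event.
#' @param tmin,tmax epoch window in ms.
#' @return an object of class `"epoch_set"` with fields `epochs`
#'   (trials x channels x samples array), `labels`, `kept`, `times_ms`,
#'   `tmin`, `tmax`, `fs`, `channels`, `montage`.
#' @export
epoch_recording <- function(rec, tmin = -100, tmax = 700) {
  stopifnot(inherits(rec, "recording"))
  if (tmax <= tmin) stop("tmax must exceed tmin")
  if (!nrow(rec$events)) stop("recording has no events to epoch")
  fs <- rec$fs
  off <- ms_to_samp(tmin, fs):(ms_to_samp(tmax, fs) - 1L)
  first <- rec$events$sample + off[1]
  last <- rec$events$sample + off[length(off)]
  bad <- which(first < 1 | last > ncol(rec$data))
  if (length(bad))
    stop(sprintf("event(s) too close to the recording edge for a [%g, %g) ms window: %s",
                 tmin, tmax, paste(bad, collapse = ", ")))
  n_tr <- nrow(rec$events); n_ch <- nrow(rec$data); n_sp <- length(off)
  ep <- array(NA_real_, c(n_tr, n_ch, n_sp),
              dimnames = list(NULL, rec$montage$channels, NULL))
  for (i in seq_len(n_tr))
    ep[i, , ] <- rec$data[, rec$events$sample[i] + off, drop = FALSE]
  structure(list(epochs = ep,
                 labels = as.character(rec$events$label),
                 kept = rep(TRUE, n_tr),
                 times_ms = samp_to_ms(off, fs),
                 tmin = tmin, tmax = tmax, fs = fs,
                 channels = rec$montage$channels,
                 montage = rec$montage,
                 rejection_log = NULL),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%d kept) x %d ch x %d samples, [%g, %g) ms @ %g Hz\n",
              length(x$labels), sum(x$kept), dim(x$epochs)[2],
              dim(x$epochs)[3], x$tmin, x$tmax, x$fs))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean of the pre-stimulus interval
#' (default -100..0 ms) from the whole epoch, so the pre-stimulus mean of
#' every corrected trial is exactly zero.
#'
#' @param es an `"epoch_set"`.
#' @param window baseline window `c(t0, t1)` in ms, half-open.
#' @return the corrected `"epoch_set"`.
#' @export
baseline_correct <- function(es, window = c(-100, 0)) {
  stopifnot(inherits(es, "epoch_set"))
  idx <- which(es$times_ms >= window[1] & es$times_ms < window[2])
  if (!length(idx))
    stop("epoch window does not include the pre-stimulus baseline interval")
  bl <- apply(es$epochs[, , idx, drop = FALSE], c(1, 2), mean)
  es$epochs <- es$epochs - as.vector(bl)   # array recycles over 3rd dim
  es
}

#' Reject artifact-contaminated trials
#'
#' A trial is rejected if (a) on any ocular channel the peak-to-peak range
#' within any sliding window of `ocular_ms` ms exceeds `ocular_uv` uV, or
#' (b) on any channel the absolute amplitude exceeds `movement_uv` uV.
#' Rejected trials keep their data but are flagged `kept = FALSE` and are
#' excluded from all downstream averages. The per-trial decision is recorded
#' in `$rejection_log` (trial, rule, channel).
#'
#' @param es an `"epoch_set"`.
#' @param montage the montage (defaults to the one attached to `es`); must
#'   declare at least one ocular channel.
#' @param ocular_uv,ocular_ms ocular peak-to-peak threshold (uV) and window
#'   length (ms).
#' @param movement_uv absolute amplitude threshold (uV) on all channels.
#' @return the `"epoch_set"` with updated `kept` flags and rejection log.
#' @export
reject_artifacts <- function(es, montage = es$montage,
                             ocular_uv = 50, ocular_ms = 50,
                             movement_uv = 200) {
  stopifnot(inherits(es, "epoch_set"))
  oc <- ocular_channels(montage)
  if (!length(oc))
    stop("artifact rejection requires at least one ocular channel")
  w <- ms_to_samp(ocular_ms, es$fs) + 1L      # inclusive 50-ms span
  log <- list()
  for (i in seq_along(es$labels)) {
    if (!es$kept[i]) next
    tr <- es$epochs[i, , ]
    hit <- which(apply(abs(tr), 1, max) > movement_uv)
    if (length(hit)) {
      es$kept[i] <- FALSE
      log[[length(log) + 1L]] <- data.frame(
        trial = i, rule = "movement", channel = es$channels[hit[1]])
      next
    }
    for (ch in oc) {
      if (running_range_max(tr[ch, ], w) > ocular_uv) {
        es$kept[i] <- FALSE
        log[[length(log) + 1L]] <- data.frame(
          trial = i, rule = "ocular", channel = ch)
        break
      }
    }
  }
  es$rejection_log <- if (length(log)) do.call(rbind, log) else
    data.frame(trial = integer(), rule = character(), channel = character())
  if (!any(es$kept))
    warning("all trials were rejected")
  es
}

#' Run the full preprocessing chain on a recording
#'
#' Average reference, band-pass filter, epoching, baseline correction and
#' artifact rejection, in that fixed order.
#'
#' @param rec a [recording()].
#' @param config a [default_config()]-style list.
#' @return an `"epoch_set"` ready for averaging.
#' @export
preprocess_recording <- function(rec, config = default_config()) {
  rec <- apply_average_reference(rec)
  rec <- bandpass_filter(rec, config$filter$low, config$filter$high,
                         config$filter$order)
  es <- epoch_recording(rec, config$epoch$tmin, config$epoch$tmax)
  es <- baseline_correct(es, config$baseline)
  reject_artifacts(es,
                   ocular_uv = config$reject$ocular_uv,
                   ocular_ms = config$reject$ocular_ms,
                   movement_uv = config$reject$movement_uv)
}
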