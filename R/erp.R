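#' Average kept trials into per-condition ERPs
#'
#' @param es an `"epoch_set"` after preprocessing.
#' @param subject subject identifier stored on each ERP.
#' @param conditions conditions to average; defaults to all labels present.
#' @return a named list of `"erp"` objects (one per condition), each holding
#'   `waveform` (channels x samples, uV), `n_trials_averaged`, `times_ms`.
#' @export
average_erp <- function(es, subject = "s1", conditions = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  if (is.null(conditions)) conditions <- unique(es$labels)
  out <- list()
  for (cond in conditions) {
    sel <- which(es$labels == cond & es$kept)
    if (!length(sel))
      stop(sprintf("condition '%s' has no kept trials", cond))
    wf <- apply(es$epochs[sel, , , drop = FALSE], c(2, 3), mean)
    rownames(wf) <- es$channels
    out[[cond]] <- structure(
      list(subject = subject, condition = cond, waveform = wf,
           n_trials_averaged = length(sel), times_ms = es$times_ms,
           fs = es$fs, channels = es$channels, montage = es$montage),
      class = "erp")
  }
  out
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("<erp> subject %s, condition %s, %d ch x %d samples (n = %d trials)\n",
              x$subject, x$condition, nrow(x$waveform), ncol(x$waveform),
              x$n_trials_averaged))
  invisible(x)
}

#' Grand average across subjects
#'
#' Arithmetic mean of per-subject ERP waveforms (each subject weighted
#' equally, regardless of trial counts).
#'
#' @param erps list of `"erp"` objects for the same condition and layout.
#' @return an `"erp"` with subject `"grand"`.
#' @export
grand_average <- function(erps) {
  stopifnot(length(erps) >= 1, all(vapply(erps, inherits, TRUE, "erp")))
  wf <- Reduce(`+`, lapply(erps, `[[`, "waveform")) / length(erps)
  e <- erps[[1]]
  e$subject <- "grand"
  e$waveform <- wf
  e$n_trials_averaged <- length(erps)
  e
}

#' Channel-group mean waveform of an ERP
#'
#' @param erp an `"erp"`.
#' @param group montage group name.
#' @param montage montage defining the group (defaults to the ERP's).
#' @return numeric vector, one value per epoch sample (uV).
#' @export
erp_group_signal <- function(erp, group, montage = erp$montage) {
  ch <- group_channels(montage, group)
  missing <- setdiff(ch, erp$channels)
  if (length(missing))
    stop(sprintf("channel %s not found", missing[1]))
  colMeans(erp$waveform[ch, , drop = FALSE])
}

#' Detect an ERP peak in its component search window
#'
#' The waveform is first averaged across the channels of the montage group;
#' P1 is the maximum in the closed 60--120 ms window and N170 the minimum in
#' the closed 100--200 ms window. Ties resolve to the earliest latency.
#'
#' @param erp an `"erp"`.
#' @param group montage group name (e.g. `"right_pt"`, `"occipital"`).
#' @param component `"P1"` or `"N170"`.
#' @param window optional custom search window `c(t0, t1)` in ms (closed).
#' @return a list of class `"peak_result"`: `component`, `latency` (ms),
#'   `amplitude` (uV), `group`.
#' @export
detect_peak <- function(erp, group, component = c("P1", "N170"),
                        window = NULL) {
  stopifnot(inherits(erp, "erp"))
  component <- match.arg(component)
  if (is.null(window))
    window <- if (component == "P1") c(60, 120) else c(100, 200)
  g <- erp_group_signal(erp, group)
  idx <- which(erp$times_ms >= window[1] & erp$times_ms <= window[2])
  if (!length(idx))
    stop("ERP waveform does not cover the peak search window")
  k <- if (component == "P1") idx[which.max(g[idx])] else
    idx[which.min(g[idx])]
  structure(list(component = component, latency = erp$times_ms[k],
                 amplitude = unname(g[k]), group = group),
            class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("%s @ %g ms, %.2f uV (%s)\n", x$component, x$latency,
              x$amplitude, x$group))
  invisible(x)
}

#' Mean amplitude over a channel group and time window
#'
#' @param erp an `"erp"`.
#' @param group montage group name.
#' @param t0,t1 window in ms, half-open `[t0, t1)`.
#' @return mean amplitude in uV.
#' @export
window_mean <- function(erp, group, t0, t1) {
  stopifnot(inherits(erp, "erp"))
  if (t1 <= t0) stop("window must satisfy t1 > t0")
  if (t0 < erp$times_ms[1] ||
      t1 > erp$times_ms[length(erp$times_ms)] + 1000 / erp$fs)
    stop(sprintf("window [%g, %g) ms lies outside the epoch", t0, t1))
  g <- erp_group_signal(erp, group)
  idx <- which(erp$times_ms >= t0 & erp$times_ms < t1)
  if (!length(idx)) stop("window contains no samples")
  mean(g[idx])
}

#' Tidy table of ERP metrics
#'
#' P1 and N170 peaks plus the five late 100-ms window means (200--300 ...
#' 600--700 ms) for each hemisphere group, per ERP.
#'
#' @param erps list of `"erp"` objects.
#' @param groups montage group names to summarize.
#' @param late_windows matrix-like list of `c(t0, t1)` late windows.
#' @return a data.frame: subject, condition, group, measure, latency_ms,
#'   amplitude_uv.
#' @export
erp_metrics <- function(erps, groups = c("left_pt", "right_pt"),
                        late_windows = lapply(seq(200, 600, 100),
                                              function(t0) c(t0, t0 + 100))) {
  rows <- list()
  for (e in erps) for (g in groups) {
    for (comp in c("P1", "N170")) {
      p <- detect_peak(e, g, comp)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = e$subject, condition = e$condition, group = g,
        measure = comp, latency_ms = p$latency, amplitude_uv = p$amplitude)
    }
    for (w in late_windows) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = e$subject, condition = e$condition, group = g,
        measure = sprintf("mean_%g_%g", w[1], w[2]), latency_ms = NA_real_,
        amplitude_uv = window_mean(e, g, w[1], w[2]))
    }
  }
  do.call(rbind, rows)
}
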