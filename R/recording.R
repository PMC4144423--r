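#' Construct a continuous EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param montage a [montage()] whose channels match the rows of `data`.
#' @param events data.frame with columns `sample` (1-based sample index of
#'   stimulus onset, strictly increasing) and `label` (condition, e.g.
#'   `"CS+"`, `"CS-"`, `"scenery"`).
#' @return an object of class `"recording"`.
#' @export
recording <- function(data, fs, montage,
                      events = data.frame(sample = integer(),
                                          label = character())) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric channels x samples matrix")
  if (!inherits(montage, "montage")) stop("montage required")
  if (nrow(data) != length(montage$channels))
    stop(sprintf("data has %d rows but montage names %d channels",
                 nrow(data), length(montage$channels)))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive sampling rate in Hz")
  events <- as.data.frame(events)
  if (!all(c("sample", "label") %in% names(events)))
    stop("events must have columns 'sample' and 'label'")
  if (nrow(events)) {
    if (any(diff(events$sample) <= 0))
      stop("event sample indices must be strictly increasing")
    if (min(events$sample) < 1 || max(events$sample) > ncol(data))
      stop("event sample indices must lie within the recording")
    if (any(!nzchar(as.character(events$label))))
      stop("event labels must be non-empty")
  }
  rownames(data) <- montage$channels
  structure(list(data = data, fs = fs, montage = montage,
                 events = events),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}
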