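#' Construct an electrode montage
#'
#' A montage names the channels of a recording, assigns each a role
#' (`"scalp"` or `"ocular"`), and defines named channel groups used as
#' regions of interest, e.g. the left/right posterior temporal groups that
#' carry face-evoked activity.
#'
#' @param channels character vector of unique channel names, in recording
#'   order.
#' @param roles character vector, one of `"scalp"` or `"ocular"` per channel.
#'   Defaults to all-scalp.
#' @param groups named list of character vectors; every group must be a
#'   subset of `channels`.
#' @return an object of class `"montage"`.
#' @examples
#' m <- montage(c("P8", "P10", "TP10", "VEOG"),
#'              roles = c("scalp", "scalp", "scalp", "ocular"),
#'              groups = list(right_pt = c("P8", "P10", "TP10")))
#' @export
montage <- function(channels, roles = NULL, groups = list()) {
  channels <- as.character(channels)
  if (anyDuplicated(channels))
    stop("channel names must be unique")
  if (is.null(roles)) roles <- rep("scalp", length(channels))
  if (length(roles) != length(channels))
    stop("one role per channel is required")
  if (!all(roles %in% c("scalp", "ocular")))
    stop("roles must be 'scalp' or 'ocular'")
  if (length(groups) && is.null(names(groups)))
    stop("groups must be named")
  for (g in names(groups)) {
    missing <- setdiff(groups[[g]], channels)
    if (length(missing))
      stop(sprintf("group '%s' names unknown channel(s): %s",
                   g, paste(missing, collapse = ", ")))
  }
  structure(list(channels = channels,
                 roles = stats::setNames(roles, channels),
                 groups = groups),
            class = "montage")
}

#' Default montage for the face-BCI pipeline
#'
#' A compact 13-channel layout containing the posterior temporal regions of
#' interest (left: P7, P9, TP9; right: P8, P10, TP10), the occipital pair
#' (O1, O2), three midline scalp channels and two ocular channels used for
#' blink/eye-movement rejection.
#'
#' @return a `"montage"` object.
#' @export
default_montage <- function() {
  ch <- c("O1", "O2", "P7", "P9", "TP9", "P8", "P10", "TP10",
          "Fz", "Cz", "Pz", "VEOG", "HEOG")
  roles <- c(rep("scalp", 11), "ocular", "ocular")
  montage(ch, roles,
          groups = list(left_pt   = c("P7", "P9", "TP9"),
                        right_pt  = c("P8", "P10", "TP10"),
                        occipital = c("O1", "O2")))
}

scalp_channels <- function(m) m$channels[m$roles[m$channels] == "scalp"]
ocular_channels <- function(m) m$channels[m$roles[m$channels] == "ocular"]

group_channels <- function(m, group) {
  if (!group %in% names(m$groups))
    stop(sprintf("montage has no group '%s'", group))
  g <- m$groups[[group]]
  if (!length(g)) stop(sprintf("group '%s' is empty", group))
  g
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels (%d scalp, %d ocular)\n",
              length(x$channels), sum(x$roles == "scalp"),
              sum(x$roles == "ocular")))
  for (g in names(x$groups))
    cat(sprintf("  %s: %s\n", g, paste(x$groups[[g]], collapse = ", ")))
  invisible(x)
}
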