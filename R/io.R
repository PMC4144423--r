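#' Write a recording to the native delimited format
#'
#' The native on-disk format is a tab-delimited channels x samples matrix
#' plus a YAML sidecar (`<path>.meta.yaml`) holding the sampling rate,
#' channel order, channel roles, amplitude unit and event list. Amplitudes
#' are stored in microvolts.
#'
#' @param rec a [recording()].
#' @param path output path for the data matrix; the sidecar is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (any(!is.finite(rec$data)))
    stop("recording contains NaN/Inf values; refusing to serialize")
  data.table::fwrite(data.table::as.data.table(rec$data), path,
                     sep = "\t", col.names = FALSE)
  meta <- list(
    fs = rec$fs,
    unit = "uV",
    channels = as.list(rec$montage$channels),
    roles = as.list(unname(rec$montage$roles)),
    events = if (nrow(rec$events)) {
      lapply(seq_len(nrow(rec$events)), function(i)
        list(sample = as.integer(rec$events$sample[i]),
             label = as.character(rec$events$label[i])))
    } else list()
  )
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

unit_to_uv <- function(unit) {
  switch(tolower(unit),
         "uv" = 1, "µv" = 1, "microvolt" = 1, "microvolts" = 1,
         "mv" = 1e3, "v" = 1e6,
         stop(sprintf("unknown amplitude unit '%s'", unit)))
}

#' Read a recording (native delimited format or EDF)
#'
#' Channels are reordered to the montage's channel order and amplitudes
#' converted to microvolts. Files ending in `.edf` (or starting with the EDF
#' magic byte) are read with the built-in EDF importer; anything else is
#' treated as the native delimited matrix + sidecar format written by
#' [write_recording()].
#'
#' @param path file path.
#' @param montage target [montage()]; every montage channel must be present
#'   in the file.
#' @return a [recording()].
#' @export
read_recording <- function(path, montage) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    return(read_edf(path, montage))
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("sidecar metadata not found: %s", sc))
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$fs)) stop("sidecar does not state the sampling rate (fs)")
  chans <- unlist(meta$channels)
  dat <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  if (nrow(dat) != length(chans))
    stop(sprintf("data has %d rows but sidecar names %d channels",
                 nrow(dat), length(chans)))
  dimnames(dat) <- list(chans, NULL)
  scale <- unit_to_uv(if (is.null(meta$unit)) "uV" else meta$unit)
  missing <- setdiff(montage$channels, chans)
  if (length(missing))
    stop(sprintf("channel %s not found", missing[1]))
  dat <- dat[montage$channels, , drop = FALSE] * scale
  events <- if (length(meta$events)) {
    data.frame(sample = vapply(meta$events, function(e) as.integer(e$sample),
                               integer(1)),
               label = vapply(meta$events, function(e) as.character(e$label),
                              character(1)))
  } else data.frame(sample = integer(), label = character())
  recording(dat, meta$fs, montage, events)
}

# ---- minimal EDF import/export (16-bit, continuous) -----------------------

read_edf_header <- function(con) {
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  h <- list(version = rd(8), patient = rd(80), recinfo = rd(80),
            startdate = rd(8), starttime = rd(8),
            header_bytes = as.integer(rd(8)))
  rd(44)                                   # reserved
  h$n_records <- as.integer(rd(8))
  h$record_dur <- as.numeric(rd(8))
  h$ns <- as.integer(rd(4))
  ns <- h$ns
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)),
                            character(1))
  h$label <- fld(16); fld(80)              # transducer, unused
  h$physdim <- fld(8)
  h$physmin <- as.numeric(fld(8)); h$physmax <- as.numeric(fld(8))
  h$digmin <- as.numeric(fld(8));  h$digmax <- as.numeric(fld(8))
  fld(80)                                  # prefiltering, unused
  h$nsamp <- as.integer(fld(8)); fld(32)   # reserved
  h
}

#' Import an EDF recording
#'
#' Reads a standard (16-bit integer) EDF file, converts each signal to its
#' physical unit, rescales to microvolts, and reorders channels to the given
#' montage. Annotation channels are skipped. EDF carries no stimulus events;
#' attach them afterwards or use the native format.
#'
#' @inheritParams read_recording
#' @return a [recording()] with an empty event list.
#' @export
read_edf <- function(path, montage) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  keep <- which(h$label != "EDF Annotations")
  if (!length(keep)) stop("EDF file contains no data signals")
  fs <- h$nsamp[keep] / h$record_dur
  if (length(unique(fs)) != 1L)
    stop("EDF signals have differing sampling rates; not supported")
  sig <- lapply(seq_len(h$ns), function(i) numeric(0))
  for (r in seq_len(h$n_records)) {
    for (i in seq_len(h$ns)) {
      d <- readBin(con, "integer", n = h$nsamp[i], size = 2,
                   signed = TRUE, endian = "little")
      if (i %in% keep) sig[[i]] <- c(sig[[i]], d)
    }
  }
  dat <- do.call(rbind, lapply(keep, function(i) {
    phys <- (sig[[i]] - h$digmin[i]) *
      (h$physmax[i] - h$physmin[i]) / (h$digmax[i] - h$digmin[i]) +
      h$physmin[i]
    dim <- h$physdim[i]
    phys * unit_to_uv(if (nzchar(dim)) dim else "uV")
  }))
  rownames(dat) <- h$label[keep]
  missing <- setdiff(montage$channels, h$label[keep])
  if (length(missing))
    stop(sprintf("channel %s not found", missing[1]))
  recording(dat[montage$channels, , drop = FALSE], fs[1], montage)
}

#' Export a recording as EDF
#'
#' Writes a standard 16-bit EDF file with 1-second data records (the
#' recording is zero-padded to a whole number of records). Intended for
#' interchange and round-trip testing; the native format of
#' [write_recording()] preserves events and exact amplitudes.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (any(!is.finite(rec$data)))
    stop("recording contains NaN/Inf values; refusing to serialize")
  ns <- nrow(rec$data)
  nsamp_rec <- as.integer(round(rec$fs))     # 1-s records
  n_rec <- as.integer(ceiling(ncol(rec$data) / nsamp_rec))
  pad <- n_rec * nsamp_rec - ncol(rec$data)
  dat <- cbind(rec$data, matrix(0, ns, pad))
  physmax <- max(1, ceiling(max(abs(dat))))
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, w) {
    s <- sprintf(paste0("%-", w, "s"), substr(x, 1, w))
    writeBin(charToRaw(s), con)
  }
  wf("0", 8); wf("X X X X", 80); wf("Startdate X X X X", 80)
  wf("01.01.00", 8); wf("00.00.00", 8)
  wf(as.character(256 + ns * 256), 8); wf("", 44)
  wf(as.character(n_rec), 8); wf("1", 8); wf(as.character(ns), 4)
  for (ch in rownames(dat)) wf(ch, 16)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf("uV", 8)
  for (i in seq_len(ns)) wf(as.character(-physmax), 8)
  for (i in seq_len(ns)) wf(as.character(physmax), 8)
  for (i in seq_len(ns)) wf("-32768", 8)
  for (i in seq_len(ns)) wf("32767", 8)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf(as.character(nsamp_rec), 8)
  for (i in seq_len(ns)) wf("", 32)
  scale <- (32767 - (-32768)) / (2 * physmax)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * nsamp_rec + 1):(r * nsamp_rec)
    for (i in seq_len(ns)) {
      d <- as.integer(round((dat[i, idx] - (-physmax)) * scale + (-32768)))
      writeBin(pmin(32767L, pmax(-32768L, d)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
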