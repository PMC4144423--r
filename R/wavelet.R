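#' Remove a least-squares linear trend
#'
#' @param x numeric vector (>= 2 samples).
#' @return the residual after subtracting the fitted line; it has zero mean
#'   and zero linear trend.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2) stop("detrending needs at least 2 samples")
  t <- seq_len(n) - (n + 1) / 2          # centered time, orthogonal to 1
  slope <- sum(t * x) / sum(t * t)
  x - mean(x) - slope * t
}

#' Build a complex Morlet wavelet kernel
#'
#' The kernel is
#' \deqn{w(t, f_0) = \exp(-t^2 / 2\sigma_t^2)\,\exp(2\pi i f_0 t) /
#'   (\sigma_t \sqrt{\pi}),}
#' with \eqn{\sigma_t = c / (2\pi f_0)} for `cycles` \eqn{c = f_0/\sigma_f},
#' sampled at `fs` on \eqn{t \in [-4\sigma_t, 4\sigma_t]} (odd length,
#' centered at t = 0). By construction \eqn{\sigma_t \sigma_f = 1/(2\pi)}.
#'
#' @param f0 center frequency in Hz (must be below fs/2).
#' @param cycles number of effective oscillation cycles \eqn{f_0/\sigma_f}.
#' @param fs sampling rate in Hz.
#' @return a list of class `"morlet_wavelet"`: `kernel` (complex), `f0`,
#'   `cycles`, `sigma_t` (s), `sigma_f` (Hz), `fs`.
#' @export
build_wavelet <- function(f0, cycles = 6, fs = 500) {
  if (f0 <= 0 || cycles <= 0) stop("f0 and cycles must be positive")
  if (f0 >= fs / 2)
    stop(sprintf("f0 = %g Hz must be below the Nyquist rate %g Hz", f0, fs / 2))
  sigma_t <- cycles / (2 * pi * f0)
  half <- as.integer(round(4 * sigma_t * fs))
  t <- (-half:half) / fs
  kernel <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f0 * t) /
    (sigma_t * sqrt(pi))
  structure(list(kernel = kernel, f0 = f0, cycles = cycles,
                 sigma_t = sigma_t, sigma_f = f0 / cycles, fs = fs),
            class = "morlet_wavelet")
}

#' Build a bank of Morlet wavelets
#'
#' Defaults to the 4--12 Hz grid in 0.1-Hz steps (81 center frequencies)
#' with 6 cycles.
#'
#' @param fmin,fmax,fstep frequency grid in Hz.
#' @param cycles cycles per wavelet.
#' @param fs sampling rate in Hz.
#' @return list of class `"wavelet_bank"` with elements `wavelets`, `freqs`.
#' @export
wavelet_bank <- function(fmin = 4, fmax = 12, fstep = 0.1, cycles = 6,
                         fs = 500) {
  freqs <- seq(fmin, fmax, by = fstep)
  structure(list(wavelets = lapply(freqs, build_wavelet, cycles = cycles,
                                   fs = fs),
                 freqs = freqs, cycles = cycles, fs = fs),
            class = "wavelet_bank")
}

# index folding for reflect padding (no edge repetition); handles pad widths
# exceeding the signal length by repeated reflection
reflect_index <- function(i, n) {
  if (n < 2) stop("reflect padding needs at least 2 samples")
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j < 0, j + p, j)
  ifelse(j >= n, p - j, j) + 1L
}

conv_same_reflect <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1L) %/% 2L
  xp <- x[reflect_index((1L - half):(n + half), n)]
  m <- length(xp) + length(kernel) - 1L
  nfft <- stats::nextn(m, 2)
  X <- stats::fft(c(xp, rep(0, nfft - length(xp))))
  K <- stats::fft(c(kernel, rep(0i, nfft - length(kernel))))
  full <- stats::fft(X * K, inverse = TRUE) / nfft
  # center of the full convolution, then strip the padding
  full[(2L * half + 1L):(2L * half + n)]
}

#' Time-frequency power via Morlet convolution
#'
#' Convolves the signal with every wavelet of the bank (same-length output,
#' reflect-padded edges; the discrete convolution is scaled by 1/fs to
#' approximate the continuous transform) and returns the squared norm
#' \eqn{|\tilde u(t, f_0)|^2}.
#'
#' @param x numeric signal (uV); detrend first (see [detrend_linear()]).
#' @param bank a [wavelet_bank()].
#' @param times_ms optional time axis for the samples of `x`.
#' @return list of class `"tfr_power"`: `power` (freqs x samples, uV^2),
#'   `freqs` (Hz), `times_ms`.
#' @export
wavelet_power <- function(x, bank, times_ms = NULL) {
  stopifnot(inherits(bank, "wavelet_bank"))
  if (length(x) < 2) stop("signal too short for wavelet analysis")
  if (is.null(times_ms)) times_ms <- samp_to_ms(seq_along(x) - 1L, bank$fs)
  if (length(times_ms) != length(x))
    stop("times_ms must match the signal length")
  pw <- t(vapply(bank$wavelets, function(w) {
    u <- conv_same_reflect(x, w$kernel) / bank$fs
    Mod(u)^2
  }, numeric(length(x))))
  structure(list(power = pw, freqs = bank$freqs, times_ms = times_ms),
            class = "tfr_power")
}

#' Late time-course features for the classifier
#'
#' One feature per channel of the right posterior temporal group: that
#' channel's mean amplitude over the 600--700 ms window of the averaged ERP.
#'
#' @param erp an `"erp"`.
#' @param montage montage defining the group (defaults to the ERP's).
#' @param group channel group name.
#' @param window feature window `c(t0, t1)` in ms, half-open.
#' @return named numeric vector (one entry per group channel) with attribute
#'   `provenance = "timecourse"`.
#' @export
timecourse_features <- function(erp, montage = erp$montage,
                                group = "right_pt", window = c(600, 700)) {
  stopifnot(inherits(erp, "erp"))
  ch <- group_channels(montage, group)
  missing <- setdiff(ch, erp$channels)
  if (length(missing))
    stop(sprintf("channel %s not found", missing[1]))
  idx <- which(erp$times_ms >= window[1] & erp$times_ms < window[2])
  if (!length(idx)) stop("epoch does not cover the feature window")
  v <- vapply(ch, function(c) mean(erp$waveform[c, idx]), numeric(1))
  attr(v, "provenance") <- "timecourse"
  v
}

#' Tile a time-frequency power map into a feature vector
#'
#' Mean power per (frequency x time) tile. Defaults tile 4--12 Hz in 2-Hz
#' bins and 0--700 ms in 100-ms bins, giving 4 x 7 = 28 features in
#' row-major, frequency-outer order. Frequency bins are half-open with the
#' last bin closed; time bins are half-open.
#'
#' @param tfr a `"tfr_power"` object.
#' @param freq_breaks frequency bin edges (Hz).
#' @param time_breaks time bin edges (ms).
#' @return named numeric feature vector with attributes
#'   `provenance = "tfr"` and `layout` (data.frame of tile bounds).
#' @export
tfr_feature_vector <- function(tfr, freq_breaks = seq(4, 12, by = 2),
                               time_breaks = seq(0, 700, by = 100)) {
  stopifnot(inherits(tfr, "tfr_power"))
  if (length(freq_breaks) < 2 || length(time_breaks) < 2)
    stop("at least one frequency and one time tile required")
  if (min(freq_breaks) < min(tfr$freqs) - 1e-9 ||
      max(freq_breaks) > max(tfr$freqs) + 1e-9)
    stop("frequency tiling lies outside the power map")
  if (min(time_breaks) < tfr$times_ms[1] - 1e-9 ||
      max(time_breaks) > tfr$times_ms[length(tfr$times_ms)] +
        (tfr$times_ms[2] - tfr$times_ms[1]) + 1e-9)
    stop("time tiling lies outside the power map")
  nf <- length(freq_breaks) - 1L
  nt <- length(time_breaks) - 1L
  vals <- numeric(nf * nt)
  nm <- character(nf * nt)
  layout <- vector("list", nf * nt)
  k <- 0L
  for (i in seq_len(nf)) {
    fin <- tfr$freqs >= freq_breaks[i] &
      (if (i == nf) tfr$freqs <= freq_breaks[i + 1] + 1e-9
       else tfr$freqs < freq_breaks[i + 1])
    for (j in seq_len(nt)) {
      tin <- tfr$times_ms >= time_breaks[j] & tfr$times_ms < time_breaks[j + 1]
      if (!any(fin) || !any(tin))
        stop("empty tile: tiling does not match the power map resolution")
      k <- k + 1L
      vals[k] <- mean(tfr$power[fin, tin])
      nm[k] <- sprintf("f%g-%g.t%g-%g", freq_breaks[i], freq_breaks[i + 1],
                       time_breaks[j], time_breaks[j + 1])
      layout[[k]] <- data.frame(f0 = freq_breaks[i], f1 = freq_breaks[i + 1],
                                t0 = time_breaks[j], t1 = time_breaks[j + 1])
    }
  }
  names(vals) <- nm
  attr(vals, "provenance") <- "tfr"
  attr(vals, "layout") <- do.call(rbind, layout)
  vals
}
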