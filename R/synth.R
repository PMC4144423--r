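CONDITIONS <- c("CS+", "CS-", "scenery")

#' Specify a synthetic multi-subject EEG study
#'
#' Defines the generative model for synthetic recordings: 12 subjects x 3
#' conditions (aversively conditioned face CS+, unconditioned face CS-,
#' scenery) x 24 trials per condition at 500 Hz. Each trial is a
#' condition-specific template (Gaussian-windowed P1 bump at 90 ms, N170
#' trough at 140 ms that is deeper for faces than scenery, and a CS+-specific
#' late negativity centered at 650 ms on the right posterior temporal
#' channels) plus 1/f background noise, 10-Hz alpha, and occasional
#' ocular/movement artifacts. Per-subject lognormal amplitude multipliers
#' model between-subject variability.
#'
#' SNR presets fix the class effect size and trial noise:
#' `"high"` (CS+ late delta = -3 uV, trial sd = 5 uV), `"moderate"`
#' (delta = -1.5 uV, sd = 10 uV) and `"null"` (all class effects zeroed:
#' delta = 0 and the scenery N170 set equal to the face N170).
#'
#' @param n_subjects number of subjects.
#' @param trials_per_condition trials per condition and subject.
#' @param fs sampling rate in Hz.
#' @param montage electrode [montage()]; must contain the ROI channels.
#' @param snr_preset `"moderate"`, `"high"` or `"null"`.
#' @param seed mandatory RNG seed; the whole study is deterministic given it.
#' @param p1 list: `latency` (ms), `sigma` (ms), `amplitude` (uV).
#' @param n170 list: `latency`, `sigma` (ms), `depth_face`,
#'   `depth_scenery` (uV, positive depths).
#' @param late list: `center`, `sigma` (ms), `delta` (uV, negative; `NULL`
#'   takes the preset value).
#' @param noise list: `sd` (uV per trial; `NULL` takes the preset),
#'   `alpha_prop` (proportion of noise variance at 10 Hz), `exponent`
#'   (1/f exponent), `ocular_sd` (uV, ocular-channel noise).
#' @param artifacts list: `p_ocular`, `p_movement` (per-trial probabilities).
#' @param subject_sd_log sd of the log-normal subject amplitude multipliers.
#' @param iti_s spacing between stimulus onsets in seconds.
#' @param pad_s padding before the first and after the last trial, seconds.
#' @return an object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_subjects = 12, trials_per_condition = 24, fs = 500,
                       montage = default_montage(),
                       snr_preset = c("moderate", "high", "null"),
                       seed,
                       p1 = list(latency = 90, sigma = 15, amplitude = 5),
                       n170 = list(latency = 140, sigma = 12,
                                   depth_face = 6, depth_scenery = 2),
                       late = list(center = 650, sigma = 40, delta = NULL),
                       noise = list(sd = NULL, alpha_prop = 0.2,
                                    exponent = 1, ocular_sd = 5),
                       artifacts = list(p_ocular = 0.08, p_movement = 0.04),
                       subject_sd_log = 0.2, iti_s = 1.5, pad_s = 2) {
  snr_preset <- match.arg(snr_preset)
  if (missing(seed)) stop("a seed is mandatory for the synthetic generator")
  preset <- switch(snr_preset,
                   high = list(delta = -3, sd = 5),
                   moderate = list(delta = -1.5, sd = 10),
                   null = list(delta = 0, sd = 10))
  if (is.null(late$delta)) late$delta <- preset$delta
  if (is.null(noise$sd)) noise$sd <- preset$sd
  if (snr_preset == "null") {
    late$delta <- 0
    n170$depth_scenery <- n170$depth_face
  }
  stopifnot(n_subjects >= 1, trials_per_condition >= 1, fs > 0)
  if (!all(is.finite(c(p1$amplitude, n170$depth_face, n170$depth_scenery,
                       late$delta, noise$sd))))
    stop("component amplitudes must be finite")
  if (artifacts$p_ocular < 0 || artifacts$p_ocular > 1 ||
      artifacts$p_movement < 0 || artifacts$p_movement > 1)
    stop("artifact probabilities must lie in [0, 1]")
  req <- c("O1", "O2", "P7", "P9", "TP9", "P8", "P10", "TP10")
  missing <- setdiff(req, montage$channels)
  if (length(missing))
    stop(sprintf("montage lacks required ROI channel(s): %s",
                 paste(missing, collapse = ", ")))
  structure(list(n_subjects = n_subjects,
                 trials_per_condition = trials_per_condition, fs = fs,
                 montage = montage, snr_preset = snr_preset,
                 seed = as.integer(seed), p1 = p1, n170 = n170, late = late,
                 noise = noise, artifacts = artifacts,
                 subject_sd_log = subject_sd_log, iti_s = iti_s,
                 pad_s = pad_s,
                 epoch = c(-100, 700)),
            class = "synth_spec")
}

# fixed scalp topographies. P1 and N170 weights sum to zero over the default
# scalp channels, so the average reference leaves them unchanged; the late
# CS+ effect lives on the right posterior temporal channels only.
topo_weights <- function(montage) {
  w0 <- function() stats::setNames(rep(0, length(montage$channels)),
                                   montage$channels)
  set <- function(w, vals) { w[intersect(names(vals), names(w))] <-
    vals[intersect(names(vals), names(w))]; w }
  p1 <- set(w0(), c(O1 = 1, O2 = 1, P7 = 0.6, P9 = 0.6, TP9 = 0.6,
                    P8 = 0.6, P10 = 0.6, TP10 = 0.6,
                    Fz = -2, Cz = -2, Pz = -1.6))
  n170 <- set(w0(), c(P7 = 1, P9 = 1, TP9 = 1, P8 = 1, P10 = 1, TP10 = 1,
                      O1 = 0.3, O2 = 0.3, Cz = -3.3, Pz = -3.3))
  late <- set(w0(), c(P8 = 1, P10 = 1, TP10 = 1))
  list(p1 = p1, n170 = n170, late = late)
}

gauss_bump <- function(t_ms, center, sigma)
  exp(-(t_ms - center)^2 / (2 * sigma^2))

# per-subject lognormal amplitude multipliers, deterministic given the seed;
# columns: p1, n170, late
subject_effects <- function(spec) {
  with_seed(spec$seed, {
    m <- matrix(exp(stats::rnorm(spec$n_subjects * 3, 0,
                                 spec$subject_sd_log)),
                spec$n_subjects, 3)
    colnames(m) <- c("p1", "n170", "late")
    m
  })
}

#' Noise-free condition template
#'
#' Deterministic given (seed, subject, condition). Faces (CS+, CS-) carry a
#' deeper N170 trough than scenery; CS+ additionally carries the late
#' negativity on the right posterior temporal channels. `subject = NULL`
#' returns the population template (all subject multipliers 1).
#'
#' @param spec a [synth_spec()].
#' @param condition `"CS+"`, `"CS-"` or `"scenery"`.
#' @param subject subject index in `1:n_subjects`, or `NULL`.
#' @return channels x samples matrix over the epoch window (-100..700 ms).
#' @export
make_template <- function(spec, condition, subject = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!condition %in% CONDITIONS)
    stop(sprintf("unknown condition '%s'", condition))
  m <- if (is.null(subject)) c(p1 = 1, n170 = 1, late = 1) else
    subject_effects(spec)[subject, ]
  off <- ms_to_samp(spec$epoch[1], spec$fs):
    (ms_to_samp(spec$epoch[2], spec$fs) - 1L)
  t_ms <- samp_to_ms(off, spec$fs)
  w <- topo_weights(spec$montage)
  depth <- if (condition == "scenery") spec$n170$depth_scenery else
    spec$n170$depth_face
  wf <- m[["p1"]] * spec$p1$amplitude *
    outer(w$p1, gauss_bump(t_ms, spec$p1$latency, spec$p1$sigma)) -
    m[["n170"]] * depth *
    outer(w$n170, gauss_bump(t_ms, spec$n170$latency, spec$n170$sigma))
  if (condition == "CS+")
    wf <- wf + m[["late"]] * spec$late$delta *
      outer(w$late, gauss_bump(t_ms, spec$late$center, spec$late$sigma))
  rownames(wf) <- spec$montage$channels
  wf
}

pink_noise <- function(n, exponent = 1) {
  m <- stats::nextn(n, c(2, 3, 5))     # fast FFT length; truncate afterwards
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  k <- 0:(m - 1)
  f <- pmin(k, m - k)
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

#' Simulate one subject's continuous recording
#'
#' Concatenates the subject's trials (condition template + 1/f noise +
#' 10-Hz alpha + occasional artifacts) into a continuous multichannel
#' recording with event markers, together with the ground truth (per-trial
#' condition and planted artifact flags).
#'
#' @param spec a [synth_spec()].
#' @param subject subject index.
#' @return list with elements `recording` (a [recording()]) and
#'   `ground_truth` (data.frame: trial, condition, onset_sample, ocular,
#'   movement).
#' @export
simulate_recording <- function(spec, subject) {
  stopifnot(inherits(spec, "synth_spec"))
  mont <- spec$montage
  fs <- spec$fs
  n_tr <- 3L * spec$trials_per_condition
  with_seed(derive_seed(spec$seed, subject), {
    conds <- sample(rep(CONDITIONS, each = spec$trials_per_condition))
    iti <- as.integer(round(spec$iti_s * fs))
    pad <- as.integer(round(spec$pad_s * fs))
    jitter <- sample(0:ms_to_samp(200, fs), n_tr, replace = TRUE)
    onsets <- pad + (seq_len(n_tr) - 1L) * iti + jitter
    total <- onsets[n_tr] + as.integer(fs)          # 1 s tail
    sc <- scalp_channels(mont)
    dat <- matrix(0, length(mont$channels), total,
                  dimnames = list(mont$channels, NULL))
    ap <- spec$noise$alpha_prop
    tt <- (0:(total - 1)) / fs
    for (ch in mont$channels) {
      if (ch %in% sc) {
        alpha <- sqrt(2) * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
        dat[ch, ] <- spec$noise$sd *
          (sqrt(1 - ap) * pink_noise(total, spec$noise$exponent) +
             sqrt(ap) * alpha)
      } else {
        dat[ch, ] <- spec$noise$ocular_sd *
          pink_noise(total, spec$noise$exponent)
      }
    }
    off <- ms_to_samp(spec$epoch[1], fs):(ms_to_samp(spec$epoch[2], fs) - 1L)
    templates <- stats::setNames(
      lapply(CONDITIONS, make_template, spec = spec, subject = subject),
      CONDITIONS)
    for (i in seq_len(n_tr))
      dat[, onsets[i] + off] <- dat[, onsets[i] + off] +
        templates[[conds[i]]]
    oc_flag <- stats::runif(n_tr) < spec$artifacts$p_ocular
    mv_flag <- stats::runif(n_tr) < spec$artifacts$p_movement
    oc_ch <- ocular_channels(mont)
    for (i in which(oc_flag)) {                     # blink on ocular channels
      ctr <- onsets[i] + as.integer(round(stats::runif(1, 0, 0.6) * fs))
      span <- max(1, ctr - as.integer(0.2 * fs)):min(total,
                                                     ctr + as.integer(0.2 * fs))
      bump <- exp(-((span - ctr) / fs)^2 / (2 * 0.025^2))
      for (ch in oc_ch)
        dat[ch, span] <- dat[ch, span] + 150 * stats::runif(1, 0.8, 1.2) * bump
    }
    for (i in which(mv_flag)) {                     # broadband movement burst
      ctr <- onsets[i] + as.integer(round(stats::runif(1, 0, 0.6) * fs))
      span <- max(1, ctr - as.integer(0.3 * fs)):min(total,
                                                     ctr + as.integer(0.3 * fs))
      burst <- exp(-((span - ctr) / fs)^2 / (2 * 0.05^2)) *
        sin(2 * pi * 8 * (span - ctr) / fs)
      amp <- 400 * stats::runif(1, 0.8, 1.2)
      # heterogeneous spatial profile (random sign and gain per channel), as
      # real movement artifacts have; a uniform profile would be cancelled
      # by the average reference before rejection sees it
      for (ch in sc)
        dat[ch, span] <- dat[ch, span] +
          amp * sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5) * burst
    }
    rec <- recording(dat, fs, mont,
                     events = data.frame(sample = onsets, label = conds))
    list(recording = rec,
         ground_truth = data.frame(trial = seq_len(n_tr), condition = conds,
                                   onset_sample = onsets, ocular = oc_flag,
                                   movement = mv_flag))
  })
}

#' Planted late-window CS+/CS- difference after the deterministic chain
#'
#' The generator's ground truth for the late effect, expressed in the space
#' where it is measured: the population CS+ minus CS- template difference is
#' passed through the deterministic pipeline stages (average reference,
#' zero-phase band-pass) and summarized as the right posterior temporal
#' 600--700 ms window mean.
#'
#' @param spec a [synth_spec()].
#' @param config pipeline configuration.
#' @return expected window-mean difference in uV (negative for CS+).
#' @export
planted_late_difference <- function(spec, config = default_config()) {
  d <- make_template(spec, "CS+") - make_template(spec, "CS-")
  sc <- scalp_channels(spec$montage)
  d[sc, ] <- sweep(d[sc, , drop = FALSE], 2, colMeans(d[sc, , drop = FALSE]))
  pad <- matrix(0, nrow(d), as.integer(spec$fs))    # 1-s zero pad per side
  dp <- cbind(pad, d, pad)
  bf <- signal::butter(config$filter$order,
                       c(config$filter$low, config$filter$high) /
                         (spec$fs / 2), type = "pass")
  dp <- t(apply(dp, 1, function(x) signal::filtfilt(bf, x)))
  d <- dp[, (ncol(pad) + 1):(ncol(pad) + ncol(d)), drop = FALSE]
  rownames(d) <- spec$montage$channels
  off <- ms_to_samp(spec$epoch[1], spec$fs):
    (ms_to_samp(spec$epoch[2], spec$fs) - 1L)
  erp <- structure(list(subject = "truth", condition = "diff", waveform = d,
                        n_trials_averaged = 1,
                        times_ms = samp_to_ms(off, spec$fs), fs = spec$fs,
                        channels = spec$montage$channels,
                        montage = spec$montage),
                   class = "erp")
  window_mean(erp, "right_pt", 600, 700)
}

#' Build the labeled feature dataset for the classifier
#'
#' Runs the full chain per subject — simulate, preprocess (average
#' reference, band-pass, epoch, baseline, reject), average per condition —
#' and extracts one feature vector per (subject, condition): either the
#' three right posterior temporal 600--700 ms means (`"timecourse"`) or the
#' tiled Morlet power map (`"tfr"`, 28 features). With defaults this yields
#' the 36-sample design (12 subjects x 3 conditions).
#'
#' @param spec a [synth_spec()].
#' @param feature_mode `"timecourse"` or `"tfr"`.
#' @param config pipeline configuration.
#' @param per_trial if `TRUE`, wavelet power is computed per kept trial and
#'   averaged afterwards instead of transforming the averaged ERP.
#' @return an object of class `"labeled_dataset"`: `X` (samples x features),
#'   `y` (factor with levels CS+, CS-, scenery), `meta` (subject, condition),
#'   `feature_mode`.
#' @export
make_feature_dataset <- function(spec,
                                 feature_mode = c("timecourse", "tfr"),
                                 config = default_config(),
                                 per_trial = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  feature_mode <- match.arg(feature_mode)
  bank <- if (feature_mode == "tfr")
    wavelet_bank(config$wavelet$fmin, config$wavelet$fmax,
                 config$wavelet$fstep, config$wavelet$cycles, spec$fs)
  else NULL
  rows <- list(); labs <- character(); meta <- list()
  for (s in seq_len(spec$n_subjects)) {
    sim <- simulate_recording(spec, s)
    es <- preprocess_recording(sim$recording, config)
    erps <- average_erp(es, subject = s, conditions = CONDITIONS)
    for (cond in CONDITIONS) {
      v <- if (feature_mode == "timecourse") {
        timecourse_features(erps[[cond]], window = config$features$window)
      } else if (!per_trial) {
        sig <- detrend_linear(erp_group_signal(erps[[cond]], "right_pt"))
        tfr <- wavelet_power(sig, bank, times_ms = erps[[cond]]$times_ms)
        tfr_feature_vector(tfr)
      } else {
        sel <- which(es$labels == cond & es$kept)
        ch <- group_channels(spec$montage, "right_pt")
        pw <- 0
        for (i in sel) {
          sig <- detrend_linear(colMeans(es$epochs[i, ch, , drop = TRUE]))
          pw <- pw + wavelet_power(sig, bank, times_ms = es$times_ms)$power
        }
        tfr <- structure(list(power = pw / length(sel), freqs = bank$freqs,
                              times_ms = es$times_ms), class = "tfr_power")
        tfr_feature_vector(tfr)
      }
      rows[[length(rows) + 1L]] <- v
      labs <- c(labs, cond)
      meta[[length(meta) + 1L]] <- data.frame(subject = s, condition = cond)
    }
  }
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  structure(list(X = X, y = factor(labs, levels = CONDITIONS),
                 meta = do.call(rbind, meta), feature_mode = feature_mode),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d %s features (%s)\n",
              nrow(x$X), ncol(x$X), x$feature_mode,
              paste(sprintf("%s: %d", levels(x$y), table(x$y)),
                    collapse = ", ")))
  invisible(x)
}
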