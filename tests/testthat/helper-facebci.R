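# shared fixtures and an independent nu-SVC oracle for the classifier tests

tiny_montage <- function() {
  montage(c("A", "B", "EOG"), roles = c("scalp", "scalp", "ocular"),
          groups = list(both = c("A", "B")))
}

# recording with one event per requested trial and deterministic content
tiny_recording <- function(n_events = 3, fs = 500, n_extra = 0,
                           mont = tiny_montage()) {
  spacing <- 500
  total <- (n_events + 1) * spacing + n_extra
  dat <- matrix(0, length(mont$channels), total,
                dimnames = list(mont$channels, NULL))
  onsets <- spacing * seq_len(n_events)
  recording(dat, fs, mont,
            events = data.frame(sample = onsets,
                                label = rep(c("CS+", "CS-", "scenery"),
                                            length.out = n_events)))
}

# build an epoch_set directly from an array (bypasses the recording stage)
make_epoch_set <- function(epochs, labels, fs = 500, tmin = -100,
                           tmax = 700, mont = tiny_montage()) {
  off <- round(tmin * fs / 1000):(round(tmax * fs / 1000) - 1)
  dimnames(epochs)[[2]] <- mont$channels
  structure(list(epochs = epochs, labels = labels,
                 kept = rep(TRUE, dim(epochs)[1]),
                 times_ms = off * 1000 / fs, tmin = tmin, tmax = tmax,
                 fs = fs, channels = mont$channels, montage = mont,
                 rejection_log = NULL),
            class = "epoch_set")
}

# wrap a channels x samples waveform as an erp object
as_erp <- function(waveform, fs = 500, tmin = -100, mont = tiny_montage(),
                   condition = "CS+", subject = "s1") {
  off <- round(tmin * fs / 1000) + 0:(ncol(waveform) - 1)
  rownames(waveform) <- mont$channels
  structure(list(subject = subject, condition = condition,
                 waveform = waveform, n_trials_averaged = 1,
                 times_ms = off * 1000 / fs, fs = fs,
                 channels = mont$channels, montage = mont),
            class = "erp")
}

# ---- independent nu-SVC dual solver (projected gradient ascent) ----------
# max -1/2 a' Q a  s.t.  0 <= a_i <= 1/l, sum(a y) = 0, sum(a) = nu.
# Since sum(a y) = 0 and sum(a) = nu, each class's coefficients lie on a
# capped simplex with sum nu/2; projection is by bisection on the threshold.

proj_capped_simplex <- function(v, cap, s) {
  lo <- min(v) - cap
  hi <- max(v)
  for (it in 1:60) {
    tau <- (lo + hi) / 2
    tot <- sum(pmin(pmax(v - tau, 0), cap))
    if (tot > s) lo <- tau else hi <- tau
  }
  pmin(pmax(v - (lo + hi) / 2, 0), cap)
}

oracle_nu_svm <- function(X, y, nu = 0.5, gamma = 1, iters = 4000) {
  y <- ifelse(y == levels(factor(y))[1], 1, -1)
  l <- length(y)
  K <- exp(-gamma * as.matrix(dist(X))^2)
  Q <- (y %o% y) * K
  cap <- 1 / l
  a <- rep(nu / l, l)
  eta <- 1 / max(colSums(abs(Q)))
  pos <- y > 0
  for (it in seq_len(iters)) {
    a <- a - eta * drop(Q %*% a)
    a[pos] <- proj_capped_simplex(a[pos], cap, nu / 2)
    a[!pos] <- proj_capped_simplex(a[!pos], cap, nu / 2)
  }
  g <- drop(K %*% (a * y))
  free <- a > 1e-8 & a < cap - 1e-8
  bp <- if (any(free & pos)) mean(g[free & pos]) else max(g[pos])
  bn <- if (any(free & !pos)) mean(g[free & !pos]) else min(g[!pos])
  b <- -(bp + bn) / 2
  list(alpha = a, y = y, b = b,
       decide = function(Z) {
         d2 <- outer(rowSums(Z^2), rowSums(X^2), "+") - 2 * tcrossprod(Z, X)
         Kz <- exp(-gamma * pmax(d2, 0))
         sign(drop(Kz %*% (a * y)) + b)
       })
}

# two seeded 2-D Gaussian clouds
toy_clouds <- function(n_per_class, sep, sd = 1, seed = 1) {
  with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n_per_class, 0, sd), ncol = 2),
               matrix(rnorm(2 * n_per_class, sep, sd), ncol = 2))
    list(X = X, y = factor(rep(c("a", "b"), each = n_per_class)))
  })
}

# cached 12-subject grand-average face ERP (shared by synth and acceptance
# tests); built once per test run
.facebci_cache <- new.env(parent = emptyenv())

grand_face_erps <- function(seed = 1) {
  key <- paste0("grand_", seed)
  if (!is.null(.facebci_cache[[key]])) return(.facebci_cache[[key]])
  spec <- synth_spec(seed = seed)
  per_subj <- lapply(seq_len(spec$n_subjects), function(s) {
    es <- preprocess_recording(simulate_recording(spec, s)$recording)
    average_erp(es, subject = s)
  })
  out <- list(
    spec = spec,
    cs_plus = grand_average(lapply(per_subj, `[[`, "CS+")),
    cs_minus = grand_average(lapply(per_subj, `[[`, "CS-")),
    faces = grand_average(unlist(lapply(per_subj, function(e)
      list(e[["CS+"]], e[["CS-"]])), recursive = FALSE)))
  .facebci_cache[[key]] <- out
  out
}

cached_dataset <- function(preset, mode, seed = 1) {
  key <- paste(preset, mode, seed, sep = "_")
  if (is.null(.facebci_cache[[key]])) {
    spec <- synth_spec(snr_preset = preset, seed = seed)
    .facebci_cache[[key]] <- make_feature_dataset(spec, mode)
  }
  .facebci_cache[[key]]
}
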