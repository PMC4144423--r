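#' Default run configuration
#'
#' Returns the pipeline's default parameters: 1--30 Hz band-pass,
#' -100..700 ms epochs with a -100..0 ms baseline, ocular rejection at
#' +-50 uV within 50 ms and movement rejection at +-200 uV, a 4--12 Hz
#' Morlet bank with 6 cycles in 0.1-Hz steps, and a nu-SVM with nu = 0.5,
#' termination tolerance 1e-6 and kernel sweep gammas 1e-4, 1e-2, 1 and
#' 1/(number of features).
#'
#' @return a nested list of class `"run_config"`.
#' @export
default_config <- function() {
  structure(list(
    filter = list(low = 1, high = 30, order = 4),
    epoch = list(tmin = -100, tmax = 700),
    baseline = c(-100, 0),
    reject = list(ocular_uv = 50, ocular_ms = 50, movement_uv = 200),
    wavelet = list(fmin = 4, fmax = 12, fstep = 0.1, cycles = 6),
    features = list(mode = "tfr", freq_bin = 2, time_bin = 100,
                    window = c(600, 700)),
    svm = list(nu = 0.5, gamma = 0.01, tol = 1e-6,
               gammas = c(1e-4, 1e-2, 1)),
    seed = NULL
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Missing keys fall back to [default_config()]; an empty file yields the
#' full default configuration. Values are validated.
#'
#' @param path YAML file path.
#' @return a `"run_config"` list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user)) {
    if (!is.list(user)) stop("config file must contain a key/value mapping")
    cfg <- utils::modifyList(cfg, user)
    class(cfg) <- "run_config"
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (filter$low <= 0 || filter$high <= filter$low)
      stop("filter band must satisfy 0 < low < high")
    if (epoch$tmax <= epoch$tmin)
      stop("epoch window must satisfy tmax > tmin")
    if (baseline[2] <= baseline[1])
      stop("baseline window must satisfy t1 > t0")
    if (reject$ocular_uv <= 0 || reject$ocular_ms <= 0 ||
        reject$movement_uv <= 0)
      stop("rejection thresholds must be positive")
    if (wavelet$fmin <= 0 || wavelet$fmax <= wavelet$fmin ||
        wavelet$fstep <= 0 || wavelet$cycles <= 0)
      stop("invalid wavelet settings")
    if (svm$nu <= 0 || svm$nu > 1) stop("nu must be in (0, 1]")
    if (svm$gamma <= 0 || any(svm$gammas <= 0)) stop("gamma must be positive")
    if (svm$tol <= 0) stop("tolerance must be positive")
  })
  cfg
}
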