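# time <-> sample conversions; stimulus onset is 0 ms, sample offsets are
# round(t * fs / 1000), storage indices are 1-based (R convention)

ms_to_samp <- function(ms, fs) as.integer(round(ms * fs / 1000))

samp_to_ms <- function(samp, fs) samp * 1000 / fs

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single numeric seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a distinct 31-bit sub-seed from a master seed and a stream index
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009 + as.double(stream) * 7919 + 1) %%
               2147483647)
}

# max over sliding windows of (local max - local min); w in samples
running_range_max <- function(x, w) {
  n <- length(x)
  if (w >= n) return(max(x) - min(x))
  m <- stats::embed(x, w)                     # (n - w + 1) x w
  cols <- as.data.frame(m)
  max(do.call(pmax, cols) - do.call(pmin, cols))
}
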