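#' Read a grayscale image
#'
#' Reads a PNG image and returns an integer intensity matrix in [0, 255].
#' Color images are converted to grayscale by averaging the RGB channels.
#'
#' @param path PNG file path.
#' @return numeric matrix in [0, 255].
#' @export
read_gray_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3)
    img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  round(img * 255)
}

#' Write a grayscale image as PNG
#'
#' @param img numeric matrix in [0, 255].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Cross-dissolve morph between two grayscale images
#'
#' Frame k (k = 0..n-1) is `round((1 - a) * src + a * dst)` with
#' `a = k / (n - 1)`, so the first frame equals the source image exactly and
#' the last equals the target.
#'
#' @param src,dst grayscale matrices of equal dimensions, intensities in
#'   [0, 255].
#' @param n_frames number of frames (>= 2).
#' @param fps frames per second (metadata; sets the sequence duration).
#' @return an object of class `"morph_sequence"`: `frames` (list of
#'   matrices), `fps`, `duration` (s).
#' @export
cross_dissolve <- function(src, dst, n_frames, fps = 30) {
  if (!all(dim(src) == dim(dst)))
    stop("source and target images must have identical dimensions")
  if (n_frames < 2) stop("a morph needs at least 2 frames")
  if (min(src, dst) < 0 || max(src, dst) > 255)
    stop("intensities must lie in [0, 255]")
  alphas <- (seq_len(n_frames) - 1) / (n_frames - 1)
  frames <- lapply(alphas, function(a) round((1 - a) * src + a * dst))
  structure(list(frames = frames, fps = fps, duration = n_frames / fps),
            class = "morph_sequence")
}

#' @export
print.morph_sequence <- function(x, ...) {
  cat(sprintf("<morph_sequence> %d frames, %g fps, %.2f s\n",
              length(x$frames), x$fps, x$duration))
  invisible(x)
}

#' Trigger a face morph from a classifier prediction
#'
#' When the predicted label is one of the triggering labels (by default the
#' aversively conditioned face, CS+), the mapped neutral source face is
#' gradually cross-dissolved into its negative-emotion target over the
#' mapped duration (default 1.5 s); any other prediction produces no output.
#'
#' @param label predicted class label.
#' @param mapping named list; each entry (named by its triggering label) is a
#'   list with `src`, `dst` (grayscale matrices) and optional `duration`
#'   in seconds.
#' @param trigger_labels labels that must trigger a morph.
#' @param fps frames per second.
#' @return a `"morph_sequence"`, or `NULL` for non-triggering labels.
#' @export
trigger_on_prediction <- function(label, mapping,
                                  trigger_labels = "CS+", fps = 30) {
  if (!label %in% trigger_labels) {
    message(sprintf("prediction '%s': no morph triggered", label))
    return(invisible(NULL))
  }
  if (!label %in% names(mapping))
    stop(sprintf("no morph mapping defined for triggering label '%s'", label))
  m <- mapping[[label]]
  duration <- if (is.null(m$duration)) 1.5 else m$duration
  message(sprintf("prediction '%s': morph triggered (%.1f s)", label,
                  duration))
  cross_dissolve(m$src, m$dst, n_frames = round(duration * fps), fps = fps)
}

#' Write a morph sequence as numbered PNG frames
#'
#' @param seq a `"morph_sequence"`.
#' @param dir output directory (created if needed).
#' @param prefix frame filename prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_morph_sequence <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "morph_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(seq$frames), function(k) {
    p <- file.path(dir, sprintf("%s_%03d.png", prefix, k))
    write_gray_image(seq$frames[[k]], p)
    p
  }, character(1))
  invisible(paths)
}
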