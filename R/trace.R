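#' Luminance trace objects
#'
#' A `luminance_trace` holds a one-dimensional sampled luminance signal
#' together with its acquisition metadata.  It is the universal currency of
#' the package: the simulator produces it, the decomposition, response-time,
#' spectral and motion-blur estimators consume it.
#'
#' @param samples Numeric vector of luminance samples (cd/m^2 when the
#'   instrument is calibrated, otherwise arbitrary linear units).
#' @param sampling_rate Sampling rate in Hz.  The reference acquisition is
#'   10,000 samples over one second.
#' @param refresh_rate Display refresh rate in Hz (default 60).
#' @param primary Color primary of the recorded patch: `"red"`, `"green"`,
#'   `"blue"` or `"white"`.
#' @param annotation Free-text metadata (monitor id, calibration state, ...).
#'
#' @return An object of class `luminance_trace`.
#' @examples
#' tr <- luminance_trace(sin(seq(0, 2 * pi, length.out = 100)) + 2,
#'                       sampling_rate = 1000)
#' mean(normalize_trace(tr)$samples)
#' @export
luminance_trace <- function(samples, sampling_rate, refresh_rate = 60,
                            primary = "white", annotation = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a luminance trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("luminance samples must all be finite", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sampling_rate must be a single positive number", call. = FALSE)
  if (sampling_rate <= 2 * refresh_rate)
    stop("sampling_rate must exceed twice the refresh rate", call. = FALSE)
  primary <- match.arg(primary, c("red", "green", "blue", "white"))
  structure(
    list(samples = samples,
         sampling_rate = as.numeric(sampling_rate),
         refresh_rate = as.numeric(refresh_rate),
         primary = primary,
         annotation = as.character(annotation)[1L]),
    class = "luminance_trace")
}

#' @export
print.luminance_trace <- function(x, ...) {
  cat(sprintf(
    "<luminance_trace> %d samples @ %g Hz (%.3f s), refresh %g Hz, %s\n",
    length(x$samples), x$sampling_rate,
    length(x$samples) / x$sampling_rate, x$refresh_rate, x$primary))
  if (nzchar(x$annotation)) cat("  ", x$annotation, "\n", sep = "")
  invisible(x)
}

#' @export
length.luminance_trace <- function(x) length(x$samples)

#' Time axis of a trace
#'
#' @param trace A [luminance_trace()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
trace_time <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' Transition measurement protocol
#'
#' Describes the periodic blink protocol used for transition recordings:
#' the patch is shown for `frames_per_level` frames at `from_level`, then
#' `frames_per_level` frames at `to_level`, periodically.
#'
#' @param from_level,to_level Commanded gray levels, integers in 0..255
#'   (unit rgbU, the digital value sent to the video card).
#' @param frames_per_level Frames spent on each level (default 10).
#' @param repetitions Number of independent repetitions recorded.
#' @return An object of class `transition_protocol`.
#' @export
transition_protocol <- function(from_level, to_level, frames_per_level = 10,
                                repetitions = 1) {
  stopifnot(length(from_level) == 1L, length(to_level) == 1L)
  if (from_level < 0 || from_level > 255 || to_level < 0 || to_level > 255)
    stop("gray levels must lie in [0, 255]", call. = FALSE)
  if (from_level == to_level)
    stop("a transition protocol needs two distinct gray levels",
         call. = FALSE)
  if (frames_per_level < 1)
    stop("frames_per_level must be >= 1", call. = FALSE)
  structure(
    list(from_level = as.integer(from_level),
         to_level = as.integer(to_level),
         frames_per_level = as.integer(frames_per_level),
         repetitions = as.integer(repetitions)),
    class = "transition_protocol")
}

#' Gray-level grid for systematic transition measurements
#'
#' The default grid 0, 63, 127, 191, 255 rgbU is the equidistant five-level
#' grid recommended by the ISO display-metrology standard.
#'
#' @param levels Strictly increasing integer gray levels in 0..255.
#' @return An object of class `level_grid`.
#' @export
level_grid <- function(levels = c(0L, 63L, 127L, 191L, 255L)) {
  levels <- as.integer(levels)
  if (length(levels) < 2L) stop("need at least 2 levels", call. = FALSE)
  if (any(levels < 0L) || any(levels > 255L))
    stop("levels must lie in [0, 255]", call. = FALSE)
  if (any(diff(levels) <= 0L))
    stop("levels must be strictly increasing", call. = FALSE)
  structure(list(levels = levels), class = "level_grid")
}

#' All ordered transitions of a level grid
#'
#' @param grid A [level_grid()].
#' @return Data frame with columns `from_level` and `to_level`; all
#'   `n * (n - 1)` ordered pairs of distinct levels, rising and falling.
#' @export
enumerate_transitions <- function(grid) {
  stopifnot(inherits(grid, "level_grid"))
  lv <- grid$levels
  pairs <- expand.grid(from_level = lv, to_level = lv,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$from_level != pairs$to_level, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Normalize a trace to unit mean
#'
#' Divides the samples by their mean, the standard normalization applied
#' before spectral analysis so that backlight modulation depths of
#' different monitors are comparable.
#'
#' @param trace A [luminance_trace()].
#' @return A [luminance_trace()] whose samples have mean 1.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "luminance_trace"))
  m <- mean(trace$samples)
  if (m <= 0)
    stop("cannot mean-normalize a trace with non-positive mean",
         call. = FALSE)
  trace$samples <- trace$samples / m
  trace
}

# -- file I/O -----------------------------------------------------------
# Plain-text dialect: '#'-prefixed key=value header lines followed by one
# luminance sample per line at full floating precision.

#' Write a luminance trace to a plain-text file
#'
#' The format is one `# key=value` header line per metadata field
#' (`sampling_rate_hz`, `refresh_rate_hz`, `primary`, `annotation`)
#' followed by one sample per line, serialized at full double precision so
#' that [read_trace()] round-trips bitwise.
#'
#' @param trace A [luminance_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "luminance_trace"))
  if (!all(is.finite(trace$samples)))
    stop("refusing to write a trace with non-finite samples", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate_hz=%.17g", trace$sampling_rate),
    sprintf("# refresh_rate_hz=%.17g", trace$refresh_rate),
    sprintf("# primary=%s", trace$primary),
    sprintf("# annotation=%s", trace$annotation),
    sprintf("%.17g", trace$samples)), con)
  invisible(path)
}

#' Read a luminance trace from a plain-text file
#'
#' @param path Path to a file written by [write_trace()] (or conforming to
#'   its dialect: `# key=value` header, one sample per line).
#' @return A [luminance_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- regmatches(hdr, regexec("^([^=]+)=(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[2L]) else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3L) m[3L] else NA_character_,
                 character(1))
  meta <- stats::setNames(as.list(vals), keys)
  for (req in c("sampling_rate_hz", "refresh_rate_hz"))
    if (is.null(meta[[req]]))
      stop("trace file header is missing required key '", req, "'",
           call. = FALSE)
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    stop("trace file contains no samples", call. = FALSE)
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1L]
    stop(sprintf("non-numeric sample at data line %d: '%s'",
                 bad, body[bad]), call. = FALSE)
  }
  luminance_trace(
    samples,
    sampling_rate = as.numeric(meta$sampling_rate_hz),
    refresh_rate = as.numeric(meta$refresh_rate_hz),
    primary = if (is.null(meta$primary)) "white" else meta$primary,
    annotation = if (is.null(meta$annotation)) "" else meta$annotation)
}

#' Frame duration in milliseconds
#'
#' @param refresh_rate Refresh rate in Hz.
#' @return Duration of one frame in ms; 16.7 ms at 60 Hz.
#' @export
frame_duration_ms <- function(refresh_rate) 1000 / refresh_rate
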