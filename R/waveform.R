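#' Uniformly sampled physiological waveform
#'
#' A `waveform` is the basic container for a single sampled signal: a numeric
#' vector of values, a sampling rate and the time of the first sample. It
#' carries pressure (Pa) or velocity (m/s) through the whole pipeline.
#'
#' @param values numeric vector of samples (Pa for pressure, m/s for velocity).
#' @param fs sampling rate in Hz, a single positive number.
#' @param t0 time of the first sample in seconds (default 0).
#' @param label signal kind, e.g. `"pressure"` or `"velocity"`.
#' @return an object of class `waveform`: a list with fields `values`, `fs`,
#'   `t0` and `label`.
#' @examples
#' w <- waveform(sin(seq(0, 2 * pi, length.out = 200)), fs = 200)
#' wf_time(w)[1:5]
#' @export
waveform <- function(values, fs, t0 = 0, label = "signal") {
  values <- as.numeric(values)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("waveform values must be finite", call. = FALSE)
  structure(list(values = values, fs = fs, t0 = as.numeric(t0),
                 label = as.character(label)),
            class = "waveform")
}

#' @rdname waveform
#' @param x a `waveform`.
#' @export
is.waveform <- function(x) inherits(x, "waveform")

#' Time grid of a waveform
#'
#' @param w a [waveform].
#' @return numeric vector of sample times in seconds.
#' @export
wf_time <- function(w) {
  stopifnot(is.waveform(w))
  w$t0 + (seq_along(w$values) - 1) / w$fs
}

#' Duration of a waveform in seconds
#'
#' Duration is the sampled extent `length(values)/fs`, i.e. the grid spans
#' `[t0, t0 + duration)`.
#'
#' @param w a [waveform].
#' @return duration in seconds.
#' @export
wf_duration <- function(w) length(w$values) / w$fs

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %s, %d samples @ %g Hz, t0 = %g s>\n",
              x$label, length(x$values), x$fs, x$t0))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.waveform <- function(x, ...) {
  data.frame(time_s = wf_time(x), value = x$values)
}

#' @export
length.waveform <- function(x) length(x$values)

# internal: check a waveform used as a single analysable beat
check_beat <- function(w, arg = "waveform") {
  if (!is.waveform(w)) stop(sprintf("'%s' must be a waveform", arg), call. = FALSE)
  if (length(w$values) < 16L)
    stop(sprintf("'%s' must have at least 16 samples", arg), call. = FALSE)
  invisible(w)
}

#' Beat annotation: fiducial points of one cardiac cycle
#'
#' Records the wave foot, the dicrotic notch and the beat period of a single
#' beat. Indices are 1-based sample indices into the beat's waveform.
#'
#' @param foot_index sample index of the wave foot (usually 1 for a segmented
#'   beat).
#' @param notch_index sample index of the dicrotic notch, i.e. the local
#'   pressure minimum marking end-systole.
#' @param period_s beat duration in seconds.
#' @param fs sampling rate of the annotated beat (Hz).
#' @return an object of class `beat_annotation` with fields `foot_index`,
#'   `notch_index`, `period_s`, `fs` and the derived notch time `TN` (s,
#'   relative to the beat start).
#' @export
beat_annotation <- function(foot_index, notch_index, period_s, fs) {
  foot_index <- as.integer(foot_index)
  notch_index <- as.integer(notch_index)
  if (foot_index < 1L) stop("'foot_index' must be >= 1", call. = FALSE)
  if (notch_index <= foot_index)
    stop("'notch_index' must exceed 'foot_index'", call. = FALSE)
  if (notch_index - foot_index >= period_s * fs)
    stop("'notch_index' must fall within one beat period of the foot",
         call. = FALSE)
  structure(list(foot_index = foot_index, notch_index = notch_index,
                 period_s = as.numeric(period_s), fs = as.numeric(fs),
                 TN = (notch_index - foot_index) / fs),
            class = "beat_annotation")
}

#' @export
print.beat_annotation <- function(x, ...) {
  cat(sprintf("<beat_annotation: foot %d, notch %d (TN = %.4g s), T = %.4g s>\n",
              x$foot_index, x$notch_index, x$TN, x$period_s))
  invisible(x)
}
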