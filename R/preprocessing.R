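# Preprocessing of raw tonometry-like recordings: beat segmentation by the
# intersecting-tangent wave foot, ensemble averaging, affine pressure
# calibration against brachial DBP/MAP, pressure-velocity alignment and
# dicrotic-notch detection.

# internal: intersecting-tangent foot location near one upstroke, as a
# fractional sample index. `i_up` is the index of maximum dP/dt; the foot is
# where the tangent at i_up meets the horizontal through the pre-upstroke
# minimum. Sub-sample resolution keeps foot-to-foot alignment unbiased.
tangent_foot <- function(values, fs, i_up, search_back) {
  lo <- max(1L, i_up - search_back)
  i_min <- lo + which.min(values[lo:i_up]) - 1L
  slope <- if (i_up > 1L && i_up < length(values))
    (values[i_up + 1L] - values[i_up - 1L]) * fs / 2
  else if (i_up > 1L) (values[i_up] - values[i_up - 1L]) * fs
  else NA_real_
  if (!is.finite(slope) || slope <= 0) return(NA_real_)
  idx <- i_up - (values[i_up] - values[i_min]) * fs / slope
  max(idx, as.numeric(i_min))
}

#' Segment a multi-beat recording into individual beats
#'
#' Divides a continuous recording into beats using the foot of the wave as
#' fiducial marker. Upstrokes are located as prominent maxima of the first
#' derivative separated by at least `min_period_s`; each foot is then refined
#' with the intersecting-tangent method (intersection of the tangent at peak
#' dP/dt with the horizontal through the pre-upstroke minimum).
#'
#' @param signal a [waveform] containing one or more full beats.
#' @param min_period_s minimum plausible beat period (s); default 0.4
#'   (150 bpm).
#' @return list of single-beat [waveform]s, each starting at a detected foot.
#'   The trailing partial beat after the last foot is returned only if it
#'   spans at least `min_period_s`.
#' @export
segment_beats <- function(signal, min_period_s = 0.4) {
  check_beat(signal, "signal")
  v <- signal$values
  fs <- signal$fs
  n <- length(v)
  if (max(v) - min(v) <= 1e-12 * max(abs(v), 1))
    stop("segmentation failed: signal is constant, no wave foot exists",
         call. = FALSE)
  dv <- diff(v) * fs
  min_gap <- max(2L, round(min_period_s * fs))
  thr <- 0.5 * max(dv)
  if (thr <= 0)
    stop("segmentation failed: no rising edge found", call. = FALSE)
  # greedy selection of derivative peaks above threshold, spaced >= min_gap
  cand <- order(dv, decreasing = TRUE)
  cand <- cand[dv[cand] >= thr]
  ups <- integer(0)
  for (i in cand) {
    if (all(abs(i - ups) >= min_gap)) ups <- c(ups, i)
  }
  ups <- sort(ups)
  if (length(ups) == 0L)
    stop("segmentation failed: no upstrokes detected", call. = FALSE)
  feet <- vapply(ups, function(i)
    tangent_foot(v, fs, i, search_back = min_gap %/% 2), numeric(1))
  feet <- as.integer(round(feet[!is.na(feet)]))
  feet <- unique(pmin(pmax(feet, 1L), n))
  if (length(feet) == 0L)
    stop("segmentation failed: foot refinement found no feet", call. = FALSE)
  bounds <- c(feet, n + 1L)
  beats <- list()
  for (k in seq_along(feet)) {
    seg <- bounds[k]:(bounds[k + 1L] - 1L)
    if (k < length(feet) || length(seg) >= min_period_s * fs)
      beats[[length(beats) + 1L]] <-
        waveform(v[seg], fs = fs, t0 = (bounds[k] - 1L) / fs,
                 label = signal$label)
  }
  if (length(beats) == 0L)
    stop("segmentation failed: no complete beat between detected feet",
         call. = FALSE)
  beats
}

#' Ensemble-average a set of beats
#'
#' Linearly time-normalises every beat to the median beat length and averages
#' pointwise, yielding a single representative beat.
#'
#' @param beats non-empty list of single-beat [waveform]s.
#' @return the ensemble-averaged [waveform] (length = median beat length,
#'   `t0 = 0`).
#' @export
ensemble_average <- function(beats) {
  if (length(beats) == 0L) stop("'beats' must be non-empty", call. = FALSE)
  stopifnot(all(vapply(beats, is.waveform, logical(1))))
  fs <- beats[[1L]]$fs
  lens <- vapply(beats, function(b) length(b$values), integer(1))
  n_out <- as.integer(round(stats::median(lens)))
  xs <- seq(0, 1, length.out = n_out)
  mat <- vapply(beats, function(b) {
    if (length(b$values) == n_out) return(b$values)
    stats::approx(seq(0, 1, length.out = length(b$values)), b$values,
                  xout = xs)$y
  }, numeric(n_out))
  waveform(rowMeans(as.matrix(mat)), fs = fs, t0 = 0,
           label = beats[[1L]]$label)
}

#' Calibrate a pressure waveform against brachial DBP and MAP
#'
#' Applies the affine map `p = alpha * raw + beta` with `alpha > 0` chosen so
#' the calibrated beat has minimum `DBP` and mean `MAP`, under the standard
#' assumption that diastolic and mean pressures are nearly constant along the
#' large arteries.
#'
#' @param raw uncalibrated pressure [waveform] (arbitrary units).
#' @param DBP target diastolic (minimum) pressure in Pa.
#' @param MAP target mean pressure in Pa; must exceed `DBP`.
#' @return calibrated pressure [waveform] in Pa.
#' @examples
#' raw <- waveform(0.5 - 0.5 * cos(2 * pi * seq(0, 1, by = 1/200)), fs = 200)
#' cal <- calibrate_pressure(raw, DBP = mmhg_to_pa(74), MAP = mmhg_to_pa(96))
#' c(min = pa_to_mmhg(min(cal$values)), mean = pa_to_mmhg(mean(cal$values)))
#' @export
calibrate_pressure <- function(raw, DBP, MAP) {
  check_beat(raw, "raw")
  if (MAP <= DBP) stop("'MAP' must exceed 'DBP'", call. = FALSE)
  m <- mean(raw$values)
  lo <- min(raw$values)
  if (m - lo <= .Machine$double.eps * max(abs(m), 1))
    stop("calibration failed: waveform mean equals its minimum", call. = FALSE)
  alpha <- (MAP - DBP) / (m - lo)
  beta <- DBP - alpha * lo
  waveform(alpha * raw$values + beta, fs = raw$fs, t0 = raw$t0,
           label = "pressure")
}

# internal: fractional foot index of a single beat (upstroke near its start)
single_beat_foot <- function(w) {
  v <- w$values
  dv <- diff(v) * w$fs
  i_up <- which.max(dv)
  f <- tangent_foot(v, w$fs, i_up, search_back = i_up)
  if (is.na(f)) stop("foot detection failed on single beat", call. = FALSE)
  f
}

#' Align a velocity beat to a pressure beat
#'
#' Pressure and velocity are typically recorded sequentially, so their beats
#' must be aligned before loop or wave-intensity analysis. The default
#' foot-to-foot method circularly shifts `U` so its intersecting-tangent foot
#' coincides with that of `P`; the cross-correlation method instead maximises
#' the correlation of the normalised upstrokes. Both waveforms are resampled
#' to a common length (the shorter of the two) on return.
#'
#' @param P single-beat pressure [waveform].
#' @param U single-beat velocity [waveform].
#' @param method `"foot"` (default) or `"xcorr"`.
#' @return list with aligned `P` and `U` [waveform]s and the applied `shift`
#'   in samples (positive = `U` moved earlier).
#' @export
align_waveforms <- function(P, U, method = c("foot", "xcorr")) {
  method <- match.arg(method)
  check_beat(P, "P"); check_beat(U, "U")
  if (abs(P$fs - U$fs) > 1e-9) stop("'P' and 'U' must share a sampling rate",
                                    call. = FALSE)
  n <- min(length(P$values), length(U$values))
  p <- P$values[seq_len(n)]
  u <- U$values[seq_len(n)]
  if (method == "foot") {
    shift <- as.integer(round(single_beat_foot(waveform(u, U$fs)) -
                              single_beat_foot(waveform(p, P$fs))))
  } else {
    # correlate the normalised derivatives: the upstrokes dominate, so the
    # peak is insensitive to the differing diastolic shapes of P and U
    norm01 <- function(x) (x - min(x)) / (max(x) - min(x))
    dp <- norm01(diff(p))
    lags <- -(n %/% 4):(n %/% 4)
    m <- n - 1L
    cc <- vapply(lags, function(s)
      stats::cor(dp, norm01(diff(u)[((seq_len(m) - 1 + s) %% m) + 1L])),
      numeric(1))
    shift <- lags[which.max(cc)]
  }
  u_shift <- u[((seq_len(n) - 1 + shift) %% n) + 1L]
  list(P = waveform(p, fs = P$fs, t0 = 0, label = P$label),
       U = waveform(u_shift, fs = U$fs, t0 = 0, label = U$label),
       shift = as.integer(shift))
}

#' Detect the dicrotic notch of a calibrated pressure beat
#'
#' Locates the dicrotic notch as the local pressure minimum within a search
#' window after the systolic peak (default: from the peak to 60% of the beat
#' length). The minimum must be strict over a +/- `strict_ms` neighbourhood,
#' so a monotonically decaying diastole (no notch) raises an error rather
#' than returning a spurious point; the caller may then supply the notch time
#' manually.
#'
#' @param P single-beat pressure [waveform].
#' @param window_frac end of the search window as a fraction of beat length;
#'   default 0.6.
#' @param strict_ms half-width (ms) of the neighbourhood over which the
#'   minimum must be strict; default 10.
#' @return a [beat_annotation] with `foot_index = 1`.
#' @export
detect_dicrotic_notch <- function(P, window_frac = 0.6, strict_ms = 10) {
  check_beat(P, "P")
  v <- P$values
  n <- length(v)
  i_peak <- which.max(v)
  i_end <- max(i_peak + 2L, floor(window_frac * n))
  if (i_end > n) i_end <- n
  if (i_end - i_peak < 3L)
    stop("notch detection failed: search window too short", call. = FALSE)
  w <- max(1L, round(strict_ms / 1000 * P$fs))
  best <- NA_integer_
  for (i in (i_peak + 1L):(i_end - 1L)) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    nb <- v[lo:hi]
    if (v[i] <= min(nb) && v[i] < max(nb) &&
        v[i] < v[max(lo, i - 1L)] + .Machine$double.eps * abs(v[i]) &&
        any(v[(i + 1L):hi] > v[i])) {
      if (is.na(best) || v[i] < v[best]) best <- i
    }
  }
  if (is.na(best))
    stop(paste("notch detection failed: no strict local minimum in the",
               "search window; supply the notch index manually"),
         call. = FALSE)
  beat_annotation(1L, best, period_s = n / P$fs, fs = P$fs)
}
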