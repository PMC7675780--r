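# Wave intensity analysis: PU-loop wave speed, separation of wave intensity
# into forward and backward components, and the areas of the three principal
# carotid waves (forward compression, backward compression, forward
# expansion). All operations accept either measured (P, U) or excess
# (Pex, Uex) pairs.

#' Wave speed from the early-systolic PU-loop slope
#'
#' Estimates the local wave speed `c = (1/rho) * dP+/dU+` from the
#' least-squares slope of pressure against velocity over the early-systolic
#' part of the loop, where only forward-travelling waves are assumed present
#' and the P-U relation is linear. The linear region starts at the pressure
#' foot (the minimum before the systolic peak) and is grown sample by sample
#' while the running least-squares fit keeps `R^2 >= r2_min`, up to 30 ms
#' past the peak of dP/dt.
#'
#' @param P,U aligned single-beat pressure (Pa) and velocity (m/s)
#'   [waveform]s.
#' @param rho blood density (kg/m^3); default 1050.
#' @param r2_min minimum coefficient of determination for the growing linear
#'   fit; default 0.98.
#' @param min_samples minimum number of samples in the region; default 5.
#' @return list with `c` (m/s), `slope` (Pa s/m), `linear_region` (index
#'   range used) and `r2`.
#' @examples
#' subj <- generate_subject(subject_truth(noise_sd_P = 0, noise_sd_U = 0,
#'                                        refl_amp = 0), seed = 1)
#' loop_wave_speed(subj$Pex_true, subj$Uex_true)$c  # = truth c, 6 m/s
#' @export
loop_wave_speed <- function(P, U, rho = 1050, r2_min = 0.98, min_samples = 5L) {
  check_beat(P, "P"); check_beat(U, "U")
  if (rho <= 0) stop("'rho' must be positive", call. = FALSE)
  p <- P$values; u <- U$values
  n <- min(length(p), length(u))
  p <- p[seq_len(n)]; u <- u[seq_len(n)]
  i_peak <- which.max(p)
  pre <- p[seq_len(i_peak)]
  # foot = last pre-peak sample still at the minimum level, so any flat
  # baseline before the upstroke is skipped
  tol <- 1e-9 * max(abs(p) , 1)
  i_start <- max(which(pre <= min(pre) + tol))
  dp <- diff(p) * P$fs
  i_maxslope <- which.max(dp[i_start:(i_peak)]) + i_start - 1L
  i_max_end <- min(n, i_maxslope + as.integer(round(0.030 * P$fs)))
  if (i_max_end - i_start + 1L < min_samples)
    stop("wave-speed estimation failed: upstroke too short for a linear fit",
         call. = FALSE)
  best <- NULL
  i_end <- i_start + min_samples - 1L
  while (i_end <= i_max_end) {
    idx <- i_start:i_end
    if (stats::sd(u[idx]) == 0) break
    fit <- stats::lm.fit(cbind(1, u[idx]), p[idx])
    ssr <- sum(fit$residuals^2)
    sst <- sum((p[idx] - mean(p[idx]))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 1
    if (r2 < r2_min) break
    best <- list(slope = fit$coefficients[2L], idx = idx, r2 = r2)
    i_end <- i_end + 1L
  }
  if (is.null(best) || !is.finite(best$slope) || best$slope <= 0)
    stop(paste("wave-speed estimation failed: no early-systolic region with",
               "acceptable linearity; consider supplying the region manually"),
         call. = FALSE)
  list(c = unname(best$slope) / rho, slope = unname(best$slope),
       linear_region = range(best$idx), r2 = best$r2)
}

#' Separate wave intensity into forward and backward components
#'
#' Computes per-sample wave intensity from first differences of pressure and
#' velocity and splits it with the water-hammer characteristic decomposition:
#' `dI+/- = +/- 1/(4 rho c) * (dP +/- rho c dU)^2`. By construction
#' `dI+ >= 0`, `dI- <= 0` and `dI+ + dI- = dP * dU` at every sample.
#'
#' @param P,U aligned single-beat pressure and velocity [waveform]s.
#' @param rho blood density (kg/m^3).
#' @param c wave speed (m/s), `> 0`.
#' @return list with numeric vectors `dI_plus`, `dI_minus` and `dI` (each of
#'   length `length(P) - 1`, units W/m^2 per sampling interval) and the
#'   sampling interval `dt`.
#' @export
separate_wave_intensity <- function(P, U, rho = 1050, c = NULL) {
  check_beat(P, "P"); check_beat(U, "U")
  if (is.null(c) || c <= 0) stop("'c' must be a positive wave speed",
                                 call. = FALSE)
  n <- min(length(P$values), length(U$values))
  dP <- diff(P$values[seq_len(n)])
  dU <- diff(U$values[seq_len(n)])
  zc <- rho * c
  dI_plus <- (dP + zc * dU)^2 / (4 * zc)
  dI_minus <- -(dP - zc * dU)^2 / (4 * zc)
  list(dI_plus = dI_plus, dI_minus = dI_minus, dI = dP * dU, dt = 1 / P$fs)
}

# internal: contiguous lobes (runs of samples above a noise floor) of a
# non-negative series. Lobes carrying less than `min_area_frac` of the
# largest lobe's area are discarded as spurious (edge fragments from noise).
# Gap merging (`merge_gap_s` > 0) is available but off by default: the
# genuine boundary between the compression and expansion lobes is itself a
# short below-floor run at the pulse peak and must not be closed.
find_lobes <- function(x, dt, floor_frac = 0.005, merge_gap_s = 0,
                       min_area_frac = 0.02) {
  if (all(x <= 0)) return(list())
  thr <- floor_frac * max(x)
  active <- x > thr
  if (!any(active)) return(list())
  if (merge_gap_s > 0) {
    r <- rle(active)
    max_gap <- max(1L, round(merge_gap_s / dt))
    ends <- cumsum(r$lengths)
    for (k in seq_along(r$values)) {
      if (!r$values[k] && r$lengths[k] <= max_gap &&
          k > 1L && k < length(r$values))
        active[(ends[k] - r$lengths[k] + 1L):ends[k]] <- TRUE
    }
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lobes <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    lobes[[length(lobes) + 1L]] <-
      list(idx = idx, area = sum(x[idx]) * dt,
           t_start = (starts[k] - 1) * dt, t_end = ends[k] * dt)
  }
  if (length(lobes) > 1L) {
    amax <- max(vapply(lobes, `[[`, numeric(1), "area"))
    lobes <- Filter(function(lb) lb$area >= min_area_frac * amax, lobes)
  }
  lobes
}

#' Areas of the principal carotid waves
#'
#' Integrates the three physiologically labelled lobes of the separated wave
#' intensity over time: the forward compression wave (FCW, first `dI+` lobe,
#' early systole, generated by ventricular contraction), the forward expansion
#' wave (FEW, last `dI+` lobe ending near the notch, from the declining
#' ventricular shortening velocity) and the backward compression wave (BCW,
#' dominant `dI-` lobe between them, attributed to reflections from the head
#' microcirculation). Lobes are bounded by crossings of a small noise floor
#' (0.5% of the series maximum); BCW is reported as a magnitude. A missing
#' FEW or BCW lobe yields a zero area with a warning flag rather than an
#' error.
#'
#' @param dI_plus,dI_minus numeric vectors from [separate_wave_intensity()].
#' @param annotation a [beat_annotation] (used to locate the notch).
#' @param dt sampling interval (s).
#' @param floor_frac noise floor as a fraction of each series' maximum
#'   magnitude; default 0.005.
#' @return list with `FCW_area`, `BCW_area`, `FEW_area` (J/m^2, all `>= 0`)
#'   and logical flags `FEW_missing`, `BCW_missing`.
#' @export
wave_areas <- function(dI_plus, dI_minus, annotation, dt,
                       floor_frac = 0.005) {
  stopifnot(length(dI_plus) == length(dI_minus))
  i_notch <- annotation$notch_index
  TN <- annotation$TN
  plus_lobes <- find_lobes(dI_plus, dt, floor_frac)
  if (length(plus_lobes) == 0L)
    return(list(FCW_area = 0, BCW_area = 0, FEW_area = 0,
                FEW_missing = TRUE, BCW_missing = TRUE))
  # FCW: dominant dI+ lobe starting in early systole (before 0.5 TN);
  # fall back to the first lobe if none starts that early
  early <- Filter(function(lb) lb$t_start <= 0.5 * TN, plus_lobes)
  fcw <- if (length(early) > 0L) {
    early[[which.max(vapply(early, `[[`, numeric(1), "area"))]]
  } else plus_lobes[[1L]]
  # FEW: dominant dI+ lobe other than the FCW that starts in late systole
  # (start within [0.4 TN, TN + 10 ms]). Accepting lobes that run past the
  # notch keeps the FEW detectable when the expansion lobe merges with the
  # small early-diastolic forward wave at coarse resolution.
  few_cand <- Filter(function(lb)
    !identical(lb$idx, fcw$idx) &&
      lb$t_start >= 0.4 * TN && lb$t_start <= TN + 0.010,
    plus_lobes)
  few <- if (length(few_cand) > 0L)
    few_cand[[which.max(vapply(few_cand, `[[`, numeric(1), "area"))]]
  else NULL
  # BCW: largest-magnitude dI- lobe between the FCW start and the FEW end
  minus_lobes <- find_lobes(-dI_minus, dt, floor_frac)
  t_hi <- if (!is.null(few)) few$t_end else TN + 0.020
  bcw <- NULL
  for (lb in minus_lobes) {
    if (lb$t_start >= fcw$t_start && lb$t_end <= t_hi + 0.010) {
      if (is.null(bcw) || lb$area > bcw$area) bcw <- lb
    }
  }
  list(FCW_area = fcw$area,
       BCW_area = if (is.null(bcw)) 0 else bcw$area,
       FEW_area = if (is.null(few)) 0 else few$area,
       FEW_missing = is.null(few),
       BCW_missing = is.null(bcw))
}

#' Savitzky-Golay smoothing of a waveform
#'
#' Least-squares local-polynomial smoothing, used before differencing when
#' waveforms carry measurement noise (first differences amplify noise and can
#' fragment the wave-intensity lobes). A window of 9 samples (40 ms at
#' 200 Hz) with a cubic polynomial preserves the systolic upstroke while
#' suppressing sample-to-sample noise.
#'
#' @param w a [waveform].
#' @param window odd window length in samples; default 9.
#' @param order polynomial order; default 3.
#' @return smoothed [waveform].
#' @export
smooth_waveform <- function(w, window = 9L, order = 3L) {
  stopifnot(is.waveform(w))
  if (window %% 2L == 0L) window <- window + 1L
  if (length(w$values) <= window) return(w)
  n <- length(w$values)
  half <- (window - 1L) %/% 2L
  x <- seq(-half, half)
  basis <- outer(x, 0:order, `^`)
  # projection row for the window centre
  h <- (basis %*% solve(crossprod(basis), t(basis)))[half + 1L, ]
  padded <- c(rep(w$values[1L], half), w$values, rep(w$values[n], half))
  sm <- stats::filter(padded, rev(h), sides = 2)
  waveform(as.numeric(sm[(half + 1L):(half + n)]), fs = w$fs, t0 = w$t0,
           label = w$label)
}

#' Full wave intensity analysis of one (P, U) pair
#'
#' Convenience wrapper: estimates the loop wave speed, separates wave
#' intensity and integrates the wave areas. With `sg_window` set, both
#' waveforms are Savitzky-Golay smoothed first ([smooth_waveform]); this is
#' recommended for noisy recordings and is the default in
#' [analyze_subject()].
#'
#' @param P,U aligned single-beat pressure and velocity [waveform]s (either
#'   measured or excess components).
#' @param annotation a [beat_annotation].
#' @param rho blood density (kg/m^3); default 1050.
#' @param source label, `"measured"` or `"excess"`.
#' @param sg_window optional odd Savitzky-Golay window (samples); `NULL`
#'   (default) disables smoothing.
#' @param ... further arguments passed to [loop_wave_speed()].
#' @return an object of class `wia_result`: list with `c`, `rho`, `dI_plus`,
#'   `dI_minus`, `FCW_area`, `BCW_area`, `FEW_area`, `linear_region`,
#'   `source` and the flags from [wave_areas()].
#' @export
wia <- function(P, U, annotation, rho = 1050, source = "measured",
                sg_window = NULL, ...) {
  if (!is.null(sg_window)) {
    P <- smooth_waveform(P, sg_window)
    U <- smooth_waveform(U, sg_window)
  }
  ws <- loop_wave_speed(P, U, rho = rho, ...)
  sep <- separate_wave_intensity(P, U, rho = rho, c = ws$c)
  ar <- wave_areas(sep$dI_plus, sep$dI_minus, annotation, sep$dt)
  structure(c(list(c = ws$c, rho = rho, dI_plus = sep$dI_plus,
                   dI_minus = sep$dI_minus, dt = sep$dt,
                   linear_region = ws$linear_region, source = source),
              ar),
            class = "wia_result")
}

#' @export
print.wia_result <- function(x, ...) {
  cat(sprintf("<wia_result (%s): c = %.3g m/s>\n", x$source, x$c))
  cat(sprintf("  FCW = %.4g, BCW = %.4g, FEW = %.4g J/m^2\n",
              x$FCW_area, x$BCW_area, x$FEW_area))
  invisible(x)
}

#' Compare measured- and excess-derived wave intensity parameters
#'
#' Runs the full wave intensity analysis on both the measured pair `(P, U)`
#' and the excess pair `(Pex, Uex)` and reports the percentage difference of
#' each measured-derived parameter relative to its excess-derived
#' counterpart, `100 * (PU - PexUex) / PexUex`.
#'
#' @param P,U measured single-beat waveforms.
#' @param Pex,Uex excess single-beat waveforms on the same grid.
#' @param annotation a [beat_annotation].
#' @param rho blood density (kg/m^3); default 1050.
#' @param sg_window optional Savitzky-Golay window passed to [wia()].
#' @return list with `measured` and `excess` `wia_result`s and `pct_diff`, a
#'   named numeric vector over `c`, `FCW_area`, `BCW_area`, `FEW_area`
#'   (`NA` where the excess-derived value is 0).
#' @export
compare_measured_vs_excess <- function(P, U, Pex, Uex, annotation,
                                       rho = 1050, sg_window = NULL) {
  m <- wia(P, U, annotation, rho = rho, source = "measured",
           sg_window = sg_window)
  e <- wia(Pex, Uex, annotation, rho = rho, source = "excess",
           sg_window = sg_window)
  pars <- c("c", "FCW_area", "BCW_area", "FEW_area")
  pct <- vapply(pars, function(nm) {
    ev <- e[[nm]]
    if (!is.finite(ev) || ev == 0) return(NA_real_)
    100 * (m[[nm]] - ev) / ev
  }, numeric(1))
  list(measured = m, excess = e, pct_diff = pct)
}
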