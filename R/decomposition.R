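# Velocity split into reservoir and excess components, and the scalar
# hemodynamic parameters derived from a decomposed beat.

#' Mean downstream resistance from diastolic averages
#'
#' `Rbar = (<P> - Pinf) / <U>`, where `<P>` and `<U>` are the time-averaged
#' measured pressure and velocity during diastole `[TN, T)`.
#'
#' @param P,U single-beat pressure and velocity [waveform]s on a common grid.
#' @param annotation a [beat_annotation].
#' @param Pinf asymptotic pressure (Pa).
#' @return mean downstream resistance (Pa s/m).
#' @export
mean_diastolic_resistance <- function(P, U, annotation, Pinf) {
  check_beat(P, "P"); check_beat(U, "U")
  n <- length(P$values)
  if (length(U$values) != n) stop("'P' and 'U' must share a grid", call. = FALSE)
  dia <- annotation$notch_index:n
  if (length(dia) < 2L) stop("diastole must contain at least 2 samples",
                             call. = FALSE)
  mU <- mean(U$values[dia])
  if (mU <= 0)
    stop("mean diastolic velocity is non-positive; cannot form Rbar",
         call. = FALSE)
  (mean(P$values[dia]) - Pinf) / mU
}

#' Decompose velocity into reservoir and excess components
#'
#' `Ur = (P - Pinf) / Rbar` pointwise (the measured pressure drives the
#' reservoir flow through the mean downstream resistance) and
#' `Uex = U - Ur`.
#'
#' @param P,U single-beat pressure and velocity [waveform]s on a common grid.
#' @param Pinf asymptotic pressure (Pa).
#' @param Rbar mean downstream resistance (Pa s/m), `> 0`.
#' @param use_reservoir_pressure if `TRUE`, use a supplied reservoir pressure
#'   instead of the measured pressure in the numerator (literature variant);
#'   pass it as `Pr`.
#' @param Pr reservoir-pressure [waveform], only used when
#'   `use_reservoir_pressure = TRUE`.
#' @return an object of class `velocity_split`: list with `Rbar`, `Ur` and
#'   `Uex` [waveform]s.
#' @export
decompose_velocity <- function(P, U, Pinf, Rbar,
                               use_reservoir_pressure = FALSE, Pr = NULL) {
  check_beat(P, "P"); check_beat(U, "U")
  if (Rbar <= 0) stop("'Rbar' must be positive", call. = FALSE)
  if (length(U$values) != length(P$values))
    stop("'P' and 'U' must share a grid", call. = FALSE)
  drive <- if (use_reservoir_pressure) {
    stopifnot(is.waveform(Pr))
    Pr$values
  } else P$values
  ur <- (drive - Pinf) / Rbar
  structure(list(Rbar = Rbar,
                 Ur = waveform(ur, fs = U$fs, t0 = U$t0,
                               label = "reservoir velocity"),
                 Uex = waveform(U$values - ur, fs = U$fs, t0 = U$t0,
                                label = "excess velocity")),
            class = "velocity_split")
}

#' @export
print.velocity_split <- function(x, ...) {
  cat(sprintf("<velocity_split: Rbar = %.4g Pa s/m, Urmax = %.3g, Uexmax = %.3g m/s>\n",
              x$Rbar, max(x$Ur$values), max(x$Uex$values)))
  invisible(x)
}

#' Diastolic mean squared error between measured and reservoir pressure
#'
#' `X2 = 1/N * sum_i (P_i - Pr_i)^2` over the `N` diastolic samples
#' `[TN, T)`.
#'
#' @param P measured pressure [waveform].
#' @param Pr reservoir pressure [waveform] on the same grid.
#' @param annotation a [beat_annotation].
#' @return mean squared diastolic error (Pa^2).
#' @export
diastolic_mse <- function(P, Pr, annotation) {
  n <- length(P$values)
  if (length(Pr$values) != n) stop("'P' and 'Pr' must share a grid", call. = FALSE)
  dia <- annotation$notch_index:n
  mean((P$values[dia] - Pr$values[dia])^2)
}

#' Scalar hemodynamic parameters of a decomposed beat
#'
#' Collects the standard per-beat summary of a reservoir-wave decomposition:
#' the maxima of the reservoir and excess pressure and velocity waveforms
#' (`Prmax`, `Pexmax`, `Urmax`, `Uexmax`), the time integrals of the reservoir
#' and excess pressure over the full beat (`PRI`, `PEI`, trapezoidal rule),
#' the diastolic mean squared error `X2` between measured and reservoir
#' pressure, and the reservoir notch pressure `Pn_bar`.
#'
#' @param fit a `reservoir_fit` from [decompose_pressure()].
#' @param split a `velocity_split` from [decompose_velocity()].
#' @param annotation a [beat_annotation] (defaults to the one stored in
#'   `fit`).
#' @return an object of class `hemodynamic_params`: a list with fields
#'   `Prmax`, `Pexmax` (Pa), `PRI`, `PEI` (Pa s), `Urmax`, `Uexmax` (m/s),
#'   `X2` (Pa^2), `Pn_bar` (Pa), `a`, `b` (1/s) and `Pinf` (Pa).
#' @export
hemodynamic_params <- function(fit, split, annotation = fit$annotation) {
  stopifnot(inherits(fit, "reservoir_fit"), inherits(split, "velocity_split"))
  tt <- wf_time(fit$Pr)
  structure(list(
    Prmax = max(fit$Pr$values),
    Pexmax = max(fit$Pex$values),
    PRI = pracma::trapz(tt, fit$Pr$values),
    PEI = pracma::trapz(tt, fit$Pex$values),
    Urmax = max(split$Ur$values),
    Uexmax = max(split$Uex$values),
    X2 = fit$X2,
    Pn_bar = fit$Pn_bar,
    a = fit$a, b = fit$b, Pinf = fit$Pinf),
    class = "hemodynamic_params")
}

#' @export
print.hemodynamic_params <- function(x, ...) {
  cat("<hemodynamic_params>\n")
  cat(sprintf("  Prmax = %.3g Pa, Pexmax = %.3g Pa\n", x$Prmax, x$Pexmax))
  cat(sprintf("  PRI = %.3g Pa s, PEI = %.3g Pa s\n", x$PRI, x$PEI))
  cat(sprintf("  Urmax = %.3g m/s, Uexmax = %.3g m/s\n", x$Urmax, x$Uexmax))
  cat(sprintf("  X2 = %.4g Pa^2, Pn_bar = %.1f Pa\n", x$X2, x$Pn_bar))
  invisible(x)
}
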