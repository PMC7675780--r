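# Synthetic carotid-like waveform generator with known ground truth.
#
# Construction: choose an excess-pressure pulse Pex(t) (half-sine systolic
# forward wave, optional mid-systolic backward wave, optional small
# early-diastolic forward tail), then obtain the reservoir pressure by
# forward-integrating the reservoir relation written as an ODE driven by the
# excess component,
#
#   dPr/dt = a P - (a + b) Pr + b Pinf = a Pex - b (Pr - Pinf),
#
# with a high-order adaptive integrator. The measured pressure is
# P = Pr + Pex. Velocity follows the same split: Ur = (P - Pinf) / Rbar and
# Uex from the water-hammer relation, Uex = (Pex_fwd - Pex_bwd) / (rho c),
# so the excess PU-loop has exact slope rho*c. Using an adaptive ODE solver
# here (rather than the closed-form quadrature used by the estimator) keeps
# the generator independent of the code it is meant to test.

#' Ground-truth parameter set for one synthetic subject
#'
#' Defines a single-beat carotid-like subject: reservoir dynamics (`a`, `b`,
#' `Pinf`, `P0`), timing (`T`, `TN`, `fs`), wave properties (`c`, `rho`,
#' `Rbar`), the excess-pressure pulse shape and additive noise levels.
#' Defaults describe a healthy middle-aged carotid artery: diastolic onset
#' pressure near 74 mmHg, asymptotic pressure 60 mmHg, heart period 0.95 s,
#' notch at 0.35 s, wave speed 6 m/s and blood density 1050 kg/m^3.
#'
#' The excess pulse is a systolic forward half-sine (`ex_amp`, `ex_onset`,
#' `ex_duration`), an optional mid-systolic backward (reflected) half-sine
#' (`refl_*`), and an optional small forward early-diastolic half-sine tail
#' starting at the notch (`tail_*`) emulating residual wave activity in early
#' diastole. All excess components vanish at and are zero outside their
#' stated support.
#'
#' @param a systolic rate constant (1/s), `> 0`.
#' @param b diastolic rate constant (1/s), `> 0`.
#' @param Pinf asymptotic pressure (Pa), `>= 0`.
#' @param P0 pressure at the start of the beat (Pa).
#' @param T cardiac period (s).
#' @param TN dicrotic-notch time (s), `0 < TN < T`.
#' @param c wave speed (m/s), `> 0`.
#' @param rho blood density (kg/m^3); default 1050.
#' @param Rbar mean downstream resistance (Pa s/m), `> 0`.
#' @param ex_amp,ex_onset,ex_duration systolic forward half-sine amplitude
#'   (Pa), onset and duration (s).
#' @param refl_amp,refl_onset,refl_duration backward (reflected) half-sine;
#'   amplitude 0 disables it.
#' @param tail_amp,tail_duration early-diastolic forward half-sine starting at
#'   `TN`; amplitude 0 disables it.
#' @param noise_sd_P,noise_sd_U additive i.i.d. Gaussian noise standard
#'   deviations for pressure (Pa) and velocity (m/s).
#' @param fs sampling rate (Hz); default 200.
#' @return an object of class `subject_truth`.
#' @examples
#' subject_truth()                       # defaults
#' subject_truth(b = 1.5, tail_amp = 0)  # clean exponential diastole
#' @export
subject_truth <- function(a = 8, b = 2, Pinf = mmhg_to_pa(60),
                          P0 = mmhg_to_pa(74), T = 0.95, TN = 0.35,
                          c = 6, rho = 1050, Rbar = 4e4,
                          ex_amp = 4000, ex_onset = 0.02, ex_duration = 0.30,
                          refl_amp = 600, refl_onset = 0.14, refl_duration = 0.15,
                          tail_amp = 400, tail_duration = 0.08,
                          noise_sd_P = 20, noise_sd_U = 0.004,
                          fs = 200) {
  truth <- list(a = a, b = b, Pinf = Pinf, P0 = P0, T = T, TN = TN,
                c = c, rho = rho, Rbar = Rbar,
                ex_amp = ex_amp, ex_onset = ex_onset, ex_duration = ex_duration,
                refl_amp = refl_amp, refl_onset = refl_onset,
                refl_duration = refl_duration,
                tail_amp = tail_amp, tail_duration = tail_duration,
                noise_sd_P = noise_sd_P, noise_sd_U = noise_sd_U, fs = fs)
  validate_subject_truth(truth)
  structure(truth, class = "subject_truth")
}

validate_subject_truth <- function(x) {
  chk <- function(cond, field, msg) {
    if (!cond) stop(sprintf("invalid 'subject_truth' field '%s': %s", field, msg),
                    call. = FALSE)
  }
  chk(x$a >= 0, "a", "must be non-negative")
  chk(x$b > 0, "b", "must be positive")
  chk(x$Pinf >= 0, "Pinf", "must be non-negative")
  chk(x$T > 0, "T", "must be positive")
  chk(x$TN > 0 && x$TN < x$T, "TN", "must satisfy 0 < TN < T")
  chk(x$fs > 0, "fs", "must be positive")
  chk(x$c > 0, "c", "must be positive")
  chk(x$rho > 0, "rho", "must be positive")
  chk(x$Rbar > 0, "Rbar", "must be positive")
  chk(x$ex_amp >= 0, "ex_amp", "must be non-negative")
  chk(x$ex_onset >= 0, "ex_onset", "must be non-negative")
  chk(x$ex_onset + x$ex_duration <= x$TN + 1e-12, "ex_duration",
      "systolic excess pulse must end by the notch")
  chk(x$refl_amp >= 0, "refl_amp", "must be non-negative")
  if (x$refl_amp > 0)
    chk(x$refl_onset >= 0 && x$refl_onset + x$refl_duration <= x$TN + 1e-12,
        "refl_duration", "reflected pulse must lie within systole")
  chk(x$tail_amp >= 0, "tail_amp", "must be non-negative")
  chk(x$TN + x$tail_duration <= x$T + 1e-12, "tail_duration",
      "diastolic tail must end within the beat")
  chk(x$noise_sd_P >= 0, "noise_sd_P", "must be non-negative")
  chk(x$noise_sd_U >= 0, "noise_sd_U", "must be non-negative")
  invisible(x)
}

#' @export
print.subject_truth <- function(x, ...) {
  cat(sprintf(paste0("<subject_truth: a = %.3g, b = %.3g 1/s, ",
                     "Pinf = %.1f mmHg, T = %.3g s, TN = %.3g s, c = %.3g m/s>\n"),
              x$a, x$b, pa_to_mmhg(x$Pinf), x$T, x$TN, x$c))
  invisible(x)
}

# half-sine pulse: amp * sin(pi (t - onset) / duration) on [onset, onset+duration]
half_sine <- function(t, amp, onset, duration) {
  if (amp == 0 || duration <= 0) return(numeric(length(t)))
  inside <- t >= onset & t <= onset + duration
  out <- numeric(length(t))
  out[inside] <- amp * sin(pi * (t[inside] - onset) / duration)
  out
}

# forward / backward excess pressure components as functions of time
excess_components <- function(truth, t) {
  fwd <- half_sine(t, truth$ex_amp, truth$ex_onset, truth$ex_duration) +
    half_sine(t, truth$tail_amp, truth$TN, truth$tail_duration)
  bwd <- half_sine(t, truth$refl_amp, truth$refl_onset, truth$refl_duration)
  list(fwd = fwd, bwd = bwd, total = fwd + bwd)
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate one synthetic subject
#'
#' Builds a single-beat pressure/velocity pair from a [subject_truth]
#' parameter set. The reservoir pressure is obtained by adaptive ODE
#' integration of `dPr/dt = a Pex - b (Pr - Pinf)` from `Pr(0) = P0`, the
#' measured pressure is `P = Pr + Pex`, and velocity components follow
#' `Ur = (P - Pinf)/Rbar` and the water-hammer relation
#' `Uex = (Pex_fwd - Pex_bwd)/(rho c)`. Gaussian noise is then added to `P`
#' and `U`. Noiseless ground-truth series are stored alongside the noisy
#' observations.
#'
#' @param truth a [subject_truth].
#' @param seed integer seed controlling the noise; the same `(truth, seed)`
#'   pair always yields identical output.
#' @return an object of class `synthetic_subject`: a list with observed
#'   waveforms `P` and `U`, ground-truth series `Pr_true`, `Pex_true`,
#'   `Ur_true`, `Uex_true`, `Pex_fwd_true`, `Pex_bwd_true` (all [waveform]s on
#'   the same grid over `[0, T)`), and `truth`.
#' @examples
#' subj <- generate_subject(subject_truth(), seed = 42)
#' subj$P
#' max(abs(subj$P$values - subj$Pr_true$values - subj$Pex_true$values -
#'         (subj$P$values - subj$Pr_true$values - subj$Pex_true$values)))
#' @export
generate_subject <- function(truth, seed = 1L) {
  if (!inherits(truth, "subject_truth")) truth <- do.call(subject_truth, truth)
  validate_subject_truth(truth)
  fs <- truth$fs
  n <- floor(truth$T * fs)
  t <- (seq_len(n) - 1) / fs
  ex <- excess_components(truth, t)

  rhs <- function(tt, y, parms) {
    exx <- excess_components(truth, tt)$total
    list(truth$a * exx - truth$b * (y[1] - truth$Pinf))
  }
  sol <- deSolve::ode(y = c(Pr = truth$P0), times = t, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-8)
  pr <- as.numeric(sol[, "Pr"])

  p_clean <- pr + ex$total
  ur <- (p_clean - truth$Pinf) / truth$Rbar
  uex <- (ex$fwd - ex$bwd) / (truth$rho * truth$c)
  u_clean <- ur + uex

  noisy <- with_seed(seed, {
    list(P = p_clean + stats::rnorm(n, 0, truth$noise_sd_P),
         U = u_clean + stats::rnorm(n, 0, truth$noise_sd_U))
  })

  structure(list(
    P = waveform(noisy$P, fs = fs, label = "pressure"),
    U = waveform(noisy$U, fs = fs, label = "velocity"),
    Pr_true = waveform(pr, fs = fs, label = "reservoir pressure (truth)"),
    Pex_true = waveform(ex$total, fs = fs, label = "excess pressure (truth)"),
    Pex_fwd_true = waveform(ex$fwd, fs = fs, label = "forward excess (truth)"),
    Pex_bwd_true = waveform(ex$bwd, fs = fs, label = "backward excess (truth)"),
    Ur_true = waveform(ur, fs = fs, label = "reservoir velocity (truth)"),
    Uex_true = waveform(uex, fs = fs, label = "excess velocity (truth)"),
    truth = truth, seed = as.integer(seed)),
    class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject: %d samples @ %g Hz, seed %d>\n",
              length(x$P$values), x$truth$fs, x$seed))
  print(x$truth)
  invisible(x)
}

#' Ground-truth beat annotation of a synthetic subject
#'
#' @param subject a `synthetic_subject`.
#' @return the [beat_annotation] implied by the stored truth (foot at sample
#'   1, notch at the sample nearest `TN`).
#' @export
true_annotation <- function(subject) {
  stopifnot(inherits(subject, "synthetic_subject"))
  tr <- subject$truth
  beat_annotation(1L, round(tr$TN * tr$fs) + 1L, tr$T, tr$fs)
}

#' Distribution specification for cohort sampling
#'
#' Describes how one [subject_truth] field is sampled across a cohort: a
#' normal distribution with the given mean and SD, truncated to
#' `[lower, upper]` by resampling. `sd = 0` gives a degenerate (fixed)
#' value.
#'
#' @param mean distribution mean.
#' @param sd standard deviation (`>= 0`).
#' @param lower,upper truncation bounds.
#' @return an object of class `param_spec`.
#' @export
param_spec <- function(mean, sd = 0, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("'sd' must be non-negative", call. = FALSE)
  if (lower > upper) stop("'lower' must not exceed 'upper'", call. = FALSE)
  if (mean < lower || mean > upper)
    stop("'mean' must lie within the truncation bounds", call. = FALSE)
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper),
            class = "param_spec")
}

sample_param <- function(spec, n_try = 100L) {
  if (spec$sd == 0) return(spec$mean)
  for (i in seq_len(n_try)) {
    x <- stats::rnorm(1, spec$mean, spec$sd)
    if (x >= spec$lower && x <= spec$upper) return(x)
  }
  stop("truncated-normal sampling failed: bounds too tight", call. = FALSE)
}

#' Default cohort parameter distributions
#'
#' Between-subject variability for [generate_cohort()]: moderate spread in
#' rate constants, pressures, timing, wave speed and excess-pulse amplitude,
#' emulating the heterogeneity of a healthy middle-aged population. Any field
#' can be overridden with a [param_spec] (or a fixed number).
#'
#' @param ... named [param_spec] (or single numeric) overrides for
#'   [subject_truth] fields.
#' @return named list of `param_spec` objects.
#' @examples
#' cohort_params(b = param_spec(2, 0.3, lower = 0.5))
#' @export
cohort_params <- function(...) {
  defaults <- list(
    a = param_spec(8, 2, lower = 2, upper = 20),
    b = param_spec(2, 0.4, lower = 0.5, upper = 5),
    Pinf = param_spec(mmhg_to_pa(60), mmhg_to_pa(6), lower = mmhg_to_pa(30),
                      upper = mmhg_to_pa(85)),
    P0 = param_spec(mmhg_to_pa(74), mmhg_to_pa(8), lower = mmhg_to_pa(50),
                    upper = mmhg_to_pa(100)),
    T = param_spec(0.95, 0.10, lower = 0.65, upper = 1.3),
    TN = param_spec(0.35, 0.02, lower = 0.28, upper = 0.45),
    c = param_spec(6, 1, lower = 3.5, upper = 12),
    rho = param_spec(1050),
    Rbar = param_spec(4e4, 6e3, lower = 2e4, upper = 8e4),
    ex_amp = param_spec(4000, 800, lower = 1500, upper = 8000),
    ex_onset = param_spec(0.02),
    ex_duration = param_spec(0.30, 0.02, lower = 0.2, upper = 0.33),
    refl_amp = param_spec(600, 150, lower = 100, upper = 1500),
    refl_onset = param_spec(0.14),
    refl_duration = param_spec(0.15),
    tail_amp = param_spec(400, 80, lower = 150, upper = 800),
    tail_duration = param_spec(0.08),
    noise_sd_P = param_spec(20),
    noise_sd_U = param_spec(0.004),
    fs = param_spec(200))
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(defaults))
      stop(sprintf("unknown subject_truth field '%s'", nm), call. = FALSE)
    defaults[[nm]] <- if (inherits(ov[[nm]], "param_spec")) ov[[nm]]
                      else param_spec(ov[[nm]])
  }
  defaults
}

#' Generate a synthetic cohort
#'
#' Samples `n` [subject_truth] parameter sets from per-field distributions and
#' generates one subject per draw. Per-subject seeds are derived
#' deterministically from the master seed, so the same call always returns an
#' identical cohort. Draws that violate the `subject_truth` invariants (e.g.
#' notch beyond the beat) are resampled up to `max_retry` times.
#'
#' @param n number of subjects, `>= 1`.
#' @param params named list of [param_spec]s as returned by [cohort_params()].
#' @param seed master integer seed.
#' @param max_retry resampling attempts per subject before failing.
#' @return an object of class `synthetic_cohort`: list with `subjects` (list
#'   of `synthetic_subject`) and `parameters` (data frame of sampled truth
#'   values, one row per subject, for audit).
#' @examples
#' coh <- generate_cohort(5, seed = 7)
#' coh$parameters$b
#' @export
generate_cohort <- function(n, params = cohort_params(), seed = 1L,
                            max_retry = 20L) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  truths <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (try in seq_len(max_retry)) {
        vals <- lapply(params, sample_param)
        tr <- tryCatch(do.call(subject_truth, vals), error = function(e) NULL)
        if (!is.null(tr)) return(tr)
      }
      stop(sprintf("could not sample a valid subject after %d retries",
                   max_retry), call. = FALSE)
    })
  })
  # per-subject noise seeds derived from the master seed, kept < 2^31
  sub_seeds <- (as.integer(seed) + 1000L * seq_len(n)) %% .Machine$integer.max
  subjects <- Map(generate_subject, truths, sub_seeds)
  audit <- do.call(rbind, lapply(truths, function(tr)
    as.data.frame(unclass(tr))))
  audit$subject_id <- seq_len(n)
  structure(list(subjects = subjects, parameters = audit, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects, master seed %d>\n",
              length(x$subjects), x$seed))
  invisible(x)
}
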