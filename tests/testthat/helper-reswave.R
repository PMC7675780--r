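# shared fixtures, all built in code

# a clean single-exponential diastolic beat: flat systolic ramp up to a peak,
# then exact decay toward Pinf (used where a fully model-matched diastole is
# needed without the generator)
make_decay_beat <- function(b = 2, Pinf = 9000, Pn = 12000, TN = 0.35,
                            T = 0.95, fs = 200, peak = 15000) {
  tt <- seq(0, T - 1 / fs, by = 1 / fs)
  p <- numeric(length(tt))
  sys <- tt < TN
  # smooth systolic arch from Pn up to peak and back to Pn at the notch
  p[sys] <- Pn + (peak - Pn) * sin(pi * tt[sys] / TN)
  p[!sys] <- (Pn - Pinf) * exp(-b * (tt[!sys] - TN)) + Pinf
  waveform(p, fs = fs, label = "pressure")
}

decay_annotation <- function(TN = 0.35, T = 0.95, fs = 200) {
  beat_annotation(1L, round(TN * fs) + 1L, T, fs)
}

# noiseless generator subject with clean diastole (no tail, no reflection)
clean_subject <- function(..., seed = 1) {
  generate_subject(subject_truth(noise_sd_P = 0, noise_sd_U = 0,
                                 tail_amp = 0, refl_amp = 0, ...),
                   seed = seed)
}

# noiseless clean subject in periodic steady state: P(0) matches the
# end-diastolic pressure, so concatenated copies form a continuous recording
periodic_subject <- function(..., seed = 1) {
  P0 <- mmhg_to_pa(74)
  for (i in 1:6) {
    s <- generate_subject(subject_truth(noise_sd_P = 0, noise_sd_U = 0,
                                        tail_amp = 0, refl_amp = 0,
                                        P0 = P0, ...), seed = seed)
    n <- length(s$P$values)
    P_end <- s$P$values[n] + (s$P$values[n] - s$P$values[n - 1])
    if (abs(P_end - P0) < 0.5) break
    P0 <- P_end
  }
  s
}

# half-sine pulse values (unit amplitude), duplicated here so the tests do
# not reach into the package internals
half_sine_vals <- function(t, onset, duration) {
  out <- numeric(length(t))
  inside <- t >= onset & t <= onset + duration
  out[inside] <- sin(pi * (t[inside] - onset) / duration)
  out
}

# independent ODE oracle for the reservoir relation, driven by the sampled
# pressure linearly interpolated in time
ode_reservoir_oracle <- function(P, a, b, Pinf) {
  tt <- wf_time(P)
  pf <- stats::approxfun(tt, P$values, rule = 2)
  k <- a + b
  sol <- deSolve::ode(c(Pr = P$values[1]), tt,
                      function(t, y, parms)
                        list(a * pf(t) - k * y[1] + b * Pinf),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-8)
  as.numeric(sol[, "Pr"])
}
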