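test_that("an exact water-hammer loop returns the constructed wave speed", {
  rho <- 1050; c_true <- 5
  tt <- seq(0, 0.95, by = 1 / 200)
  pex <- 3000 * half_sine_vals(tt, 0.02, 0.3)
  P <- waveform(pex + 9000, fs = 200)
  U <- waveform(pex / (rho * c_true), fs = 200)
  ws <- loop_wave_speed(P, U, rho = rho)
  expect_equal(ws$c, 5, tolerance = 1e-9)
  expect_equal(ws$slope, rho * c_true, tolerance = 1e-6)
  # slope 5250 Pa/(m/s) at rho 1050 is 5 m/s by definition
  expect_equal(5250 / 1050, 5)
})

test_that("wave speed is invariant to constant offsets in P and U", {
  s <- clean_subject()
  c0 <- loop_wave_speed(s$Pex_true, s$Uex_true)$c
  P2 <- waveform(s$Pex_true$values + 2000, fs = 200)
  U2 <- waveform(s$Uex_true$values + 0.3, fs = 200)
  expect_equal(loop_wave_speed(P2, U2)$c, c0, tolerance = 1e-9)
})

test_that("the excess loop recovers c_true even with a mid-systolic reflection", {
  for (c_true in c(4, 6, 9, 12)) {
    s <- generate_subject(subject_truth(c = c_true, noise_sd_P = 0,
                                        noise_sd_U = 0), seed = 2)
    ws <- loop_wave_speed(s$Pex_true, s$Uex_true)
    expect_lt(abs(ws$c - c_true) / c_true, 0.03)
  }
})

test_that("wave-speed estimation fails informatively on degenerate loops", {
  P <- waveform(rep(9000, 100), fs = 200)
  U <- waveform(rep(0.1, 100), fs = 200)
  expect_error(loop_wave_speed(P, U), "linear")
})

test_that("intensity separation matches hand-evaluated increments", {
  # single increments dP = 100 Pa, dU = 0.01 m/s at rho c = 5250
  P <- waveform(c(rep(1000, 8), 1000 + cumsum(rep(100, 8))), fs = 200)
  U <- waveform(c(rep(0.1, 8), 0.1 + cumsum(rep(0.01, 8))), fs = 200)
  sep <- separate_wave_intensity(P, U, rho = 1050, c = 5)
  i <- 10L  # an interior all-moving increment
  expect_equal(sep$dI_plus[i], 152.5^2 / 21000, tolerance = 1e-12)
  expect_equal(sep$dI_minus[i], -47.5^2 / 21000, tolerance = 1e-12)
})

test_that("forward-only motion has identically zero backward intensity", {
  s <- clean_subject()
  sep <- separate_wave_intensity(s$Pex_true, s$Uex_true, rho = s$truth$rho,
                                 c = s$truth$c)
  expect_lt(max(abs(sep$dI_minus)), 1e-12 * max(sep$dI_plus))
})

test_that("dI+ + dI- equals dP dU to machine precision on arbitrary signals", {
  set.seed(11)
  P <- waveform(10000 + 500 * rnorm(150), fs = 200)
  U <- waveform(0.3 + 0.05 * rnorm(150), fs = 200)
  sep <- separate_wave_intensity(P, U, rho = 1050, c = 7)
  expect_lt(max(abs(sep$dI_plus + sep$dI_minus - sep$dI)),
            1e-12 * max(abs(sep$dI)))
  expect_true(all(sep$dI_plus >= 0))
  expect_true(all(sep$dI_minus <= 0))
})

test_that("a half-sine intensity lobe integrates to 2Ad/pi", {
  fs <- 200; A <- 2; d <- 0.2
  tt <- seq(0, 0.95, by = 1 / fs)
  dIp <- A * half_sine_vals(tt, 0.05, d)
  ann <- beat_annotation(1L, 120L, 0.95, fs)
  ar <- wave_areas(dIp, rep(0, length(dIp)), ann, dt = 1 / fs)
  expect_equal(ar$FCW_area, 2 * A * d / pi, tolerance = 0.005 * 2 * A * d / pi)
  expect_equal(ar$FEW_area, 0)
  expect_equal(ar$BCW_area, 0)
  expect_true(ar$FEW_missing && ar$BCW_missing)
})

test_that("all-zero intensity yields zero areas without error", {
  ann <- beat_annotation(1L, 70L, 0.95, 200)
  ar <- wave_areas(rep(0, 189), rep(0, 189), ann, dt = 1 / 200)
  expect_equal(ar$FCW_area + ar$BCW_area + ar$FEW_area, 0)
})

test_that("the backward lobe area matches the injected reflected wave energy", {
  s <- generate_subject(subject_truth(refl_amp = 900, noise_sd_P = 0,
                                      noise_sd_U = 0), seed = 3)
  tr <- s$truth
  ann <- true_annotation(s)
  # oracle: intensity of the isolated backward component alone; only its
  # rising (compression) phase forms the BCW lobe - the falling phase is a
  # backward expansion wave
  Ub <- waveform(-s$Pex_bwd_true$values / (tr$rho * tr$c), fs = tr$fs)
  sep_b <- separate_wave_intensity(s$Pex_bwd_true, Ub, rho = tr$rho,
                                   c = tr$c)
  rising <- diff(s$Pex_bwd_true$values) > 0
  injected <- sum(-sep_b$dI_minus[rising]) * sep_b$dt
  res <- wia(s$Pex_true, s$Uex_true, ann, rho = tr$rho, source = "excess")
  expect_lt(abs(res$BCW_area - injected) / injected, 0.10)
})

test_that("without reflection the backward area is under 1% of the forward area", {
  s <- clean_subject()
  res <- wia(s$Pex_true, s$Uex_true, true_annotation(s), source = "excess")
  expect_lt(res$BCW_area, 0.01 * res$FCW_area)
})

test_that("measured-vs-excess comparison is zero on identical inputs and correct arithmetic", {
  s <- generate_subject(subject_truth(noise_sd_P = 0, noise_sd_U = 0),
                        seed = 4)
  ann <- true_annotation(s)
  cmp <- compare_measured_vs_excess(s$Pex_true, s$Uex_true,
                                    s$Pex_true, s$Uex_true, ann)
  expect_true(all(abs(cmp$pct_diff) < 1e-9, na.rm = TRUE))
  # percentage convention: PU 6.0 vs PexUex 5.0 is +20%
  expect_equal(percent_change(5, 6), 20)
})

test_that("the reservoir contribution makes PU-derived parameters exceed excess-derived ones", {
  s <- generate_subject(subject_truth(noise_sd_P = 0, noise_sd_U = 0),
                        seed = 4)
  ann <- true_annotation(s)
  fit <- decompose_pressure(s$P, ann, fit_config(3, "whole"))
  Rbar <- mean_diastolic_resistance(s$P, s$U, ann, fit$Pinf)
  split <- decompose_velocity(s$P, s$U, fit$Pinf, Rbar)
  cmp <- compare_measured_vs_excess(s$P, s$U, fit$Pex, split$Uex, ann)
  expect_gte(cmp$measured$c, cmp$excess$c)
  expect_gte(cmp$measured$FCW_area, cmp$excess$FCW_area)
})

test_that("Savitzky-Golay smoothing is near-exact on cubic signals and tames noise", {
  tt <- seq(0, 1, by = 1 / 200)
  cubic <- waveform(2 + 3 * tt - tt^2 + 0.5 * tt^3, fs = 200)
  sm <- smooth_waveform(cubic, 9)
  interior <- 10:190
  expect_lt(max(abs(sm$values[interior] - cubic$values[interior])), 1e-10)
  set.seed(5)
  noisy <- waveform(cubic$values + rnorm(length(tt), 0, 0.1), fs = 200)
  smn <- smooth_waveform(noisy, 9)
  expect_lt(sd(smn$values[interior] - cubic$values[interior]),
            0.7 * sd(noisy$values[interior] - cubic$values[interior]))
})
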