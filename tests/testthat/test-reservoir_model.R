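test_that("constant pressure at the asymptote is a fixed point of the reservoir relation", {
  P <- waveform(rep(8000, 200), fs = 200)
  Pr <- reservoir_pressure_full(P, a = 10, b = 2, Pinf = 8000)
  expect_lt(max(abs(Pr$values - 8000)), 1e-9)
})

test_that("with a = 0 the closed form is a pure decay independent of P", {
  set.seed(1)
  P <- waveform(10000 + 500 * rnorm(200), fs = 200)
  Pr <- reservoir_pressure_full(P, a = 0, b = 1.5, Pinf = 7000)
  tt <- wf_time(P)
  expected <- 7000 + (P$values[1] - 7000) * exp(-1.5 * tt)
  expect_lt(max(abs(Pr$values - expected)), 1e-9)
  expect_error(reservoir_pressure_full(P, a = 0, b = 0, Pinf = 7000),
               "asymptote")
})

test_that("closed form matches an independent adaptive ODE oracle on a half-sine beat", {
  tt <- seq(0, 0.95 - 1 / 200, by = 1 / 200)
  p <- 9000 + 4000 * half_sine_vals(tt, onset = 0.02, duration = 0.3)
  P <- waveform(p, fs = 200)
  Pr <- reservoir_pressure_full(P, a = 10, b = 2, Pinf = 8000)
  oracle <- ode_reservoir_oracle(P, a = 10, b = 2, Pinf = 8000)
  expect_lt(max(abs(Pr$values - oracle)), 0.1)
})

test_that("the stable weights survive very stiff rate constants without overflow", {
  P <- waveform(10000 + 2000 * sin(seq(0, pi, length.out = 400)), fs = 200)
  Pr <- reservoir_pressure_full(P, a = 90, b = 10, Pinf = 8000)
  expect_true(all(is.finite(Pr$values)))
  # with a + b large the reservoir tracks its quasi-steady target
  target <- (90 * P$values + 10 * 8000) / 100
  expect_lt(max(abs(Pr$values[-(1:40)] - target[-(1:40)])), 150)
})

test_that("the diastolic decay evaluates its boundary and hand-checked values", {
  expect_equal(diastolic_decay(0.35, 10665.6, 7999.2, b = 1, TN = 0.35),
               10665.6)
  expect_equal(diastolic_decay(c(0.4, 1.4), 10000, 10000, b = 0, TN = 0.4),
               c(10000, 10000))
  # 60 + 20 exp(-0.5) mmHg at half a second past the notch
  val <- diastolic_decay(0.85, mmhg_to_pa(80), mmhg_to_pa(60), b = 1,
                         TN = 0.35)
  expect_equal(pa_to_mmhg(val), 60 + 20 * exp(-0.5), tolerance = 1e-12)
  expect_equal(round(pa_to_mmhg(val), 2), 72.13)
  expect_error(diastolic_decay(0.2, 10000, 8000, b = 1, TN = 0.35), "TN")
})

test_that("all four configs recover (b, Pinf) exactly on model-matched decays", {
  beat <- make_decay_beat(b = 2, Pinf = 9000, Pn = 12000)
  ann <- decay_annotation()
  for (cf in standard_fit_configs()) {
    fit <- fit_diastole(beat, ann, cf)
    expect_lt(abs(fit$b - 2) / 2, 1e-6)
    expect_lt(abs(fit$Pinf - 9000) / 9000, 1e-6)
    expect_true(fit$converged)
    if (cf$dof == 2) expect_identical(fit$Pn_bar, fit$Pn)
  }
})

test_that("median fitted b stays within 5% of truth under 50 Pa noise (3 DOF whole)", {
  beat <- make_decay_beat(b = 2, Pinf = 9000, Pn = 12000)
  ann <- decay_annotation()
  cf <- fit_config(3, "whole")
  set.seed(101)
  b_hat <- replicate(250, {
    noisy <- waveform(beat$values + rnorm(length(beat$values), 0, 50),
                      fs = beat$fs)
    fit_diastole(noisy, ann, cf)$b
  })
  expect_lt(abs(median(b_hat) - 2) / 2, 0.05)
})

test_that("the last-two-thirds window fits its own window better when an early-diastolic bump is present", {
  s <- generate_subject(subject_truth(noise_sd_P = 0, noise_sd_U = 0,
                                      refl_amp = 0, tail_amp = 400),
                        seed = 1)
  ann <- true_annotation(s)
  fit_whole <- fit_diastole(s$P, ann, fit_config(3, "whole"))
  fit_23 <- fit_diastole(s$P, ann, fit_config(3, "last23"))
  idx23 <- fit_23$window_idx
  tt <- (idx23 - 1) / s$P$fs
  resid_on_23 <- function(f) {
    pr <- diastolic_decay(tt, f$Pn_bar, f$Pinf, f$b, ann$TN)
    sum((pr - s$P$values[idx23])^2)
  }
  expect_lt(resid_on_23(fit_23), resid_on_23(fit_whole))
})

test_that("window bookkeeping: whole covers diastole, last23 drops its first third", {
  beat <- make_decay_beat()
  ann <- decay_annotation()
  n <- length(beat$values)
  iw <- fit_diastole(beat, ann, fit_config(3, "whole"))$window_idx
  i23 <- fit_diastole(beat, ann, fit_config(3, "last23"))$window_idx
  expect_equal(iw, ann$notch_index:n)
  n_dia <- n - ann$notch_index + 1
  expect_equal(i23[1], ann$notch_index + ceiling(n_dia / 3))
  expect_equal(i23[length(i23)], n)
  short_ann <- beat_annotation(1L, n - 4L, ann$period_s, beat$fs)
  expect_error(fit_diastole(beat, short_ann, fit_config(3, "whole")),
               "window too short")
})

test_that("the systolic rate solve recovers a known rate constant", {
  # quadrature-limited: tight at a fine grid, still sub-0.1% at 200 Hz
  for (case in list(list(fs = 1000, tol = 1e-4), list(fs = 200, tol = 1e-3))) {
    tr <- subject_truth(a = 12, noise_sd_P = 0, noise_sd_U = 0,
                        tail_amp = 0, refl_amp = 0, fs = case$fs)
    s <- generate_subject(tr, seed = 1)
    ann <- true_annotation(s)
    Pn_bar <- s$Pr_true$values[ann$notch_index]
    sol <- solve_systolic_rate(s$P, b = tr$b, Pinf = tr$Pinf,
                               Pn_bar = Pn_bar, TN = ann$TN)
    expect_true(sol$converged)
    expect_lt(abs(sol$a - 12) / 12, case$tol)
  }
})

test_that("the boundary root a = 0 is found when the target sits at the a = 0 value", {
  s <- clean_subject()
  ann <- true_annotation(s)
  tr <- s$truth
  pr0 <- reservoir_pressure_full(s$P, a = 0, b = tr$b, Pinf = tr$Pinf)
  target <- pr0$values[ann$notch_index]
  sol <- solve_systolic_rate(s$P, b = tr$b, Pinf = tr$Pinf,
                             Pn_bar = target, TN = ann$TN)
  expect_lt(sol$a, 1e-6)
})

test_that("the solver agrees with a bisection oracle on the notch residual", {
  s <- clean_subject()
  ann <- true_annotation(s)
  tr <- s$truth
  Pn_bar <- s$Pr_true$values[ann$notch_index]
  resid <- function(a)
    reservoir_pressure_full(s$P, a, tr$b, tr$Pinf)$values[ann$notch_index] -
      Pn_bar
  # the residual is monotone in a on [0, 100]; bracket and bisect
  expect_lt(resid(0), 0)
  expect_gt(resid(100), 0)
  a_bis <- uniroot(resid, c(0, 100), tol = 1e-10)$root
  sol <- solve_systolic_rate(s$P, tr$b, tr$Pinf, Pn_bar, ann$TN)
  expect_lt(abs(sol$a - a_bis), 1e-6)
})

test_that("decompose_pressure satisfies its defining identities", {
  s <- clean_subject()
  ann <- true_annotation(s)
  fit <- decompose_pressure(s$P, ann, fit_config(3, "whole"))
  # conservation is definitional and exact
  expect_identical(max(abs(s$P$values - fit$Pr$values - fit$Pex$values)), 0)
  # model-matched data: near-zero diastolic error and truth recovery
  expect_lt(fit$X2, 1e-6)
  expect_lt(abs(fit$b - s$truth$b) / s$truth$b, 1e-6)
  expect_lt(abs(fit$Pinf - s$truth$Pinf) / s$truth$Pinf, 1e-6)
  # initial condition and notch continuity of the assembled waveform
  expect_equal(fit$Pr$values[1], s$P$values[1])
  expect_lt(abs(fit$Pr$values[ann$notch_index] - fit$Pn_bar), 1e-6)
  expect_true(fit$converged)
})

test_that("on noiseless model-matched data all four configs agree with truth", {
  s <- clean_subject()
  ann <- true_annotation(s)
  for (cf in standard_fit_configs()) {
    fit <- decompose_pressure(s$P, ann, cf)
    expect_lt(abs(fit$b - s$truth$b) / s$truth$b, 1e-4)
    expect_lt(abs(fit$Pinf - s$truth$Pinf) / s$truth$Pinf, 1e-4)
  }
})

test_that("an early-diastolic excess bump raises X2 more for 2 DOF than 3 DOF", {
  s <- generate_subject(subject_truth(noise_sd_P = 0, noise_sd_U = 0,
                                      tail_amp = 400), seed = 4)
  ann <- true_annotation(s)
  x2_3 <- decompose_pressure(s$P, ann, fit_config(3, "whole"))$X2
  x2_2 <- decompose_pressure(s$P, ann, fit_config(2, "whole"))$X2
  expect_lt(x2_3, x2_2)
})

test_that("the implied decay rate is strictly increasing in Pinf and diverges at Pn_bar", {
  Pn_bar <- 11000; Pr_hat <- 9500; t_hat <- 0.8; TN <- 0.35
  grid <- seq(0, Pr_hat - 1e-6, length.out = 50)
  b_grid <- implied_decay_rate(Pr_hat, t_hat, Pn_bar, grid, TN)
  expect_true(all(diff(b_grid) > 0))
  # near the vertical asymptote: with the data point itself close to Pn_bar,
  # pushing Pinf toward it makes b arbitrarily large
  Pr_close <- Pn_bar - 1  # 1 Pa below the notch value
  near <- Pr_close - 10^seq(0, -8, length.out = 50)
  b_near <- implied_decay_rate(Pr_close, t_hat, Pn_bar, near, TN)
  expect_true(all(diff(b_near) > 0))
  expect_gt(max(b_near), 30)
})
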