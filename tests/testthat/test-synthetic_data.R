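test_that("equilibrium truth is a fixed point: zero excess from Pinf gives flat P and zero U", {
  tr <- subject_truth(ex_amp = 0, refl_amp = 0, tail_amp = 0,
                      P0 = mmhg_to_pa(60), Pinf = mmhg_to_pa(60),
                      noise_sd_P = 0, noise_sd_U = 0)
  s <- generate_subject(tr, seed = 1)
  expect_lt(max(abs(s$P$values - tr$Pinf)), 1e-6)
  expect_lt(max(abs(s$U$values)), 1e-12)
})

test_that("with a = 0 the reservoir decays exponentially regardless of excess", {
  tr <- subject_truth(a = 0, ex_amp = 0, refl_amp = 0, tail_amp = 0,
                      noise_sd_P = 0, noise_sd_U = 0)
  s <- generate_subject(tr, seed = 1)
  tt <- wf_time(s$P)
  expected <- tr$Pinf + (tr$P0 - tr$Pinf) * exp(-tr$b * tt)
  expect_lt(max(abs(s$Pr_true$values - expected)), 1e-6)
})

test_that("components are conserved by construction at every sample", {
  s <- generate_subject(subject_truth(noise_sd_P = 0, noise_sd_U = 0),
                        seed = 3)
  expect_lt(max(abs(s$P$values - s$Pr_true$values - s$Pex_true$values)), 1e-9)
  expect_lt(max(abs(s$U$values - s$Ur_true$values - s$Uex_true$values)), 1e-15)
  expect_lt(max(abs(s$Pex_true$values - s$Pex_fwd_true$values -
                    s$Pex_bwd_true$values)), 1e-12)
})

test_that("noiseless diastole with zero excess tail follows the exponential decay exactly", {
  s <- clean_subject()
  tr <- s$truth
  ann <- true_annotation(s)
  idx <- ann$notch_index:length(s$P$values)
  tt <- wf_time(s$P)[idx]
  Pn_bar <- s$Pr_true$values[ann$notch_index]
  expected <- diastolic_decay(tt, Pn_bar, tr$Pinf, tr$b, ann$TN)
  expect_lt(max(abs(s$P$values[idx] - expected)), 1e-5)
})

test_that("identical (truth, seed) gives bit-identical subjects", {
  tr <- subject_truth()
  s1 <- generate_subject(tr, seed = 17)
  s2 <- generate_subject(tr, seed = 17)
  expect_identical(s1$P$values, s2$P$values)
  expect_identical(s1$U$values, s2$U$values)
  s3 <- generate_subject(tr, seed = 18)
  expect_false(identical(s1$P$values, s3$P$values))
})

test_that("invalid truth fields name the offending field", {
  expect_error(subject_truth(TN = 2, T = 1), "TN")
  expect_error(subject_truth(b = -1), "'b'")
  expect_error(subject_truth(ex_duration = 0.9), "ex_duration")
  expect_error(subject_truth(noise_sd_P = -5), "noise_sd_P")
})

test_that("round trip: decomposing generated P with the exact parameters recovers Pex", {
  # quadrature error falls with the square of the sampling interval; at a
  # fine grid the recovered excess matches the stored truth to 1e-6 x amp
  tr <- subject_truth(noise_sd_P = 0, noise_sd_U = 0, fs = 8000)
  s <- generate_subject(tr, seed = 1)
  pr <- reservoir_pressure_full(s$P, tr$a, tr$b, tr$Pinf)
  pex <- s$P$values - pr$values
  expect_lt(max(abs(pex - s$Pex_true$values)), 1e-6 * tr$ex_amp)
  # at the default 200 Hz grid the same round trip is sampling-limited but
  # still tracks the truth to a fraction of a percent of the pulse amplitude
  s2 <- generate_subject(subject_truth(noise_sd_P = 0, noise_sd_U = 0),
                         seed = 1)
  pr2 <- reservoir_pressure_full(s2$P, s2$truth$a, s2$truth$b, s2$truth$Pinf)
  expect_lt(max(abs((s2$P$values - pr2$values) - s2$Pex_true$values)),
            1e-3 * s2$truth$ex_amp)
})

test_that("degenerate zero-variance cohort reproduces generate_subject on the means", {
  prm <- cohort_params()
  for (nm in names(prm)) prm[[nm]]$sd <- 0
  coh <- generate_cohort(1, prm, seed = 5)
  means <- lapply(prm, `[[`, "mean")
  ref <- generate_subject(do.call(subject_truth, means),
                          seed = coh$subjects[[1]]$seed)
  expect_identical(coh$subjects[[1]]$P$values, ref$P$values)
})

test_that("cohorts are deterministic in the master seed", {
  c1 <- generate_cohort(8, seed = 42)
  c2 <- generate_cohort(8, seed = 42)
  for (i in seq_len(8)) {
    expect_identical(c1$subjects[[i]]$P$values, c2$subjects[[i]]$P$values)
    expect_identical(c1$subjects[[i]]$U$values, c2$subjects[[i]]$U$values)
  }
  expect_equal(nrow(c1$parameters), 8)
})

test_that("cohort-sampled b is recovered on average by the 3-DOF whole-window fit", {
  n <- 60
  coh <- generate_cohort(
    n, cohort_params(b = param_spec(2.0, 0.3, lower = 0.5),
                     tail_amp = 0, refl_amp = 0,
                     noise_sd_P = 0, noise_sd_U = 0),
    seed = 9)
  b_hat <- vapply(coh$subjects, function(s) {
    fit_diastole(s$P, true_annotation(s), fit_config(3, "whole"))$b
  }, numeric(1))
  b_true <- coh$parameters$b
  # noiseless model-matched fits recover each subject's own b
  expect_lt(max(abs(b_hat - b_true) / b_true), 1e-6)
  # and the sample mean sits within 3 SE of the sampling mean 2.0
  se <- sd(b_hat) / sqrt(n)
  expect_lt(abs(mean(b_hat) - 2.0), 3 * se + 1e-9)
})
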