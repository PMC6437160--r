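test_that("kinetic_trace validates its invariants", {
  expect_error(kinetic_trace(1:5, 1:5), ">= 8")
  expect_error(kinetic_trace(c(1:7, 7), rnorm(8)), "increasing")
  expect_error(kinetic_trace(1:8, 1:7), "mismatch")
  tr <- kinetic_trace(1:8, rep(0, 8), unit = "min")
  expect_s3_class(tr, "kinetic_trace")
  expect_identical(tr$unit, "min")
})

test_that("fit_single_exponential recovers noiseless rates to 1e-6 relative", {
  for (rate in c(150, 13.9, 0.22)) {
    t <- seq(6.8e-4, 6 / rate, length.out = 200)
    tr <- kinetic_trace(t, 0.18 - 0.13 * exp(-rate * t), wavelength_nm = 418)
    f <- fit_single_exponential(tr)
    expect_true(f$converged)
    expect_lt(abs(f$rate - rate) / rate, 1e-6)
  }
})

test_that("constant traces are flagged as degenerate, not fitted", {
  tr <- kinetic_trace(seq_len(50), rep(0.3, 50))
  f <- fit_single_exponential(tr)
  expect_false(f$converged)
  expect_identical(f$reason, "degenerate amplitude")
  expect_lt(abs(f$amplitude), 1e-9)
})

test_that("k_obs at published assay conditions is recovered within 5%", {
  k_on <- 1.16e7; k_off <- 13.92   # K_D * k_on with K_D = 1.2 uM
  tr <- gen_binding_traces(k_on, k_off, o2_concs = 10e-6,
                           noise = noise_spec(0.002, 31))[[1]]
  f <- fit_single_exponential(tr)
  truth <- k_on * 1e-5 + k_off
  expect_lt(abs(f$rate - truth) / truth, 0.05)
})

test_that("fit_kobs_vs_conc matches the closed-form WLS oracle", {
  # exact points on a line: recovered exactly
  conc <- c(5, 10, 20) * 1e-6
  kobs <- 5.6e6 * conc + 47
  bk <- fit_kobs_vs_conc(conc, kobs)
  expect_equal(bk$k_on, 5.6e6, tolerance = 1e-9)
  expect_equal(bk$k_off, 47, tolerance = 1e-9)
  expect_equal(bk$K_D, 47 / 5.6e6, tolerance = 1e-9)
  # weighted 3-point case vs independent closed form
  set.seed(99)
  kobs_n <- kobs + rnorm(3, 0, 3)
  se <- c(1, 2, 4)
  bk_w <- fit_kobs_vs_conc(conc, kobs_n, se = se)
  orc <- wls_oracle(conc, kobs_n, w = 1 / se^2)
  expect_equal(bk_w$k_on, unname(orc["slope"]), tolerance = 1e-10)
  expect_equal(bk_w$k_off, unname(orc["intercept"]), tolerance = 1e-10)
  # degenerate flat input: slope ~ 0, K_D flagged undetermined
  flat <- fit_kobs_vs_conc(conc, rep(30, 3))
  expect_false(flat$K_D_determined)
  expect_true(is.na(flat$K_D))
  expect_error(fit_kobs_vs_conc(c(1e-6, 1e-6, 1e-6), c(1, 2, 3)), "distinct")
  expect_error(fit_kobs_vs_conc(conc[1:2], kobs[1:2]), "distinct")
})

test_that("full synthetic wild-type panel recovers K_D near 1.2 uM", {
  k_on <- 1.16e7; kd_true <- 1.2e-6
  traces <- gen_binding_traces(k_on, kd_true * k_on,
                               noise = noise_spec(0.002, 7))
  fits <- lapply(traces, fit_single_exponential)
  bk <- fit_kobs_vs_conc(vapply(traces, function(x) x$ligand_conc, numeric(1)),
                         vapply(fits, function(f) f$rate, numeric(1)),
                         se = vapply(fits, function(f) f$rate_se, numeric(1)))
  expect_lt(abs(bk$k_on - k_on) / k_on, 0.05)
  expect_lt(abs(bk$K_D - kd_true) / kd_true, 0.15)
})

test_that("hemin-loss rates are recovered at all Table-style truths", {
  # noiseless: exact to 1e-6
  tr0 <- gen_hemin_loss_trace(1.44, noise = noise_spec(0, NULL))
  f0 <- fit_hemin_loss(tr0)
  expect_lt(abs(f0$rate - 1.44) / 1.44, 1e-6)
  expect_identical(f0$unit, "h")
  # noisy recovery within 5%, and the variant/WT ratio ~ 5 at pH 7
  f_wt <- suppressWarnings(   # 350 min is just under 2 half-lives at 0.22/h
    fit_hemin_loss(gen_hemin_loss_trace(0.22, noise = noise_spec(0.002, 11))))
  f_mut <- fit_hemin_loss(gen_hemin_loss_trace(1.19,
                                               noise = noise_spec(0.002, 12)))
  expect_lt(abs(f_wt$rate - 0.22) / 0.22, 0.05)
  expect_lt(abs(f_mut$rate - 1.19) / 1.19, 0.05)
  expect_equal(unname(f_mut$rate / f_wt$rate), 1.19 / 0.22, tolerance = 0.1)
  # unit discipline: a seconds trace is rejected, not converted
  tr_s <- kinetic_trace(1:10, exp(-(1:10)), unit = "s")
  expect_error(fit_hemin_loss(tr_s), "unit")
})

test_that("short hemin-loss records warn about < 2 half-lives", {
  tr <- gen_hemin_loss_trace(0.1, t_grid_min = seq(0, 120, 2),
                             noise = noise_spec(0.001, 4))
  expect_warning(fit_hemin_loss(tr), "half-lives")
})

test_that("autoxidation rate is recovered from spectral series", {
  b <- mb_basis()
  # noiseless: exact
  ser0 <- gen_autoxidation_series(1.96, seq(0, 2.5, length.out = 25),
                                  noise = noise_spec(0, NULL))
  f0 <- fit_autoxidation(ser0, b)
  expect_lt(abs(f0$rate - 1.96) / 1.96, 1e-6)
  # noisy: within 5%
  ser <- gen_autoxidation_series(1.96, seq(0, 2.5, length.out = 25),
                                 noise = noise_spec(0.002, 17))
  f <- fit_autoxidation(ser, b)
  expect_lt(abs(f$rate - 1.96) / 1.96, 0.05)
  # degenerate: constant series flagged
  cs <- gen_autoxidation_series(0, seq(0, 2, length.out = 10),
                                noise = noise_spec(0, NULL))
  fc <- fit_autoxidation(cs, b)
  expect_identical(fc$reason, "f_met non-increasing")
})

test_that("rate recovery is unbiased over replicates (property)", {
  # 200 seeded replicates at sigma = 0.002: median relative error < 2%,
  # 95% of replicates within 10%
  errs <- vapply(1:200, function(s) {
    tr <- gen_hemin_loss_trace(1.19, t_grid_min = seq(0, 350, by = 5),
                               noise = noise_spec(0.002, s))
    abs(fit_hemin_loss(tr)$rate - 1.19) / 1.19
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
  expect_gte(mean(errs <= 0.10), 0.95)
})
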