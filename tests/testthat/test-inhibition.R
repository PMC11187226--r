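test_that("the hyperbolic inhibition fit is exact on model-generated points", {
  f <- fit_ki(exact_kobs_series())
  expect_equal(f$k_max, 0.04, tolerance = 1e-8)
  expect_equal(f$K_i, 2.0, tolerance = 1e-8)
  # half-saturation identity: at [I] = K_i the model gives k_max / 2
  expect_equal(f$k_max / (1 + f$K_i / f$K_i), f$k_max / 2)
})

test_that("a series generated at the measured K_i of the lead inhibitor is recovered", {
  ser <- generate_kobs_series(0.037, ki_intronistat_B["est"],
                              noise_sd = 0.01, replicates = 3, seed = 3)
  f <- fit_ki(ser)
  expect_lt(abs(f$K_i - ki_intronistat_B[["est"]]), 3 * f$se[["K_i"]])
  # noiseless series recovers the constant to optimizer precision
  f0 <- fit_ki(generate_kobs_series(0.037, ki_intronistat_B[["est"]]))
  expect_equal(f0$K_i, ki_intronistat_B[["est"]], tolerance = 1e-8)
})

test_that("fitted K_i scales linearly with the concentration unit", {
  set.seed(7)
  ser <- generate_kobs_series(0.05, 3, noise_sd = 0.05, seed = 21)
  f1 <- fit_ki(ser)
  ser2 <- ser; ser2$conc_uM <- ser$conc_uM * 1000
  f2 <- fit_ki(ser2)
  expect_equal(f2$K_i, 1000 * f1$K_i, tolerance = 1e-6)
  expect_equal(f2$k_max, f1$k_max, tolerance = 1e-6)
})

test_that("flat k_obs series are flagged non-identifiable; bad input errors", {
  flat <- data.frame(conc_uM = c(0, 5, 50), kobs_per_min = rep(0.03, 3))
  expect_true(fit_ki(flat)$nonidentifiable)
  expect_error(fit_ki(data.frame(conc_uM = c(0, 5),
                                 kobs_per_min = c(0.03, 0.02))), "3")
  expect_error(fit_ki(data.frame(conc_uM = c(0, 0, 5),
                                 kobs_per_min = c(0.03, 0.03, 0.02))),
               "distinct")
})

test_that("reacted-precursor normalisation maps the references to 100 and 0", {
  rec <- data.frame(conc_uM = c(0, 5, 250),
                    frac_precursor_15min = c(0.2, 0.55, 0.9),
                    is_dmso = c(TRUE, FALSE, FALSE),
                    is_imax = c(FALSE, FALSE, TRUE))
  out <- percent_reacted_precursor(rec)
  expect_equal(out$percent, c(100, 50, 0))
  # affine-map property against direct formula evaluation on random records
  set.seed(5)
  for (i in 1:20) {
    f <- runif(6)
    rec <- data.frame(conc_uM = c(0, 1, 2, 5, 10, 250),
                      frac_precursor_15min = f,
                      is_dmso = c(TRUE, rep(FALSE, 5)),
                      is_imax = c(rep(FALSE, 5), TRUE))
    out <- percent_reacted_precursor(rec)
    expect_equal(out$percent, 100 * (f[6] - f) / (f[6] - f[1]))
  }
  rec$frac_precursor_15min <- rep(0.4, 6)
  expect_error(percent_reacted_precursor(rec), "coincide")
})

test_that("IC50 fitting is exact on the model and calibrated under FRET-style noise", {
  d <- generate_dose_response(2.3)
  f <- fit_ic50(d, "percent_reacted_precursor")
  expect_equal(f$IC50, 2.3, tolerance = 1e-8)
  expect_equal(100 / (1 + f$IC50 / f$IC50), 50)  # half-response at IC50
  ok <- vapply(1:100, function(s) {
    fs <- fit_ic50(generate_dose_response(2.5, noise_sd = 3, seed = s),
                   "percent_activity")
    abs(fs$IC50 - 2.5) <= 2 * fs$se
  }, logical(1L))
  expect_gte(mean(ok), 0.9)
})

test_that("FRET initial slopes convert to percent activity relative to DMSO", {
  tt <- seq(0, 60, by = 2)
  dmso <- data.frame(time = tt, signal = 5 + 0.8 * tt)
  traces <- list(data.frame(time = tt, signal = 5 + 0.8 * tt),
                 data.frame(time = tt, signal = rep(5, length(tt))),
                 data.frame(time = tt, signal = 5 + 0.4 * tt))
  out <- fret_initial_slopes(traces, c(0, 1000, 2.5), dmso)
  expect_equal(out$percent, c(100, 0, 50), tolerance = 1e-9)
  flat_ref <- data.frame(time = tt, signal = rep(1, length(tt)))
  expect_error(fret_initial_slopes(traces, c(0, 1000, 2.5), flat_ref),
               "positive")
})

test_that("step selectivity reproduces the fold-changes of the printed constants", {
  sel <- step_selectivity(control_rates(), inhibited_rates_50uM())
  expect_equal(sel$fold_1, 0.037 / 0.007, tolerance = 1e-12)
  expect_equal(sel$fold_2, 31, tolerance = 1e-12)
  expect_equal(sel$selectivity_ratio, 31 / (0.037 / 0.007), tolerance = 1e-12)
  same <- step_selectivity(control_rates(), control_rates())
  expect_equal(unlist(same), c(fold_1 = 1, fold_2 = 1,
                               selectivity_ratio = 1))
})
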