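test_that("gel generation with zero noise reproduces the model exactly and is seed-stable", {
  d0 <- assay_design(concentrations = c(0, 50), replicates = 2,
                     noise_sd = 0, seed = 3)
  rates <- list(`0` = control_rates(), `50` = inhibited_rates_50uM())
  g <- generate_gel_timecourses(rates, d0)
  ref <- species_fractions(d0$timepoints, control_rates())
  r1 <- g[g$conc_uM == 0 & g$replicate == "r1", ]
  expect_equal(r1$frac_precursor, ref$precursor)
  expect_equal(r1$frac_intermediate, ref$intermediate)
  dn <- assay_design(concentrations = 0, replicates = 3, noise_sd = 0.02,
                     seed = 7)
  a <- generate_gel_timecourses(list(`0` = control_rates()), dn)
  b <- generate_gel_timecourses(list(`0` = control_rates()), dn)
  expect_identical(a, b)
  # distinct replicate streams
  expect_false(identical(a[a$replicate == "r1", "frac_precursor"],
                         a[a$replicate == "r2", "frac_precursor"]))
})

test_that("noisy gel fractions are valid and unbiased in the replicate mean", {
  # the intensity noise is truncated at zero, which biases species whose
  # true fraction sits near the boundary; the law-of-large-numbers check
  # therefore uses grid points where all three species are well away from
  # 0 and 1 (>= 3 noise s.d.)
  d <- assay_design(concentrations = 0, replicates = 1000, noise_sd = 0.02,
                    seed = 99, timepoints = c(15, 30, 60))
  g <- generate_gel_timecourses(list(`0` = control_rates()), d)
  expect_true(all(g$frac_precursor >= 0 & g$frac_precursor <= 1))
  sums <- g$frac_precursor + g$frac_intermediate + g$frac_product
  expect_lt(max(abs(sums - 1)), 1e-12)
  ref <- species_fractions(d$timepoints, control_rates())
  expect_true(all(as.matrix(ref[, 2:4]) >= 3 * d$noise_sd))
  for (sp in c("frac_precursor", "frac_intermediate", "frac_product")) {
    means <- tapply(g[[sp]], g$time_min, mean)
    truth <- switch(sp, frac_precursor = ref$precursor,
                    frac_intermediate = ref$intermediate,
                    frac_product = ref$product)
    expect_lt(max(abs(means[as.character(d$timepoints)] - truth)), 0.005)
  }
})

test_that("k_obs generation hits the model identities and round-trips the fit", {
  s <- generate_kobs_series(0.04, 2, concentrations = c(0, 2, 10))
  expect_equal(s$kobs_per_min[s$conc_uM == 0], 0.04)
  expect_equal(s$kobs_per_min[s$conc_uM == 2], 0.02)
  f <- fit_ki(generate_kobs_series(0.04, 2))
  expect_equal(f$k_max, 0.04, tolerance = 1e-8)
  expect_equal(f$K_i, 2, tolerance = 1e-8)
  a <- generate_kobs_series(0.04, 2, noise_sd = 0.05, seed = 5)
  expect_identical(a, generate_kobs_series(0.04, 2, noise_sd = 0.05,
                                           seed = 5))
})

test_that("ITC and BLI generators delegate to the forward models deterministically", {
  p <- binding_thermodynamics(7.58e-6, -10.04, 1)
  expect_identical(generate_itc(p, seed = 2)$heats,
                   simulate_itc(p, seed = 2)$heats)
  noisy <- generate_itc(p, noise_sd = 0.1, seed = 2)
  expect_identical(noisy$heats, generate_itc(p, noise_sd = 0.1,
                                             seed = 2)$heats)
  kin <- bli_kinetics(10.1, 132, 0.001, 0.026, 0.5, 0.5)
  expect_identical(generate_bli(kin, seed = 4),
                   simulate_bli(kin, seed = 4))
  nb <- generate_bli(kin, noise_sd = 0.005, seed = 4)
  expect_identical(nb, generate_bli(kin, noise_sd = 0.005, seed = 4))
  # noiseless generation composed with the matching fit is the identity
  fit <- fit_itc_single_site(generate_itc(p))
  expect_equal(fit$thermo$K_D, p$K_D, tolerance = 1e-4)
})
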