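test_that("the forward model matches an independent equilibrium root-finder at every injection", {
  p <- binding_thermodynamics(7.58e-6, -10.04, 0.95)
  d <- itc_design()
  tit <- simulate_itc(p, d)
  # replay the dilution bookkeeping, solving each equilibrium by uniroot
  V0 <- d$cell_volume_L
  M <- d$cell_conc_M; X <- 0; mx_prev <- 0
  for (i in seq_along(d$injection_volumes_L)) {
    v <- d$injection_volumes_L[i]
    f <- 1 - v / V0
    M <- M * f
    X <- X * f + d$syringe_conc_M * v / V0
    S <- p$N * M
    mx <- uniroot(function(m) m * p$K_D - (S - m) * (X - m),
                  c(0, min(S, X)), tol = 1e-18)$root
    q <- p$deltaH * V0 * (mx - mx_prev * f) / (d$syringe_conc_M * v)
    expect_equal(tit$heats$heat_kcal_per_mol[i], q, tolerance = 1e-7)
    mx_prev <- mx
  }
})

test_that("ligand and receptor mass are conserved through all injections", {
  p <- binding_thermodynamics(5e-6, -8, 1.1)
  tit <- simulate_itc(p, itc_design())
  expect_lt(tit$mass_balance$ligand_rel_error, 1e-9)
  expect_lt(tit$mass_balance$receptor_rel_error, 1e-9)
})

test_that("saturation limits of the heat profile behave physically", {
  # tight binding, small first injection: per-mole heat of the first
  # injection approaches the molar enthalpy
  tight <- binding_thermodynamics(1e-9, -12, 1)
  tit <- simulate_itc(tight, itc_design())
  expect_equal(tit$heats$heat_kcal_per_mol[1L], -12, tolerance = 0.12)
  # total heat over full, rapid saturation ~ N dH (cell moles)
  d <- itc_design(syringe_conc_M = 6000e-6,
                  injection_volumes_L = rep(1e-6, 12L))
  tit2 <- simulate_itc(tight, d)
  tot <- sum(tit2$heats$heat_kcal_per_mol * d$syringe_conc_M *
               d$injection_volumes_L)
  ref <- tight$N * tight$deltaH * d$cell_conc_M * d$cell_volume_L
  expect_equal(tot, ref, tolerance = 0.01)
  # zero enthalpy: all heats vanish and the fit flags non-identifiability
  z <- binding_thermodynamics(5e-6, 0, 1)
  titz <- simulate_itc(z, itc_design())
  expect_true(all(titz$heats$heat_kcal_per_mol == 0))
  expect_true(fit_itc_single_site(titz)$nonidentifiable)
})

test_that("the single-site fit round-trips the generating parameters", {
  p <- binding_thermodynamics(7.58e-6, -10.04, 1)
  fit <- fit_itc_single_site(simulate_itc(p))
  expect_equal(fit$thermo$K_D, p$K_D, tolerance = 1e-4)
  expect_equal(fit$thermo$deltaH, p$deltaH, tolerance = 1e-4)
  expect_equal(fit$thermo$N, 1, tolerance = 1e-4)
  expect_equal(fit$offset, 0, tolerance = 1e-4)
  # derived quantities satisfy the Gibbs identity
  expect_equal(fit$thermo$deltaG,
               fit$thermo$deltaH + fit$thermo$minus_TdS, tolerance = 1e-9)
  expect_gt(fit$c_value, 1)
})

test_that("K_D is recovered within 25 percent under 2 percent heat noise", {
  p <- binding_thermodynamics(7.58e-6, -10.04, 1)
  err <- vapply(1:40, function(s) {
    f <- fit_itc_single_site(generate_itc(p, noise_sd = 0.02 * 10.04,
                                          seed = s))
    abs(f$thermo$K_D - p$K_D) / p$K_D
  }, numeric(1L))
  expect_lt(median(err), 0.25)
})

test_that("a c-value outside the fittable range triggers a warning", {
  weak <- binding_thermodynamics(0.05, -8, 1)  # c ~ 6e-4
  tit <- simulate_itc(weak, itc_design())
  expect_warning(fit_itc_single_site(tit), "c-value")
})
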