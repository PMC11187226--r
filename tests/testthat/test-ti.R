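test_that("the lambda schedule reproduces published Gauss-Legendre tables", {
  s1 <- gauss_legendre_schedule(1)
  expect_equal(s1$nodes, 0.5)
  expect_equal(s1$weights, 1)
  s2 <- gauss_legendre_schedule(2)
  expect_equal(s2$nodes, c(0.21132, 0.78868), tolerance = 1e-5)
  s12 <- gauss_legendre_schedule(12)
  expect_equal(round(s12$nodes, 5), published_lambdas)
  expect_equal(round(s12$weights[1:6], 5), published_weights6)
  # independent reference implementation, orders 2..24
  library(pracma)
  for (n in 2:24) {
    ref <- pracma::gaussLegendre(n, 0, 1)
    s <- gauss_legendre_schedule(n)
    expect_lt(max(abs(s$nodes - ref$x)), 1e-10)
    expect_lt(max(abs(s$weights - ref$w)), 1e-10)
  }
  expect_error(gauss_legendre_schedule(0), "order")
  expect_error(gauss_legendre_schedule(65), "order")
})

test_that("schedule nodes and weights carry the mirror symmetry of the rule", {
  for (n in c(3, 8, 12, 17)) {
    s <- gauss_legendre_schedule(n)
    expect_true(all(diff(s$nodes) > 0))
    expect_equal(s$nodes, rev(1 - s$nodes), tolerance = 1e-12)
    expect_equal(s$weights, rev(s$weights), tolerance = 1e-12)
    expect_equal(sum(s$weights), 1, tolerance = 1e-12)
    expect_true(all(s$weights > 0))
  }
})

test_that("window sampling matches the closed-form Gaussian moments", {
  sys <- harmonic_system(1, 4)
  for (lam in c(0.00922, 0.43738, 0.99078)) {
    smp <- sample_dudl(sys, lam, n_steps = 4000, seed = 99)
    expect_lt(abs(smp$mean - exact_dudl_mean(sys, lam)), 3 * smp$se)
    expect_false(smp$acceptance_warning)
  }
})

test_that("identical end states give identically zero dU/dlambda", {
  sys <- harmonic_system(2, 2)
  smp <- sample_dudl(sys, 0.5, n_steps = 500, seed = 4)
  expect_equal(smp$mean, 0)
  expect_equal(smp$var, 0)
})

test_that("window sampling is bit-reproducible for a fixed seed and leaves the RNG alone", {
  sys <- harmonic_system(1, 3)
  set.seed(123); before <- runif(1)
  a <- sample_dudl(sys, 0.3, n_steps = 800, seed = 42)
  set.seed(123); mid <- runif(1)
  b <- sample_dudl(sys, 0.3, n_steps = 800, seed = 42)
  expect_identical(a$mean, b$mean)
  expect_identical(a$var, b$var)
  expect_identical(before, mid)
})

test_that("quadrature of exact window means recovers closed-form free energies", {
  sch <- gauss_legendre_schedule(12)
  systems <- list(
    harmonic_system(1, 4),
    toy_alchemical_system("shifted_well", list(k = 2, mu = -1),
                          list(k = 2, mu = 1.5)),
    toy_alchemical_system("linear_field", list(k = 1, b = 0),
                          list(k = 3, b = 2), kT = 0.5, dim = 2))
  for (sys in systems) {
    samples <- lapply(sch$nodes, function(l)
      list(lambda = l, mean = exact_dudl_mean(sys, l), se = 0))
    est <- estimate_deltaG(sch, samples)
    expect_equal(est$deltaG, exact_deltaG(sys), tolerance = 1e-6)
  }
  # harmonic morph: dG = (kT/2) ln(k_B/k_A)
  expect_equal(exact_deltaG(harmonic_system(1, 4)), 0.5 * log(4))
})

test_that("Gauss quadrature integrates polynomial window means exactly", {
  sch <- gauss_legendre_schedule(12)
  set.seed(8)
  co <- runif(24, -2, 2)  # degree 23 = 2 * order - 1
  samples <- lapply(sch$nodes, function(l)
    list(lambda = l, mean = sum(co * l^(0:23)), se = 0))
  est <- estimate_deltaG(sch, samples)
  expect_equal(est$deltaG, sum(co / (1:24)), tolerance = 1e-12)
})

test_that("schedule/sample mismatches raise a domain error", {
  sch <- gauss_legendre_schedule(3)
  samples <- lapply(c(0.1, 0.5, 0.9), function(l)
    list(lambda = l, mean = 0, se = 0))
  expect_error(estimate_deltaG(sch, samples), "match")
  expect_error(estimate_deltaG(sch, samples[1:2]), "one window sample")
})

test_that("cycle assembly does arithmetic and error quadrature only", {
  cyc <- assemble_cycle(list(deltaG = -5, se = 0.1),
                        list(deltaG = -3, se = 0.1))
  expect_equal(cyc$ddG, -2)
  expect_equal(cyc$se, sqrt(0.02), tolerance = 1e-12)
  same <- assemble_cycle(list(deltaG = -4, se = 0.2),
                         list(deltaG = -4, se = 0.2))
  expect_equal(same$ddG, 0)
})

test_that("end-to-end TI runs recover closed-form ddG and respect symmetry and seeds", {
  b <- harmonic_system(1, 4)
  u <- harmonic_system(1, 2)
  cyc <- run_ti(b, u, n_steps = 1500, seed = 5)
  expect_lt(abs(cyc$ddG - (0.5 * log(4) - 0.5 * log(2))), 3 * cyc$se)
  # null transformation
  null <- run_ti(b, b, n_steps = 800, seed = 6)
  expect_lt(abs(null$ddG), 3 * max(null$se, 1e-12))
  # antisymmetry under A/B swap on both legs
  fwd <- run_ti(b, u, n_steps = 1200, seed = 9)
  rev <- run_ti(harmonic_system(4, 1), harmonic_system(2, 1),
                n_steps = 1200, seed = 10)
  expect_lt(abs(fwd$ddG + rev$ddG), 3 * sqrt(fwd$se^2 + rev$se^2))
  # determinism
  again <- run_ti(b, u, n_steps = 1200, seed = 9)
  expect_identical(fwd$ddG, again$ddG)
  expect_identical(fwd$se, again$se)
})

test_that("cycle closure holds for three toy states", {
  kA <- 1; kB <- 2.5; kC <- 6
  mk <- function(k1, k2) list(bound = harmonic_system(k1, k2, kT = 1),
                              unbound = harmonic_system(k1, k2, kT = 2))
  run <- function(p, seed) run_ti(p$bound, p$unbound, n_steps = 1200,
                                  seed = seed)
  ab <- run(mk(kA, kB), 21); bc <- run(mk(kB, kC), 22)
  ca <- run(mk(kC, kA), 23)
  total <- ab$ddG + bc$ddG + ca$ddG
  expect_lt(abs(total), 3 * sqrt(ab$se^2 + bc$se^2 + ca$se^2))
})

test_that("the Monte-Carlo error shrinks like one over root n", {
  sys <- harmonic_system(1, 4)
  exact <- exact_dudl_mean(sys, 0.5)
  rmse <- vapply(c(400L, 6400L), function(n) {
    errs <- vapply(1:12, function(s)
      sample_dudl(sys, 0.5, n_steps = n, seed = s)$mean - exact,
      numeric(1L))
    sqrt(mean(errs^2))
  }, numeric(1L))
  # 16x the samples: expect ~4x smaller error (allow a factor-2 band)
  expect_gt(rmse[1L] / rmse[2L], 2)
  expect_lt(rmse[1L] / rmse[2L], 8)
})
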