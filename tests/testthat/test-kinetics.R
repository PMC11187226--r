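test_that("species fractions satisfy the initial condition and the frozen control-point values", {
  r <- control_rates()
  f0 <- species_fractions(0, r)
  expect_equal(unlist(f0[, 2:4]), c(precursor = 1, intermediate = 0,
                                    product = 0))
  # frozen from the closed form and confirmed by numerical integration
  f30 <- species_fractions(30, r)
  expect_equal(f30$precursor, 0.3295590, tolerance = 1e-6)
  expect_equal(f30$intermediate, 0.4008013, tolerance = 1e-6)
  expect_equal(f30$product, 0.2696401, tolerance = 1e-6)
})

test_that("the degenerate-rate limit uses the k t e^(-k t) series formula", {
  f <- species_fractions(10, splicing_rates(0.03, 0.03))
  expect_equal(f$intermediate, 0.3 * exp(-0.3), tolerance = 1e-12)
  # continuity: closed form approaches the limit as the rates merge
  gaps <- vapply(c(1e-3, 1e-5, 1e-7), function(eps) {
    a <- species_fractions(10, splicing_rates(0.1, 0.1 * (1 + eps)))
    b <- species_fractions(10, splicing_rates(0.1, 0.1))
    abs(a$intermediate - b$intermediate)
  }, numeric(1L))
  expect_lt(gaps[3L], 1e-8)
  expect_true(all(diff(gaps) < 0))
})

test_that("closed form agrees with numerical integration of the two-ODE system", {
  library(deSolve)
  r <- splicing_rates(0.085, 0.012)
  tt <- seq(0, 200, by = 5)
  rhs <- function(t, y, p) list(c(-p[1] * y[1], p[1] * y[1] - p[2] * y[2]))
  num <- ode(c(P = 1, I = 0), tt, rhs, c(r$k1, r$k2), method = "ode45",
             atol = 1e-10, rtol = 1e-10)
  cf <- species_fractions(tt, r)
  expect_lt(max(abs(cf$precursor - num[, "P"])), 1e-6)
  expect_lt(max(abs(cf$intermediate - num[, "I"])), 1e-6)
})

test_that("mass is conserved and precursor/product are monotone for random rates", {
  set.seed(41)
  for (i in 1:50) {
    r <- splicing_rates(runif(1, 1e-3, 0.5), runif(1, 1e-3, 0.5))
    tt <- sort(runif(20, 0, 300))
    f <- species_fractions(tt, r)
    expect_lt(max(abs(rowSums(f[, 2:4]) - 1)), 1e-9)
    expect_true(all(as.matrix(f[, 2:4]) >= 0 & as.matrix(f[, 2:4]) <= 1))
    expect_true(all(diff(f$precursor) < 0))
    expect_true(all(diff(f$product) > -1e-12))
  }
})

test_that("intermediate peak time matches the closed form and a grid maximisation", {
  expect_equal(intermediate_peak_time(control_rates()), 29.48845,
               tolerance = 1e-5)
  tt <- seq(0.01, 100, by = 0.001)
  grid_peak <- tt[which.max(species_fractions(tt, control_rates())$intermediate)]
  expect_equal(intermediate_peak_time(control_rates()), grid_peak,
               tolerance = 1e-3)
  expect_equal(intermediate_peak_time(splicing_rates(0.05, 0.05)), 20)
  # continuity across the degeneracy threshold
  expect_lt(abs(intermediate_peak_time(splicing_rates(0.1, 0.1 + 1e-9)) -
                  intermediate_peak_time(splicing_rates(0.1, 0.1))), 1e-4)
})

test_that("time-course simulation composes the closed form and honours limits", {
  one <- simulate_time_course(0, control_rates())
  expect_equal(nrow(one), 1L)
  expect_equal(one$frac_precursor, 1)
  tc <- simulate_time_course(c(0, 30), control_rates(), conc_uM = 10)
  expect_equal(tc$frac_intermediate[2L], 0.4008013, tolerance = 1e-6)
  expect_equal(unique(tc$conc_uM), 10)
  # very fast second step: the intermediate never accumulates
  fast <- simulate_time_course(c(0, 1, 5, 20, 100),
                               splicing_rates(1e-2, 1e4))
  expect_lt(max(fast$frac_intermediate), 1e-4)
})

test_that("invalid kinetic inputs raise domain errors", {
  expect_error(splicing_rates(-0.1, 0.2), "k1")
  expect_error(splicing_rates(0.1, 0), "k2")
  expect_error(species_fractions(-1, control_rates()), "t")
  expect_error(simulate_time_course(c(5, 1), control_rates()), "increasing")
  expect_error(simulate_time_course(c(0, 10), control_rates(),
                                    conc_uM = -2), "conc_uM")
})
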