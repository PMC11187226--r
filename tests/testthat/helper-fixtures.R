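# shared fixtures: the study's printed constants and small builders

control_rates <- function() splicing_rates(0.037, 0.031)
inhibited_rates_50uM <- function() splicing_rates(0.007, 0.001)

# printed binding constants (inhibition constants in uM with s.e.m.)
ki_compound_12 <- c(est = 5.3, se = 0.2)
ki_compound_17 <- c(est = 3.9, se = 0.5)
ki_intronistat_A <- c(est = 2.1, se = 0.2)
ki_intronistat_B <- c(est = 1.700, se = 0.004)

# published 12-window lambda schedule (nodes and the 6 distinct weights)
published_lambdas <- c(0.00922, 0.04794, 0.11505, 0.20634, 0.31608, 0.43738,
                       0.56262, 0.68392, 0.79366, 0.88495, 0.95206, 0.99078)
published_weights6 <- c(0.02359, 0.05347, 0.08004, 0.10158, 0.11675, 0.12457)

exact_kobs_series <- function(k_max = 0.04, K_i = 2,
                              conc = c(0, 1, 2, 5, 10, 50)) {
  data.frame(conc_uM = conc, kobs_per_min = k_max / (1 + conc / K_i))
}

harmonic_system <- function(kA = 1, kB = 4, kT = 1)
  toy_alchemical_system("harmonic_stiffness", list(k = kA), list(k = kB),
                        kT = kT)
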