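#' Gel splicing-assay design
#'
#' Sampling design for synthetic gel time courses. Defaults mirror the
#' study conditions: triplicates, inhibitor series 0 (DMSO), 10, 50 and
#' 250 uM, a time grid spanning 0-120 min, and band-intensity noise with
#' standard deviation 0.02.
#'
#' @param timepoints time grid in minutes.
#' @param concentrations inhibitor concentrations in micromolar.
#' @param replicates number of independent replicates (>= 1).
#' @param noise_sd standard deviation of the Gaussian band-intensity noise
#'   applied before renormalisation.
#' @param seed root seed; per-replicate/concentration streams are derived
#'   deterministically.
#' @return Object of class \code{"assay_design"}.
#' @export
assay_design <- function(timepoints = c(0, 1, 2, 5, 10, 15, 30, 60, 120),
                         concentrations = c(0, 10, 50, 250),
                         replicates = 3L, noise_sd = 0.02, seed = 1L) {
  if (replicates < 1L) stop_domain("`replicates` must be >= 1")
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(timepoints = timepoints, concentrations = concentrations,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 seed = seed),
            class = "assay_design")
}

#' Generate synthetic gel time courses
#'
#' Forward-simulates the two-step splicing model at each design
#' concentration and adds zero-mean Gaussian noise to each species' "band
#' intensity" before renormalisation (noise acts on intensities, as in gel
#' densitometry, not directly on fractions): intensities are truncated at
#' zero and renormalised to sum to 1. Pure function of (rates, design,
#' seed).
#'
#' @param rates_by_conc named list mapping concentration (as character, in
#'   micromolar) to \code{\link{splicing_rates}}; must cover every design
#'   concentration.
#' @param design an \code{\link{assay_design}}.
#' @return A stacked time-course data frame (layout of
#'   \code{\link{simulate_time_course}}) over all concentrations and
#'   replicates.
#' @examples
#' d <- assay_design(concentrations = 0, replicates = 2)
#' generate_gel_timecourses(list(`0` = splicing_rates(0.037, 0.031)), d)
#' @export
generate_gel_timecourses <- function(rates_by_conc, design = assay_design()) {
  need <- as.character(design$concentrations)
  if (!all(need %in% names(rates_by_conc)))
    stop_domain("`rates_by_conc` must name every design concentration")
  out <- list()
  stream <- 0L
  for (conc in design$concentrations) {
    rates <- as_splicing_rates(rates_by_conc[[as.character(conc)]])
    base <- species_fractions(design$timepoints, rates)
    for (r in seq_len(design$replicates)) {
      stream <- stream + 1L
      fr <- as.matrix(base[, c("precursor", "intermediate", "product")])
      if (design$noise_sd > 0) {
        noise <- with_seed(derive_seed(design$seed, stream),
                           matrix(stats::rnorm(length(fr), 0,
                                               design$noise_sd),
                                  nrow = nrow(fr)))
        fr <- pmax(fr + noise, 0)
        tot <- rowSums(fr)
        tot[tot == 0] <- 1
        fr <- fr / tot
      }
      out[[stream]] <- data.frame(time_min = design$timepoints,
                                  frac_precursor = fr[, 1L],
                                  frac_intermediate = fr[, 2L],
                                  frac_product = fr[, 3L],
                                  replicate = paste0("r", r),
                                  conc_uM = conc,
                                  stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("species_time_course", "data.frame")
  res
}

#' Generate a synthetic k_obs-vs-concentration series
#'
#' Hyperbolic competitive-inhibition model values
#' \code{k_max / (1 + [I]/K_i)} with multiplicative log-normal noise
#' (\code{noise_sd} on the log scale). Pure function of (parameters,
#' design, seed).
#'
#' @param k_max uninhibited rate constant (min^-1).
#' @param K_i inhibition constant (micromolar).
#' @param concentrations inhibitor concentrations (micromolar); the default
#'   spans the micromolar K_i of the lead inhibitor.
#' @param noise_sd log-scale noise standard deviation (0 = exact).
#' @param replicates independent k_obs measurements per concentration.
#' @param seed integer seed.
#' @return Data frame with columns \code{conc_uM}, \code{kobs_per_min} and,
#'   when \code{replicates > 1}, the per-concentration mean with
#'   \code{se_per_min} (s.e.m.).
#' @export
generate_kobs_series <- function(k_max, K_i,
                                 concentrations = c(0, 0.5, 1, 2, 5, 10,
                                                    25, 50),
                                 noise_sd = 0, replicates = 1L, seed = 1L) {
  check_number(k_max, "k_max", lower = 0, strict = TRUE)
  check_number(K_i, "K_i", lower = 0, strict = TRUE)
  mu <- k_max / (1 + concentrations / K_i)
  if (replicates == 1L) {
    k <- if (noise_sd > 0)
      mu * exp(with_seed(seed, stats::rnorm(length(mu), 0, noise_sd)))
    else mu
    return(data.frame(conc_uM = concentrations, kobs_per_min = k))
  }
  draws <- with_seed(seed,
                     matrix(stats::rnorm(length(mu) * replicates, 0,
                                         noise_sd),
                            nrow = length(mu)))
  k <- mu * exp(draws)
  data.frame(conc_uM = concentrations,
             kobs_per_min = rowMeans(k),
             se_per_min = apply(k, 1L, stats::sd) / sqrt(replicates))
}

#' Generate a synthetic normalised dose-response series
#'
#' Model responses \code{100 / (1 + [I]/IC50)} with additive Gaussian noise
#' in percent. The default concentration design is the FRET assay's 11
#' log-spaced concentrations from 0.25 to 1000 uM.
#'
#' @param IC50 half-maximal inhibitory concentration (micromolar).
#' @param concentrations concentrations in micromolar.
#' @param noise_sd additive noise in percent.
#' @param seed integer seed.
#' @return Data frame with columns \code{conc_uM} and \code{percent}.
#' @export
generate_dose_response <- function(IC50,
                                   concentrations =
                                     exp(seq(log(0.25), log(1000),
                                             length.out = 11L)),
                                   noise_sd = 0, seed = 1L) {
  check_number(IC50, "IC50", lower = 0, strict = TRUE)
  pc <- 100 / (1 + concentrations / IC50)
  if (noise_sd > 0)
    pc <- pc + with_seed(seed, stats::rnorm(length(pc), 0, noise_sd))
  data.frame(conc_uM = concentrations, percent = pc)
}

#' Generate a synthetic ITC titration
#'
#' Delegates to \code{\link{simulate_itc}} with additive Gaussian heat
#' noise; a thin naming wrapper so all generators live together.
#'
#' @inheritParams simulate_itc
#' @return An \code{"itc_titration"} object (see \code{\link{simulate_itc}}).
#' @export
generate_itc <- function(params, design = itc_design(), noise_sd = 0,
                         seed = 1L) {
  simulate_itc(params, design, noise_sd = noise_sd, seed = seed)
}

#' Generate synthetic BLI sensorgrams
#'
#' Delegates to \code{\link{simulate_bli}} with additive Gaussian response
#' noise.
#'
#' @inheritParams simulate_bli
#' @return Sensorgram data frame (see \code{\link{simulate_bli}}).
#' @export
generate_bli <- function(kinetics, conc_uM = c(12.5, 25, 50, 100),
                         t_assoc = 300, t_dissoc = 300, dt = 2,
                         noise_sd = 0, seed = 1L) {
  simulate_bli(kinetics, conc_uM = conc_uM, t_assoc = t_assoc,
               t_dissoc = t_dissoc, dt = dt, noise_sd = noise_sd,
               seed = seed)
}
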