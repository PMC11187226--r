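#' Step-specific splicing rate constants
#'
#' Container for the two first-order rate constants of the irreversible
#' sequential splicing scheme: precursor (5e-I-3e) -> intermediate (I-3e)
#' with rate \code{k1}, and intermediate -> free linear intron (I) with rate
#' \code{k2}. Units are min^-1 throughout.
#'
#' @param k1 first-step rate constant (min^-1), must be positive and finite.
#' @param k2 second-step rate constant (min^-1), must be positive and finite.
#' @return An object of class \code{"splicing_rates"}: a list with elements
#'   \code{k1} and \code{k2}.
#' @examples
#' splicing_rates(0.037, 0.031)  # uninhibited control constants
#' @export
splicing_rates <- function(k1, k2) {
  check_number(k1, "k1", lower = 0, strict = TRUE)
  check_number(k2, "k2", lower = 0, strict = TRUE)
  structure(list(k1 = k1, k2 = k2), class = "splicing_rates")
}

#' @export
print.splicing_rates <- function(x, ...) {
  cat(sprintf("Splicing rate constants: k1 = %g min^-1, k2 = %g min^-1\n",
              x$k1, x$k2))
  invisible(x)
}

as_splicing_rates <- function(x) {
  if (inherits(x, "splicing_rates")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(splicing_rates(x[[1L]], x[[2L]]))
  stop_domain("cannot interpret input as splicing rate constants")
}

# relative gap below which the k1 == k2 series limit is used, to avoid
# catastrophic cancellation in k1/(k2 - k1) * (exp(-k1 t) - exp(-k2 t))
.degenerate_tol <- 1e-6

#' Species fractions of the two-step splicing scheme
#'
#' Closed-form (Bateman) solution of the irreversible sequential first-order
#' scheme with unit initial precursor: precursor \eqn{e^{-k_1 t}},
#' intermediate \eqn{k_1/(k_2-k_1)(e^{-k_1 t} - e^{-k_2 t})} (with the
#' continuous limit \eqn{k t e^{-k t}} at \eqn{k_1 = k_2}), product by mass
#' balance. Near-degenerate rate pairs (relative gap below 1e-6) are routed
#' through the limit formula at the mean rate to avoid cancellation.
#'
#' @param t time(s) in minutes, each >= 0; may be a vector.
#' @param rates a \code{\link{splicing_rates}} object (or length-2 numeric).
#' @return A data frame with columns \code{time}, \code{precursor},
#'   \code{intermediate}, \code{product}; one row per element of \code{t}.
#'   Rows sum to 1 and every entry lies in [0, 1].
#' @examples
#' species_fractions(30, splicing_rates(0.037, 0.031))
#' @export
species_fractions <- function(t, rates) {
  rates <- as_splicing_rates(rates)
  if (!is.numeric(t) || length(t) < 1L || any(!is.finite(t)) || any(t < 0))
    stop_domain("`t` must be finite and >= 0 (minutes)")
  k1 <- rates$k1; k2 <- rates$k2
  p <- exp(-k1 * t)
  if (abs(k1 - k2) < .degenerate_tol * max(k1, k2)) {
    k <- (k1 + k2) / 2
    i <- k * t * exp(-k * t)
  } else {
    i <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  }
  i <- pmin(pmax(i, 0), 1)
  prod <- pmin(pmax(1 - p - i, 0), 1)
  data.frame(time = t, precursor = p, intermediate = i, product = prod)
}

#' Time of maximal intermediate accumulation
#'
#' The intermediate (I-3e) pool peaks at \eqn{t^* = \ln(k_1/k_2)/(k_1-k_2)}
#' (and at \eqn{1/k} when \eqn{k_1 = k_2 = k}). A useful diagnostic for the
#' intermediate build-up induced by second-step inhibitors.
#'
#' @inheritParams species_fractions
#' @return Peak time in minutes (positive scalar).
#' @examples
#' intermediate_peak_time(splicing_rates(0.037, 0.031))  # ~29.5 min
#' @export
intermediate_peak_time <- function(rates) {
  rates <- as_splicing_rates(rates)
  k1 <- rates$k1; k2 <- rates$k2
  if (abs(k1 - k2) < .degenerate_tol * max(k1, k2)) return(2 / (k1 + k2))
  log(k1 / k2) / (k1 - k2)
}

#' Simulate a noiseless splicing time course
#'
#' Evaluates \code{\link{species_fractions}} on a time grid and packages the
#' result in the tabular layout used for gel time-course I/O.
#'
#' @param times strictly increasing time grid in minutes, each >= 0.
#' @param rates a \code{\link{splicing_rates}} object.
#' @param conc_uM inhibitor concentration in micromolar (0 for DMSO control).
#' @param replicate replicate label.
#' @return A data frame of class \code{"species_time_course"} with columns
#'   \code{time_min}, \code{frac_precursor}, \code{frac_intermediate},
#'   \code{frac_product}, \code{replicate}, \code{conc_uM}.
#' @examples
#' simulate_time_course(c(0, 5, 15, 30, 60), splicing_rates(0.037, 0.031))
#' @export
simulate_time_course <- function(times, rates, conc_uM = 0, replicate = "r1") {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)) ||
      any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop_domain("`times` must be a strictly increasing grid of minutes >= 0")
  check_number(conc_uM, "conc_uM", lower = 0)
  fr <- species_fractions(times, rates)
  out <- data.frame(time_min = fr$time,
                    frac_precursor = fr$precursor,
                    frac_intermediate = fr$intermediate,
                    frac_product = fr$product,
                    replicate = as.character(replicate),
                    conc_uM = conc_uM,
                    stringsAsFactors = FALSE)
  class(out) <- c("species_time_course", "data.frame")
  out
}

time_course_columns <- c("time_min", "frac_precursor", "frac_intermediate",
                         "frac_product", "replicate", "conc_uM")

validate_time_course <- function(df, min_points = 1L) {
  if (!is.data.frame(df) || !all(time_course_columns %in% names(df)))
    stop_domain("time course must have columns: %s",
                paste(time_course_columns, collapse = ", "))
  num <- c("time_min", "frac_precursor", "frac_intermediate", "frac_product",
           "conc_uM")
  for (cl in num)
    if (!is.numeric(df[[cl]]) || any(!is.finite(df[[cl]])))
      stop_domain("column `%s` must be finite numeric", cl)
  fr <- df[, c("frac_precursor", "frac_intermediate", "frac_product")]
  if (any(fr < -1e-9) || any(fr > 1 + 1e-9))
    stop_domain("species fractions must lie in [0, 1]")
  if (any(df$time_min < 0)) stop_domain("times must be >= 0")
  if (nrow(df) < min_points)
    stop_domain("at least %d time points are required", min_points)
  invisible(df)
}
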