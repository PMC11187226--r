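#' Toy alchemical system with Gaussian end states
#'
#' Analytic test systems for the thermodynamic-integration estimator. Each
#' end state is a (multi-dimensional, separable) quadratic potential
#' \eqn{U_s(x) = \tfrac12 a_s x^2 + c_s x + e_s} per coordinate, so the
#' Boltzmann distribution at every coupling value is Gaussian and both the
#' window averages of dU/dlambda and the end-to-end free-energy difference
#' have closed forms. The lambda-coupled potential is the linear
#' interpolation \eqn{U(x;\lambda) = (1-\lambda) U_A(x) + \lambda U_B(x)}.
#'
#' Families:
#' \describe{
#'   \item{harmonic_stiffness}{\code{params = list(k)}; stiffness morph,
#'     exact dG = (d kT / 2) ln(k_B/k_A).}
#'   \item{shifted_well}{\code{params = list(k, mu)}; well-centre morph,
#'     dG depends only on the stiffness ratio.}
#'   \item{linear_field}{\code{params = list(k, b)}; harmonic well in a
#'     linear field, dG includes the field term -b^2/(2k).}
#' }
#'
#' @param family potential family id.
#' @param state_a,state_b named parameter lists for the two end states
#'   (see families above).
#' @param kT thermal energy in the system's energy units (> 0).
#' @param dim dimensionality, 1 to 3 (the same 1-d parameters apply to each
#'   coordinate).
#' @return Object of class \code{"toy_alchemical_system"}.
#' @examples
#' toy_alchemical_system("harmonic_stiffness", list(k = 1), list(k = 4))
#' @export
toy_alchemical_system <- function(family = c("harmonic_stiffness",
                                             "shifted_well", "linear_field"),
                                  state_a, state_b, kT = 1, dim = 1L) {
  family <- match.arg(family)
  check_number(kT, "kT", lower = 0, strict = TRUE)
  if (!dim %in% 1:3) stop_domain("`dim` must be 1, 2 or 3")
  qa <- quad_coef(family, state_a)
  qb <- quad_coef(family, state_b)
  if (qa$a <= 0 || qb$a <= 0)
    stop_domain("end-state potentials must be confining (stiffness > 0)")
  structure(list(family = family, state_a = state_a, state_b = state_b,
                 qa = qa, qb = qb, kT = kT, dim = as.integer(dim)),
            class = "toy_alchemical_system")
}

# per-coordinate quadratic coefficients U = a x^2 / 2 + c x + e
quad_coef <- function(family, st) {
  switch(family,
         harmonic_stiffness = {
           check_number(st$k, "k", lower = 0, strict = TRUE)
           list(a = st$k, c = 0, e = 0)
         },
         shifted_well = {
           check_number(st$k, "k", lower = 0, strict = TRUE)
           check_number(st$mu, "mu")
           list(a = st$k, c = -st$k * st$mu, e = st$k * st$mu^2 / 2)
         },
         linear_field = {
           check_number(st$k, "k", lower = 0, strict = TRUE)
           check_number(st$b, "b")
           list(a = st$k, c = st$b, e = 0)
         })
}

# lambda-interpolated coefficients
coef_at_lambda <- function(system, lambda) {
  list(a = (1 - lambda) * system$qa$a + lambda * system$qb$a,
       c = (1 - lambda) * system$qa$c + lambda * system$qb$c,
       e = (1 - lambda) * system$qa$e + lambda * system$qb$e)
}

# potential energy and dU/dlambda for a coordinate vector x
toy_energy <- function(system, x, lambda) {
  q <- coef_at_lambda(system, lambda)
  sum(q$a * x^2 / 2 + q$c * x + q$e)
}

toy_dudl <- function(system, x) {
  da <- system$qb$a - system$qa$a
  dc <- system$qb$c - system$qa$c
  de <- system$qb$e - system$qa$e
  sum(da * x^2 / 2 + dc * x + de)
}

#' Exact window average of dU/dlambda
#'
#' Closed-form Boltzmann average of \eqn{\partial U/\partial\lambda =
#' U_B - U_A} at coupling \code{lambda}, from the Gaussian moments of the
#' interpolated potential (mean \eqn{-c/a}, variance \eqn{kT/a} per
#' coordinate).
#'
#' @param system a \code{\link{toy_alchemical_system}}.
#' @param lambda coupling value in [0, 1] (vectorised).
#' @return Exact mean of dU/dlambda (energy units).
#' @export
exact_dudl_mean <- function(system, lambda) {
  if (any(lambda < 0 | lambda > 1)) stop_domain("lambda must lie in [0, 1]")
  vapply(lambda, function(l) {
    q <- coef_at_lambda(system, l)
    m <- -q$c / q$a
    v <- system$kT / q$a
    da <- system$qb$a - system$qa$a
    dc <- system$qb$c - system$qa$c
    de <- system$qb$e - system$qa$e
    system$dim * (da * (v + m^2) / 2 + dc * m + de)
  }, numeric(1L))
}

#' Exact alchemical free-energy difference of a toy system
#'
#' From the Gaussian partition functions of the two end states:
#' per coordinate \eqn{G_s = (kT/2)\ln a_s - c_s^2/(2 a_s) + e_s} up to a
#' state-independent constant, so
#' \eqn{\Delta G = d\,[G_B - G_A]}.
#'
#' @param system a \code{\link{toy_alchemical_system}}.
#' @return Exact dG (energy units).
#' @examples
#' s <- toy_alchemical_system("harmonic_stiffness", list(k = 1), list(k = 4))
#' exact_deltaG(s)  # (kT/2) ln 4
#' @export
exact_deltaG <- function(system) {
  g <- function(q) system$kT / 2 * log(q$a) - q$c^2 / (2 * q$a) + q$e
  system$dim * (g(system$qb) - g(system$qa))
}
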