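#' Thermodynamic conditions
#'
#' Temperature and constants used to interconvert dissociation/inhibition
#' constants and free energies. The gas constant is fixed at
#' 1.9872042586e-3 kcal mol^-1 K^-1 and the standard concentration at 1 M;
#' natural logarithms are used throughout.
#'
#' @param temperature absolute temperature in kelvin (default 298.15 K,
#'   i.e. 25 C, the binding-assay temperature).
#' @return Object of class \code{"thermo_conditions"} with fields \code{T},
#'   \code{R} and \code{c0}.
#' @export
thermo_conditions <- function(temperature = 298.15) {
  check_number(temperature, "temperature", lower = 0, strict = TRUE)
  structure(list(T = temperature, R = 1.9872042586e-3, c0 = 1),
            class = "thermo_conditions")
}

#' Binding free energy from a dissociation constant
#'
#' \deqn{\Delta G = R T \ln(K_D / c^\circ)}
#'
#' @param K_D dissociation constant in molar (> 0).
#' @param conditions a \code{\link{thermo_conditions}} object.
#' @return Free energy of binding in kcal/mol (negative for favourable
#'   binding at sub-molar K_D).
#' @examples
#' deltaG_from_KD(7.58e-6)  # ~ -6.99 kcal/mol at 25 C
#' @export
deltaG_from_KD <- function(K_D, conditions = thermo_conditions()) {
  check_number(K_D, "K_D", lower = 0, strict = TRUE)
  conditions$R * conditions$T * log(K_D / conditions$c0)
}

#' Entropic term of the Gibbs decomposition
#'
#' Completes the triple (dH, dG, -TdS): \code{-TdS = dG - dH}.
#'
#' @param deltaG free energy of binding, kcal/mol.
#' @param deltaH enthalpy of binding, kcal/mol.
#' @return \code{-T dS} in kcal/mol.
#' @examples
#' minus_T_deltaS(-7.02, -10.04)  # 3.02
#' @export
minus_T_deltaS <- function(deltaG, deltaH) {
  check_number(deltaG, "deltaG")
  check_number(deltaH, "deltaH")
  deltaG - deltaH
}

#' Binding thermodynamics container
#'
#' Assembles the full single-site binding description from K_D, enthalpy and
#' stoichiometry; dG and -TdS are derived through
#' \code{\link{deltaG_from_KD}} and \code{\link{minus_T_deltaS}} so the
#' Gibbs identity dG = dH + (-TdS) holds by construction.
#'
#' @param K_D dissociation constant, molar.
#' @param deltaH binding enthalpy, kcal/mol.
#' @param N binding stoichiometry (sites per receptor).
#' @param conditions a \code{\link{thermo_conditions}} object.
#' @param se optional named numeric of standard errors (\code{K_D},
#'   \code{deltaH}, \code{N}).
#' @return Object of class \code{"binding_thermodynamics"}.
#' @export
binding_thermodynamics <- function(K_D, deltaH, N = 1,
                                   conditions = thermo_conditions(),
                                   se = NULL) {
  check_number(K_D, "K_D", lower = 0, strict = TRUE)
  check_number(deltaH, "deltaH")
  check_number(N, "N", lower = 0, strict = TRUE)
  dG <- deltaG_from_KD(K_D, conditions)
  structure(list(K_D = K_D, deltaH = deltaH, deltaG = dG,
                 minus_TdS = minus_T_deltaS(dG, deltaH), N = N,
                 conditions = conditions, se = se),
            class = "binding_thermodynamics")
}

#' @export
print.binding_thermodynamics <- function(x, ...) {
  cat(sprintf(paste0("Single-site binding thermodynamics (T = %.2f K)\n",
                     "  K_D  = %.4g M (%.3g uM)\n  N    = %.4g\n",
                     "  dH   = %.4g kcal/mol\n  dG   = %.4g kcal/mol\n",
                     "  -TdS = %.4g kcal/mol\n"),
              x$conditions$T, x$K_D, x$K_D * 1e6, x$N, x$deltaH, x$deltaG,
              x$minus_TdS))
  invisible(x)
}

#' Relative binding free energy from a pair of inhibition constants
#'
#' \deqn{\Delta\Delta G_{A\to B} = R T \ln(K_{i,B} / K_{i,A})}
#' with first-order (delta-method) error propagation
#' \eqn{s.e. = R T \sqrt{(\sigma_A/K_{i,A})^2 + (\sigma_B/K_{i,B})^2}}.
#' Antisymmetric under swapping the two compounds.
#'
#' @param Ki_A,Ki_B inhibition constants of compounds A and B (any common
#'   concentration unit; the ratio is what matters).
#' @param se_A,se_B standard errors of the two constants (same unit).
#' @param labels length-2 character vector naming compounds A and B.
#' @param conditions a \code{\link{thermo_conditions}} object.
#' @return Object of class \code{"relative_binding_free_energy"}:
#'   \code{ddG} (kcal/mol), \code{se}, \code{labels},
#'   \code{source = "experimental_Ki"}.
#' @examples
#' ddG_from_Ki(5.3, 3.9, 0.2, 0.5, labels = c("compound 12", "compound 17"))
#' @export
ddG_from_Ki <- function(Ki_A, Ki_B, se_A = 0, se_B = 0,
                        labels = c("A", "B"),
                        conditions = thermo_conditions()) {
  check_number(Ki_A, "Ki_A", lower = 0, strict = TRUE)
  check_number(Ki_B, "Ki_B", lower = 0, strict = TRUE)
  check_number(se_A, "se_A", lower = 0)
  check_number(se_B, "se_B", lower = 0)
  RT <- conditions$R * conditions$T
  # log difference keeps the antisymmetry ddG(A,B) = -ddG(B,A) exact
  structure(list(ddG = RT * (log(Ki_B) - log(Ki_A)),
                 se = RT * sqrt((se_A / Ki_A)^2 + (se_B / Ki_B)^2),
                 labels = labels, source = "experimental_Ki",
                 conditions = conditions),
            class = "relative_binding_free_energy")
}

#' @export
print.relative_binding_free_energy <- function(x, ...) {
  cat(sprintf("ddG(%s -> %s) = %.3f +/- %.3f kcal/mol [%s]\n",
              x$labels[1L], x$labels[2L], x$ddG, x$se, x$source))
  invisible(x)
}
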