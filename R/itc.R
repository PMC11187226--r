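#' ITC experimental design
#'
#' Geometry of an isothermal titration calorimetry experiment. Defaults are
#' the study design: 30 uM receptor in the cell, 600 uM ligand in the
#' syringe, 16 injections of 2.5 uL into a 200 uL overflow cell at 25 C.
#'
#' @param cell_conc_M receptor concentration loaded in the cell (molar).
#' @param syringe_conc_M ligand concentration in the syringe (molar).
#' @param injection_volumes_L vector of injection volumes (litres).
#' @param cell_volume_L working cell volume (litres).
#' @param conditions a \code{\link{thermo_conditions}} object.
#' @return Object of class \code{"itc_design"}.
#' @export
itc_design <- function(cell_conc_M = 30e-6, syringe_conc_M = 600e-6,
                       injection_volumes_L = rep(2.5e-6, 16L),
                       cell_volume_L = 200e-6,
                       conditions = thermo_conditions()) {
  check_number(cell_conc_M, "cell_conc_M", lower = 0, strict = TRUE)
  check_number(syringe_conc_M, "syringe_conc_M", lower = 0, strict = TRUE)
  check_number(cell_volume_L, "cell_volume_L", lower = 0, strict = TRUE)
  if (any(!is.finite(injection_volumes_L)) || any(injection_volumes_L <= 0))
    stop_domain("injection volumes must be positive")
  structure(list(cell_conc_M = cell_conc_M, syringe_conc_M = syringe_conc_M,
                 injection_volumes_L = injection_volumes_L,
                 cell_volume_L = cell_volume_L, conditions = conditions),
            class = "itc_design")
}

# equilibrium complex concentration for a single-site model:
# sites S = N*M, ligand X; MX solves the quadratic
# MX^2 - (S + X + KD) MX + S X = 0, taking the physical root
itc_bound_conc <- function(S, X, KD) {
  b <- S + X + KD
  mx <- (b - sqrt(pmax(b * b - 4 * S * X, 0))) / 2
  pmin(mx, pmin(S, X))
}

#' Simulate an ITC titration (single-site forward model)
#'
#' Per-injection integrated heats from the exact single-site equilibrium
#' (quadratic solution for the bound fraction) with discrete displacement
#' dilution for the overflow cell: each injection of volume v replaces a
#' fraction v/V0 of the (pre-injection) cell content with syringe solution.
#' The heat of injection i is
#' \deqn{Q_i = \Delta H V_0 ([MX]_i - [MX]_{i-1}(1 - v_i/V_0))}
#' normalised per mole of injected ligand. Optional Gaussian noise on the
#' normalised heats; deterministic given \code{seed}.
#'
#' @param params a \code{\link{binding_thermodynamics}} object (N, K_D, dH).
#' @param design an \code{\link{itc_design}}.
#' @param noise_sd standard deviation of additive heat noise
#'   (kcal per mole of injectant; 0 for the noiseless model).
#' @param seed integer seed for the noise stream.
#' @param offset constant per-injection heat offset (kcal/mol of injectant),
#'   emulating the residual dilution heat after blank subtraction.
#' @return Object of class \code{"itc_titration"}: the design plus a data
#'   frame \code{heats} with columns \code{injection}, \code{volume_uL},
#'   \code{molar_ratio} (cumulative ligand/receptor in the cell) and
#'   \code{heat_kcal_per_mol}, and a \code{mass_balance} record.
#' @export
simulate_itc <- function(params, design = itc_design(), noise_sd = 0,
                         seed = 1L, offset = 0) {
  if (!inherits(params, "binding_thermodynamics"))
    stop_domain("`params` must be a binding_thermodynamics object")
  if (!inherits(design, "itc_design"))
    stop_domain("`design` must be an itc_design object")
  check_number(noise_sd, "noise_sd", lower = 0)
  V0 <- design$cell_volume_L
  s <- design$syringe_conc_M
  vols <- design$injection_volumes_L
  n <- length(vols)

  M <- design$cell_conc_M   # total receptor in cell
  X <- 0                    # total ligand in cell
  mx_prev <- 0
  injected <- 0; displaced_X <- 0; displaced_M <- 0
  q <- numeric(n); ratio <- numeric(n)
  mass_err <- numeric(n)
  for (i in seq_len(n)) {
    v <- vols[i]
    f <- 1 - v / V0
    displaced_X <- displaced_X + X * v
    displaced_M <- displaced_M + M * v
    M <- M * f
    X <- X * f + s * v / V0
    injected <- injected + s * v
    mx <- itc_bound_conc(params$N * M, X, params$K_D)
    q[i] <- params$deltaH * V0 * (mx - mx_prev * f) / (s * v) + offset
    mx_prev <- mx
    ratio[i] <- X / M
    mass_err[i] <- abs(X * V0 + displaced_X - injected) /
      max(injected, .Machine$double.xmin)
  }
  if (noise_sd > 0)
    q <- q + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  structure(list(design = design,
                 heats = data.frame(injection = seq_len(n),
                                    volume_uL = vols * 1e6,
                                    molar_ratio = ratio,
                                    heat_kcal_per_mol = q),
                 params = params,
                 mass_balance = list(
                   ligand_rel_error = max(mass_err),
                   receptor_rel_error =
                     abs(M * V0 + displaced_M - design$cell_conc_M * V0) /
                     (design$cell_conc_M * V0))),
            class = "itc_titration")
}

#' Fit the single-site binding isotherm to ITC heats
#'
#' Nonlinear least-squares fit of stoichiometry N, dissociation constant
#' K_D, binding enthalpy dH and a constant per-injection heat offset (the
#' blank-subtraction residual) to integrated injection heats, using the same
#' displacement-dilution forward model as \code{\link{simulate_itc}}.
#' dG and -TdS are derived from the fitted K_D at the design temperature.
#' A warning is issued when the Wiseman c-value (N [cell]/K_D) leaves the
#' fittable range [1, 1000].
#'
#' @param titration an \code{\link{itc_titration}}, or a list with a
#'   \code{design} (\code{\link{itc_design}}) and \code{heats} data frame
#'   (columns \code{injection}, \code{volume_uL},
#'   \code{heat_kcal_per_mol}).
#' @param start optional named list of starting values (\code{N},
#'   \code{K_D}, \code{deltaH}, \code{offset}).
#' @return Object of class \code{"itc_fit"}: \code{thermo} (a
#'   \code{\link{binding_thermodynamics}} with standard errors),
#'   \code{offset}, \code{c_value}, residuals and a
#'   \code{nonidentifiable} flag (set for flat heat profiles).
#' @export
fit_itc_single_site <- function(titration, start = NULL) {
  design <- titration$design
  heats <- titration$heats
  if (!inherits(design, "itc_design") || !is.data.frame(heats))
    stop_domain("`titration` must carry an itc_design and a heats table")
  q <- heats$heat_kcal_per_mol
  if (length(q) < 6L)
    stop_domain("at least 6 injections are required")
  vols <- heats$volume_uL * 1e-6

  if (stats::sd(q) < 1e-9 && abs(mean(q)) < 1e-9) {
    return(structure(list(thermo = NULL, offset = 0, c_value = NA_real_,
                          residuals = q * 0, nonidentifiable = TRUE,
                          convergence = list(info = NA)),
                     class = "itc_fit"))
  }

  model_heats <- function(N, KD, dH, off) {
    d <- design; d$injection_volumes_L <- vols
    p <- binding_thermodynamics(KD, dH, N, design$conditions)
    simulate_itc(p, d, noise_sd = 0, offset = off)$heats$heat_kcal_per_mol
  }

  if (is.null(start)) {
    dh0 <- q[1L] - q[length(q)]
    if (abs(dh0) < 1e-6) dh0 <- sign(q[1L] + 1e-12) * max(abs(q), 1e-3)
    # molar ratio at half-drop approximates N; c from transition sharpness
    ratio <- heats$molar_ratio
    if (is.null(ratio)) {
      cum <- cumsum(design$syringe_conc_M * vols / design$cell_volume_L)
      ratio <- cum / design$cell_conc_M
    }
    mid <- ratio[which.min(abs(q - (q[1L] + q[length(q)]) / 2))]
    n0 <- max(min(mid, 5), 0.2)
    starts <- list(c(n0, design$cell_conc_M / 5, dh0, 0),
                   c(n0, design$cell_conc_M / 50, dh0, 0),
                   c(1, design$cell_conc_M, dh0, 0))
  } else {
    starts <- list(c(start$N, start$K_D, start$deltaH,
                     if (is.null(start$offset)) 0 else start$offset))
  }

  resid_fun <- function(par)
    model_heats(exp(par[1L]), exp(par[2L]), par[3L], par[4L]) - q
  best <- NULL
  for (s0 in starts) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = c(log(s0[1L]), log(s0[2L]), s0[3L], s0[4L]), fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
      error = function(cond) NULL)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance))
      best <- f
  }
  if (is.null(best)) stop_fit("ITC single-site fit failed to converge")

  N <- exp(best$par[1L]); KD <- exp(best$par[2L])
  dH <- best$par[3L]; off <- best$par[4L]
  vc <- tryCatch(nlslm_vcov(best), error = function(cond)
    matrix(NA_real_, 4L, 4L))
  se <- sqrt(pmax(diag(vc), 0))
  se_nat <- c(K_D = KD * se[2L], deltaH = se[3L], N = N * se[1L])
  cval <- N * design$cell_conc_M / KD
  if (is.finite(cval) && (cval < 1 || cval > 1000))
    warning(sprintf("Wiseman c-value %.3g outside [1, 1000]; ",
                    cval), "K_D weakly constrained")
  structure(list(thermo = binding_thermodynamics(KD, dH, N,
                                                 design$conditions,
                                                 se = se_nat),
                 offset = off, c_value = cval,
                 residuals = resid_fun(best$par),
                 residual_ss = best$deviance,
                 nonidentifiable = FALSE,
                 convergence = list(info = best$info,
                                    message = best$message)),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  if (x$nonidentifiable) {
    cat("ITC fit: flat heat profile; K_D not identifiable (dH ~ 0)\n")
    return(invisible(x))
  }
  cat(sprintf("ITC single-site fit (c-value %.3g, offset %.3g)\n",
              x$c_value, x$offset))
  print(x$thermo)
  invisible(x)
}
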