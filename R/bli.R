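#' Biphasic (2:1 heterogeneous) BLI kinetics parameters
#'
#' Two independent surface-site classes, each following 1:1 Langmuir
#' kinetics. \code{K_Di = k_offi / k_oni} by construction.
#'
#' @param k_on1,k_on2 association rate constants, M^-1 s^-1.
#' @param k_off1,k_off2 dissociation rate constants, s^-1.
#' @param Rmax1,Rmax2 maximal responses of the two phases (nm).
#' @return Object of class \code{"bli_kinetics"} with the rates, amplitudes
#'   and derived \code{K_D1}, \code{K_D2} (molar).
#' @examples
#' bli_kinetics(10.1, 132.0, 0.001, 0.026, 0.5, 0.5)
#' @export
bli_kinetics <- function(k_on1, k_on2, k_off1, k_off2, Rmax1, Rmax2) {
  for (nm in c("k_on1", "k_on2", "k_off1", "k_off2"))
    check_number(get(nm), nm, lower = 0, strict = TRUE)
  check_number(Rmax1, "Rmax1", lower = 0)
  check_number(Rmax2, "Rmax2", lower = 0)
  structure(list(k_on1 = k_on1, k_on2 = k_on2, k_off1 = k_off1,
                 k_off2 = k_off2, Rmax1 = Rmax1, Rmax2 = Rmax2,
                 K_D1 = k_off1 / k_on1, K_D2 = k_off2 / k_on2),
            class = "bli_kinetics")
}

#' @export
print.bli_kinetics <- function(x, ...) {
  cat("Biphasic BLI kinetics (two independent site classes)\n")
  cat(sprintf("  phase 1: k_on %.4g M^-1 s^-1, k_off %.4g s^-1, K_D %.4g M (Rmax %.3g nm)\n",
              x$k_on1, x$k_off1, x$K_D1, x$Rmax1))
  cat(sprintf("  phase 2: k_on %.4g M^-1 s^-1, k_off %.4g s^-1, K_D %.4g M (Rmax %.3g nm)\n",
              x$k_on2, x$k_off2, x$K_D2, x$Rmax2))
  invisible(x)
}

bli_phase_response <- function(t, conc, kon, koff, Rmax, t_assoc) {
  kobs <- kon * conc + koff
  Req <- Rmax * conc / (conc + koff / kon)
  r <- ifelse(t <= t_assoc,
              Req * (1 - exp(-kobs * t)),
              Req * (1 - exp(-kobs * t_assoc)) *
                exp(-koff * (t - t_assoc)))
  r
}

#' Simulate biphasic BLI sensorgrams
#'
#' Association/dissociation traces of the 2:1 heterogeneous model (sum of
#' two independent 1:1 Langmuir phases) over a set of analyte
#' concentrations. Defaults follow the study design: analyte at
#' 12.5-100 uM, 300 s association, 300 s dissociation.
#'
#' @param kinetics a \code{\link{bli_kinetics}} object.
#' @param conc_uM analyte concentrations in micromolar.
#' @param t_assoc,t_dissoc association/dissociation phase lengths (s).
#' @param dt sampling interval (s).
#' @param noise_sd additive Gaussian noise on the response (nm).
#' @param seed integer seed for the noise stream.
#' @return Data frame with columns \code{time_s}, \code{response_nm},
#'   \code{conc_uM}, \code{phase} (\code{"association"} or
#'   \code{"dissociation"}).
#' @export
simulate_bli <- function(kinetics, conc_uM = c(12.5, 25, 50, 100),
                         t_assoc = 300, t_dissoc = 300, dt = 2,
                         noise_sd = 0, seed = 1L) {
  if (!inherits(kinetics, "bli_kinetics"))
    stop_domain("`kinetics` must be a bli_kinetics object")
  if (any(conc_uM <= 0)) stop_domain("analyte concentrations must be > 0")
  tt <- seq(0, t_assoc + t_dissoc, by = dt)
  out <- do.call(rbind, lapply(conc_uM, function(cu) {
    cM <- cu * 1e-6
    r <- bli_phase_response(tt, cM, kinetics$k_on1, kinetics$k_off1,
                            kinetics$Rmax1, t_assoc) +
      bli_phase_response(tt, cM, kinetics$k_on2, kinetics$k_off2,
                         kinetics$Rmax2, t_assoc)
    data.frame(time_s = tt, response_nm = r, conc_uM = cu,
               phase = ifelse(tt <= t_assoc, "association", "dissociation"),
               stringsAsFactors = FALSE)
  }))
  if (noise_sd > 0)
    out$response_nm <- out$response_nm +
      with_seed(seed, stats::rnorm(nrow(out), 0, noise_sd))
  out
}

#' Global biphasic fit of BLI sensorgrams
#'
#' Fits the 2:1 heterogeneous model (two independent 1:1 Langmuir site
#' classes, shared rate constants and amplitudes across all analyte
#' concentrations) to a sensorgram set by global nonlinear least squares.
#' Affinities are obtained from the rate-constant ratios,
#' \code{K_Di = k_offi / k_oni}. Starting values come from a single-phase
#' pre-fit split multiplicatively into two phases, refined by multistart.
#'
#' @param sensorgrams data frame with columns \code{time_s},
#'   \code{response_nm}, \code{conc_uM}, \code{phase} (as produced by
#'   \code{\link{simulate_bli}}).
#' @param t_assoc length of the association phase (s); inferred from the
#'   phase column when NULL.
#' @param start optional \code{\link{bli_kinetics}} used as the only start.
#' @return Object of class \code{"bli_fit"}: \code{kinetics}
#'   (\code{\link{bli_kinetics}}), standard errors, residual sum of squares
#'   and a \code{single_phase_warning} flag set when one amplitude
#'   collapses to ~0.
#' @export
fit_bli_biphasic <- function(sensorgrams, t_assoc = NULL, start = NULL) {
  need <- c("time_s", "response_nm", "conc_uM", "phase")
  if (!is.data.frame(sensorgrams) || !all(need %in% names(sensorgrams)))
    stop_domain("`sensorgrams` needs columns %s", paste(need, collapse = ", "))
  concs <- sort(unique(sensorgrams$conc_uM))
  if (length(concs) < 3L)
    stop_domain("at least 3 analyte concentrations are required")
  if (!all(c("association", "dissociation") %in% sensorgrams$phase))
    stop_domain("both association and dissociation phases are required")
  if (is.null(t_assoc))
    t_assoc <- max(sensorgrams$time_s[sensorgrams$phase == "association"])

  t <- sensorgrams$time_s
  y <- sensorgrams$response_nm
  cM <- sensorgrams$conc_uM * 1e-6

  model <- function(kon1, koff1, kon2, koff2, R1, R2)
    bli_phase_response(t, cM, kon1, koff1, R1, t_assoc) +
    bli_phase_response(t, cM, kon2, koff2, R2, t_assoc)

  # par = log(kon1, koff1, kon2, koff2, R1, R2)
  resid_fun <- function(par) {
    p <- exp(par)
    model(p[1L], p[2L], p[3L], p[4L], p[5L], p[6L]) - y
  }

  base <- bli_base_start(sensorgrams, t_assoc)
  starts <- if (!is.null(start)) {
    list(log(c(start$k_on1, start$k_off1, start$k_on2, start$k_off2,
               max(start$Rmax1, 1e-6), max(start$Rmax2, 1e-6))))
  } else {
    bli_start_values(base)
  }

  best <- NULL
  for (s0 in starts) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = s0, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)),
      error = function(cond) NULL)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance))
      best <- f
  }
  if (is.null(best)) stop_fit("BLI global fit failed to converge")

  # nested 1:1 model: with a second amplitude of ~0 the biphasic model is
  # unidentifiable, so prefer the single-phase fit when it already
  # explains the data (parsimony on the nested pair)
  resid_one <- function(par) {
    p <- exp(par)
    bli_phase_response(t, cM, p[1L], p[2L], p[3L], t_assoc) - y
  }
  fit1 <- tryCatch(minpack.lm::nls.lm(
    par = log(base), fn = resid_one,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15)),
    error = function(cond) NULL)
  scale <- sum(y^2)
  single <- !is.null(fit1) &&
    (fit1$deviance < 1e-12 * scale ||
       fit1$deviance <= best$deviance * (1 + 1e-6))

  if (single) {
    p1 <- exp(fit1$par)
    kin <- bli_kinetics(p1[1L], p1[1L], p1[2L], p1[2L], p1[3L], 0)
    vc <- tryCatch(nlslm_vcov(fit1), error = function(cond)
      matrix(NA_real_, 3L, 3L))
    se1 <- sqrt(pmax(diag(vc), 0)) * p1
    se <- c(k_on1 = se1[1L], k_off1 = se1[2L], k_on2 = NA_real_,
            k_off2 = NA_real_, Rmax1 = se1[3L], Rmax2 = 0)
    warning("second phase amplitude ~0; data fit a single 1:1 phase")
    return(structure(list(kinetics = kin, se = se,
                          residual_ss = fit1$deviance,
                          single_phase_warning = TRUE,
                          convergence = list(info = fit1$info,
                                             message = fit1$message)),
                     class = "bli_fit"))
  }

  p <- exp(best$par)
  # phase 1 is the slow-dissociating class
  if (p[2L] > p[4L]) p <- p[c(3L, 4L, 1L, 2L, 6L, 5L)]
  kin <- bli_kinetics(p[1L], p[3L], p[2L], p[4L], p[5L], p[6L])
  vc <- tryCatch(nlslm_vcov(best), error = function(cond)
    matrix(NA_real_, 6L, 6L))
  se <- sqrt(pmax(diag(vc), 0)) * exp(best$par)  # delta method, log scale
  names(se) <- c("k_on1", "k_off1", "k_on2", "k_off2", "Rmax1", "Rmax2")
  structure(list(kinetics = kin, se = se, residual_ss = best$deviance,
                 single_phase_warning = single,
                 convergence = list(info = best$info,
                                    message = best$message)),
            class = "bli_fit")
}

#' @export
print.bli_fit <- function(x, ...) {
  cat(sprintf("Global biphasic BLI fit (RSS %.3g)\n", x$residual_ss))
  print(x$kinetics)
  if (x$single_phase_warning)
    cat("  note: second phase amplitude ~0 (effectively 1:1)\n")
  invisible(x)
}

# crude single-phase starting values: (kon, koff, Rmax)
bli_base_start <- function(sg, t_assoc) {
  dis <- sg[sg$phase == "dissociation" & sg$response_nm > 0, ]
  koff0 <- tryCatch({
    top <- dis[dis$conc_uM == max(dis$conc_uM), ]
    sl <- stats::coef(stats::lm(log(pmax(top$response_nm, 1e-9)) ~
                                  top$time_s))[[2L]]
    max(-sl, 1e-5)
  }, error = function(cond) 1e-3)
  Rtot <- max(sg$response_nm)
  cmax <- max(sg$conc_uM) * 1e-6
  asso <- sg[sg$phase == "association" & sg$conc_uM == max(sg$conc_uM), ]
  kobs0 <- tryCatch({
    req <- max(asso$response_nm)
    z <- 1 - asso$response_nm / (req * 1.02)
    sl <- stats::coef(stats::lm(log(pmax(z, 1e-6)) ~ asso$time_s))[[2L]]
    max(-sl, 1e-4)
  }, error = function(cond) 1e-2)
  kon0 <- max((kobs0 - koff0) / cmax, koff0 / cmax / 10, 1e-2)
  c(kon0, koff0, Rtot)
}

# multiplicative splits of the single-phase start into two phases
bli_start_values <- function(base) {
  kon0 <- base[1L]; koff0 <- base[2L]; Rtot <- base[3L]
  splits <- list(c(1, 1), c(0.2, 5), c(5, 0.2), c(0.1, 10))
  lapply(splits, function(sp)
    log(c(kon0 * sp[1L], koff0 * sp[1L], kon0 * sp[2L], koff0 * sp[2L],
          Rtot / 2, Rtot / 2)))
}
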