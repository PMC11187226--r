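#' Fit the competitive-inhibition constant from a k_obs series
#'
#' Least-squares fit of the hyperbolic competitive-inhibition model
#' \deqn{k_{obs} = k_{max} / (1 + [I]/K_i)}
#' to observed rate constants across inhibitor concentrations.
#'
#' @param series data frame with columns \code{conc_uM} (inhibitor
#'   concentration, micromolar, >= 0, distinct) and \code{kobs_per_min}
#'   (observed rate, min^-1, > 0); an optional \code{se_per_min} column
#'   carries per-point standard errors (reported back; used as
#'   inverse-variance weights only when \code{weighted = TRUE}).
#' @param step_label optional label (\code{"first"}/\code{"second"}/other)
#'   recording which splicing step the series describes.
#' @param weighted if TRUE and \code{se_per_min} is present, minimise
#'   inverse-variance-weighted absolute residuals. The default (FALSE)
#'   minimises relative residuals, matching the roughly constant
#'   coefficient of variation of rate constants estimated from
#'   exponential fits; per-point s.e. estimates from very few replicates
#'   are too noisy to make reliable weights.
#' @return Object of class \code{"inhibition_fit"}: \code{k_max}, \code{K_i}
#'   (micromolar), standard errors, \code{vcov}, residuals, \code{step_label}
#'   and a \code{nonidentifiable} flag.
#' @examples
#' s <- data.frame(conc_uM = c(0, 1, 2, 5, 10, 50),
#'                 kobs_per_min = 0.04 / (1 + c(0, 1, 2, 5, 10, 50) / 2))
#' fit_ki(s)
#' @export
fit_ki <- function(series, step_label = NA_character_, weighted = FALSE) {
  if (!is.data.frame(series) ||
      !all(c("conc_uM", "kobs_per_min") %in% names(series)))
    stop_domain("`series` needs columns conc_uM and kobs_per_min")
  conc <- series$conc_uM; kobs <- series$kobs_per_min
  if (any(!is.finite(conc)) || any(conc < 0) || anyDuplicated(conc))
    stop_domain("concentrations must be distinct, finite and >= 0")
  if (any(!is.finite(kobs)) || any(kobs <= 0))
    stop_domain("k_obs values must be positive")
  if (length(unique(conc)) < 3L)
    stop_domain("at least 3 distinct concentrations are required")

  nonident <- stats::sd(kobs) < 1e-12 * mean(kobs)
  use_w <- weighted && "se_per_min" %in% names(series) &&
    all(is.finite(series$se_per_min)) && all(series$se_per_min > 0)
  w <- if (use_w) 1 / series$se_per_min^2 else rep(1, length(conc))

  kmax0 <- if (any(conc == 0)) mean(kobs[conc == 0]) else max(kobs)
  half <- kobs / kmax0
  ki0 <- tryCatch({
    v <- conc[half > 0 & half < 1] / (1 / half[half > 0 & half < 1] - 1)
    m <- stats::median(v[is.finite(v) & v > 0])
    if (is.finite(m) && m > 0) m else max(conc[conc > 0]) / 2
  }, error = function(cond) max(conc[conc > 0]) / 2)

  resid_fun <- function(par) {
    mu <- exp(par[1L]) / (1 + conc / exp(par[2L]))
    if (use_w) sqrt(w) * (mu - kobs) else (mu - kobs) / mu
  }
  fit <- minpack.lm::nls.lm(par = log(c(kmax0, ki0)), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  est <- exp(fit$par)
  vc_log <- tryCatch(nlslm_vcov(fit), error = function(cond)
    matrix(NA_real_, 2L, 2L))
  J <- diag(est)
  vc <- J %*% vc_log %*% J
  dimnames(vc) <- list(c("k_max", "K_i"), c("k_max", "K_i"))
  se <- sqrt(pmax(diag(vc), 0))
  structure(list(k_max = est[1L], K_i = est[2L],
                 se = stats::setNames(se, c("k_max", "K_i")), vcov = vc,
                 residuals = resid_fun(fit$par), residual_ss = fit$deviance,
                 step_label = step_label, nonidentifiable = nonident,
                 convergence = list(info = fit$info, message = fit$message)),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("Competitive inhibition fit%s\n",
              if (is.na(x$step_label)) "" else paste0(" (", x$step_label,
                                                      " step)")))
  cat(sprintf("  k_max = %.5g +/- %.2g min^-1\n", x$k_max, x$se["k_max"]))
  cat(sprintf("  K_i   = %.5g +/- %.2g uM\n", x$K_i, x$se["K_i"]))
  if (x$nonidentifiable) cat("  warning: k_obs series is flat;",
                             "K_i is not identifiable\n")
  invisible(x)
}

# covariance of an nls.lm fit: sigma^2 * (J'J)^-1 via the stored hessian
nlslm_vcov <- function(fit) {
  p <- length(fit$par)
  n <- length(fit$fvec)
  dof <- max(n - p, 1L)
  s2 <- fit$deviance / dof
  h <- tryCatch(solve(fit$hessian), error = function(cond)
    MASS_ginv(fit$hessian))
  s2 * h  # nls.lm stores J'J as `hessian`
}

MASS_ginv <- function(m) {
  s <- svd(m)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Percentage of reacted precursor for the gel dose response
#'
#' Normalises the precursor fraction measured at 15 min to the assay's
#' reference points: the DMSO control maps to 100 percent and the highest
#' inhibitor concentration to 0 percent:
#' \deqn{\% = 100 (F_{[I]max} - F_{[I]}) / (F_{[I]max} - F_{DMSO})}
#'
#' @param records data frame with columns \code{conc_uM},
#'   \code{frac_precursor_15min} (in [0, 1]), and logical columns
#'   \code{is_dmso} and \code{is_imax} flagging exactly one reference row
#'   each.
#' @return Data frame with columns \code{conc_uM} and \code{percent}.
#' @examples
#' rec <- data.frame(conc_uM = c(0, 5, 250),
#'                   frac_precursor_15min = c(0.2, 0.55, 0.9),
#'                   is_dmso = c(TRUE, FALSE, FALSE),
#'                   is_imax = c(FALSE, FALSE, TRUE))
#' percent_reacted_precursor(rec)  # 100, 50, 0
#' @export
percent_reacted_precursor <- function(records) {
  need <- c("conc_uM", "frac_precursor_15min", "is_dmso", "is_imax")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_domain("`records` needs columns %s", paste(need, collapse = ", "))
  f <- records$frac_precursor_15min
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop_domain("fractions must lie in [0, 1]")
  if (sum(records$is_dmso) != 1L || sum(records$is_imax) != 1L)
    stop_domain("exactly one DMSO and one [I]max reference record required")
  f_dmso <- f[records$is_dmso]
  f_imax <- f[records$is_imax]
  if (abs(f_imax - f_dmso) < 1e-12)
    stop_domain("DMSO and [I]max reference fractions coincide")
  data.frame(conc_uM = records$conc_uM,
             percent = 100 * (f_imax - f) / (f_imax - f_dmso))
}

#' Fit IC50 from a normalised dose-response series
#'
#' One-parameter least-squares fit of the normalised inhibition hyperbola
#' \deqn{\% = 100 / (1 + [I]/IC_{50})}
#' used for both the gel reacted-precursor readout and the FRET activity
#' readout.
#'
#' @param dose_response data frame with columns \code{conc_uM} and
#'   \code{percent}.
#' @param response_kind \code{"percent_reacted_precursor"} or
#'   \code{"percent_activity"}.
#' @return Object of class \code{"dose_response_fit"}: \code{IC50}
#'   (micromolar), \code{se}, \code{response_kind}, residuals and a
#'   \code{monotone_warning} flag set when responses rise with concentration
#'   beyond noise.
#' @examples
#' d <- data.frame(conc_uM = c(0.5, 2, 8), percent = 100 / (1 + c(0.5, 2, 8) / 2.3))
#' fit_ic50(d, "percent_activity")
#' @export
fit_ic50 <- function(dose_response,
                     response_kind = c("percent_reacted_precursor",
                                       "percent_activity")) {
  response_kind <- match.arg(response_kind)
  if (!is.data.frame(dose_response) ||
      !all(c("conc_uM", "percent") %in% names(dose_response)))
    stop_domain("`dose_response` needs columns conc_uM and percent")
  conc <- dose_response$conc_uM; pc <- dose_response$percent
  if (length(unique(conc)) < 3L)
    stop_domain("at least 3 distinct concentrations are required")
  pos <- conc > 0
  warn_mono <- FALSE
  if (sum(pos) >= 3L) {
    sl <- stats::coef(stats::lm(pc[pos] ~ log(conc[pos])))[[2L]]
    warn_mono <- sl > 2  # percent clearly increasing with concentration
  }
  ic0 <- tryCatch({
    v <- conc[pos & pc > 0 & pc < 100] * pc[pos & pc > 0 & pc < 100] /
      (100 - pc[pos & pc > 0 & pc < 100])
    m <- stats::median(v[is.finite(v) & v > 0])
    if (is.finite(m) && m > 0) m else stats::median(conc[pos])
  }, error = function(cond) stats::median(conc[pos]))
  fit <- minpack.lm::nls.lm(par = log(ic0),
                            fn = function(par)
                              100 / (1 + conc / exp(par)) - pc,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  ic50 <- exp(fit$par)
  se <- ic50 * sqrt(diag(as.matrix(nlslm_vcov(fit)))[1L])
  if (warn_mono)
    warning("dose response increases with concentration; IC50 fit flagged")
  structure(list(IC50 = ic50, se = se, response_kind = response_kind,
                 residuals = 100 / (1 + conc / ic50) - pc,
                 residual_ss = fit$deviance,
                 monotone_warning = warn_mono),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit (%s)\n  IC50 = %.4g +/- %.2g uM\n",
              x$response_kind, x$IC50, x$se))
  invisible(x)
}

#' Percent activity from FRET initial slopes
#'
#' For the FRET spliced-exon-reopening readout, intron activity at each
#' inhibitor concentration is the initial slope of the fluorescence trace
#' relative to the DMSO control: \code{100 * slope([I]) / slope(DMSO)}.
#' Slopes come from a linear fit over the configurable initial window.
#'
#' @param traces named list of data frames with columns \code{time} and
#'   \code{signal}; one trace per inhibitor concentration.
#' @param concentrations numeric vector of concentrations (micromolar),
#'   parallel to \code{traces}.
#' @param dmso_trace the DMSO (no-inhibitor) control trace.
#' @param window_frac fraction of early time points used for the slope
#'   (default 0.2; at least 3 points are always used).
#' @return Data frame with columns \code{conc_uM} and \code{percent}
#'   (percent activity).
#' @export
fret_initial_slopes <- function(traces, concentrations, dmso_trace,
                                window_frac = 0.2) {
  if (length(traces) != length(concentrations))
    stop_domain("`traces` and `concentrations` lengths differ")
  s0 <- initial_slope(dmso_trace, window_frac)
  if (!is.finite(s0) || s0 < 1e-12)
    stop_domain("DMSO reference slope must be positive")
  pct <- vapply(traces, function(tr)
    100 * initial_slope(tr, window_frac) / s0, numeric(1L))
  data.frame(conc_uM = concentrations, percent = unname(pct))
}

initial_slope <- function(trace, window_frac) {
  if (!is.data.frame(trace) || !all(c("time", "signal") %in% names(trace)))
    stop_domain("each trace needs columns time and signal")
  n <- max(3L, ceiling(window_frac * nrow(trace)))
  if (nrow(trace) < 3L) stop_domain("at least 3 early time points required")
  tr <- trace[order(trace$time), ][seq_len(min(n, nrow(trace))), ]
  stats::coef(stats::lm(signal ~ time, data = tr))[[2L]]
}

#' Fold-inhibition of each splicing step and step selectivity
#'
#' Fold slow-down of each step under inhibition,
#' \code{fold_i = k_i(control) / k_i(inhibited)}, and the selectivity ratio
#' \code{fold_2 / fold_1} quantifying preferential second-step inhibition.
#'
#' @param control \code{\link{splicing_rates}} without inhibitor.
#' @param inhibited \code{\link{splicing_rates}} in the presence of
#'   inhibitor.
#' @return List with \code{fold_1}, \code{fold_2},
#'   \code{selectivity_ratio}.
#' @examples
#' step_selectivity(splicing_rates(0.037, 0.031), splicing_rates(0.007, 0.001))
#' @export
step_selectivity <- function(control, inhibited) {
  control <- as_splicing_rates(control)
  inhibited <- as_splicing_rates(inhibited)
  f1 <- control$k1 / inhibited$k1
  f2 <- control$k2 / inhibited$k2
  list(fold_1 = f1, fold_2 = f2, selectivity_ratio = f2 / f1)
}
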