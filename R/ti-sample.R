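#' Metropolis sampling of dU/dlambda in one lambda window
#'
#' Random-walk Metropolis sampling of the Boltzmann distribution of the
#' lambda-interpolated toy potential, returning the sample mean and
#' variance of \eqn{\partial U/\partial\lambda = U_B - U_A}. The proposal
#' step is auto-tuned during burn-in towards 40 percent acceptance and then
#' frozen. Deterministic given \code{seed}: the caller's RNG state is left
#' untouched.
#'
#' @param system a \code{\link{toy_alchemical_system}}.
#' @param lambda coupling value in [0, 1].
#' @param n_steps number of production Metropolis steps (after burn-in).
#' @param burn_in fraction of additional steps discarded while tuning
#'   (default 0.2, i.e. 20 percent of \code{n_steps}).
#' @param seed integer seed.
#' @return Object of class \code{"ti_window_sample"}: \code{lambda},
#'   \code{mean}, \code{var}, \code{n}, \code{ess} (autocorrelation-adjusted
#'   effective sample size), \code{se} (= sqrt(var/ess)),
#'   \code{acceptance}, \code{seed} and an \code{acceptance_warning} flag
#'   when the tuned acceptance rate falls outside [0.1, 0.9].
#' @export
sample_dudl <- function(system, lambda, n_steps = 2000L, burn_in = 0.2,
                        seed = 1L) {
  if (!inherits(system, "toy_alchemical_system"))
    stop_domain("`system` must be a toy_alchemical_system")
  check_number(lambda, "lambda", lower = 0)
  if (lambda > 1) stop_domain("lambda must lie in [0, 1]")
  if (n_steps < 10L) stop_domain("`n_steps` must be at least 10")

  q <- coef_at_lambda(system, lambda)
  d <- system$dim
  kT <- system$kT
  n_burn <- max(50L, ceiling(burn_in * n_steps))

  res <- with_seed(seed, {
    x <- rep(-q$c / q$a, d)            # start at the mode
    u <- toy_energy(system, x, lambda)
    step <- sqrt(kT / q$a) * 2.4       # near-optimal for a Gaussian target
    acc_win <- 0L; win <- 0L
    # burn-in with step tuning every 50 steps
    for (s in seq_len(n_burn)) {
      prop <- x + stats::runif(d, -step, step)
      up <- toy_energy(system, prop, lambda)
      if (log(stats::runif(1L)) < (u - up) / kT) {
        x <- prop; u <- up; acc_win <- acc_win + 1L
      }
      win <- win + 1L
      if (win == 50L) {
        step <- step * exp(acc_win / 50 - 0.40)
        acc_win <- 0L; win <- 0L
      }
    }
    dudl <- numeric(n_steps)
    acc <- 0L
    for (s in seq_len(n_steps)) {
      prop <- x + stats::runif(d, -step, step)
      up <- toy_energy(system, prop, lambda)
      if (log(stats::runif(1L)) < (u - up) / kT) {
        x <- prop; u <- up; acc <- acc + 1L
      }
      dudl[s] <- toy_dudl(system, x)
    }
    list(dudl = dudl, acceptance = acc / n_steps, step = step)
  })

  m <- mean(res$dudl)
  v <- stats::var(res$dudl)
  ess <- if (v < .Machine$double.eps) n_steps else ess_initial_positive(res$dudl)
  warn <- res$acceptance < 0.1 || res$acceptance > 0.9
  if (warn)
    warning(sprintf("Metropolis acceptance %.2f outside [0.1, 0.9] at lambda %.3g",
                    res$acceptance, lambda))
  structure(list(lambda = lambda, mean = m, var = v, n = n_steps,
                 ess = max(1, ess), se = sqrt(v / max(1, ess)),
                 acceptance = res$acceptance, step = res$step, seed = seed,
                 acceptance_warning = warn),
            class = "ti_window_sample")
}

# effective sample size by the initial-positive-sequence estimator
ess_initial_positive <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  v0 <- sum(xc^2) / n
  if (v0 <= 0) return(n)
  rho_sum <- 0
  for (k in seq_len(min(n - 1L, 1000L))) {
    rho <- sum(xc[seq_len(n - k)] * xc[(k + 1L):n]) / (n * v0)
    if (rho <= 0) break
    rho_sum <- rho_sum + rho
  }
  max(1, n / (1 + 2 * rho_sum))
}

#' @export
print.ti_window_sample <- function(x, ...) {
  cat(sprintf("lambda %.5f: <dU/dl> = %.5g +/- %.2g (n %d, ess %.0f, acc %.2f)\n",
              x$lambda, x$mean, x$se, x$n, x$ess, x$acceptance))
  invisible(x)
}
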