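#' Solve the baseline hazard from a cumulative-incidence calibration
#'
#' Under an exponential time-to-event model the probability of an event by
#' time `tau` is `1 - exp(-lambda0 * tau)`. This inverts that relationship so
#' the baseline hazard can be stated as "an expected cumulative incidence of
#' `cum_incidence` over `tau` years" for a reference subject (all covariates
#' zero, control arm, unit frailty).
#'
#' @param cum_incidence Probability of an event by `tau`; must be in `[0, 1)`.
#' @param tau Follow-up horizon in years; must be positive.
#' @return Baseline hazard rate per year (`-log(1 - cum_incidence) / tau`).
#' @examples
#' solve_baseline_hazard(0.25, 2) # -log(0.75)/2
#' @export
solve_baseline_hazard <- function(cum_incidence, tau) {
  stopifnot(is.numeric(cum_incidence), length(cum_incidence) == 1L,
            is.numeric(tau), length(tau) == 1L)
  if (tau <= 0) stop("`tau` must be positive")
  if (cum_incidence < 0 || cum_incidence >= 1) {
    stop("`cum_incidence` must lie in [0, 1): an incidence of 1 has no finite rate")
  }
  -log1p(-cum_incidence) / tau
}

#' Specify a cluster-randomized trial design
#'
#' Bundles all parameters of the data-generating model for a two-arm
#' cluster-randomized trial with exponential time-to-event outcomes:
#' per-subject hazard `lambda0 * gamma_i * exp(x_i' beta + T_i * log(delta))`
#' with administrative censoring at `tau`. The baseline hazard `lambda0` is
#' not a free parameter; it is derived from `baseline_cum_incidence` and
#' `tau` via [solve_baseline_hazard()].
#'
#' @param g Clusters per arm (>= 2).
#' @param n Subjects per cluster (>= 1).
#' @param delta Hazard ratio of treatment vs control; `delta = 1` is the null.
#' @param beta Log-hazard coefficients for the cluster-level covariates.
#'   Either a scalar (broadcast to all covariates) or a vector of length
#'   `num_covariates`.
#' @param frailty_var Variance `sigma^2` of the mean-one gamma frailty shared
#'   within a cluster; `0` disables frailty.
#' @param num_covariates Number of binary cluster-level covariates.
#' @param covariate_prob Bernoulli success probability for each covariate.
#' @param tau Administrative censoring time in years.
#' @param baseline_cum_incidence Expected cumulative incidence by `tau` for a
#'   reference subject.
#' @return An object of class `"trial_design"`.
#' @examples
#' trial_design(g = 8, n = 100, delta = 0.5, beta = 0.25)
#' @export
trial_design <- function(g, n, delta = 1, beta = 0, frailty_var = 0,
                         num_covariates = 4L, covariate_prob = 0.3,
                         tau = 2, baseline_cum_incidence = 0.25) {
  g <- as.integer(g); n <- as.integer(n)
  num_covariates <- as.integer(num_covariates)
  if (g < 2L) stop("`g` must be at least 2 clusters per arm")
  if (n < 1L) stop("`n` must be at least 1 subject per cluster")
  if (delta <= 0) stop("`delta` (hazard ratio) must be positive")
  if (frailty_var < 0) stop("`frailty_var` must be nonnegative")
  if (covariate_prob < 0 || covariate_prob > 1) stop("`covariate_prob` must be a probability")
  if (baseline_cum_incidence <= 0 || baseline_cum_incidence >= 1) {
    stop("`baseline_cum_incidence` must lie strictly between 0 and 1")
  }
  if (length(beta) == 1L) beta <- rep(as.numeric(beta), num_covariates)
  if (length(beta) != num_covariates) {
    stop("`beta` must be a scalar or have length `num_covariates`")
  }
  structure(
    list(g = g, n = n, delta = delta, beta = as.numeric(beta),
         frailty_var = frailty_var, num_covariates = num_covariates,
         covariate_prob = covariate_prob, tau = tau,
         baseline_cum_incidence = baseline_cum_incidence,
         baseline_hazard = solve_baseline_hazard(baseline_cum_incidence, tau)),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Cluster-randomized trial design\n")
  cat(sprintf("  %d clusters/arm x %d subjects/cluster (N = %d)\n",
              x$g, x$n, 2L * x$g * x$n))
  cat(sprintf("  hazard ratio delta = %g; beta = (%s); frailty var = %g\n",
              x$delta, paste(format(x$beta), collapse = ", "), x$frailty_var))
  cat(sprintf("  baseline hazard %.5f/yr (%.0f%% incidence by tau = %g yr)\n",
              x$baseline_hazard, 100 * x$baseline_cum_incidence, x$tau))
  invisible(x)
}
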