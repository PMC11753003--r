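#' Fit a Cox proportional-hazards model to a cluster-randomized trial
#'
#' Fits the partial likelihood (Breslow tie convention) for the treatment
#' indicator and/or the first `S` cluster-level covariates, via
#' [survival::coxph()]. Both the model-based (inverse-information) and the
#' cluster-robust (Huber sandwich, clusters as the grouping unit) covariance
#' are retained, along with the Breslow baseline cumulative hazard needed for
#' Cox-Snell residuals. With `S = 0` and no treatment term the fit reduces to
#' the null model: an empty coefficient vector and the Nelson-Aalen/Breslow
#' baseline hazard.
#'
#' Monotone partial likelihoods (separation) are not fatal: the fit is
#' returned with coefficients capped at `|beta| = 15` and `converged = FALSE`
#' so a simulation engine can count and exclude such fits.
#'
#' @param data A `trial_dataset` (or any data frame with `time`, `event`,
#'   `cluster_id`, covariate columns `x1`, `x2`, ..., and `arm`).
#' @param S Number of adjustment covariates (the first `S` of the covariate
#'   columns; they are exchangeable by construction in simulated designs).
#' @param include_treatment Include the `arm` term? Use `FALSE` for the
#'   null-hypothesis fit that feeds the permutation test.
#' @param covariates Optional explicit covariate column names, overriding `S`.
#' @return An object of class `"crt_cox_fit"` with elements `coefficients`,
#'   `model_cov`, `robust_cov`, `baseline_cumhaz` (step function data),
#'   `loglik`, `converged`, `iterations`, and the per-subject linear
#'   predictor `lp`.
#' @export
fit_cox <- function(data, S = 0L, include_treatment = FALSE, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- if (S > 0L) paste0("x", seq_len(S)) else character(0)
  }
  stopifnot(all(covariates %in% names(data)))
  if (sum(data$event) < 1L) stop("no events in the data; the partial likelihood is undefined")
  terms <- c(if (include_treatment) "arm", covariates)

  if (length(terms) == 0L) {
    fit <- list(coefficients = numeric(0),
                model_cov = matrix(0, 0, 0), robust_cov = matrix(0, 0, 0),
                loglik = .breslow_loglik(data$time, data$event, rep(0, nrow(data))),
                converged = TRUE, iterations = 0L,
                lp = rep(0, nrow(data)))
  } else {
    inest <- vapply(data[terms], function(v) stats::var(as.numeric(v)) == 0, logical(1))
    if (any(inest)) {
      # zero-variance design column: coefficient inestimable
      return(.cox_failed_fit(data, terms,
                             sprintf("term(s) %s constant across subjects",
                                     paste(terms[inest], collapse = ", "))))
    }
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(terms, collapse = " + ")))
    converged <- TRUE
    cfit <- withCallingHandlers(
      survival::coxph(fml, data = data, ties = "breslow",
                      cluster = data$cluster_id, robust = TRUE),
      warning = function(w) {
        if (grepl("infinite|did not converge|out of iterations|singular",
                  conditionMessage(w))) converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    beta <- cfit$coefficients
    if (anyNA(beta) || any(abs(beta) > 15)) {
      beta[is.na(beta)] <- 0
      beta <- pmin(pmax(beta, -15), 15)
      converged <- FALSE
    }
    X <- stats::model.matrix(fml, data = data)[, -1L, drop = FALSE]
    fit <- list(coefficients = beta,
                model_cov = cfit$naive.var, robust_cov = cfit$var,
                loglik = cfit$loglik[length(cfit$loglik)],
                converged = converged, iterations = cfit$iter,
                lp = drop(X %*% beta))
    fit$coxph <- cfit
    fit$X <- X
  }
  fit$terms <- terms
  fit$include_treatment <- include_treatment
  fit$time <- data$time
  fit$event <- data$event
  fit$cluster_id <- data$cluster_id
  fit$baseline_cumhaz <- breslow_cumhaz(data$time, data$event, exp(fit$lp))
  class(fit) <- "crt_cox_fit"
  fit
}

.cox_failed_fit <- function(data, terms, reason) {
  beta <- stats::setNames(rep(0, length(terms)), terms)
  k <- length(terms)
  structure(list(coefficients = beta,
                 model_cov = matrix(NA_real_, k, k),
                 robust_cov = matrix(NA_real_, k, k),
                 loglik = NA_real_, converged = FALSE, iterations = 0L,
                 lp = rep(0, nrow(data)), terms = terms,
                 include_treatment = "arm" %in% terms,
                 time = data$time, event = data$event,
                 cluster_id = data$cluster_id,
                 baseline_cumhaz = breslow_cumhaz(data$time, data$event,
                                                  rep(1, nrow(data))),
                 failure = reason),
            class = "crt_cox_fit")
}

#' @export
print.crt_cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties)\n")
  if (length(x$coefficients) == 0L) {
    cat("  null model (baseline hazard only)\n")
  } else {
    se_m <- sqrt(diag(x$model_cov)); se_r <- sqrt(diag(x$robust_cov))
    print(data.frame(term = names(x$coefficients), estimate = x$coefficients,
                     se_model = se_m, se_robust = se_r, row.names = NULL))
  }
  if (!x$converged) cat("  ** fit flagged as non-converged **\n")
  invisible(x)
}

# Breslow partial log-likelihood at a fixed linear predictor
.breslow_loglik <- function(time, event, lp) {
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]; r_s <- exp(lp[o])
  risk_from <- rev(cumsum(rev(r_s)))
  first <- !duplicated(t_s)
  denom <- risk_from[first][match(t_s, t_s[first])]
  sum(lp[o][e_s == 1]) - sum(e_s * log(denom))
}

#' Breslow baseline cumulative hazard
#'
#' `H0(t) = sum over event times s <= t of d_s / sum(risk at s)`, where the
#' risk score of subject `j` is `exp(lp_j)`. Right-continuous step function.
#'
#' @param time Observed times.
#' @param event 0/1 event indicators.
#' @param risk Per-subject risk scores `exp(lp)`; defaults to 1 (null model,
#'   giving the Nelson-Aalen estimator).
#' @return A list with sorted unique event `times`, the cumulative hazard
#'   `cumhaz` at each, and an evaluator accessible via [eval_cumhaz()].
#' @export
breslow_cumhaz <- function(time, event, risk = rep(1, length(time))) {
  stopifnot(length(time) == length(event), length(risk) == length(time))
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]; r_s <- risk[o]
  risk_from <- rev(cumsum(rev(r_s)))            # sum of risk over {t >= t_s[i]}
  first <- which(!duplicated(t_s))
  ut <- t_s[first]
  denom <- risk_from[first]
  d <- as.vector(rowsum(e_s, group = match(t_s, ut)))
  keep <- d > 0
  structure(list(times = ut[keep], cumhaz = cumsum(d[keep] / denom[keep])),
            class = "breslow_cumhaz")
}

#' Evaluate a Breslow cumulative hazard at given times
#'
#' Right-continuous step convention: `H0(y)` accumulates all event times
#' `<= y`; times before the first event map to 0.
#'
#' @param H A [breslow_cumhaz()] object.
#' @param times Evaluation times.
#' @return Numeric vector of cumulative hazards.
#' @export
eval_cumhaz <- function(H, times) {
  idx <- findInterval(times, H$times)
  c(0, H$cumhaz)[idx + 1L]
}

#' Cluster-robust (sandwich) covariance of a Cox fit
#'
#' Huber sandwich `A^{-1} (sum_i U_i U_i') A^{-1}` where `U_i` aggregates the
#' score residuals of cluster `i` and `A` is the observed information;
#' computed from the dfbeta residuals collapsed by cluster. With one subject
#' per cluster this is the Lin-Wei robust variance.
#'
#' @param fit A `"crt_cox_fit"` with at least one coefficient.
#' @param cluster_ids Grouping; defaults to the fit's own cluster ids.
#' @return Symmetric covariance matrix.
#' @export
robust_variance <- function(fit, cluster_ids = fit$cluster_id) {
  stopifnot(inherits(fit, "crt_cox_fit"))
  if (length(fit$coefficients) == 0L) stop("null model has no coefficients")
  if (is.null(fit$coxph)) stop("fit carries no model object (failed fit?)")
  D <- stats::residuals(fit$coxph, type = "dfbeta", collapse = cluster_ids)
  D <- as.matrix(D)
  crossprod(D)
}

#' Cox-Snell residuals
#'
#' `r_Cj = exp(x_j' beta_hat) * H0(y_j)`: the fitted cumulative hazard at
#' each subject's observed time. Unit-exponential (censored at the subject's
#' censoring time) when the model is correct. For the null-model fit feeding
#' the permutation test the linear predictor contains no treatment term.
#'
#' @param fit A `"crt_cox_fit"`.
#' @return Nonnegative vector, one residual per subject.
#' @export
cox_snell_residuals <- function(fit) {
  stopifnot(inherits(fit, "crt_cox_fit"))
  exp(fit$lp) * eval_cumhaz(fit$baseline_cumhaz, fit$time)
}

#' Deviance residuals from Cox-Snell residuals
#'
#' `r_Dj = sign(d_j - r_Cj) * sqrt(-2 * (d_j - r_Cj + d_j * log(r_Cj)))`
#' with event indicator `d_j`. A censored subject with `r_C = 0` maps to 0 by
#' continuity; an event with `r_C = 0` would be infinite and raises an error
#' (it cannot occur under the Breslow baseline, which jumps at every event).
#'
#' @param cox_snell Nonnegative Cox-Snell residuals.
#' @param event 0/1 event indicators.
#' @return Signed residual vector, same length.
#' @export
deviance_residuals <- function(cox_snell, event) {
  stopifnot(length(cox_snell) == length(event), all(cox_snell >= 0),
            all(event %in% c(0, 1)))
  if (any(event == 1 & cox_snell == 0)) {
    stop("event subject with zero Cox-Snell residual: deviance residual is infinite")
  }
  dev <- numeric(length(cox_snell))
  cens <- event == 0
  dev[cens] <- -sqrt(2 * cox_snell[cens])
  ev <- !cens
  arg <- -2 * (1 - cox_snell[ev] + log(cox_snell[ev]))
  dev[ev] <- sign(1 - cox_snell[ev]) * sqrt(pmax(arg, 0))
  dev
}

#' Wald test of the treatment hazard ratio
#'
#' Two-sided Wald test of `H0: HR = null_hr` using either the model-based or
#' the cluster-robust standard error: reject when the `level` confidence
#' interval for the hazard ratio excludes `null_hr`.
#'
#' @param fit A `"crt_cox_fit"` that includes the treatment term.
#' @param variance `"robust"` (default) or `"model"`.
#' @param null_hr Null hazard ratio, default 1.
#' @param level Confidence level, default 0.95.
#' @return A list with `estimate` (hazard ratio), `ci`, `p_value`, `reject`,
#'   and the standard error used.
#' @export
wald_reject <- function(fit, variance = c("robust", "model"),
                        null_hr = 1, level = 0.95) {
  stopifnot(inherits(fit, "crt_cox_fit"))
  variance <- match.arg(variance)
  if (!("arm" %in% names(fit$coefficients))) {
    stop("fit has no treatment ('arm') term")
  }
  i <- match("arm", names(fit$coefficients))
  V <- if (variance == "robust") fit$robust_cov else fit$model_cov
  se <- sqrt(V[i, i])
  est <- fit$coefficients[[i]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- exp(est + c(-1, 1) * z * se)
  zstat <- (est - log(null_hr)) / se
  list(estimate = exp(est), se = se, ci = ci,
       p_value = 2 * stats::pnorm(-abs(zstat)),
       reject = null_hr < ci[1] || null_hr > ci[2])
}

#' Summarize a Cox fit as a tidy table
#'
#' @param fit A `"crt_cox_fit"`.
#' @param level Confidence level for the (robust) intervals.
#' @return Data frame with one row per term: `term, estimate, se_model,
#'   se_robust, ci_low, ci_high, p` (robust-based CI and p).
#' @export
cox_summary_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "crt_cox_fit"))
  if (length(fit$coefficients) == 0L) {
    return(data.frame(term = character(0), estimate = numeric(0),
                      se_model = numeric(0), se_robust = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0), p = numeric(0)))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  se_m <- sqrt(diag(fit$model_cov)); se_r <- sqrt(diag(fit$robust_cov))
  data.frame(term = names(b), estimate = unname(b),
             se_model = se_m, se_robust = se_r,
             ci_low = unname(exp(b - z * se_r)),
             ci_high = unname(exp(b + z * se_r)),
             p = unname(2 * stats::pnorm(-abs(b / se_r))), row.names = NULL)
}
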