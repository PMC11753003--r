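#' Monte-Carlo standard error of a simulated proportion
#'
#' `sqrt(p * (1 - p) / n)`; zero exactly when the estimate is 0 or 1.
#'
#' @param p Estimated proportion(s).
#' @param n Number of simulation replicates.
#' @return Standard error(s).
#' @export
mcse <- function(p, n) sqrt(p * (1 - p) / n)

#' Define a simulation scenario
#'
#' One cell of the simulation study: a data-generating design, a
#' randomization constraint `q`, the analysis methods and adjustment levels
#' to run, and the Monte-Carlo settings.
#'
#' @param design A [trial_design()].
#' @param q Constraint percentile; `1` is simple randomization.
#' @param methods Subset of `"cox_robust"`, `"cox_frailty"`, `"permutation"`.
#' @param S_values Adjustment levels, subset of `0:num_covariates`.
#' @param n_sim Number of replicates.
#' @param seed Master seed; every replicate derives its own sub-seeds from
#'   it, so results do not depend on execution order.
#' @param n_draws Allocation draws per replicate when the space is sampled
#'   (small designs are enumerated instead, see [allocation_space()]).
#' @return An object of class `"crt_scenario"`.
#' @export
crt_scenario <- function(design, q = 1,
                         methods = c("cox_robust", "cox_frailty", "permutation"),
                         S_values = 0:4, n_sim = 500L, seed = 1L,
                         n_draws = 20000L) {
  stopifnot(inherits(design, "trial_design"))
  methods <- match.arg(methods, c("cox_robust", "cox_frailty", "permutation"),
                       several.ok = TRUE)
  if (q <= 0 || q > 1) stop("`q` must lie in (0, 1]")
  if (n_sim < 1L) stop("`n_sim` must be at least 1")
  if (any(S_values < 0L) || any(S_values > design$num_covariates)) {
    stop("`S_values` must lie in 0..num_covariates")
  }
  check_pairing(design$beta, design$frailty_var)
  structure(list(design = design, q = q, methods = methods,
                 S_values = as.integer(S_values), n_sim = as.integer(n_sim),
                 seed = as.integer(seed), n_draws = as.integer(n_draws)),
            class = "crt_scenario")
}

# per-replicate sub-seeds: stage columns are covariates, frailties,
# space sampling, allocation selection, outcomes
.replicate_seeds <- function(scenario) {
  set.seed(scenario$seed)
  matrix(sample.int(2147483646L, scenario$n_sim * 5L, replace = TRUE),
         nrow = scenario$n_sim, ncol = 5L)
}

# shared enumerated allocation space, or NULL when sampling is needed
.scenario_space_template <- function(scenario) {
  m <- 2L * scenario$design$g
  if (choose(m, scenario$design$g) <= 1e6) {
    allocation_space(m, method = "enumerate")
  } else NULL
}

#' Run a single simulation replicate
#'
#' One replicate draws the cluster covariates and frailties, builds and
#' scores the allocation space from that same covariate matrix, constrains
#' it at `q`, selects the trial's allocation, simulates outcomes, and runs
#' every requested analysis at every adjustment level `S`. Covariates that
#' happen to be constant across all clusters in a replicate carry no balance
#' or adjustment information and are dropped from both the score and the
#' models for that replicate.
#'
#' Replicate `i` always consumes sub-seeds `i` of the master seed, so
#' [run_scenario()] results are reproducible and independent of scheduling,
#' and scenarios differing only in `q` or analysis settings share identical
#' datasets at each replicate index.
#'
#' @param scenario A [crt_scenario()].
#' @param replicate_index Replicate number in `1..n_sim`.
#' @param return_data Also return the simulated dataset and design objects.
#' @return A data frame with one row per (method, S): logical `reject`
#'   (`NA` when the fit was flagged) and `flagged`. With
#'   `return_data = TRUE`, a list also carrying `data`, `space`, `selection`.
#' @export
run_replicate <- function(scenario, replicate_index, return_data = FALSE) {
  stopifnot(inherits(scenario, "crt_scenario"),
            replicate_index >= 1L, replicate_index <= scenario$n_sim)
  seeds <- .replicate_seeds(scenario)[replicate_index, ]
  .run_replicate_impl(scenario, seeds, .scenario_space_template(scenario),
                      return_data = return_data)
}

.run_replicate_impl <- function(scenario, seeds, space_template,
                                return_data = FALSE) {
  design <- scenario$design
  m <- 2L * design$g

  set.seed(seeds[1])
  covariates <- draw_cluster_covariates(m, design$covariate_prob,
                                        design$num_covariates)
  set.seed(seeds[2])
  frailties <- draw_frailties(m, design$frailty_var)

  if (is.null(space_template)) {
    set.seed(seeds[3])
    space <- allocation_space(m, n_draws = scenario$n_draws, method = "sample")
  } else {
    space <- space_template
  }
  active <- which(apply(covariates, 1, stats::var) > 0)
  if (length(active) > 0) {
    space <- score_allocations(space, covariates[active, , drop = FALSE])
  } else {
    space$scores <- rep(0, nrow(space$assign))
  }
  space <- constrain(space, scenario$q)

  set.seed(seeds[4])
  selection <- select_allocation(space)

  set.seed(seeds[5])
  data <- simulate_trial(design, covariates, frailties, selection$assignment)

  rows <- expand.grid(method = scenario$methods, S = scenario$S_values,
                      stringsAsFactors = FALSE)
  rows$reject <- NA
  rows$flagged <- FALSE
  rbar_cache <- list()
  for (r in seq_len(nrow(rows))) {
    S <- rows$S[r]
    idx <- intersect(seq_len(S), active)
    covs <- if (length(idx)) paste0("x", idx) else character(0)
    res <- switch(
      rows$method[r],
      cox_robust = {
        fit <- fit_cox(data, covariates = covs, include_treatment = TRUE)
        if (fit$converged) list(wald_reject(fit, "robust")$reject, FALSE)
        else list(NA, TRUE)
      },
      cox_frailty = {
        fit <- fit_mixed_cox(data, covariates = covs, include_treatment = TRUE)
        if (fit$converged) list(mixed_wald_reject(fit)$reject, FALSE)
        else list(NA, TRUE)
      },
      permutation = {
        key <- paste0("S_", paste(covs, collapse = ","))
        if (is.null(rbar_cache[[key]])) {
          nf <- fit_cox(data, covariates = covs, include_treatment = FALSE)
          rbar_cache[[key]] <-
            if (nf$converged) cluster_residual_means(
              deviance_residuals(cox_snell_residuals(nf), data$event),
              data$cluster_id)
            else NA
        }
        rbar <- rbar_cache[[key]]
        if (length(rbar) == 1L && is.na(rbar[1])) list(NA, TRUE)
        else list(permutation_pvalue(rbar, space, selection$assignment,
                                     use_constrained = TRUE)$reject, FALSE)
      })
    rows$reject[r] <- res[[1]]
    rows$flagged[r] <- res[[2]]
  }
  if (return_data) {
    list(results = rows, data = data, space = space, selection = selection,
         covariates = covariates, frailties = frailties)
  } else rows
}

#' Run a full simulation scenario
#'
#' Executes all `n_sim` replicates of a scenario and aggregates per
#' (method, S) rejection rates with Monte-Carlo standard errors. Flagged
#' (non-converged) fits are excluded from that cell's denominator and their
#' count reported, rather than silently biasing the rate in either
#' direction.
#'
#' @param scenario A [crt_scenario()].
#' @param progress Print a dot every 50 replicates.
#' @return A data frame of class `"scenario_result"`, one row per
#'   (method, S): `g, n, delta, beta, sigma2, q, method, S, reject_rate,
#'   mcse, n_sim, n_eff, n_flagged`.
#' @export
run_scenario <- function(scenario, progress = FALSE) {
  stopifnot(inherits(scenario, "crt_scenario"))
  seeds <- .replicate_seeds(scenario)
  template <- .scenario_space_template(scenario)
  acc <- vector("list", scenario$n_sim)
  for (i in seq_len(scenario$n_sim)) {
    acc[[i]] <- .run_replicate_impl(scenario, seeds[i, ], template)
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  all <- do.call(rbind, acc)
  des <- scenario$design
  agg <- do.call(rbind, lapply(
    split(all, list(all$method, all$S), drop = TRUE),
    function(d) {
      ok <- !d$flagged
      n_eff <- sum(ok)
      rate <- if (n_eff > 0) mean(d$reject[ok]) else NA_real_
      data.frame(g = des$g, n = des$n, delta = des$delta,
                 beta = des$beta[1], sigma2 = des$frailty_var,
                 q = scenario$q, method = d$method[1], S = d$S[1],
                 reject_rate = rate, mcse = mcse(rate, n_eff),
                 n_sim = scenario$n_sim, n_eff = n_eff,
                 n_flagged = sum(d$flagged))
    }))
  agg <- agg[order(agg$method, agg$S), ]
  rownames(agg) <- NULL
  class(agg) <- c("scenario_result", "data.frame")
  attr(agg, "scenario") <- scenario
  agg
}

#' Expand the study's scenario grid
#'
#' Builds the Cartesian scenario grid with the study's pairing rule:
#' prognostic settings put the cluster effect in the covariates
#' (`beta > 0`, no frailty) and non-prognostic settings put it in the gamma
#' frailty (`beta = 0`, `sigma2 > 0`). Combining `beta > 0` with
#' `sigma2 > 0` is rejected: the frailty would add intraclass correlation on
#' top of the covariate-driven correlation, making the prognostic vs
#' non-prognostic comparison uninterpretable.
#'
#' @param g Clusters-per-arm values.
#' @param delta Hazard ratios.
#' @param beta Prognostic coefficient values (each used with `sigma2 = 0`);
#'   may include 0, which is skipped on the prognostic side.
#' @param sigma2 Non-prognostic frailty variances (each used with
#'   `beta = 0`); may include 0, which is skipped.
#' @param q Constraint percentiles.
#' @param n Subjects per cluster.
#' @param n_sim,seed,n_draws Passed to [crt_scenario()]; seeds are offset by
#'   grid position so scenarios are independent but reproducible.
#' @param baseline_cum_incidence Two-year incidence calibration.
#' @param methods,S_values Passed to [crt_scenario()].
#' @return List of [crt_scenario()] objects; the parameter table is attached
#'   as `attr(, "grid")`.
#' @export
scenario_grid <- function(g = c(8L, 13L), delta = c(1, 0.5),
                          beta = c(0.25, 0.35, 0.50),
                          sigma2 = c(0.087, 0.143, 0.268),
                          q = c(1, 0.10, 0.01), n = 100L,
                          n_sim = 1000L, seed = 1L, n_draws = 20000L,
                          baseline_cum_incidence = 0.25,
                          methods = c("cox_robust", "cox_frailty", "permutation"),
                          S_values = 0:4) {
  prog <- expand.grid(g = g, delta = delta, beta = beta[beta > 0], sigma2 = 0,
                      q = q, stringsAsFactors = FALSE)
  nonprog <- expand.grid(g = g, delta = delta, beta = 0,
                         sigma2 = sigma2[sigma2 > 0], q = q,
                         stringsAsFactors = FALSE)
  grid <- rbind(prog, nonprog)
  scenarios <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    design <- trial_design(g = row$g, n = n, delta = row$delta,
                           beta = row$beta, frailty_var = row$sigma2,
                           baseline_cum_incidence = baseline_cum_incidence)
    crt_scenario(design, q = row$q, methods = methods, S_values = S_values,
                 n_sim = n_sim, seed = (seed + i - 1L) %% 2147483647L,
                 n_draws = n_draws)
  })
  attr(scenarios, "grid") <- grid
  scenarios
}

#' Validate a prognostic/non-prognostic parameter pairing
#'
#' @param beta Covariate coefficient (scalar or vector).
#' @param sigma2 Frailty variance.
#' @return Invisibly `TRUE`; errors when both are positive.
#' @export
check_pairing <- function(beta, sigma2) {
  if (any(beta > 0) && sigma2 > 0) {
    stop("beta > 0 combined with sigma2 > 0: frailty on top of prognostic ",
         "covariates induces extra intraclass correlation, making the ",
         "prognostic vs non-prognostic comparison uninterpretable")
  }
  invisible(TRUE)
}
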