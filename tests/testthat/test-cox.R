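test_that("the fitted coefficient maximizes the Breslow partial likelihood", {
  dat <- tiny_cox_data()
  beta_grid <- oracle_grid_beta(dat$time, dat$event, dat$x1)
  fit <- fit_cox(dat, S = 1)
  expect_lt(abs(fit$coefficients[["x1"]] - beta_grid), 1e-3)
  expect_true(fit$converged)
  # the package loglik agrees with the loop oracle at the optimum
  expect_equal(fit$loglik,
               oracle_breslow_loglik(fit$coefficients[["x1"]],
                                     dat$time, dat$event, dat$x1),
               tolerance = 1e-8)
})

test_that("oracle equivalence holds on random small datasets", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10L
    dat <- data.frame(cluster_id = 1:n, subject_id = 1L,
                      time = round(rexp(n), 3) + 0.001,
                      event = rbinom(n, 1, 0.7),
                      x1 = rbinom(n, 1, 0.5), arm = NA_integer_)
    if (sum(dat$event) < 2 || var(dat$x1) == 0) next
    fit <- fit_cox(dat, S = 1)
    if (!fit$converged) next  # separation: grid argmax sits at the boundary
    expect_lt(abs(fit$coefficients[["x1"]] -
                  oracle_grid_beta(dat$time, dat$event, dat$x1)), 1e-3)
  }
})

test_that("null model reduces to the Nelson-Aalen/Breslow baseline", {
  trial <- small_trial(seed = 20)
  fit <- fit_cox(trial$data, S = 0)
  expect_length(fit$coefficients, 0)
  ref <- survival::basehaz(
    survival::coxph(survival::Surv(time, event) ~ 1, data = trial$data,
                    ties = "breslow"), centered = FALSE)
  mine <- eval_cumhaz(fit$baseline_cumhaz, ref$time)
  expect_equal(mine, ref$hazard, tolerance = 1e-8)
})

test_that("constant design column yields a flagged, not crashed, fit", {
  dat <- tiny_cox_data()
  dat$x1 <- 1L
  fit <- fit_cox(dat, S = 1)
  expect_false(fit$converged)
  expect_error(fit_cox(dat[dat$event == 0, ], S = 0), "no events")
})

test_that("Cox-Snell residuals follow the Breslow construction", {
  trial <- small_trial(seed = 21)
  fit <- fit_cox(trial$data, S = 0)
  rc <- cox_snell_residuals(fit)
  expect_true(all(rc >= 0))
  # smallest event time among N all at risk: first Breslow increment 1/N
  n <- nrow(trial$data)
  j <- which.min(trial$data$time)
  expect_equal(trial$data$event[j], 1L)
  expect_equal(rc[j], 1 / n)
  # martingale identity: sum(delta - r_C) = 0 for the fitted model
  expect_equal(sum(trial$data$event - rc), 0, tolerance = 1e-9)
  fit4 <- fit_cox(trial$data, S = 4, include_treatment = TRUE)
  rc4 <- cox_snell_residuals(fit4)
  expect_equal(sum(trial$data$event - rc4), 0, tolerance = 1e-9)
  # beta = 0 fit: r_C is the baseline cumulative hazard itself
  expect_equal(rc, eval_cumhaz(fit$baseline_cumhaz, trial$data$time))
})

test_that("deviance residuals match the closed form and survival's", {
  # hand evaluations
  expect_equal(deviance_residuals(1, 1), 0)
  expect_equal(deviance_residuals(0.5, 0), -1)
  expect_equal(deviance_residuals(0.5, 1), sqrt(-2 * (0.5 + log(0.5))))
  expect_equal(deviance_residuals(0, 0), 0)
  expect_error(deviance_residuals(0, 1), "infinite")
  # sign agrees with sign(delta - r_C)
  set.seed(22)
  rc <- runif(50, 0.01, 3)
  ev <- rbinom(50, 1, 0.5)
  expect_true(all(sign(deviance_residuals(rc, ev)) == sign(ev - rc) |
                  deviance_residuals(rc, ev) == 0))
  # cross-check against survival's residuals on a fitted model
  trial <- small_trial(seed = 23)
  fit <- fit_cox(trial$data, S = 2, include_treatment = TRUE)
  sfit <- survival::coxph(survival::Surv(time, event) ~ arm + x1 + x2,
                          data = trial$data, ties = "breslow")
  mine <- deviance_residuals(cox_snell_residuals(fit), trial$data$event)
  expect_equal(unname(mine), unname(residuals(sfit, type = "deviance")),
               tolerance = 1e-6)
})

test_that("cluster-robust variance matches the collapsed-dfbeta sandwich", {
  trial <- small_trial(seed = 24)
  fit <- fit_cox(trial$data, S = 2, include_treatment = TRUE)
  V <- robust_variance(fit)
  expect_equal(V, fit$robust_cov, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(V, t(V))
  expect_true(all(diag(V) >= 0))
  # one subject per cluster: reduces to the unclustered Lin-Wei sandwich
  dat <- trial$data
  dat$cluster_id <- seq_len(nrow(dat))
  fit1 <- fit_cox(dat, S = 2, include_treatment = TRUE)
  ref <- survival::coxph(survival::Surv(time, event) ~ arm + x1 + x2,
                         data = dat, ties = "breslow", robust = TRUE)
  expect_equal(robust_variance(fit1), ref$var, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("coefficients are invariant to rescaling the time axis", {
  trial <- small_trial(seed = 25)
  fit <- fit_cox(trial$data, S = 3, include_treatment = TRUE)
  scaled <- trial$data
  scaled$time <- scaled$time * 37.2
  fit2 <- fit_cox(scaled, S = 3, include_treatment = TRUE)
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-8)
})

test_that("Wald rejection follows the confidence interval", {
  trial <- small_trial(seed = 26)
  fit <- fit_cox(trial$data, S = 0, include_treatment = TRUE)
  # synthetic fits with controlled estimate and SE
  fake <- fit
  fake$coefficients <- c(arm = -0.6931)
  fake$robust_cov <- matrix(0.01, 1, 1, dimnames = list("arm", "arm"))
  fake$model_cov <- fake$robust_cov
  out <- wald_reject(fake)
  expect_true(out$reject)
  expect_equal(out$ci, exp(-0.6931 + c(-1, 1) * qnorm(0.975) * 0.1),
               tolerance = 1e-10)
  fake$coefficients <- c(arm = 0)
  expect_false(wald_reject(fake)$reject)
  expect_error(wald_reject(fit_cox(trial$data, S = 1)), "no treatment")
  # summary table is consistent with the test
  tab <- cox_summary_table(fit)
  expect_named(tab, c("term", "estimate", "se_model", "se_robust",
                      "ci_low", "ci_high", "p"))
})
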