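test_that("baseline hazard inverts the exponential incidence calibration", {
  expect_equal(solve_baseline_hazard(0.25, 2), -log(0.75) / 2)
  expect_equal(solve_baseline_hazard(0, 2), 0)
  expect_equal(solve_baseline_hazard(1 - exp(-2), 2), 1)
  expect_error(solve_baseline_hazard(1, 2), "cum_incidence")
  expect_error(solve_baseline_hazard(0.25, 0), "tau")
})

test_that("cluster covariates are Bernoulli with the requested probability", {
  set.seed(1)
  expect_true(all(draw_cluster_covariates(10, 0) == 0))
  expect_true(all(draw_cluster_covariates(10, 1) == 1))
  # per-entry mean over many replicate draws within 3 binomial SEs of 0.3
  draws <- replicate(10000, draw_cluster_covariates(16, 0.3)[1, 1])
  expect_lt(abs(mean(draws) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  expect_equal(dim(draw_cluster_covariates(16, 0.3)), c(4L, 16L))
})

test_that("gamma frailties have mean one and the requested variance", {
  expect_identical(draw_frailties(8, 0), rep(1, 8))
  expect_error(draw_frailties(8, -0.1), "nonnegative")
  set.seed(2)
  x <- draw_frailties(1e5, 0.268)
  expect_lt(abs(mean(x) - 1), 3 * sqrt(0.268 / 1e5))
  set.seed(3)
  y <- draw_frailties(1e5, 0.087)
  expect_lt(abs(var(y) - 0.087), 0.01)
  expect_true(all(x > 0))
})

test_that("simulated trials respect the rate model and censoring contract", {
  design <- trial_design(g = 8, n = 500, delta = 1, beta = 0)
  m <- 16L
  covs <- matrix(0L, 4, m)
  alloc <- rep(c(0L, 1L), 8)
  set.seed(4)
  dat <- simulate_trial(design, covs, allocation = alloc)
  n_tot <- nrow(dat)
  # event fraction calibrated to the 25% two-year incidence
  expect_lt(abs(mean(dat$event) - 0.25), 3 * sqrt(0.25 * 0.75 / n_tot))
  # censoring contract
  expect_true(all(dat$time <= design$tau))
  expect_identical(dat$event, as.integer(dat$latent_time <= design$tau))
  expect_identical(dat$time, pmin(dat$latent_time, design$tau))

  # treated-arm event proportion under delta = 0.5: 1 - 0.75^0.5
  design2 <- trial_design(g = 8, n = 500, delta = 0.5, beta = 0)
  set.seed(5)
  dat2 <- simulate_trial(design2, covs, allocation = alloc)
  trt <- dat2$arm == 1
  expect_lt(abs(mean(dat2$event[trt]) - (1 - 0.75^0.5)),
            3 * sqrt(0.134 * 0.866 / sum(trt)))
})

test_that("doubling the baseline hazard exactly halves latent times draw-for-draw", {
  covs <- matrix(0L, 4, 8)
  alloc <- rep(c(0L, 1L), 4)
  d1 <- trial_design(g = 4, n = 50, baseline_cum_incidence = 0.25)
  # incidence chosen so the derived rate is exactly twice d1's
  d2 <- trial_design(g = 4, n = 50, baseline_cum_incidence = 1 - 0.75^2)
  expect_equal(d2$baseline_hazard, 2 * d1$baseline_hazard)
  set.seed(6); t1 <- simulate_trial(d1, covs, allocation = alloc)$latent_time
  set.seed(6); t2 <- simulate_trial(d2, covs, allocation = alloc)$latent_time
  expect_equal(t2, t1 / 2)
})

test_that("identical seeds reproduce identical datasets", {
  design <- trial_design(g = 4, n = 10, beta = 0.25)
  covs <- matrix(rbinom(32, 1, 0.5), 4)
  alloc <- rep(c(0L, 1L), 4)
  set.seed(7); a <- simulate_trial(design, covs, allocation = alloc)
  set.seed(7); b <- simulate_trial(design, covs, allocation = alloc)
  expect_identical(a, b)
})

test_that("simulate_trial validates dimensions and allocations", {
  design <- trial_design(g = 4, n = 10)
  covs <- matrix(0L, 4, 8)
  expect_error(simulate_trial(design, covs[, 1:6]), "matrix")
  expect_error(simulate_trial(design, covs, allocation = rep(1L, 8)),
               "exactly g")
  expect_error(simulate_trial(design, covs, frailties = rep(-1, 8)),
               "positive")
})

test_that("empirical ICC matches hand computation and its invariances", {
  times <- c(0, 2, 4, 6)
  ids <- c(1, 1, 2, 2)
  # cluster means 1 and 5 -> between-var 8; within vars 2 and 2 -> mean 2
  expect_equal(empirical_icc(times, ids), 0.8)
  # scale invariance
  expect_equal(empirical_icc(17.3 * times, ids), 0.8)
  # sigma_w = 0 -> ICC 1
  expect_equal(empirical_icc(c(1, 1, 3, 3), ids), 1)
  # one common distribution, many subjects -> ICC near 0
  set.seed(8)
  x <- rexp(4000)
  expect_lt(empirical_icc(x, rep(1:8, each = 500)), 0.02)
  expect_error(empirical_icc(c(1, 1, 1, 1), ids), "undefined")
  expect_error(empirical_icc(1:4, c(1, 2, 3, 4)), "2 subjects")
})
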