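# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: straightforward loops, enumeration, and closed
# forms only.

# Breslow partial log-likelihood for a single binary covariate, by direct
# summation over events (risk sets recomputed from scratch each time).
oracle_breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (j in which(event == 1)) {
    at_risk <- which(time >= time[j])
    ll <- ll + beta * x[j] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# grid-search maximizer of the oracle likelihood
oracle_grid_beta <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  n1 <- n0 <- numeric(sum(event))
  ev <- which(event == 1)
  for (i in seq_along(ev)) {
    at_risk <- which(time >= time[ev[i]])
    n1[i] <- sum(x[at_risk] == 1)
    n0[i] <- sum(x[at_risk] == 0)
  }
  xev <- x[ev]
  ll <- vapply(grid, function(b) sum(b * xev - log(n1 * exp(b) + n0)),
               numeric(1))
  grid[which.max(ll)]
}

# all g-of-2g assignments by direct enumeration
oracle_enumerate <- function(m) {
  g <- m %/% 2L
  combos <- utils::combn(m, g)
  lapply(seq_len(ncol(combos)), function(j) {
    a <- integer(m); a[combos[, j]] <- 1L; a
  })
}

# the 6-subject worked dataset: one subject per cluster, one binary
# covariate, interleaved so the partial likelihood has an interior maximum
tiny_cox_data <- function() {
  data.frame(cluster_id = 1:6, subject_id = 1L,
             time = c(1, 2, 3, 4, 5, 6),
             event = c(1L, 1L, 0L, 1L, 1L, 1L),
             x1 = c(1L, 0L, 1L, 0L, 1L, 0L),
             arm = NA_integer_)
}

# a small simulated trial with a realized allocation, for fit-level tests
small_trial <- function(seed = 42, g = 4L, n = 25L, delta = 1, beta = 0.25,
                        frailty_var = 0) {
  design <- trial_design(g = g, n = n, delta = delta, beta = beta,
                         frailty_var = frailty_var)
  set.seed(seed)
  m <- 2L * g
  covariates <- draw_cluster_covariates(m, design$covariate_prob,
                                        design$num_covariates)
  frailties <- draw_frailties(m, frailty_var)
  allocation <- sample(rep(c(0L, 1L), g))
  list(design = design, covariates = covariates, frailties = frailties,
       allocation = allocation,
       data = simulate_trial(design, covariates, frailties, allocation))
}
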