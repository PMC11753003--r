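test_that("enumeration produces every balanced allocation exactly once", {
  sp <- allocation_space(4)
  expect_identical(sp$method, "enumerate")
  expect_equal(nrow(sp$assign), 6L)
  expect_true(all(rowSums(sp$assign) == 2L))
  expect_equal(anyDuplicated(sp$assign), 0L)
  # membership agrees with brute-force enumeration
  oracle <- oracle_enumerate(4L)
  oracle_keys <- sort(vapply(oracle, function(a) sum(a * 2^(0:3)), numeric(1)))
  mine_keys <- sort(drop(sp$assign %*% 2^(0:3)))
  expect_equal(mine_keys, oracle_keys)
  expect_equal(nrow(allocation_space(6)$assign), 20L)
})

test_that("sampled spaces are deduplicated and bounded by the binomial coefficient", {
  set.seed(11)
  sp <- allocation_space(16, n_draws = 20000, method = "sample")
  expect_lte(nrow(sp$assign), choose(16, 8))
  expect_equal(anyDuplicated(sp$assign), 0L)
  expect_true(all(rowSums(sp$assign) == 8L))
})

test_that("imbalance score matches hand computation and is mirror-symmetric", {
  # 4 clusters, one covariate (1,1,0,0), arms {1,2} vs {3,4}:
  # sample variance 1/3, squared mean difference 1 -> B = 3
  covs <- matrix(c(1, 1, 0, 0), nrow = 1)
  expect_equal(imbalance_score(c(1, 1, 0, 0), covs), 3)
  # perfect balance -> 0
  expect_equal(imbalance_score(c(1, 0, 1, 0), covs), 0)
  # zero-variance covariate rejected, naming the covariate
  expect_error(imbalance_score(c(1, 1, 0, 0), matrix(1, 1, 4)), "covariate 1")

  # mirror symmetry over a whole enumerated space, several sizes
  for (m in c(4L, 6L, 8L)) {
    set.seed(m)
    covs <- draw_cluster_covariates(m, 0.5, 3)
    while (any(apply(covs, 1, var) == 0)) covs <- draw_cluster_covariates(m, 0.5, 3)
    sp <- score_allocations(allocation_space(m), covs)
    mirror_scores <- apply(1L - sp$assign, 1, imbalance_score, covariates = covs)
    expect_equal(sp$scores, mirror_scores, tolerance = 1e-12)
  }
})

test_that("vectorized scoring equals the one-allocation score", {
  set.seed(12)
  covs <- draw_cluster_covariates(8, 0.5, 4)
  while (any(apply(covs, 1, var) == 0)) covs <- draw_cluster_covariates(8, 0.5, 4)
  sp <- score_allocations(allocation_space(8), covs)
  direct <- apply(sp$assign, 1, imbalance_score, covariates = covs)
  expect_equal(sp$scores, direct, tolerance = 1e-12)
})

test_that("constraining keeps the bottom q fraction with inclusive ties", {
  sp <- allocation_space(4)
  # 100 distinct scores, q = 0.10 -> exactly 10 retained
  sp100 <- sp; sp100$assign <- matrix(0L, 100, 4); sp100$scores <- sample(100)
  out <- constrain(sp100, 0.10)
  expect_equal(sum(out$constrained), 10L)
  expect_true(all(sort(sp100$scores)[1:10] == sort(sp100$scores[out$constrained])))
  # q = 1 keeps everything
  expect_true(all(constrain(sp100, 1)$constrained))
  # ties at the cutoff are all retained
  sp_tied <- sp; sp_tied$scores <- rep(2, 6)
  expect_true(all(constrain(sp_tied, 0.01)$constrained))
  # monotone: q = 0.01 subset of q = 0.10
  set.seed(13)
  covs <- draw_cluster_covariates(16, 0.3, 4)
  sp16 <- score_allocations(allocation_space(16), covs)
  c01 <- constrain(sp16, 0.01)$constrained
  c10 <- constrain(sp16, 0.10)$constrained
  expect_true(all(!c01 | c10))
  expect_error(constrain(sp16, 0), "q")
  expect_error(constrain(allocation_space(4), 0.1), "score")
})

test_that("ratio balance filter applies open ratio bounds and count tolerance", {
  sp <- allocation_space(4)
  # identical arm means for the balanced allocations -> retained
  covs <- matrix(c(2, 3, 2, 3), nrow = 1)
  out <- ratio_balance_filter(sp, covs)
  kept <- sp$assign[out$constrained, , drop = FALSE]
  ratios <- apply(kept, 1, function(a) {
    sum(covs[1, a == 1]) / sum(covs[1, a == 0])
  })
  expect_true(all(ratios > 1 / 1.1 & ratios < 1.1))
  # a ratio of 1.2 on some covariate is outside (1/1.1, 1.1) -> excluded
  covs2 <- matrix(c(1.2, 1.2, 1, 1), nrow = 1)
  out2 <- ratio_balance_filter(sp, covs2)
  expect_false(out2$constrained[which(rowSums(sp$assign[, 1:2]) == 2)][1])
  # categorical counts (3,2) vs (2,3) with tolerance 1 -> retained
  sp10 <- allocation_space(10)
  labels <- rep(c("north", "south"), each = 5)
  covs10 <- matrix(rep(c(2, 3), 5), nrow = 1)
  out3 <- ratio_balance_filter(sp10, covs10, count_covariate = labels,
                               count_tolerance = 1)
  kept3 <- sp10$assign[out3$constrained, , drop = FALSE]
  north_in_A <- rowSums(kept3[, 1:5, drop = FALSE])
  expect_true(all(abs(north_in_A - (5 - north_in_A)) <= 1))
})

test_that("validity report flags pairs co-assigned too often or too rarely", {
  # full space for 2g = 4: any fixed pair is together in 2 of 6 allocations
  # -> 1/3, inside (0.25, 0.75), so nothing is flagged
  sp <- constrain(score_allocations(allocation_space(4),
                                    matrix(c(1, 0, 1, 0), 1)), 1)
  rep <- check_validity(sp)
  expect_equal(diag(rep$coassignment), rep(1, 4))
  off <- rep$coassignment[upper.tri(rep$coassignment)]
  expect_true(all(abs(off - 1 / 3) < 1e-12))
  expect_equal(nrow(rep$flagged_pairs), 0L)
  # two clusters always together -> proportion 1 -> flagged
  sp2 <- allocation_space(4)
  sp2$scores <- ifelse(sp2$assign[, 1] == sp2$assign[, 2], 0, 1)
  sp2 <- constrain(sp2, 0.1)
  rep2 <- check_validity(sp2)
  expect_true(any(rep2$flagged_pairs$cluster_a == 1 &
                  rep2$flagged_pairs$cluster_b == 2))
})

test_that("final selection is uniform over the constrained set with a fair coin", {
  sp <- constrain(score_allocations(allocation_space(4),
                                    matrix(c(1, 0, 1, 0), 1)), 1)
  set.seed(14)
  draws <- replicate(3000, {
    sel <- select_allocation(sp)
    c(sel$index, sel$treatment_is_A)
  })
  counts <- tabulate(draws[1, ], nbins = 6)
  expect_gt(chisq.test(counts)$p.value, 1e-3)
  expect_gt(binom.test(sum(draws[2, ]), 3000, 0.5)$p.value, 1e-3)
  # single-allocation space returns that allocation
  sp1 <- sp; sp1$constrained <- seq_len(6) == 3
  sel <- select_allocation(sp1)
  expect_true(all(sel$assignment == sp$assign[3, ]) ||
              all(sel$assignment == 1L - sp$assign[3, ]))
})
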