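#' Cluster means of residuals
#'
#' The permutation statistic operates on per-cluster means of the deviance
#' residuals from the null-model Cox fit.
#'
#' @param residuals Per-subject residuals.
#' @param cluster_ids Cluster membership, same length.
#' @return Named vector of cluster means, ordered by cluster id.
#' @export
cluster_residual_means <- function(residuals, cluster_ids) {
  stopifnot(length(residuals) == length(cluster_ids))
  groups <- split(residuals, cluster_ids)
  if (any(lengths(groups) == 0L)) stop("empty cluster")
  vapply(groups, mean, numeric(1))
}

#' Residual-difference permutation statistic
#'
#' `S = g^{-1} sum_i (2 T_i - 1) rbar_i`: the scaled difference between the
#' treated-arm and control-arm sums of cluster-mean residuals. Swapping the
#' arms negates the statistic exactly.
#'
#' @param assignment 0/1 treatment indicator per cluster, `g` of `2g` ones.
#' @param rbar Cluster-mean residuals, length `2g`, in cluster order.
#' @return Signed scalar.
#' @export
statistic_S <- function(assignment, rbar) {
  m <- length(rbar)
  if (length(assignment) != m || 2L * sum(assignment) != m) {
    stop("`assignment` must place exactly half of the clusters in each arm")
  }
  g <- m %/% 2L
  sum((2 * assignment - 1) * rbar) / g
}

#' Permutation test over the (constrained) randomization space
#'
#' Computes the residual statistic for every allocation in the referenced
#' space and the two-sided p-value `#(|S*| >= |S_obs|) / M`, with the
#' observed allocation included in both numerator and denominator (so the
#' p-value is never 0). The reference space must be the one actually used at
#' randomization: the constrained subset for a constrained design, the full
#' deduplicated space for simple randomization. The residuals come from a
#' treatment-free null fit, so they are computed once per dataset and held
#' fixed across permutations.
#'
#' @param rbar Cluster-mean deviance residuals, length `2g`.
#' @param space An [allocation_space()]; its constrained subset is used when
#'   `use_constrained = TRUE` (the default; with `q = 1` the constrained
#'   subset is the whole space).
#' @param observed The realized treatment assignment (0/1 vector). Must be a
#'   member of the referenced space, up to arm relabeling; anything else
#'   signals a design/analysis mismatch.
#' @param use_constrained Permute over the constrained subset (`TRUE`) or
#'   the full deduplicated space (`FALSE`).
#' @param alpha Rejection threshold applied as `p <= alpha`.
#' @return An object of class `"crt_permtest"` with `statistic`,
#'   `null_stats`, `p_value`, `space_size`, `reject`.
#' @export
permutation_pvalue <- function(rbar, space, observed, use_constrained = TRUE,
                               alpha = 0.05) {
  stopifnot(inherits(space, "allocation_space"))
  A <- if (use_constrained) .constrained_assign(space) else space$assign
  m <- ncol(A)
  if (length(rbar) != m) stop("`rbar` must have one entry per cluster")
  keys <- .assignment_key(A)
  obs <- as.integer(observed)
  if (!(.assignment_key(rbind(obs)) %in% keys ||
        .assignment_key(rbind(1L - obs)) %in% keys)) {
    stop("observed allocation is not in the referenced permutation space; ",
         "the test must permute over the space actually used at randomization")
  }
  g <- m %/% 2L
  null_stats <- drop((2 * A - 1) %*% rbar) / g
  s_obs <- statistic_S(obs, rbar)
  p <- mean(abs(null_stats) >= abs(s_obs) - 1e-12)
  structure(list(statistic = s_obs, null_stats = null_stats, p_value = p,
                 space_size = nrow(A), reject = p <= alpha, alpha = alpha),
            class = "crt_permtest")
}

#' @export
print.crt_permtest <- function(x, ...) {
  cat(sprintf("Residual permutation test: S = %.5f, p = %.4f over %d allocations%s\n",
              x$statistic, x$p_value, x$space_size,
              if (x$reject) sprintf(" (reject at alpha = %g)", x$alpha) else ""))
  invisible(x)
}

#' Run the full permutation analysis on a trial dataset
#'
#' Convenience wrapper: fits the treatment-free null Cox model with `S`
#' adjustment covariates, computes Cox-Snell then deviance residuals, takes
#' cluster means, and runs [permutation_pvalue()] against the supplied
#' randomization space.
#'
#' @param data A `trial_dataset` with the realized `arm` column.
#' @param space The [allocation_space()] used at randomization (scored and
#'   constrained as in the design).
#' @param S Number of adjustment covariates in the null fit.
#' @inheritParams permutation_pvalue
#' @return A `"crt_permtest"` object; the null fit is attached as
#'   `attr(, "null_fit")`.
#' @export
permutation_test <- function(data, space, S = 0L, use_constrained = TRUE,
                             alpha = 0.05) {
  if (anyNA(data$arm)) stop("dataset has no realized arm assignment")
  null_fit <- fit_cox(data, S = S, include_treatment = FALSE)
  rbar <- cluster_residual_means(
    deviance_residuals(cox_snell_residuals(null_fit), data$event),
    data$cluster_id)
  observed <- vapply(split(data$arm, data$cluster_id), function(a) a[1L],
                     numeric(1))
  out <- permutation_pvalue(rbar, space, observed,
                            use_constrained = use_constrained, alpha = alpha)
  attr(out, "null_fit") <- null_fit
  out
}
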