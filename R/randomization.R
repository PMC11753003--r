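#' Build the candidate allocation space for a two-arm cluster design
#'
#' Candidate allocations assign exactly `g` of the `2g` clusters to one arm.
#' For small designs (`choose(2g, g) <= enumerate_limit`) the space is fully
#' enumerated, making downstream tests exact; otherwise `n_draws` allocations
#' are sampled uniformly with replacement and duplicates are removed. An
#' allocation and its mirror (arm swap) are distinct members of the space:
#' the permutation null distribution must be symmetric under arm relabeling.
#'
#' @param num_clusters Total clusters `2g` (even).
#' @param n_draws Number of uniform draws when sampling.
#' @param method `"auto"` (default), `"enumerate"`, or `"sample"`.
#' @param enumerate_limit Largest `choose(2g, g)` enumerated under `"auto"`.
#' @return An object of class `"allocation_space"` with the 0/1 assignment
#'   matrix in `$assign` (one row per unique allocation); scores and the
#'   constrained subset are filled in by [score_allocations()] and
#'   [constrain()].
#' @export
allocation_space <- function(num_clusters, n_draws = 20000L,
                             method = c("auto", "enumerate", "sample"),
                             enumerate_limit = 1e6) {
  method <- match.arg(method)
  m <- as.integer(num_clusters)
  if (m < 4L || m %% 2L != 0L) stop("`num_clusters` must be an even integer >= 4")
  g <- m %/% 2L
  total <- choose(m, g)
  if (method == "auto") {
    method <- if (total <= enumerate_limit) "enumerate" else "sample"
  }
  if (method == "enumerate") {
    sel <- utils::combn(m, g)
    A <- matrix(0L, ncol(sel), m)
    A[cbind(rep(seq_len(ncol(sel)), each = g), as.vector(sel))] <- 1L
  } else {
    if (n_draws < 1L) stop("`n_draws` must be at least 1")
    A <- .sample_assignments(n_draws, m, g)
    A <- A[!duplicated(.assignment_key(A)), , drop = FALSE]
  }
  structure(list(assign = A, g = g, method = method,
                 scores = NULL, q = NULL, cutoff = NULL, constrained = NULL),
            class = "allocation_space")
}

# uniform g-of-m assignments, vectorized over draws
.sample_assignments <- function(n_draws, m, g) {
  U <- matrix(stats::runif(n_draws * m), n_draws, m)
  o <- order(row(U), U)
  cols <- matrix(col(U)[o], nrow = n_draws, byrow = TRUE)
  A <- matrix(0L, n_draws, m)
  A[cbind(rep(seq_len(n_draws), g), as.vector(cols[, seq_len(g), drop = FALSE]))] <- 1L
  A
}

# exact integer key for assignment rows (m <= 52 keeps doubles exact)
.assignment_key <- function(A) {
  drop(A %*% 2^(seq_len(ncol(A)) - 1))
}

#' @export
print.allocation_space <- function(x, ...) {
  cat(sprintf("Allocation space: %d unique allocations of %d clusters (%s)\n",
              nrow(x$assign), ncol(x$assign), x$method))
  if (!is.null(x$scores)) cat(sprintf("  imbalance scores in [%.4g, %.4g]\n",
                                      min(x$scores), max(x$scores)))
  if (!is.null(x$constrained)) {
    cat(sprintf("  constrained subset: %d allocations (q = %s)\n",
                sum(x$constrained), format(x$q)))
  }
  invisible(x)
}

#' Inverse-variance imbalance score of one allocation
#'
#' `B = sum_k w_k (xbar_Ak - xbar_Bk)^2`, where `xbar_Ak` is the mean of
#' covariate `k` over the clusters in arm A and `w_k` is the inverse of the
#' sample variance (denominator `2g - 1`) of covariate `k` across all `2g`
#' clusters. `B = 0` means perfect balance; `B` is invariant to swapping the
#' arm labels.
#'
#' @param assignment 0/1 vector with exactly `g` ones.
#' @param covariates Covariate matrix, one row per covariate, one column per
#'   cluster. Every covariate must vary across clusters, else its weight is
#'   undefined.
#' @return Nonnegative scalar.
#' @export
imbalance_score <- function(assignment, covariates) {
  m <- ncol(covariates)
  g <- m %/% 2L
  if (length(assignment) != m || sum(assignment) != g) {
    stop("`assignment` must place exactly g of the 2g clusters in arm A")
  }
  w <- .covariate_weights(covariates)
  dbar <- drop(covariates %*% assignment) / g -
    drop(covariates %*% (1 - assignment)) / g
  sum(w * dbar^2)
}

.covariate_weights <- function(covariates) {
  v <- apply(covariates, 1, stats::var)
  if (any(v == 0)) {
    stop(sprintf("covariate %d has zero variance across clusters; its inverse-variance weight is undefined",
                 which(v == 0)[1]))
  }
  1 / v
}

#' Score every allocation in a space
#'
#' Computes the imbalance score of [imbalance_score()] for all allocations at
#' once and stores the result in the space.
#'
#' @param space An [allocation_space()].
#' @param covariates Covariate matrix (rows = covariates, columns = clusters).
#' @return The space with `$scores` filled in.
#' @export
score_allocations <- function(space, covariates) {
  stopifnot(inherits(space, "allocation_space"))
  if (ncol(covariates) != ncol(space$assign)) {
    stop("`covariates` must have one column per cluster")
  }
  w <- .covariate_weights(covariates)
  g <- space$g
  # arm-mean differences for all allocations simultaneously: M x K
  dbar <- (space$assign %*% t(covariates) - (1 - space$assign) %*% t(covariates)) / g
  space$scores <- drop(dbar^2 %*% w)
  space$q <- NULL; space$cutoff <- NULL; space$constrained <- NULL
  space
}

#' Constrain a scored allocation space to its most balanced fraction
#'
#' Retains allocations whose imbalance score is at or below the empirical
#' q-th percentile (the `ceiling(M * q)`-th smallest score). The comparison
#' is inclusive, so ties at the cutoff are all kept and the constrained set
#' is never empty. `q = 1` keeps the whole space: constrained randomization
#' with `q = 1` is simple randomization.
#'
#' @param space A scored [allocation_space()].
#' @param q Percentile in `(0, 1]`.
#' @return The space with `$constrained` (logical), `$cutoff`, and `$q` set.
#' @export
constrain <- function(space, q) {
  stopifnot(inherits(space, "allocation_space"))
  if (is.null(space$scores)) stop("score the space first (see `score_allocations()`)")
  if (q <= 0 || q > 1) stop("`q` must lie in (0, 1]")
  M <- nrow(space$assign)
  cutoff <- sort(space$scores)[ceiling(M * q)]
  space$q <- q
  space$cutoff <- cutoff
  space$constrained <- space$scores <= cutoff
  space
}

#' Constrain a space by per-covariate arm-mean ratios
#'
#' The alternative, ratio-based balance rule: an allocation is retained when,
#' for every covariate, the ratio of arm means `mean_A / mean_B` lies
#' strictly inside `(lower, upper)`, and (optionally) the per-category
#' cluster counts of a categorical covariate differ between arms by at most
#' `count_tolerance`. Allocations with a zero arm mean on any covariate are
#' excluded (the ratio is undefined); their count is recorded in
#' `attr(space$constrained, "n_zero_mean")`.
#'
#' @param space An [allocation_space()] (scores not required).
#' @param covariates Covariate matrix (rows = covariates, columns = clusters);
#'   here typically continuous cluster summaries rather than 0/1 indicators.
#' @param lower,upper Open ratio bounds, default `1/1.1` and `1.1`.
#' @param count_covariate Optional vector of categorical labels (length `2g`)
#'   whose per-category counts must balance between arms.
#' @param count_tolerance Maximum allowed per-category count difference.
#' @return The space with `$constrained` set (`$q` marked `"ratio"`).
#' @export
ratio_balance_filter <- function(space, covariates, lower = 1 / 1.1, upper = 1.1,
                                 count_covariate = NULL, count_tolerance = 1L) {
  stopifnot(inherits(space, "allocation_space"), lower < upper)
  A <- space$assign
  g <- space$g
  meanA <- A %*% t(covariates) / g
  meanB <- (1 - A) %*% t(covariates) / g
  zero <- rowSums(meanA == 0 | meanB == 0) > 0
  ratio <- meanA / meanB
  ok <- !zero & rowSums(ratio <= lower | ratio >= upper) == 0
  if (!is.null(count_covariate)) {
    if (length(count_covariate) != ncol(A)) {
      stop("`count_covariate` must have one label per cluster")
    }
    Z <- stats::model.matrix(~ factor(count_covariate) - 1)
    cntA <- A %*% Z
    tot <- matrix(colSums(Z), nrow(A), ncol(Z), byrow = TRUE)
    ok <- ok & rowSums(abs(2 * cntA - tot) > count_tolerance) == 0
  }
  if (!any(ok)) stop("no allocation satisfies the ratio balance criteria")
  space$q <- "ratio"
  space$cutoff <- NULL
  space$constrained <- ok
  attr(space$constrained, "n_zero_mean") <- sum(zero)
  space
}

# assignment matrix of the constrained subset (whole space if unconstrained)
.constrained_assign <- function(space) {
  if (is.null(space$constrained)) space$assign
  else space$assign[space$constrained, , drop = FALSE]
}

#' Statistical-validity check of a constrained allocation space
#'
#' For every pair of clusters, computes the proportion of allocations in the
#' constrained space that place both clusters in the same arm. A constrained
#' design is statistically valid when no pair is (almost) always together or
#' always apart; pairs with co-assignment proportion <= 0.25 or >= 0.75 are
#' flagged.
#'
#' @param space A constrained [allocation_space()] (the full space is used if
#'   no constraint has been applied).
#' @return A list of class `"validity_report"` with the symmetric
#'   `coassignment` matrix (diagonal 1) and a `flagged_pairs` data frame.
#' @export
check_validity <- function(space) {
  stopifnot(inherits(space, "allocation_space"))
  A <- .constrained_assign(space)
  M <- nrow(A)
  P <- (crossprod(A) + crossprod(1 - A)) / M
  idx <- which(upper.tri(P) & (P <= 0.25 | P >= 0.75), arr.ind = TRUE)
  flagged <- data.frame(cluster_a = idx[, 1], cluster_b = idx[, 2],
                        proportion = P[idx])
  structure(list(coassignment = P, flagged_pairs = flagged, space_size = M),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("Validity check over %d allocations: %d flagged pair(s)\n",
              x$space_size, nrow(x$flagged_pairs)))
  if (nrow(x$flagged_pairs) > 0) print(x$flagged_pairs)
  invisible(x)
}

#' Select the final allocation and label the treatment arm
#'
#' Draws one allocation uniformly from the constrained set, then flips a fair
#' coin to decide which side is the treatment arm.
#'
#' @param space A constrained [allocation_space()] (or unconstrained, for
#'   simple randomization).
#' @return A list with `assignment` (0/1 treatment indicator per cluster),
#'   `index` (row of `space$assign` drawn), and `treatment_is_A`.
#' @export
select_allocation <- function(space) {
  stopifnot(inherits(space, "allocation_space"))
  rows <- if (is.null(space$constrained)) seq_len(nrow(space$assign))
          else which(space$constrained)
  idx <- rows[sample.int(length(rows), 1L)]
  treatment_is_A <- stats::runif(1) < 0.5
  a <- space$assign[idx, ]
  list(assignment = if (treatment_is_A) a else 1L - a,
       index = idx, treatment_is_A = treatment_is_A)
}
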