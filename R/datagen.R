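#' Draw binary cluster-level covariates
#'
#' Each of the `num_covariates` covariates is an independent Bernoulli(`p`)
#' draw per cluster, held constant for all subjects in the cluster.
#'
#' @param num_clusters Total number of clusters (both arms), `2g`.
#' @param p Bernoulli success probability.
#' @param num_covariates Number of covariates (rows of the result).
#' @return Integer matrix with `num_covariates` rows and `num_clusters`
#'   columns, entries 0/1.
#' @export
draw_cluster_covariates <- function(num_clusters, p = 0.3, num_covariates = 4L) {
  stopifnot(num_clusters >= 1, p >= 0, p <= 1)
  matrix(stats::rbinom(num_covariates * num_clusters, 1L, p),
         nrow = num_covariates, ncol = num_clusters)
}

#' Draw mean-one gamma frailties
#'
#' Cluster-level multiplicative frailties `gamma_i ~ Gamma(shape = 1/sigma^2,
#' scale = sigma^2)`, which have mean 1 and variance `sigma^2`. A variance of
#' zero returns the all-ones vector exactly (the no-frailty case).
#'
#' @param num_clusters Number of frailties to draw.
#' @param frailty_var Frailty variance `sigma^2 >= 0`.
#' @return Numeric vector of positive frailties, length `num_clusters`.
#' @export
draw_frailties <- function(num_clusters, frailty_var) {
  stopifnot(num_clusters >= 1)
  if (frailty_var < 0) stop("`frailty_var` must be nonnegative")
  if (frailty_var == 0) return(rep(1, num_clusters))
  stats::rgamma(num_clusters, shape = 1 / frailty_var, scale = frailty_var)
}

#' Simulate a clustered exponential time-to-event trial
#'
#' Latent event times for subject `j` of cluster `i` are exponential with
#' rate `lambda0 * gamma_i * exp(x_i' beta + T_i * log(delta))`; observed
#' times are administratively censored at `design$tau`. Latent (uncensored)
#' times are retained in the `latent_time` column so the intraclass
#' correlation can be measured before censoring.
#'
#' @param design A [trial_design()].
#' @param covariates Binary covariate matrix, `num_covariates` x `2g`
#'   (from [draw_cluster_covariates()]).
#' @param frailties Positive frailty vector of length `2g`
#'   (from [draw_frailties()]); defaults to no frailty.
#' @param allocation Treatment indicator per cluster (length `2g`, `g` ones
#'   and `g` zeros), or `NULL` to leave the trial unrandomized (`arm = NA`;
#'   outcomes are then generated under `T_i = 0`, appropriate only for
#'   `delta = 1` pre-randomization smoke data).
#' @return A `trial_dataset`: a data frame with one row per subject and
#'   columns `cluster_id`, `subject_id`, `time`, `event`, `latent_time`,
#'   `x1..x<k>`, `arm`.
#' @export
simulate_trial <- function(design, covariates, frailties = NULL, allocation = NULL) {
  stopifnot(inherits(design, "trial_design"))
  m <- 2L * design$g
  if (is.null(frailties)) frailties <- rep(1, m)
  if (!is.matrix(covariates) || ncol(covariates) != m ||
      nrow(covariates) != design$num_covariates) {
    stop(sprintf("`covariates` must be a %d x %d matrix", design$num_covariates, m))
  }
  if (length(frailties) != m || any(frailties <= 0)) {
    stop("`frailties` must be positive and of length 2g")
  }
  if (!is.null(allocation)) {
    if (length(allocation) != m || sum(allocation) != design$g ||
        !all(allocation %in% c(0L, 1L))) {
      stop("`allocation` must assign exactly g of the 2g clusters to treatment")
    }
  }
  trt <- if (is.null(allocation)) rep(0L, m) else as.integer(allocation)
  rate_cl <- design$baseline_hazard * frailties *
    exp(drop(crossprod(covariates, design$beta)) + trt * log(design$delta))

  cl <- rep(seq_len(m), each = design$n)
  latent <- stats::rexp(m * design$n, rate = rate_cl[cl])
  out <- data.frame(
    cluster_id = cl,
    subject_id = rep(seq_len(design$n), times = m),
    time = pmin(latent, design$tau),
    event = as.integer(latent <= design$tau),
    latent_time = latent
  )
  xs <- t(covariates)[cl, , drop = FALSE]
  colnames(xs) <- paste0("x", seq_len(design$num_covariates))
  out <- cbind(out, as.data.frame(xs))
  out$arm <- if (is.null(allocation)) NA_integer_ else trt[cl]
  class(out) <- c("trial_dataset", "data.frame")
  out
}

#' Empirical intraclass correlation of clustered outcomes
#'
#' Computes `sigma2_b / (sigma2_b + sigma2_w)` where `sigma2_b` is the sample
#' variance of the cluster means and `sigma2_w` is the within-cluster sample
#' variance averaged across clusters. Intended for the latent (pre-censoring)
#' outcomes, since censoring distorts variance-based correlation measures.
#' Both components use (n - 1) denominators.
#'
#' @param times Numeric outcomes (typically `latent_time`).
#' @param cluster_ids Cluster membership, same length as `times`.
#' @return Proportion in `[0, 1]`.
#' @export
empirical_icc <- function(times, cluster_ids) {
  stopifnot(length(times) == length(cluster_ids))
  groups <- split(times, cluster_ids)
  if (length(groups) < 2L) stop("need at least 2 clusters")
  if (any(lengths(groups) < 2L)) stop("need at least 2 subjects per cluster")
  sb <- stats::var(vapply(groups, mean, numeric(1)))
  sw <- mean(vapply(groups, stats::var, numeric(1)))
  if (sb + sw == 0) stop("ICC undefined: both variance components are zero")
  sb / (sb + sw)
}
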