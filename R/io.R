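#' Write a trial dataset as delimited text
#'
#' Columns `cluster_id,subject_id,time,event,x1,...,arm`; times are written
#' with 17 significant digits so a write/read round trip is bit-exact. The
#' `arm` column is left empty when the trial is not yet randomized. The
#' latent (pre-censoring) times are an optional extra column.
#'
#' @param data A `trial_dataset`.
#' @param path Output file path.
#' @param include_latent Also write the `latent_time` column.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path, include_latent = FALSE) {
  xcols <- grep("^x[0-9]+$", names(data), value = TRUE)
  cols <- c("cluster_id", "subject_id", "time", "event", xcols, "arm",
            if (include_latent && "latent_time" %in% names(data)) "latent_time")
  out <- data[cols]
  for (num in intersect(c("time", "latent_time"), cols)) {
    out[[num]] <- sprintf("%.17g", out[[num]])
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a trial dataset from delimited text
#'
#' Validates the schema written by [write_trial_csv()]: required columns,
#' binary event indicator, nonnegative times, and cluster-level constancy of
#' the covariates and arm label within each cluster.
#'
#' @param path CSV file path.
#' @return A validated `trial_dataset`.
#' @export
read_trial_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = NA)
  required <- c("cluster_id", "subject_id", "time", "event")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!("arm" %in% names(d))) d$arm <- NA_integer_
  xcols <- grep("^x[0-9]+$", names(d), value = TRUE)
  bad <- which(!(d$event %in% c(0L, 1L)))
  if (length(bad) > 0) stop("non-binary `event` at row ", bad[1])
  bad <- which(d$time < 0)
  if (length(bad) > 0) stop("negative `time` at row ", bad[1])
  for (col in c(xcols, "arm")) {
    per_cluster <- tapply(d[[col]], d$cluster_id,
                          function(v) length(unique(v[!is.na(v)])))
    if (any(per_cluster > 1L)) {
      stop(sprintf("cluster %s has inconsistent values of `%s`",
                   names(which(per_cluster > 1L))[1], col))
    }
  }
  class(d) <- c("trial_dataset", "data.frame")
  d
}

#' Export an allocation space as CSV
#'
#' One row per unique allocation: the assignment as a bitstring, its
#' imbalance score (if computed), and a 0/1 flag for membership in the
#' constrained subset.
#'
#' @param space An [allocation_space()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_allocation_csv <- function(space, path) {
  stopifnot(inherits(space, "allocation_space"))
  df <- data.frame(
    assignment = apply(space$assign, 1, paste, collapse = ""),
    score = if (is.null(space$scores)) NA_real_ else space$scores,
    constrained = if (is.null(space$constrained)) 1L
                  else as.integer(space$constrained))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' YAML (or JSON) configuration with keys mirroring [trial_design()] fields
#' plus `q`, `n_sim`, `seed`, and optional `n_draws`, `methods`, `S_values`.
#' Unknown keys are rejected so silent misconfiguration cannot occur.
#'
#' @param path Config file path.
#' @return A [crt_scenario()].
#' @export
read_config <- function(path) {
  # keep YAML-1.1 boolean-like keys (notably `n`) as literal strings
  cfg <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
  design_keys <- c("g", "n", "delta", "beta", "frailty_var", "num_covariates",
                   "covariate_prob", "tau", "baseline_cum_incidence")
  run_keys <- c("q", "n_sim", "seed", "n_draws", "methods", "S_values")
  unknown <- setdiff(names(cfg), c(design_keys, run_keys))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!all(c("g", "n") %in% names(cfg))) stop("config must set `g` and `n`")
  design <- do.call(trial_design, cfg[intersect(design_keys, names(cfg))])
  args <- cfg[intersect(run_keys, names(cfg))]
  args$design <- design
  do.call(crt_scenario, args)
}

#' Built-in miniature fixtures with oracle sidecars
#'
#' Three small, fully reproducible datasets used throughout the test suite
#' and documentation:
#' * `"tiny"` - a fixed 6-subject, one-covariate dataset (one subject per
#'   cluster) whose Breslow partial-likelihood maximizer is found by the
#'   brute-force grid search in the sidecar;
#' * `"worked"` - a simulated 4-cluster, 3-subjects-per-cluster null trial
#'   whose sidecar carries the full brute-force enumeration of the
#'   `choose(4, 2) = 6` allocation permutation distribution;
#' * `"null"` - a g = 8 null-hypothesis trial (delta = 1) for smoke tests.
#'
#' @param kind `"tiny"`, `"worked"`, or `"null"`.
#' @param seed Seed for the simulated fixtures.
#' @return List with `data` (a `trial_dataset`) and `sidecar` (a list of
#'   oracle-computed expectations, each computed by direct enumeration or
#'   grid search, independent of the package's estimation code paths).
#' @export
make_fixture <- function(kind = c("tiny", "worked", "null"), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "tiny") {
    # interleaved covariate keeps the partial likelihood strictly concave
    # with an interior maximizer (a blocked covariate separates here)
    data <- data.frame(cluster_id = 1:6, subject_id = 1L,
                       time = c(1, 2, 3, 4, 5, 6),
                       event = c(1L, 1L, 0L, 1L, 1L, 1L),
                       latent_time = c(1, 2, NA, 4, 5, 6),
                       x1 = c(1L, 0L, 1L, 0L, 1L, 0L),
                       arm = NA_integer_)
    class(data) <- c("trial_dataset", "data.frame")
    grid <- seq(-5, 5, by = 1e-4)
    ll <- vapply(grid, .grid_breslow_loglik, numeric(1),
                 time = data$time, event = data$event, x = data$x1)
    sidecar <- list(grid_beta_hat = grid[which.max(ll)],
                    grid_step = 1e-4,
                    note = "beta_hat from brute-force grid search of the Breslow partial likelihood")
    return(list(data = data, sidecar = sidecar))
  }
  if (kind == "worked") {
    design <- trial_design(g = 2, n = 3, delta = 1, beta = 0.25,
                           num_covariates = 1, covariate_prob = 0.5)
    set.seed(seed)
    covariates <- draw_cluster_covariates(4L, 0.5, 1L)
    # ensure the single covariate varies so the imbalance score is defined
    while (stats::var(covariates[1, ]) == 0) {
      covariates <- draw_cluster_covariates(4L, 0.5, 1L)
    }
    allocation <- c(1L, 1L, 0L, 0L)
    data <- simulate_trial(design, covariates, allocation = allocation)
    # brute-force sidecar: every 2-of-4 allocation, by direct enumeration
    combos <- utils::combn(4L, 2L)
    alloc_list <- lapply(seq_len(ncol(combos)), function(j) {
      a <- integer(4); a[combos[, j]] <- 1L; a
    })
    sidecar <- list(space_size = length(alloc_list),
                    allocations = alloc_list,
                    covariates = covariates,
                    observed = allocation,
                    note = "allocations enumerated with utils::combn, independent of allocation_space()")
    return(list(data = data, sidecar = sidecar))
  }
  design <- trial_design(g = 8, n = 20, delta = 1, beta = 0.25)
  set.seed(seed)
  covariates <- draw_cluster_covariates(16L, design$covariate_prob, 4L)
  allocation <- rep(c(1L, 0L), 8)
  data <- simulate_trial(design, covariates, allocation = allocation)
  list(data = data, sidecar = list(design = design, covariates = covariates,
                                   observed = allocation))
}

# brute-force Breslow partial log-likelihood for a single covariate;
# written for grid-search oracles, deliberately loop-based and simple
.grid_breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (j in which(event == 1)) {
    at_risk <- time >= time[j]
    ll <- ll + beta * x[j] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}
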