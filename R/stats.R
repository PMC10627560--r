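# Tree-shape and rate summary statistics, and the sampling-from-prior
# validation harness.
#
# The harness is the package's single arbiter of correctness for the
# complete-tree density and the augmented operators: an MCMC run without
# data targets the tree prior, so its marginal distributions of tree and
# rate statistics must match plain forward simulation under the same priors
# and the same conditioning (fixed taxon count, fixed crown age). Any
# mistake in the density, a Hastings ratio, or a proposal shows up as a
# distribution mismatch.

#' Gamma statistic of an ultrametric tree
#'
#' Standardised summary of internode-interval placement: negative values
#' mean nodes crowd toward the root, positive toward the tips; under the
#' pure-birth (Yule) model the statistic is asymptotically standard normal.
#'
#' With internode intervals g_2..g_n and `T = sum_j j g_j`, the statistic is
#' `[(1/(n-2)) sum_{i=2..n-1} sum_{k=2..i} k g_k - T/2] / (T sqrt(1/(12(n-2))))`.
#'
#' @param tree an ultrametric `clads_tree` with n >= 3 tips.
#' @return the gamma statistic.
#' @export
gamma_statistic <- function(tree) {
  n <- tree$n_tip
  if (n < 3L) stop("gamma statistic needs at least 3 tips")
  iv <- internode_intervals(tree)
  kg <- iv$k * iv$duration
  total <- sum(kg)
  if (total <= 0) stop("zero total internode length")
  cum <- cumsum(kg)
  inner <- mean(cum[seq_len(n - 2L)])   # partial sums for i = 2..n-1
  (inner - total / 2) / (total * sqrt(1 / (12 * (n - 2L))))
}

#' Colless imbalance index
#'
#' Sum over internal nodes of the absolute difference between the numbers
#' of tips descending from the two children. 0 for a perfectly balanced
#' tree; `(n-1)(n-2)/2` for a caterpillar.
#'
#' @param tree a binary `clads_tree`.
#' @return a non-negative integer.
#' @export
colless_index <- function(tree) {
  nn <- n_nodes(tree)
  counts <- integer(nn)
  counts[seq_len(tree$n_tip)] <- 1L
  ord <- order(tree$age[(tree$n_tip + 1L):nn])  # young internals first
  total <- 0L
  internals <- ((tree$n_tip + 1L):nn)[ord]
  for (i in internals) {
    kids <- tree$children[i, ]
    counts[i] <- counts[kids[1L]] + counts[kids[2L]]
    total <- total + abs(counts[kids[1L]] - counts[kids[2L]])
  }
  total
}

## ------------------------------------------------------------- harness --

#' Sampling-from-prior validation
#'
#' Compares two routes to the same distribution over trees and parameters:
#' path A runs the data-augmented MCMC without data (so the chain targets
#' the tree prior) on a fixed taxon count and crown age; path B draws
#' parameters from the same priors and simulates the process forward,
#' keeping trees with exactly `n_taxa` sampled tips whose reconstructed
#' root is the crown. Four statistics are compared by two-sample
#' Kolmogorov-Smirnov tests with Bonferroni correction: the gamma
#' statistic, the Colless index, the mean birth rate across the
#' reconstructed tree, and the birth-rate variance parameter sigma_lambda.
#'
#' The MCMC path is thinned to `n_samples` draws after discarding
#' `burn_frac` of the chain; `n_iter` defaults to `thin * n_samples /
#' (1 - burn_frac)` so the requested sample size is reached.
#'
#' @param n_taxa taxon count both paths condition on.
#' @param root_age crown age both paths condition on.
#' @param n_samples samples per path.
#' @param params base [clads_params()]; its `estimate` set names the
#'   scalars drawn from priors (default: lambda0, alpha_lambda,
#'   sigma_lambda, epsilon; rho fixed).
#' @param priors named list of [prior_spec()]s used by both paths.
#' @param thin MCMC thinning interval.
#' @param burn_frac fraction of the chain discarded as burn-in.
#' @param seed integer seed.
#' @param mcmc_max_events Gillespie event cap per subtree proposal in the
#'   MCMC path (bounds the per-step cost in supercritical excursions;
#'   capped simulations are invalid proposals).
#' @param forward_max_tries forward-simulation budget; if it is exhausted
#'   before `n_samples` acceptances the harness returns what it has,
#'   flagged, instead of hanging.
#' @param weights operator weights for the MCMC path.
#' @return an object of class `clads_prior_check`: data frames of per-path
#'   statistics, the KS table (`statistic`, `D`, `p`, `p_bonferroni`),
#'   effective sample sizes, and the settings.
#' @export
prior_sampling_validation <- function(n_taxa = 10L, root_age = 10,
                                      n_samples = 5000L,
                                      params = clads_params(
                                        lambda0 = 0.1, alpha_lambda = 1,
                                        sigma_lambda = 0.5,
                                        death_mode = "turnover",
                                        epsilon = 0.5, rho = 0.9,
                                        estimate = c("lambda0",
                                                     "alpha_lambda",
                                                     "sigma_lambda",
                                                     "epsilon")),
                                      priors = validation_priors(),
                                      thin = 120L, burn_frac = 0.1,
                                      seed = 1L,
                                      mcmc_max_events = 120L,
                                      forward_max_tries = 3e6,
                                      weights = list(subtree_resim = 20,
                                                     node_shift = 40,
                                                     wilson_balding = 30,
                                                     subtree_exchange = 30,
                                                     rate_slice = 20,
                                                     ess = 6,
                                                     scalar = 8,
                                                     slice = 2,
                                                     cslice = 6,
                                                     clock = 0)) {
  stopifnot(n_samples >= 2L)
  set.seed(seed)

  ## path A: MCMC without data -------------------------------------------
  n_iter <- ceiling(thin * n_samples / (1 - burn_frac))
  start <- random_ultrametric_tree(n_taxa, root_age)
  chain <- run_chain(start, params, n_iter = n_iter, priors = priors,
                     sample_every = thin, weights = weights,
                     windows = list(scalar = 3, root_age = 1.2,
                                    clock = 1.3),
                     max_events = mcmc_max_events,
                     init_params_from_priors = FALSE)
  tr <- chain$trace
  keep <- tr$Sample > burn_frac * n_iter
  tr <- tr[keep, ]
  tr <- tr[seq_len(min(n_samples, nrow(tr))), ]
  mcmc_stats <- data.frame(gamma = tr$gamma, colless = tr$colless,
                           mean_birth_rate = tr$mean_birth_rate,
                           sigma_lambda = tr$sigma_lambda)

  ## path B: forward simulation ------------------------------------------
  fb <- forward_prior_sample(params, priors, n_taxa, root_age, n_samples,
                             forward_max_tries)
  forward_stats <- fb$stats
  truncated <- fb$truncated

  ## compare --------------------------------------------------------------
  # The chain's logged samples are autocorrelated; a two-sample KS test
  # needs (approximately) independent draws. Subsample the MCMC side at
  # the integrated autocorrelation time, estimated from the smallest
  # rank-based effective sample size across the four statistics
  # (rank-based because KS is a rank test). The residual dependence at
  # this interval slightly deflates null p-values, i.e. it errs toward a
  # stricter test. The forward side is independent and enters at full
  # size.
  ess <- vapply(mcmc_stats, function(x) {
    effective_size(stats::qnorm(rank(x, ties.method = "average") /
                                  (length(x) + 1L)))
  }, numeric(1L))
  step <- max(1L, ceiling(nrow(mcmc_stats) / max(min(ess), 1)))
  mcmc_indep <- mcmc_stats[seq(1L, nrow(mcmc_stats), by = step), ,
                           drop = FALSE]
  ks <- compare_statistic_samples(mcmc_indep, forward_stats)
  structure(list(mcmc = mcmc_stats, forward = forward_stats, ks = ks,
                 mcmc_indep = mcmc_indep, subsample_step = step,
                 ess = ess, truncated = truncated,
                 settings = list(n_taxa = n_taxa, root_age = root_age,
                                 n_samples = n_samples, thin = thin,
                                 n_iter = n_iter, seed = seed,
                                 forward_tries = fb$tries),
                 acceptance = chain$acceptance),
            class = "clads_prior_check")
}

# Forward path of the validation: draw parameters from the priors,
# simulate the process at the fixed crown age, keep replicates with exactly
# n_taxa sampled tips whose reconstructed root is the crown (the event the
# MCMC path conditions on), and record the four comparison statistics.
forward_prior_sample <- function(params, priors, n_taxa, root_age,
                                 n_samples, max_tries = 2e6) {
  fwd <- matrix(NA_real_, n_samples, 4L,
                dimnames = list(NULL, c("gamma", "colless",
                                        "mean_birth_rate", "sigma_lambda")))
  got <- 0L
  tries <- 0
  while (got < n_samples && tries < max_tries) {
    tries <- tries + 1
    p <- draw_params_from_priors(params, priors)
    comp <- simulate_complete_tree(p, root_age,
                                   max_lineages = 50L * n_taxa + 500L)
    rec <- prune_to_reconstructed(comp)
    if (is.null(rec) || rec$n_sampled != n_taxa || !rec$root_is_crown) next
    got <- got + 1L
    fwd[got, ] <- c(gamma_statistic(rec$tree), colless_index(rec$tree),
                    rec$mean_birth_rate, p$sigma_lambda)
  }
  list(stats = as.data.frame(fwd[seq_len(got), , drop = FALSE]),
       truncated = got < n_samples, tries = tries)
}

# two-sample KS per shared column; degenerate (constant) statistics are
# flagged and skipped rather than tested
compare_statistic_samples <- function(a, b) {
  out <- lapply(names(a), function(nm) {
    x <- a[[nm]][is.finite(a[[nm]])]
    y <- b[[nm]][is.finite(b[[nm]])]
    if (length(unique(x)) < 2L && length(unique(y)) < 2L)
      return(data.frame(statistic = nm, D = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    kt <- suppressWarnings(stats::ks.test(x, y))
    data.frame(statistic = nm, D = unname(kt$statistic),
               p = kt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_bonferroni <- pmin(1, out$p * sum(!out$degenerate))
  out
}

#' @export
print.clads_prior_check <- function(x, ...) {
  cat(sprintf(
    "sampling-from-prior check: %d taxa, crown age %g, %d samples/path\n",
    x$settings$n_taxa, x$settings$root_age, x$settings$n_samples))
  if (x$truncated)
    cat("NOTE: forward path truncated by the simulation budget (",
        nrow(x$forward), " samples)\n", sep = "")
  cat(sprintf("KS on %d independence-subsampled MCMC draws (step %d) vs %d forward draws:\n",
              nrow(x$mcmc_indep), x$subsample_step, nrow(x$forward)))
  print(x$ks, row.names = FALSE)
  cat("MCMC effective sample sizes (rank scale):\n")
  print(round(x$ess))
  invisible(x)
}

#' @export
plot.clads_prior_check <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(op))
  for (nm in names(x$mcmc)) {
    a <- x$mcmc[[nm]]; b <- x$forward[[nm]]
    if (nm %in% c("mean_birth_rate")) { a <- log(a); b <- log(b) }
    rng <- range(c(a, b), finite = TRUE)
    br <- seq(rng[1], rng[2], length.out = 40L)
    ha <- graphics::hist(a, breaks = br, plot = FALSE)
    hb <- graphics::hist(b, breaks = br, plot = FALSE)
    ylim <- c(0, max(ha$density, hb$density))
    graphics::plot(ha, freq = FALSE, col = grDevices::adjustcolor("darkgreen", 0.4),
                   border = NA, main = nm, xlab = nm, ylim = ylim)
    graphics::plot(hb, freq = FALSE, col = grDevices::adjustcolor("firebrick", 0.4),
                   border = NA, add = TRUE)
  }
  invisible(x)
}

#' Write the validation report as TSV
#'
#' @param x a `clads_prior_check`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prior_check <- function(x, path) {
  utils::write.table(x$ks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ------------------------------------------------- parameter recovery --

#' Fixed-tree parameter recovery experiment
#'
#' For each replicate: draw true parameters from the priors, simulate a
#' reconstructed tree with a tip count in `[n_tip_min, n_tip_max]` and the
#' crown as root, then run fixed-tree inference (subtree resimulation plus
#' scalar moves) and record whether the central 90% credible interval for
#' sigma_lambda covers the truth. Because the truths are drawn from the
#' same priors the inference uses, nominal coverage is exact, so the
#' replicate successes are Binomial(n_replicates, 0.9).
#'
#' @param n_replicates number of simulated datasets.
#' @param n_tip_min,n_tip_max accepted tip-count window.
#' @param crown_age crown age of the simulated trees.
#' @param n_iter chain length per replicate.
#' @param burn_frac burn-in fraction discarded.
#' @param params base [clads_params()] (defines death mode, rho, and the
#'   estimated set). The default is the pure-birth (ClaDS0) variant: the
#'   turnover machinery is exercised by [prior_sampling_validation()], and
#'   pure birth admits an exact independent oracle for the fixed-tree
#'   posterior, which is how the recovery experiment itself was verified.
#' @param priors priors for both simulation truths and inference.
#' @param seed integer seed.
#' @param level credible level (default 0.90).
#' @return data frame with one row per replicate: the true values, the
#'   credible bounds, and `covered`.
#' @export
parameter_recovery_experiment <- function(n_replicates = 20L,
                                          n_tip_min = 40L, n_tip_max = 60L,
                                          crown_age = 25,
                                          n_iter = 30000L, burn_frac = 0.25,
                                          params = clads_params(
                                            lambda0 = 0.2,
                                            sigma_lambda = 0.3,
                                            death_mode = "none", rho = 1,
                                            estimate = c("lambda0",
                                                         "alpha_lambda",
                                                         "sigma_lambda")),
                                          priors = default_priors(),
                                          seed = 1L, level = 0.90) {
  set.seed(seed)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    # Joint rejection over (truth, tree) pairs: the truth is redrawn for
    # every simulation attempt. Holding a truth fixed across attempts
    # would re-weight the accepted truths by their per-truth acceptance
    # probability and break the Binomial(n, level) coverage calibration.
    rec <- NULL
    truth <- params
    repeat {
      truth <- draw_params_from_priors(params, priors)
      raw <- .sim_complete_cpp(truth, crown_age, 20L * n_tip_max, 5000L)
      if (!raw$valid || raw$n_sampled < n_tip_min ||
          raw$n_sampled > n_tip_max) next
      rec <- prune_to_reconstructed(complete_from_raw(raw))
      if (!is.null(rec) && rec$root_is_crown) break
    }
    start <- params
    start$sigma_lambda <- max(start$sigma_lambda, 0.3)  # interior start
    chain <- run_chain(rec$tree, start, n_iter = n_iter, priors = priors,
                       fixed_tree = TRUE, sample_every = 50L,
                       windows = list(scalar = 3, root_age = 1.2,
                                      clock = 1.3),
                       weights = list(subtree_resim = 15, node_shift = 0,
                                      wilson_balding = 0,
                                      subtree_exchange = 0,
                                      rate_slice = 20, ess = 6, scalar = 2,
                                      slice = 0.5, cslice = 4, clock = 0))
    tr <- chain$trace
    post <- tr$sigma_lambda[tr$Sample > burn_frac * n_iter]
    qs <- stats::quantile(post, c((1 - level) / 2, 1 - (1 - level) / 2))
    rows[[r]] <- data.frame(
      replicate = r, n_tip = rec$tree$n_tip,
      sigma_lambda_true = truth$sigma_lambda,
      lambda0_true = truth$lambda0,
      alpha_lambda_true = truth$alpha_lambda,
      lower = qs[[1L]], upper = qs[[2L]],
      posterior_median = stats::median(post),
      covered = truth$sigma_lambda >= qs[[1L]] &&
                truth$sigma_lambda <= qs[[2L]])
  }
  do.call(rbind, rows)
}
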