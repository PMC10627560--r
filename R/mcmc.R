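# The Metropolis-Hastings chain driver.
#
# A `clads_state` bundles the model parameters, the augmented tree, the
# priors, optional alignment data with a strict clock rate, and cached
# log-densities. The posterior is
#   log prior(params) + log complete-tree density(aug | params)
#     [+ log alignment likelihood(tree, clock) in full inference].
# Running without data samples the tree prior itself, which is what the
# sampling-from-prior validation exploits.

#' Build an MCMC state
#'
#' @param tree a `clads_tree` (starting or fixed tree).
#' @param params a [clads_params()] object.
#' @param priors named list of [prior_spec()] objects (defaults:
#'   [default_priors()]).
#' @param aln optional [clads_alignment()] for full inference.
#' @param clock_rate strict molecular clock rate (substitutions per unit
#'   time) when an alignment is given.
#' @param fixed_root keep the root age fixed (`TRUE`, the default) or give
#'   it a scale operator.
#' @param max_events Gillespie event cap per subtree simulation.
#' @param windows named list of operator scale windows.
#' @return an object of class `clads_state` with finite cached densities.
#' @export
clads_state <- function(tree, params, priors = default_priors(), aln = NULL,
                        clock_rate = 1, fixed_root = TRUE,
                        max_events = 1000L,
                        windows = list(scalar = 1.5, root_age = 1.2,
                                       clock = 1.3)) {
  check_identifiability(params)
  aug <- initial_augmentation(tree, params, max_events = max_events)
  st <- structure(
    list(params = params, aug = aug, priors = priors, aln = aln,
         clock_rate = clock_rate, fixed_root = fixed_root,
         max_events = max_events, windows = windows,
         log_prior = NA_real_, log_aug = NA_real_, log_lik = 0),
    class = "clads_state")
  st <- refresh_densities(st, touched = c("params", "tree", "aug", "clock"))
  if (!is.finite(state_posterior(st)))
    stop("could not initialise a state with finite posterior")
  st
}

state_posterior <- function(state) {
  state$log_prior + state$log_aug + state$log_lik
}

# `edges = NULL` recomputes every per-edge contribution; otherwise only the
# listed edges are refreshed in the cached contribution vector.
refresh_densities <- function(state, touched, edges = NULL) {
  state$log_prior <- log_prior(state$params, state$priors)
  if (!state$fixed_root && !is.null(state$priors$root_age)) {
    tr <- state$aug$tree
    state$log_prior <- state$log_prior +
      prior_log_density(state$priors$root_age, tr$age[tr$root])
  }
  state$contrib <- edge_contributions(state$aug, state$params,
                                      if (is.null(edges)) NULL
                                      else state$contrib, edges)
  total <- sum(state$contrib)
  state$log_aug <- if (is.nan(total)) -Inf else total
  if (!is.null(state$aln) && any(c("tree", "clock") %in% touched))
    state$log_lik <- tree_log_likelihood(state$aug$tree, state$aln,
                                         state$clock_rate)
  state
}

#' One Metropolis-Hastings step
#'
#' Draws a proposal from `op`, auto-rejects invalid proposals without
#' evaluating the target, and otherwise accepts with probability
#' `min(1, exp(delta log-posterior + log Hastings))`.
#'
#' @param state a `clads_state` with finite posterior.
#' @param op an operator function (see [augmented_subtree_resim()] and
#'   friends).
#' @return list with the (possibly unchanged) `state` and a logical
#'   `accepted`.
#' @export
mh_step <- function(state, op) {
  if (!is.finite(state_posterior(state)))
    stop("current state has non-finite posterior")
  prop <- op(state)
  if (is_rejection(prop)) return(list(state = state, accepted = FALSE))
  if (isTRUE(prop$gibbs))  # slice updates already sample the conditional
    return(list(state = prop$state, accepted = TRUE))
  ns <- refresh_densities(prop$state, prop$touched, prop$edges %||% NULL)
  delta <- state_posterior(ns) - state_posterior(state) + prop$log_hastings
  if (is.finite(delta) && log(stats::runif(1L)) < delta)
    list(state = ns, accepted = TRUE)
  else
    list(state = state, accepted = FALSE)
}

default_weights <- function() {
  list(subtree_resim = 20, node_shift = 10, wilson_balding = 10,
       subtree_exchange = 10, rate_slice = 15, ess = 4, scalar = 3,
       slice = 1, cslice = 4, clock = 3)
}

build_operators <- function(state, weights) {
  ops <- list(); w <- numeric(0)
  add <- function(name, fn, wt) {
    if (wt > 0) { ops[[name]] <<- fn; w[name] <<- wt }
  }
  add("subtree_resim", augmented_subtree_resim, weights$subtree_resim)
  add("node_shift", augmented_node_shift, weights$node_shift)
  add("wilson_balding", augmented_wilson_balding, weights$wilson_balding)
  add("subtree_exchange", augmented_subtree_exchange,
      weights$subtree_exchange)
  add("edge_rate_slice", op_slice_edge_rate(),
      weights$rate_slice %||% 0)
  if (state$params$death_mode %in% c("turnover", "none") &&
      state$params$sigma_lambda > 0)
    add("ess_field", op_ess_field(), weights$ess %||% 0)
  joint_ok <- isTRUE(state$use_noncentered) &&
    state$params$death_mode %in% c("turnover", "none") &&
    state$params$sigma_lambda > 0
  slice_w <- weights$slice %||% 0
  for (nm in state$params$estimate) {
    latent_coupled <- nm %in% c("lambda0", "alpha_lambda", "sigma_lambda")
    if (joint_ok && latent_coupled) {
      add(paste0("scale_", nm), op_joint_rate(nm, state$windows$scalar),
          weights$scalar)
      # interweaving: the centered scale move alongside the non-centered
      # one (ASIS); with many latent draws each parameterisation alone
      # leaves the hyperparameter conditionally pinned
      add(paste0("cscale_", nm), op_scale_param(nm, state$windows$scalar),
          weights$scalar)
    } else {
      add(paste0("scale_", nm), op_scale_param(nm, state$windows$scalar),
          weights$scalar)
      if (!is.null(state$priors[[nm]]) &&
          state$priors[[nm]]$dist != "fixed")
        add(paste0("kick_", nm), op_prior_kick(nm), weights$scalar * 0.5)
    }
    if (joint_ok || !latent_coupled)
      add(paste0("slice_", nm), op_slice_rate(nm), slice_w)
    # centered counterpart: exact conditional given the latent rates (the
    # other half of the interweaving sandwich); O(1) via inheritance
    # sufficient statistics where the death rate is derived
    cslice_w <- weights$cslice %||% slice_w
    if (latent_coupled && cslice_w > 0) {
      if (nm %in% c("alpha_lambda", "sigma_lambda"))
        add(paste0("cslice_", nm),
            if (joint_ok) op_cslice_stats(nm)
            else op_slice_rate(nm, centered = TRUE), cslice_w)
      else
        add(paste0("cslice_", nm), op_slice_rate(nm, centered = TRUE),
            cslice_w)
    }
  }
  if (!is.null(state$aln) && isTRUE(state$estimate_clock))
    add("scale_clock", op_scale_clock(state$windows$clock), weights$clock)
  list(ops = ops, weights = w)
}

trace_columns <- function(state) {
  c("Sample", "posterior", "likelihood", "prior", "aug_density",
    intersect(PARAM_NAMES, c(state$params$estimate,
                             "lambda0", "alpha_lambda", "sigma_lambda",
                             switch(state$params$death_mode,
                                    turnover = "epsilon",
                                    lognormal = c("mu0", "alpha_mu",
                                                  "sigma_mu"),
                                    none = NULL),
                             "rho")),
    "root_age", "tree_length", "gamma", "colless", "mean_birth_rate")
}

trace_row <- function(state, iter, cols) {
  tr <- state$aug$tree
  vals <- c(Sample = iter,
            posterior = state_posterior(state),
            likelihood = state$log_lik,
            prior = state$log_prior,
            aug_density = state$log_aug,
            unlist(state$params[PARAM_NAMES]),
            root_age = tr$age[tr$root],
            tree_length = tree_length(tr),
            gamma = if (tr$n_tip >= 3L) gamma_statistic(tr) else NA_real_,
            colless = colless_index(tr),
            mean_birth_rate = mean_birth_rate(state$aug))
  vals[cols]
}

#' Run a ClaDS MCMC chain
#'
#' Executes the Metropolis-Hastings loop with operators selected at random
#' in proportion to their weights. Without an alignment the chain samples
#' from the tree prior. The trace is Tracer-compatible (tab-separated,
#' first column `Sample`) and includes the tree statistics used by the
#' validation harness. Deterministic given `seed`.
#'
#' @param tree starting (or fixed) `clads_tree`.
#' @param params a [clads_params()] object; its `estimate` field decides
#'   which scalars move.
#' @param n_iter number of MCMC iterations.
#' @param priors named list of [prior_spec()]s.
#' @param aln optional [clads_alignment()] (full inference).
#' @param clock_rate strict clock rate; `estimate_clock` adds a scale
#'   operator for it.
#' @param estimate_clock logical.
#' @param fixed_tree if `TRUE`, all tree-topology/age operators are
#'   disabled (fixed-tree inference; the augmentation still moves).
#' @param fixed_root keep the root age fixed.
#' @param sample_every thinning interval for the trace.
#' @param tree_every write a tree to the Nexus log every this many
#'   iterations (0 disables tree logging).
#' @param tree_log path of the Nexus tree log (required if
#'   `tree_every > 0`).
#' @param trace_file optional path; the trace is also written as TSV.
#' @param weights named list of operator weights, see
#'   `cladsmc:::default_weights`.
#' @param seed integer seed (optional).
#' @param init_params_from_priors draw the estimated scalars from their
#'   priors before starting (used when sampling from the prior).
#' @param use_noncentered enable the non-centered joint/slice updates for
#'   the birth hyperparameters (default); disable to fall back to plain
#'   centered scale moves.
#' @param max_events Gillespie event cap per subtree simulation.
#' @param windows operator scale windows.
#' @return an object of class `clads_chain`: `trace` (data frame),
#'   `acceptance` (per-operator data frame), `final_state`.
#' @export
run_chain <- function(tree, params, n_iter,
                      priors = default_priors(), aln = NULL,
                      clock_rate = 1, estimate_clock = FALSE,
                      fixed_tree = FALSE, fixed_root = TRUE,
                      sample_every = 100L, tree_every = 0L, tree_log = NULL,
                      trace_file = NULL, weights = default_weights(),
                      seed = NULL, init_params_from_priors = FALSE,
                      use_noncentered = TRUE,
                      max_events = 1000L,
                      windows = list(scalar = 1.5, root_age = 1.2,
                                     clock = 1.3)) {
  if (!is.null(seed)) set.seed(seed)
  check_identifiability(params)
  if (sum(unlist(weights)) <= 0) stop("all operator weights are zero")
  if (init_params_from_priors)
    params <- draw_params_from_priors(params, priors)
  if (fixed_tree)
    weights[c("node_shift", "wilson_balding", "subtree_exchange")] <- 0
  state <- clads_state(tree, params, priors, aln, clock_rate, fixed_root,
                       max_events, windows)
  state$estimate_clock <- estimate_clock
  state$use_noncentered <- use_noncentered
  reg <- build_operators(state, weights)
  if (length(reg$ops) == 0L) stop("no operators enabled")
  cols <- trace_columns(state)
  n_samples <- if (n_iter > 0) floor(n_iter / sample_every) else 0L
  trace <- matrix(NA_real_, nrow = n_samples, ncol = length(cols),
                  dimnames = list(NULL, cols))
  n_prop <- n_acc <- stats::setNames(numeric(length(reg$ops)),
                                     names(reg$ops))
  nx <- NULL
  if (tree_every > 0L) {
    if (is.null(tree_log)) stop("tree_every > 0 needs a tree_log path")
    nx <- nexus_log_open(tree_log, tree$label)
  }
  row <- 0L
  cw <- cumsum(reg$weights) / sum(reg$weights)
  if (n_iter > 0) for (iter in seq_len(n_iter)) {
    k <- min(1L + sum(cw < stats::runif(1L)), length(cw))
    res <- mh_step(state, reg$ops[[k]])
    state <- res$state
    n_prop[k] <- n_prop[k] + 1
    n_acc[k] <- n_acc[k] + res$accepted
    if (iter %% sample_every == 0L) {
      row <- row + 1L
      trace[row, ] <- trace_row(state, iter, cols)
    }
    if (!is.null(nx) && iter %% tree_every == 0L)
      nexus_log_add(nx, state$aug$tree, paste0("STATE_", iter))
  }
  if (!is.null(nx)) nexus_log_close(nx)
  trace <- as.data.frame(trace)
  if (!is.null(trace_file))
    utils::write.table(trace, trace_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  acc <- data.frame(operator = names(reg$ops), proposed = as.vector(n_prop),
                    accepted = as.vector(n_acc),
                    rate = as.vector(ifelse(n_prop > 0, n_acc / n_prop, NA)))
  structure(list(trace = trace, acceptance = acc, final_state = state),
            class = "clads_chain")
}

#' @export
print.clads_chain <- function(x, ...) {
  cat(sprintf("clads_chain: %d logged samples\n", nrow(x$trace)))
  print(x$acceptance, row.names = FALSE)
  invisible(x)
}

#' Effective sample size of a trace vector
#'
#' Spectral estimate via an autoregressive fit (`stats::ar`), the classical
#' `spectrum0` approach. Used to size and thin validation chains.
#'
#' @param x numeric vector of (possibly autocorrelated) samples.
#' @return the estimated effective sample size.
#' @export
effective_size <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(50L, n %/% 4L)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(n)
  s0 <- fit$var.pred / (1 - sum(fit$ar))^2
  max(1, min(n, n * stats::var(x) / s0))
}
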