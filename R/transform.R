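# Non-centered joint moves for the birth-rate hyperparameters.
#
# Every inherited birth rate in the augmentation is a lognormal draw
#   log lambda_child = log(alpha_lambda * lambda_parent) + sigma_lambda * z
# with a standard-normal deviation z. A plain scale move on sigma_lambda or
# alpha_lambda mixes poorly because the latent draws pin the hyperparameter
# (the classical centered-parameterisation pathology of augmented
# samplers). The joint moves below scale the hyperparameter and
# deterministically recompute every latent rate keeping its z fixed, which
# turns the conditional into a nearly marginal update. The subtree records
# carry draw ids (1 = seed, birth i -> 2i and 2i+1) linking every stored
# rate to the draw that produced it, so the transform can be replayed
# parents-before-children.
#
# Supported for the turnover and pure-birth death modes, where death rates
# are derived (mu = epsilon * lambda); in lognormal death mode the engine
# falls back to plain scale moves.

# Rebuild all latent birth rates under new (lambda0, alpha_lambda,
# sigma_lambda), keeping standardized deviations fixed. Returns the
# transformed augmentation plus the log-Jacobian ingredients:
# sum(log V_new - log V_old) over all draws and the draw count.
transform_birth_rates <- function(aug, params_old, params_new) {
  stopifnot(params_old$sigma_lambda > 0, params_new$sigma_lambda > 0)
  tr <- aug$tree
  edges <- edge_ids(tr)
  edges <- edges[order(tr$age[tr$parent[edges]], decreasing = TRUE)]
  res <- .transform_rates_cpp(aug$sub, tr$parent, tr$root,
                              as.integer(edges), params_old, params_new)
  aug$sub <- res$subs
  list(aug = aug, sum_log_ratio = res$sum_log_ratio,
       n_draws = res$n_draws)
}

# Joint operator on one of lambda0 / alpha_lambda / sigma_lambda with the
# latent rates moved along. Two proposal flavours: a multiplicative scale
# move (local) and an independence draw from the parameter's prior (a
# "prior kick" that crosses tails in one jump). Hastings ratio, from the
# triangular log-scale Jacobian of the latent transform:
#   (scalar proposal term) + sum(log V'/V) + n_draws * log(sigma'/sigma)
# where the last term appears only for the sigma move, and the scalar term
# is log f for the scale flavour or log g(old) - log g(new) for the
# independence flavour.
op_joint_rate <- function(name, s = 1.5, kick_prob = 0.15) {
  force(name); force(s); force(kick_prob)
  function(state) {
    old <- state$params[[name]]
    if (stats::runif(1L) < kick_prob) {
      pr <- state$priors[[name]]
      new_val <- prior_draw(pr, old)
      scalar_term <- prior_log_density(pr, old) -
        prior_log_density(pr, new_val)
    } else {
      mv <- scale_move(old, s)
      new_val <- mv$value
      scalar_term <- mv$log_hastings
    }
    p_new <- state$params
    p_new[[name]] <- new_val
    res <- transform_birth_rates(state$aug, state$params, p_new)
    st <- state
    st$params <- p_new
    st$aug <- res$aug
    lhr <- scalar_term + res$sum_log_ratio +
      if (name == "sigma_lambda") res$n_draws * log(new_val / old) else 0
    list(state = st, log_hastings = lhr, touched = c("params", "aug"))
  }
}

# Slice-sampling update (stepping-out and shrinkage) of one scalar on the
# log scale, jointly with the non-centered latent transform for the birth
# hyperparameters. The slice target in u = log(theta) is
#   G(u) = log prior + log complete-tree density + c(theta) * u + sum log V_j(u)
# where the last two terms are the log-scale Jacobian of the latent
# transform (c = n_draws + 1 for sigma_lambda, 1 otherwise, and the
# sum-log-V term is absent for parameters without latent coupling). Being
# an exact draw from the full conditional, the update needs no tuning and
# crosses posterior tails in one sweep; it leaves the target invariant as a
# Gibbs step (`gibbs = TRUE` tells the chain driver to install the state
# without a Metropolis test).
# Generic 1-D slice sampler (stepping-out and shrinkage, Neal 2003) over
# an evaluator returning list(state =, g =). Returns the accepted state or
# NULL when the slice degenerates.
slice_sample_1d <- function(eval_u, u0, g0, w = 1.5, max_steps = 20L) {
  logy <- g0 + log(stats::runif(1L))
  lo <- u0 - w * stats::runif(1L)
  hi <- lo + w
  steps <- max_steps
  while (steps > 0L && eval_u(lo)$g > logy) { lo <- lo - w; steps <- steps - 1L }
  while (steps > 0L && eval_u(hi)$g > logy) { hi <- hi + w; steps <- steps - 1L }
  repeat {
    u1 <- stats::runif(1L, lo, hi)
    cand <- eval_u(u1)
    if (cand$g > logy) return(cand$state)
    if (u1 < u0) lo <- u1 else hi <- u1
    if (hi - lo < 1e-12) return(NULL)
  }
}

op_slice_rate <- function(name, w = 1.5, max_steps = 10L,
                          centered = FALSE) {
  force(name); force(w); force(max_steps); force(centered)
  latent_names <- c("lambda0", "alpha_lambda", "sigma_lambda")
  function(state) {
    base <- state$params[[name]]
    transform_latents <- !centered && name %in% latent_names
    crown_only <- centered && name %in% c("lambda0", "mu0")
    eval_u <- function(u) {
      val <- exp(u)
      p_new <- state$params
      p_new[[name]] <- val
      st <- state
      st$params <- p_new
      extra <- u
      if (transform_latents) {
        res <- transform_birth_rates(state$aug, state$params, p_new)
        st$aug <- res$aug
        extra <- extra + res$sum_log_ratio +
          if (name == "sigma_lambda") res$n_draws * u else 0
        st <- refresh_densities(st, touched = c("params", "aug"))
      } else if (crown_only) {
        st <- refresh_densities(st, touched = "params",
                                edges = st$aug$tree$children[
                                  st$aug$tree$root, ])
      } else {
        st <- refresh_densities(st, touched = "params")
      }
      list(state = st, g = state_posterior(st) + extra)
    }
    u0 <- log(base)
    e0 <- eval_u(u0)
    if (!is.finite(e0$g)) return(reject_proposal())
    out <- slice_sample_1d(eval_u, u0, e0$g, w, max_steps)
    if (is.null(out)) return(reject_proposal())
    list(state = out, gibbs = TRUE, log_hastings = 0,
         touched = c("params", "aug"))
  }
}

# Centered slice update of alpha_lambda or sigma_lambda through the
# inheritance sufficient statistics: with the latent rates held fixed,
# only the lognormal inheritance terms move, and they depend on the
# latents through per-edge (N, sum d, sum d^2) of the log-deviations
# d = log(child) - log(parent). Slice evaluations are O(1) and the
# accepted state's cached contributions are shifted by exact per-edge
# deltas. Turnover / pure-birth modes only (death rates derived).
op_cslice_stats <- function(name, w = 1.5, max_steps = 20L) {
  force(name); force(w); force(max_steps)
  stopifnot(name %in% c("alpha_lambda", "sigma_lambda"))
  function(state) {
    stats <- .inherit_stats_cpp(state$aug$sub, state$aug$tree$parent,
                                state$aug$tree$root,
                                state$params$lambda0)
    Ns <- stats[, 1L]; S1 <- stats[, 2L]; S2 <- stats[, 3L]
    N <- sum(Ns); S1t <- sum(S1); S2t <- sum(S2)
    inh_term <- function(al, sl, n, s1, s2) {
      la <- log(al)
      -n * log(sl) - (s2 - 2 * la * s1 + n * la^2) / (2 * sl^2)
    }
    al0 <- state$params$alpha_lambda
    sl0 <- state$params$sigma_lambda
    pr <- state$priors[[name]]
    base_term <- inh_term(al0, sl0, N, S1t, S2t)
    g_of <- function(u) {
      val <- exp(u)
      al <- if (name == "alpha_lambda") val else al0
      sl <- if (name == "sigma_lambda") val else sl0
      prior_log_density(pr, val) + u + inh_term(al, sl, N, S1t, S2t)
    }
    eval_u <- function(u) list(state = u, g = g_of(u))
    u0 <- log(state$params[[name]])
    g0 <- g_of(u0)
    if (!is.finite(g0)) return(reject_proposal())
    u_new <- slice_sample_1d(eval_u, u0, g0, w, max_steps)
    if (is.null(u_new)) return(reject_proposal())
    val <- exp(u_new)
    al <- if (name == "alpha_lambda") val else al0
    sl <- if (name == "sigma_lambda") val else sl0
    st <- state
    st$params[[name]] <- val
    delta <- inh_term(al, sl, Ns, S1, S2) -
      inh_term(al0, sl0, Ns, S1, S2)
    st$contrib <- state$contrib + delta
    tot <- sum(st$contrib)
    st$log_aug <- if (is.nan(tot)) -Inf else tot
    st$log_prior <- log_prior(st$params, st$priors)
    if (!st$fixed_root && !is.null(st$priors$root_age))
      st$log_prior <- st$log_prior +
        prior_log_density(st$priors$root_age,
                          st$aug$tree$age[st$aug$tree$root])
    list(state = st, gibbs = TRUE, log_hastings = 0,
         touched = c("params", "aug"))
  }
}

# overwrite every stored occurrence of the seed draw (draw id 1) of one
# subtree with a new value; derived death rates follow in turnover mode
set_seed_rate <- function(sub, value, params) {
  death <- switch(params$death_mode,
                  turnover = params$epsilon * value,
                  none = 0,
                  lognormal = sub$seed[["death"]])
  sub$seed <- c(birth = value, death = death)
  sub$seg_lam[sub$seg_did == 1L] <- value
  sub$spine_seg_lam[sub$spine_seg_did == 1L] <- value
  if (sub$spine_did == 1L) {
    sd <- switch(params$death_mode, turnover = params$epsilon * value,
                 none = 0, lognormal = sub$spine[["death"]])
    sub$spine <- c(birth = value, death = sd)
  }
  if (length(sub$b_parent_did))
    sub$b_p_lam[sub$b_parent_did == 1L] <- value
  if (length(sub$d_did))
    sub$d_lam[sub$d_did == 1L] <- value
  sub$log_q <- NA_real_
  sub
}

# Slice update of one edge's seed birth rate (the rate the reconstructed
# edge starts with), holding every other draw fixed. An exact conditional
# update that equilibrates the latent rates much faster than whole-subtree
# resimulation alone, at the cost of three edge-contribution evaluations
# per slice step.
op_slice_edge_rate <- function(w = 1.5, max_steps = 20L) {
  force(w); force(max_steps)
  function(state) {
    tr <- state$aug$tree
    e <- sample(edge_ids(tr), 1L)
    dep <- dependent_edges(tr, e)
    eval_u <- function(u) {
      st <- state
      st$aug$sub[[e]] <- set_seed_rate(state$aug$sub[[e]], exp(u),
                                       state$params)
      st$contrib <- edge_contributions(st$aug, st$params, st$contrib, dep)
      tot <- sum(st$contrib)
      st$log_aug <- if (is.nan(tot)) -Inf else tot
      list(state = st, g = state_posterior(st) + u)
    }
    u0 <- log(state$aug$sub[[e]]$seed[["birth"]])
    e0 <- eval_u(u0)
    if (!is.finite(e0$g)) return(reject_proposal())
    out <- slice_sample_1d(eval_u, u0, e0$g, w, max_steps)
    if (is.null(out)) return(reject_proposal())
    list(state = out, gibbs = TRUE, log_hastings = 0, touched = "aug")
  }
}

# Elliptical slice sampling (Murray, Adams & MacKay 2010) of the whole
# standardized-deviation field z. The inheritance prior of z is exactly
# N(0, I), so the update draws an auxiliary field nu ~ N(0, I) and
# shrinks on the ellipse z' = z cos(t) + nu sin(t) against the
# non-Gaussian remainder of the density
#   L(z) = log_aug + sum(log V(z)) + sum(z^2)/2   (up to constants),
# i.e. the complete-tree density with the inheritance factors stripped
# back out. A coherent field move like this relaxes aggregate latent
# summaries (the empirical deviation variance that pins sigma_lambda)
# orders of magnitude faster than one-edge updates. Turnover and
# pure-birth modes with sigma_lambda > 0.
op_ess_field <- function() {
  function(state) {
    tr <- state$aug$tree
    if (state$params$sigma_lambda <= 0 ||
        state$params$death_mode == "lognormal")
      return(reject_proposal())
    edges <- edge_ids(tr)
    # identity fallback on enormous augmentations (supercritical
    # excursions): bounds the cost of a full-field rebuild; an identity
    # kernel is trivially invariant
    n_seg <- sum(vapply(state$aug$sub[edges], function(s)
      length(s$seg_dt), numeric(1L)))
    if (n_seg > 4000) return(reject_proposal())
    edges <- edges[order(tr$age[tr$parent[edges]], decreasing = TRUE)]
    got <- .get_z_cpp(state$aug$sub, tr$parent, tr$root,
                      as.integer(edges), state$params)
    z <- got$z
    L0 <- state$log_aug + got$sum_log_v + sum(z^2) / 2
    if (!is.finite(L0)) return(reject_proposal())
    nu <- stats::rnorm(length(z))
    logy <- L0 + log(stats::runif(1L))
    theta <- stats::runif(1L, 0, 2 * pi)
    lo <- theta - 2 * pi
    hi <- theta
    repeat {
      z_new <- z * cos(theta) + nu * sin(theta)
      res <- .set_z_cpp(state$aug$sub, tr$parent, tr$root,
                        as.integer(edges), state$params, z_new)
      st <- state
      st$aug$sub <- res$subs
      st$contrib <- edge_contributions(st$aug, st$params)
      tot <- sum(st$contrib)
      st$log_aug <- if (is.nan(tot)) -Inf else tot
      L1 <- st$log_aug + res$sum_log_v + sum(z_new^2) / 2
      if (is.finite(L1) && L1 > logy)
        return(list(state = st, gibbs = TRUE, log_hastings = 0,
                    touched = "aug"))
      if (theta < 0) lo <- theta else hi <- theta
      if (hi - lo < 1e-10) return(reject_proposal())
      theta <- stats::runif(1L, lo, hi)
    }
  }
}

# plain scalar prior-kick (parameters without latent coupling, e.g. the
# turnover epsilon)
op_prior_kick <- function(name) {
  force(name)
  function(state) {
    pr <- state$priors[[name]]
    if (pr$dist == "fixed") return(reject_proposal())
    old <- state$params[[name]]
    new_val <- prior_draw(pr, old)
    st <- state
    st$params[[name]] <- new_val
    list(state = st,
         log_hastings = prior_log_density(pr, old) -
           prior_log_density(pr, new_val),
         touched = "params")
  }
}
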