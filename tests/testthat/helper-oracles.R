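# Independent oracles: term-by-term, loop-wise reimplementations of the
# model densities, sharing no code with the package internals (the
# lognormal density is spelled out through dnorm on the log scale instead
# of dlnorm / the compiled kernel).

oracle_lnorm <- function(x, location, sigma) {
  stats::dnorm(log(x), mean = log(location), sd = sigma, log = TRUE) - log(x)
}

# inheritance density (or sigma = 0 constraint) of a single rate pair
oracle_pair_density <- function(lam, mu, anc_lam, anc_mu, params) {
  ll <- 0
  if (params$sigma_lambda > 0) {
    ll <- ll + oracle_lnorm(lam, params$alpha_lambda * anc_lam,
                            params$sigma_lambda)
  } else if (abs(lam - params$alpha_lambda * anc_lam) >
             1e-12 * max(1, params$alpha_lambda * anc_lam)) {
    return(-Inf)
  }
  if (params$death_mode == "lognormal") {
    if (params$sigma_mu > 0) {
      ll <- ll + oracle_lnorm(mu, params$alpha_mu * anc_mu, params$sigma_mu)
    } else if (abs(mu - params$alpha_mu * anc_mu) >
               1e-12 * max(1, params$alpha_mu * anc_mu)) {
      return(-Inf)
    }
  }
  ll
}

oracle_mu_of <- function(sub, params, what) {
  if (params$death_mode == "lognormal") sub[[what]]
  else if (params$death_mode == "turnover")
    params$epsilon * sub[[sub_lam_name(what)]]
  else 0 * sub[[sub_lam_name(what)]]
}

sub_lam_name <- function(what) sub("_mu", "_lam", what, fixed = TRUE)

# walks every recorded term of one subtree with scalar loops
oracle_subtree_core <- function(sub, anc, params) {
  ll <- oracle_pair_density(sub$seed[["birth"]], sub$seed[["death"]],
                            anc[["birth"]], anc[["death"]], params)
  if (!is.finite(ll)) return(-Inf)
  seg_mu <- oracle_mu_of(sub, params, "seg_mu")
  for (i in seq_along(sub$seg_lam))
    ll <- ll - (sub$seg_lam[i] + seg_mu[i]) * sub$seg_dt[i]
  for (i in seq_along(sub$b_p_lam)) {
    ll <- ll + log(sub$b_p_lam[i])
    pm <- if (params$death_mode == "lognormal") sub$b_p_mu[i] else 0
    d1 <- oracle_pair_density(sub$b_c1_lam[i],
                              if (params$death_mode == "lognormal")
                                sub$b_c1_mu[i] else 0,
                              sub$b_p_lam[i], pm, params)
    d2 <- oracle_pair_density(sub$b_c2_lam[i],
                              if (params$death_mode == "lognormal")
                                sub$b_c2_mu[i] else 0,
                              sub$b_p_lam[i], pm, params)
    if (!is.finite(d1) || !is.finite(d2)) return(-Inf)
    ll <- ll + d1 + d2
  }
  d_mu <- oracle_mu_of(sub, params, "d_mu")
  for (m in d_mu) {
    if (m <= 0) return(-Inf)
    ll <- ll + log(m)
  }
  if (sub$n_hidden > 0) {
    if (params$rho >= 1) return(-Inf)
    ll <- ll + sub$n_hidden * log(1 - params$rho)
  }
  ll
}

oracle_subtree_q <- function(sub, anc, params) {
  core <- oracle_subtree_core(sub, anc, params)
  if (!is.finite(core)) return(-Inf)
  core - log(sub$k)
}

oracle_edge_contrib <- function(sub, anc, params) {
  core <- oracle_subtree_core(sub, anc, params)
  if (!is.finite(core)) return(-Inf)
  if (sub$ends_at_present) core + log(params$rho)
  else core + log(sub$spine[["birth"]])
}

oracle_complete_density <- function(aug, params) {
  tr <- aug$tree
  total <- 0
  for (e in setdiff(seq_along(tr$age), tr$root)) {
    p <- tr$parent[e]
    anc <- if (p == tr$root) {
      mu0 <- switch(params$death_mode, turnover = params$epsilon * params$lambda0,
                    lognormal = params$mu0, none = 0)
      c(birth = params$lambda0, death = mu0)
    } else aug$sub[[p]]$spine
    contrib <- oracle_edge_contrib(aug$sub[[e]], anc, params)
    if (!is.finite(contrib)) return(-Inf)
    total <- total + contrib
  }
  total
}

# brute-force pruning likelihood: enumerate all internal-state assignments
oracle_tree_likelihood <- function(tree, aln, clock_rate) {
  n <- tree$n_tip
  nn <- length(tree$age)
  internals <- (n + 1L):nn
  idx <- match(tree$label, aln$taxa)
  codes <- aln$codes[idx, , drop = FALSE]
  trans <- function(a, b, d) {
    e <- exp(-4 * d / 3)
    if (a == b) 0.25 + 0.75 * e else 0.25 - 0.25 * e
  }
  total <- 0
  for (site in seq_len(aln$n_sites)) {
    lik <- 0
    grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
    for (gi in seq_len(nrow(grid))) {
      assign_state <- integer(nn)
      assign_state[internals] <- grid[gi, ]
      pr <- 0.25
      ok <- TRUE
      for (node in internals) {
        for (k in tree$children[node, ]) {
          d <- clock_rate * (tree$age[node] - tree$age[k])
          if (k <= n) {
            obs <- codes[k, site]
            if (obs == 0L) {
              pr <- pr * 1   # ambiguous: sum over tip states = 1 weight
            } else {
              pr <- pr * trans(assign_state[node], obs, d)
            }
          } else {
            pr <- pr * trans(assign_state[node], assign_state[k], d)
          }
        }
      }
      if (ok) lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}
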