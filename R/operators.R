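# Metropolis-Hastings operators.
#
# Every operator takes the current `clads_state` and returns either `NULL`
# (no eligible move — counted as a rejection) or
# `list(state = <proposal>, log_hastings = <numeric>, touched = <chr>)`.
# `log_hastings = -Inf` marks an auto-rejected proposal (an invalid subtree
# simulation anywhere in the move rejects the whole proposal, and the target
# is never evaluated). Tree operators resimulate at most the subtrees whose
# edges they touch — the edge above the moved node and the edges directly
# below it — and add `log q(old subtree) - log q(new subtree)` per
# resimulated edge to the Hastings ratio; scalar-parameter moves never
# resample subtrees.
#
# Cached subtree `log_q` values are never reused across parameter changes:
# old-subtree densities are recomputed by replay under the current
# parameters, which keeps the ratio exact after any accepted scalar move.

reject_proposal <- function() list(state = NULL, log_hastings = -Inf,
                                   touched = character(0))

is_rejection <- function(prop) is.null(prop) || !is.finite(prop$log_hastings)

#' Multiplicative scale move
#'
#' Proposes `x' = f x` with `f = s^(2u-1)`, `u ~ Uniform(0,1)`; the Hastings
#' correction is `log f`. The standard positive-parameter random walk.
#'
#' @param x current (positive) value.
#' @param s scale window (> 1).
#' @return list with `value` and `log_hastings`.
#' @export
scale_move <- function(x, s = 1.5) {
  stopifnot(x > 0, s > 1)
  f <- s^(2 * stats::runif(1L) - 1)
  list(value = f * x, log_hastings = log(f))
}

# scalar-parameter operator factory; subtrees are left untouched
op_scale_param <- function(name, s = 1.5) {
  force(name); force(s)
  function(state) {
    mv <- scale_move(state$params[[name]], s)
    st <- state
    st$params[[name]] <- mv$value
    # lambda0 / mu0 only enter the target through the crown-edge seeds
    edges <- if (name %in% c("lambda0", "mu0"))
      state$aug$tree$children[state$aug$tree$root, ]
    else NULL
    list(state = st, log_hastings = mv$log_hastings, touched = "params",
         edges = edges)
  }
}

# Resimulate the subtrees of `edges` (ordered parents-before-children) in
# `state`, returning the updated state plus the summed log q difference, or
# NULL if any simulation is invalid. Old densities are replayed under the
# ancestral rates currently in `state`; new simulations are seeded from the
# (possibly freshly resimulated) parent spines in the proposal.
resim_edges <- function(state, new_state, edges) {
  params <- state$params
  lhr <- 0
  for (e in edges) {
    anc_old <- ancestral_rates_of(state$aug, e, params)
    lq_old <- subtree_proposal_log_density(state$aug$sub[[e]], anc_old, params)
    if (!is.finite(lq_old)) return(NULL)  # stale/incoherent state guard
    lhr <- lhr + lq_old
  }
  tr <- new_state$aug$tree
  # order new simulations root-to-tip so seeds come from fresh parents
  ord <- order(tr$age[tr$parent[edges]], decreasing = TRUE)
  for (e in edges[ord]) {
    p <- tr$parent[e]
    anc <- if (p == tr$root) root_rates(params)
           else new_state$aug$sub[[p]]$spine
    dur <- tr$age[p] - tr$age[e]
    if (dur <= 0) return(NULL)
    s <- simulate_subtree(dur, is_tip(tr, e), tr$age[e], anc, params,
                          state$max_events)
    if (is.null(s)) return(NULL)
    new_state$aug$sub[[e]] <- s
    lhr <- lhr - subtree_proposal_log_density(s, anc, params)
  }
  list(state = new_state, log_hastings = lhr)
}

#' Augmented subtree resimulation operator
#'
#' Chooses one edge of the reconstructed tree uniformly at random and
#' resimulates its complete subtree from the current parent spine-tip rates.
#' The reconstructed tree itself is not modified. Hastings ratio:
#' `log q(old subtree) - log q(new subtree)`.
#'
#' @param state a `clads_state`.
#' @return a proposal list (see package internals) or an auto-rejection.
#' @export
augmented_subtree_resim <- function(state) {
  tr <- state$aug$tree
  e <- sample(edge_ids(tr), 1L)
  res <- resim_edges(state, state, e)
  if (is.null(res)) return(reject_proposal())
  list(state = res$state, log_hastings = res$log_hastings, touched = "aug",
       edges = dependent_edges(tr, e))
}

#' Augmented node shift operator
#'
#' Picks an eligible internal node uniformly, proposes a new age uniform
#' between its oldest child and its parent, and resimulates the (at most
#' three) incident subtrees: the edge above the node and the two edges below
#' it. The uniform bounded age move is symmetric, so the Hastings ratio is
#' the subtree-resimulation term alone. The root is eligible only in
#' free-root-age mode, where its age gets a scale move instead.
#'
#' @param state a `clads_state`.
#' @return a proposal list or an auto-rejection.
#' @export
augmented_node_shift <- function(state) {
  tr <- state$aug$tree
  internal <- setdiff((tr$n_tip + 1L):n_nodes(tr), tr$root)
  if (!state$fixed_root) internal <- c(internal, tr$root)
  if (length(internal) == 0L) return(reject_proposal())
  N <- if (length(internal) == 1L) internal else sample(internal, 1L)
  kids <- tr$children[N, ]
  lhr_age <- 0
  if (N == tr$root) {
    mv <- scale_move(tr$age[N], state$windows$root_age)
    new_age <- mv$value
    lhr_age <- mv$log_hastings
    if (new_age <= max(tr$age[kids])) return(reject_proposal())
    edges <- kids
  } else {
    lo <- max(tr$age[kids])
    hi <- tr$age[tr$parent[N]]
    new_age <- stats::runif(1L, lo, hi)
    edges <- c(N, kids)
  }
  st <- state
  st$aug$tree$age[N] <- new_age
  res <- resim_edges(state, st, edges)
  if (is.null(res)) return(reject_proposal())
  list(state = res$state, log_hastings = res$log_hastings + lhr_age,
       touched = c("tree", "aug"),
       edges = dependents_of(res$state$aug$tree, edges))
}

# union of the contribution entries affected by resimulating `edges`
dependents_of <- function(tree, edges) {
  unique(unlist(lapply(edges, function(e) dependent_edges(tree, e))))
}

#' Augmented Wilson-Balding operator
#'
#' Prune-and-regraft: detaches the edge above a uniformly chosen node
#' (excluding the root and its children, so the fixed root is preserved),
#' suppresses its old parent, and reattaches that parent onto a uniformly
#' chosen destination edge at an age drawn uniformly on the feasible
#' interval. Infeasible draws (destination inside the pruned clade, empty
#' age window) are rejected, which keeps the choice probabilities symmetric;
#' the Hastings ratio is `log(new window / old window)` plus the subtree
#' resimulation terms for the pruned edge, the filled gap, and the two
#' halves of the bisected destination edge.
#'
#' @param state a `clads_state`.
#' @return a proposal list or an auto-rejection.
#' @export
augmented_wilson_balding <- function(state) {
  tr <- state$aug$tree
  nn <- n_nodes(tr)
  elig <- which(seq_len(nn) != tr$root & tr$parent != tr$root &
                tr$parent != 0L)
  if (length(elig) == 0L) return(reject_proposal())
  i <- if (length(elig) == 1L) elig else sample(elig, 1L)
  p <- tr$parent[i]
  g <- tr$parent[p]
  sib <- setdiff(tr$children[p, ], i)
  dest <- setdiff(seq_len(nn), tr$root)
  j <- if (length(dest) == 1L) dest else sample(dest, 1L)
  if (j == i || j == p) return(reject_proposal())
  if (descendant_of(tr, j, i)) return(reject_proposal())
  pj <- tr$parent[j]
  pj_eff <- if (pj == p) g else pj   # top of the destination edge after pruning
  lo <- max(tr$age[i], tr$age[j])
  if (tr$age[pj_eff] <= lo) return(reject_proposal())
  w_new <- tr$age[pj_eff] - lo
  w_old <- tr$age[g] - max(tr$age[i], tr$age[sib])
  u <- stats::runif(1L, lo, tr$age[pj_eff])

  st <- state
  ntr <- tr
  # detach p: replace child p of g by sib
  ntr$children[g, ][ntr$children[g, ] == p] <- sib
  ntr$parent[sib] <- g
  # attach p onto (j, pj_eff)
  ntr$children[pj_eff, ][ntr$children[pj_eff, ] == j] <- p
  ntr$parent[p] <- pj_eff
  ntr$children[p, ] <- c(i, j)
  ntr$parent[j] <- p
  ntr$age[p] <- u
  st$aug$tree <- ntr

  edges <- unique(c(i, sib, p, j))  # j == sib collapses to three edges
  res <- resim_edges(state, st, edges)
  if (is.null(res)) return(reject_proposal())
  list(state = res$state,
       log_hastings = res$log_hastings + log(w_new) - log(w_old),
       touched = c("tree", "aug"),
       edges = dependents_of(res$state$aug$tree, edges))
}

#' Augmented narrow subtree exchange operator
#'
#' Swaps a uniformly chosen child of a non-root internal node with that
#' node's sibling (its "uncle") when the age ordering permits. The topology
#' move is symmetric (Hastings term 0); the subtrees of the two re-attached
#' edges are resimulated and contribute `log q(old) - log q(new)`.
#'
#' @param state a `clads_state`.
#' @return a proposal list or an auto-rejection.
#' @export
augmented_subtree_exchange <- function(state) {
  tr <- state$aug$tree
  internal <- setdiff((tr$n_tip + 1L):n_nodes(tr), tr$root)
  if (length(internal) == 0L) return(reject_proposal())
  p <- if (length(internal) == 1L) internal else sample(internal, 1L)
  g <- tr$parent[p]
  u <- setdiff(tr$children[g, ], p)
  cc <- tr$children[p, ][sample.int(2L, 1L)]
  if (tr$age[u] >= tr$age[p]) return(reject_proposal())
  st <- state
  ntr <- tr
  ntr$children[g, ][ntr$children[g, ] == u] <- cc
  ntr$children[p, ][ntr$children[p, ] == cc] <- u
  ntr$parent[cc] <- g
  ntr$parent[u] <- p
  st$aug$tree <- ntr
  res <- resim_edges(state, st, c(cc, u))
  if (is.null(res)) return(reject_proposal())
  list(state = res$state, log_hastings = res$log_hastings,
       touched = c("tree", "aug"),
       edges = dependents_of(res$state$aug$tree, c(cc, u)))
}

# clock-rate scale move (full inference)
op_scale_clock <- function(s = 1.3) {
  force(s)
  function(state) {
    mv <- scale_move(state$clock_rate, s)
    st <- state
    st$clock_rate <- mv$value
    list(state = st, log_hastings = mv$log_hastings, touched = "clock")
  }
}
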