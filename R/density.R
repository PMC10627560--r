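# Joint log-density of a complete (augmented) tree under the ClaDS model.
#
# An augmented tree maps every edge of the reconstructed tree (keyed by the
# edge's child node id) to a `clads_subtree`. The joint density of the
# complete tree factorises over edges: each subtree contributes its seed
# inheritance density (given the parent edge's spine-tip rates, or the root
# rates for the two crown edges), exponential survival terms for every
# constant-rate lineage segment, birth-rate factors and daughter inheritance
# densities at hidden births, death-rate factors at deaths, (1-rho) flags
# for hidden extant tips, plus log(rho) for its sampled tip (edges ending at
# present) or the birth-rate factor of the split (edges ending at an
# internal node). The crown split itself is not charged a birth factor: the
# process starts at the crown with rate lambda0, and the two crown edges'
# seed draws carry the inheritance terms.

#' Assemble an augmented tree
#'
#' @param tree a `clads_tree`.
#' @param subtrees list indexed by node id; one `clads_subtree` per non-root
#'   node (the edge above it).
#' @return an object of class `clads_augmented`.
#' @export
augmented_tree <- function(tree, subtrees) {
  for (e in edge_ids(tree))
    if (is.null(subtrees[[e]]))
      stop("missing subtree for edge above node ", e)
  structure(list(tree = tree, sub = subtrees), class = "clads_augmented")
}

# ancestral rates seeding the edge above node e
ancestral_rates_of <- function(aug, e, params) {
  p <- aug$tree$parent[e]
  if (p == aug$tree$root) root_rates(params) else aug$sub[[p]]$spine
}

#' Log-density of a complete (augmented) tree
#'
#' The joint density of the reconstructed tree together with its hidden
#' lineages and per-lineage rates; the quantity the data-augmented MCMC
#' targets (times the parameter priors and, in full inference, the
#' alignment likelihood). Structurally impossible augmentations — hidden
#' survivors with `rho = 1`, deterministic-inheritance (`sigma = 0`)
#' constraints violated, deaths with a zero death rate — yield `-Inf`, not
#' an error.
#'
#' @param aug a `clads_augmented` tree.
#' @param params a [clads_params()] object.
#' @return the log-density.
#' @export
complete_tree_log_density <- function(aug, params) {
  total <- 0
  for (e in edge_ids(aug$tree)) {
    anc <- ancestral_rates_of(aug, e, params)
    contrib <- subtree_target_contrib(aug$sub[[e]], anc, params)
    if (!is.finite(contrib)) return(-Inf)
    total <- total + contrib
  }
  total
}

# Per-edge contribution vector (indexed by edge child id; the root entry
# stays 0). The MCMC caches this so proposals that touch few edges only
# recompute those entries; -Inf entries mark invalid augmentations.
edge_contributions <- function(aug, params, contrib = NULL, edges = NULL) {
  if (is.null(contrib)) contrib <- numeric(n_nodes(aug$tree))
  if (is.null(edges)) edges <- edge_ids(aug$tree)
  .edge_contribs_cpp(aug$sub, aug$tree$parent, aug$tree$root,
                     root_rates(params), params, as.integer(edges), contrib)
}

# edges whose target contribution depends on edge e's subtree: e itself and
# (through the spine-tip rates that seed the daughters) the child edges of
# e's child node
dependent_edges <- function(tree, e) {
  kids <- tree$children[e, ]
  if (is.na(kids[1L])) e else c(e, kids)
}

#' Initialise an augmentation for a reconstructed tree
#'
#' Simulates a complete subtree for every edge, root-to-tips, so each seed
#' is drawn from the parent edge's freshly simulated spine-tip rates. If the
#' simulation fails `tries` times for an edge, the spine-only
#' [default_subtree()] is installed instead (rates set to the deterministic
#' inheritance value `alpha * parent rate`), which always yields a finite
#' density when `rho < 1` or no hidden survivors exist.
#'
#' @param tree a `clads_tree`.
#' @param params a [clads_params()] object.
#' @param tries simulation attempts per edge before falling back.
#' @param max_events Gillespie event cap per subtree.
#' @return a `clads_augmented` tree.
#' @export
initial_augmentation <- function(tree, params, tries = 10L,
                                 max_events = 1000L) {
  sub <- vector("list", n_nodes(tree))
  # root-to-tip order: parents before children
  ord <- order(tree$age[tree$parent[edge_ids(tree)]], decreasing = TRUE)
  for (e in edge_ids(tree)[ord]) {
    p <- tree$parent[e]
    anc <- if (p == tree$root) root_rates(params) else sub[[p]]$spine
    dur <- tree$age[p] - tree$age[e]
    at_present <- is_tip(tree, e)
    s <- NULL
    for (i in seq_len(tries)) {
      s <- simulate_subtree(dur, at_present, tree$age[e], anc, params,
                            max_events)
      if (!is.null(s)) break
    }
    if (is.null(s)) {
      det <- draw_deterministic_rates(anc, params)
      s <- default_subtree(dur, det, at_present)
    }
    sub[[e]] <- s
  }
  augmented_tree(tree, sub)
}

# deterministic inheritance value (kernel mode when sigma = 0; also a sane
# fallback seed when sigma > 0)
draw_deterministic_rates <- function(anc, params) {
  lam <- params$alpha_lambda * anc[["birth"]]
  mu <- switch(params$death_mode,
               turnover = params$epsilon * lam,
               lognormal = params$alpha_mu * anc[["death"]],
               none = 0)
  c(birth = lam, death = mu)
}

#' Branch-length-weighted mean birth rate of an augmented tree
#'
#' Averages the birth rate over the spine segments of the reconstructed
#' tree (the lineage portions that appear in the reconstructed phylogeny),
#' weighting by segment duration. Hidden side branches do not contribute.
#'
#' @param aug a `clads_augmented` tree.
#' @return the weighted mean birth rate.
#' @export
mean_birth_rate <- function(aug) {
  num <- 0; den <- 0
  for (e in edge_ids(aug$tree)) {
    s <- aug$sub[[e]]
    num <- num + sum(s$spine_seg_lam * s$spine_seg_dt)
    den <- den + sum(s$spine_seg_dt)
  }
  if (den <= 0) stop("zero total tree length")
  num / den
}
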