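# Gillespie simulation of complete ClaDS trees and of per-edge complete
# subtrees, plus the exact log-density of the subtree proposal process.
#
# A `clads_subtree` records the hidden part of the complete tree hanging off
# one reconstructed edge in flattened form: constant-rate lineage segments,
# hidden birth events (with the inherited daughter rates), death events,
# hidden extant tips, the seed rates drawn from the ancestral lineage, and
# the spine (the one surviving lineage identified with the reconstructed
# edge). Flattened records are all the density computations need; the
# chronological simulation itself accumulates the same log-density via
# exponential waiting times and event-choice probabilities, which gives an
# arithmetically independent cross-check (record vs replay).
#
# In turnover mode death rates are never stored: mu = epsilon * lambda is
# recomputed from the current parameters, so scalar moves on epsilon leave
# stored subtrees valid.

subtree_skeleton <- function() {
  list(seed = c(birth = NA_real_, death = NA_real_),
       spine = c(birth = NA_real_, death = NA_real_),
       k = 1L, ends_at_present = FALSE,
       seg_lam = numeric(0), seg_mu = numeric(0), seg_dt = numeric(0),
       spine_seg_lam = numeric(0), spine_seg_dt = numeric(0),
       b_p_lam = numeric(0), b_c1_lam = numeric(0), b_c2_lam = numeric(0),
       b_p_mu = numeric(0), b_c1_mu = numeric(0), b_c2_mu = numeric(0),
       d_lam = numeric(0), d_mu = numeric(0),
       n_hidden = 0L,
       seg_did = integer(0), spine_seg_did = integer(0), spine_did = 1L,
       b_parent_did = integer(0), d_did = integer(0), log_q = NA_real_)
}

#' Simulate the complete subtree of one reconstructed edge
#'
#' Runs the ClaDS Gillespie process along a reconstructed edge, conditional
#' on the edge surviving: one seed lineage with rates drawn from the
#' ancestral rates, birth/death events at the summed lineage rates, a
#' uniformly chosen spine among the survivors at the edge end, and hidden
#' survivors simulated onward until extinction or the present. Invalid
#' outcomes (all lineages die before the edge end; a hidden lineage reaches
#' the present and is flagged sampled; `rho = 1` with hidden survivors; the
#' event cap is exceeded) return `NULL` rather than raising an error —
#' operators treat that as an automatic rejection.
#'
#' The returned subtree caches `log_q`, the exact log-density of the
#' simulation that produced it, accumulated chronologically; see
#' [subtree_proposal_log_density()] for the factorised replay.
#'
#' @param edge_duration duration of the reconstructed edge (> 0).
#' @param ends_at_present does the edge end at a sampled tip?
#' @param time_to_present time from the edge end to the present (0 when
#'   `ends_at_present`).
#' @param ancestral_rates named vector `c(birth =, death =)` of the parent
#'   lineage (spine tip of the parent edge, or the root rates).
#' @param params a [clads_params()] object.
#' @param max_events cap on Gillespie events before the simulation is
#'   declared invalid (guards against supercritical runaway).
#' @return a `clads_subtree`, or `NULL` if the simulation is invalid.
#' @export
simulate_subtree <- function(edge_duration, ends_at_present, time_to_present,
                             ancestral_rates, params, max_events = 1000L) {
  .sim_subtree_cpp(edge_duration, ends_at_present, time_to_present,
                   ancestral_rates[["birth"]], ancestral_rates[["death"]],
                   params, as.integer(max_events))
}

#' Spine-only default subtree
#'
#' The fallback augmentation used during chain initialisation when repeated
#' subtree simulation fails: the complete subtree is assumed to match the
#' reconstructed edge exactly (no hidden births, deaths or survivors), with
#' the given lineage rates. Its `log_q` is left `NA`; compute it with
#' [subtree_proposal_log_density()] once the ancestral rates are known.
#'
#' @param edge_duration duration of the reconstructed edge (>= 0).
#' @param rates named vector `c(birth =, death =)` for the spine lineage.
#' @param ends_at_present does the edge end at a sampled tip?
#' @return a `clads_subtree` with zero hidden lineages.
#' @export
default_subtree <- function(edge_duration, rates, ends_at_present = FALSE) {
  sub <- subtree_skeleton()
  sub$seed <- c(birth = rates[["birth"]], death = rates[["death"]])
  sub$spine <- sub$seed
  sub$ends_at_present <- ends_at_present
  sub$seg_lam <- rates[["birth"]]
  sub$seg_mu <- rates[["death"]]
  sub$seg_dt <- edge_duration
  sub$seg_did <- 1L
  sub$spine_seg_lam <- rates[["birth"]]
  sub$spine_seg_dt <- edge_duration
  sub$spine_seg_did <- 1L
  class(sub) <- "clads_subtree"
  sub
}

# Shared terms of the subtree simulation density and the complete-tree
# density: seed inheritance, segment survival, hidden births (event rate and
# inheritance), deaths, and hidden-tip sampling flags. Returns -Inf when the
# subtree is inconsistent with the parameters (sigma = 0 constraint violated,
# deaths with epsilon = 0, hidden survivors with rho = 1).
subtree_core_terms <- function(sub, ancestral_rates, params) {
  .subtree_core_cpp(sub, ancestral_rates[["birth"]],
                    ancestral_rates[["death"]], params)
}

#' Exact log-density of a subtree under the simulation proposal
#'
#' Replays a `clads_subtree` through the factorised form of the Gillespie
#' density: seed-rate inheritance, per-segment exponential survival,
#' event-rate factors at hidden births and deaths, inheritance densities of
#' hidden daughters, the uniform spine choice `1/k`, and `(1 - rho)` flags
#' for hidden extant tips. For a freshly simulated subtree this reproduces
#' the chronologically accumulated `log_q` (to floating-point error), which
#' the test suite uses as a record-replay cross-check. Returns `-Inf` for
#' subtrees inconsistent with the parameters.
#'
#' @param sub a `clads_subtree`.
#' @param ancestral_rates rates of the ancestral lineage the seed was drawn
#'   from.
#' @param params a [clads_params()] object.
#' @return the log proposal density.
#' @export
subtree_proposal_log_density <- function(sub, ancestral_rates, params) {
  core <- subtree_core_terms(sub, ancestral_rates, params)
  if (!is.finite(core)) return(-Inf)
  core - log(sub$k)
}

# Contribution of one edge's subtree to the complete-tree log-density:
# the shared core, plus log(rho) for the sampled spine tip when the edge
# ends at present, or the birth-event rate factor log(lambda_spine) when the
# edge ends at an internal node of the reconstructed tree. (The uniform
# spine choice is proposal bookkeeping and does not appear here.)
subtree_target_contrib <- function(sub, ancestral_rates, params) {
  core <- subtree_core_terms(sub, ancestral_rates, params)
  if (!is.finite(core)) return(-Inf)
  if (sub$ends_at_present) core + log(params$rho)
  else core + log(sub$spine[["birth"]])
}

## ------------------------------------------------- forward full process --

#' Gillespie simulation of a complete ClaDS tree
#'
#' Simulates the full birth-death process from a crown start: two initial
#' lineages whose rates are drawn from the root rates `(lambda0, mu0)` by
#' the inheritance kernel, then exact event-driven simulation until the
#' present, followed by independent Bernoulli(`rho`) sampling flags on the
#' extant lineages. Trees in which the whole process dies are returned with
#' zero extant lineages; the caller decides whether to reject.
#'
#' @param params a [clads_params()] object.
#' @param crown_age time from the crown (root) to the present (> 0).
#' @param max_lineages cap on simultaneously extant lineages; exceeding it
#'   marks the replicate as rejected (`valid = FALSE`).
#' @param max_events cap on total Gillespie events (guards against
#'   supercritical rate explosions at modest lineage counts); exceeding it
#'   also marks the replicate rejected.
#' @return an object of class `clads_complete`: flat per-lineage arrays
#'   `parent`, `lam`, `mu`, `t0`, `t1` (forward times from the crown),
#'   `status` (`"birth"`, `"death"`, `"extant"`), `sampled`, plus
#'   `crown_age` and `valid`.
#' @export
simulate_complete_tree <- function(params, crown_age, max_lineages = 5000L,
                                   max_events = 5000L) {
  if (crown_age <= 0) stop("crown_age must be positive")
  complete_from_raw(.sim_complete_cpp(params, crown_age,
                                      as.integer(max_lineages),
                                      as.integer(max_events)))
}

# assemble the user-facing record from the raw simulator output
complete_from_raw <- function(raw) {
  structure(list(parent = raw$parent, lam = raw$lam, mu = raw$mu,
                 t0 = raw$t0, t1 = raw$t1,
                 status = c("extant", "birth", "death")[raw$status_code + 1L],
                 sampled = raw$sampled, crown_age = raw$crown_age,
                 valid = raw$valid, n_sampled = raw$n_sampled),
            class = "clads_complete")
}

#' Prune a complete tree to the reconstructed tree of sampled tips
#'
#' Removes every lineage without sampled descendants and suppresses the
#' resulting degree-2 nodes, summing durations. Also reports the
#' branch-length-weighted mean birth rate over the retained (reconstructed)
#' part of the complete tree, and whether both crown lineages were retained
#' (in which case the reconstructed root age equals the crown age).
#'
#' @param complete a `clads_complete` from [simulate_complete_tree()].
#' @return `NULL` if fewer than 2 tips were sampled, otherwise a list with
#'   `tree` (a `clads_tree`), `mean_birth_rate`, `root_is_crown`, and
#'   `n_sampled`.
#' @export
prune_to_reconstructed <- function(complete) {
  if (!complete$valid) return(NULL)
  nrec <- length(complete$parent)
  keep_count <- integer(nrec)
  keep_count[complete$status == "extant" & complete$sampled] <- 1L
  for (i in nrec:1) {   # children always have larger indices than parents
    p <- complete$parent[i]
    if (p > 0L) keep_count[p] <- keep_count[p] + keep_count[i]
  }
  kept <- keep_count > 0L
  n_sampled <- sum(complete$status == "extant" & complete$sampled)
  if (n_sampled < 2L) return(NULL)

  child_list <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    p <- complete$parent[i]
    if (p > 0L && kept[i]) child_list[[p]] <- c(child_list[[p]], i)
  }
  crown <- complete$crown_age

  nn <- 2L * n_sampled - 1L
  parent <- integer(nn); children <- matrix(NA_integer_, nn, 2L)
  age <- numeric(nn)
  next_tip <- 0L; next_int <- n_sampled

  # returns the reconstructed node standing for complete-lineage i
  build <- function(i, recon_parent) {
    repeat {
      kids <- child_list[[i]]
      if (complete$status[i] == "extant") {
        next_tip <<- next_tip + 1L
        id <- next_tip
        parent[id] <<- recon_parent
        age[id] <<- 0
        return(id)
      }
      if (length(kids) == 2L) {
        next_int <<- next_int + 1L
        id <- next_int
        parent[id] <<- recon_parent
        age[id] <<- crown - complete$t1[i]
        c1 <- build(kids[1L], id)
        c2 <- build(kids[2L], id)
        children[id, ] <<- c(c1, c2)
        return(id)
      }
      i <- kids[1L]  # pass-through: one kept child, suppress this node
    }
  }

  crown_kids <- which(complete$parent == 0L & kept)
  if (length(crown_kids) == 2L) {
    root <- n_sampled + 1L
    next_int <- root
    parent[root] <- 0L
    age[root] <- crown
    c1 <- build(crown_kids[1L], root)
    c2 <- build(crown_kids[2L], root)
    children[root, ] <- c(c1, c2)
    root_is_crown <- TRUE
  } else {
    # descend to the first kept branching point
    i <- crown_kids[1L]
    while (length(child_list[[i]]) == 1L) i <- child_list[[i]][1L]
    root <- n_sampled + 1L
    next_int <- root
    parent[root] <- 0L
    age[root] <- crown - complete$t1[i]
    kids <- child_list[[i]]
    c1 <- build(kids[1L], root)
    c2 <- build(kids[2L], root)
    children[root, ] <- c(c1, c2)
    root_is_crown <- FALSE
  }
  tree <- clads_tree(parent, children, age,
                     labels_for(n_sampled), root)
  dur <- complete$t1 - complete$t0
  w <- kept & !is.na(dur)
  mbr <- sum(complete$lam[w] * dur[w]) / sum(dur[w])
  list(tree = tree, mean_birth_rate = mbr,
       root_is_crown = root_is_crown, n_sampled = n_sampled)
}

labels_for <- function(n) paste0("t", seq_len(n))

#' Simulate a reconstructed ClaDS tree by rejection
#'
#' Draws forward simulations at a fixed crown age and keeps the first whose
#' reconstructed tree has a sampled-tip count inside `[n_min, n_max]` and
#' (optionally) retains both crown lineages, so the reconstructed root age
#' equals the crown age.
#'
#' @param params a [clads_params()] object.
#' @param crown_age crown age of the process.
#' @param n_min,n_max accepted range of sampled tip counts.
#' @param require_crown_root keep only trees whose reconstructed root is the
#'   crown.
#' @param max_tries simulation budget before giving up with an error.
#' @param max_lineages passed to [simulate_complete_tree()].
#' @return a list as returned by [prune_to_reconstructed()], with the
#'   number of attempts in `$tries`.
#' @export
simulate_reconstructed_tree <- function(params, crown_age, n_min, n_max = n_min,
                                        require_crown_root = TRUE,
                                        max_tries = 10000L,
                                        max_lineages = 5000L) {
  for (try in seq_len(max_tries)) {
    comp <- simulate_complete_tree(params, crown_age, max_lineages)
    rec <- prune_to_reconstructed(comp)
    if (is.null(rec)) next
    if (rec$n_sampled < n_min || rec$n_sampled > n_max) next
    if (require_crown_root && !rec$root_is_crown) next
    rec$tries <- try
    rec$complete <- comp
    return(rec)
  }
  stop("no accepted tree within ", max_tries, " forward simulations")
}

#' Write a complete tree as annotated Newick
#'
#' Serialises a `clads_complete` with per-lineage birth and death rates in
#' `[&lambda=,mu=]` metadata comments. Off the default output path of the
#' samplers (complete trees are large); intended for occasional inspection.
#'
#' @param complete a `clads_complete`.
#' @return a Newick string with rate annotations.
#' @export
write_complete_newick <- function(complete) {
  build <- function(i) {
    kids <- which(complete$parent == i)
    ann <- sprintf("[&lambda=%.6g,mu=%.6g]", complete$lam[i], complete$mu[i])
    bl <- complete$t1[i] - complete$t0[i]
    core <- if (complete$status[i] == "birth")
      paste0("(", build(kids[1L]), ",", build(kids[2L]), ")")
    else sprintf("L%d", i)
    sprintf("%s%s:%.12g", core, ann, bl)
  }
  top <- which(complete$parent == 0L)
  paste0("(", build(top[1L]), ",", build(top[2L]), ");")
}
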