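# Gillespie simulators: forward complete trees, pruning, subtree proposals
# and their exact densities.

test_that("Yule forward simulation matches the crown expectation 2e^(lt)", {
  set.seed(11)
  p <- fixture_params_yule(lambda0 = 0.1)
  n <- 4000L
  tips <- vapply(seq_len(n), function(i) {
    comp <- simulate_complete_tree(p, 10)
    sum(comp$status == "extant")
  }, numeric(1))
  se <- sd(tips) / sqrt(n)
  expect_lt(abs(mean(tips) - 2 * exp(1)), 3 * se)
})

test_that("a vanishing crown age leaves exactly the two crown lineages", {
  set.seed(12)
  p <- fixture_params_turnover()
  comp <- simulate_complete_tree(p, 1e-9)
  expect_equal(sum(comp$status == "extant"), 2L)
})

test_that("pruning is the identity without deaths at rho = 1", {
  set.seed(13)
  p <- fixture_params_yule(lambda0 = 0.15)
  for (i in 1:20) {
    comp <- simulate_complete_tree(p, 8)
    rec <- prune_to_reconstructed(comp)
    if (is.null(rec)) next
    expect_equal(rec$n_sampled, sum(comp$status == "extant"))
    expect_true(rec$root_is_crown)
    dur <- comp$t1 - comp$t0
    expect_equal(tree_length(rec$tree), sum(dur), tolerance = 1e-9)
  }
})

test_that("pruning a hand-built complete tree collapses extinct lineages", {
  # crown age 3; crown lineage 1 dies at t = 1; crown lineage 2 splits at
  # t = 1 into two lineages that survive to the present, both sampled
  comp <- structure(list(
    parent = c(0L, 0L, 2L, 2L),
    lam = c(0.10, 0.20, 0.25, 0.15),
    mu = c(0.05, 0.02, 0.01, 0.03),
    t0 = c(0, 0, 1, 1),
    t1 = c(1, 1, 3, 3),
    status = c("death", "birth", "extant", "extant"),
    sampled = c(FALSE, FALSE, TRUE, TRUE),
    crown_age = 3, valid = TRUE), class = "clads_complete")
  rec <- prune_to_reconstructed(comp)
  expect_equal(rec$n_sampled, 2L)
  expect_false(rec$root_is_crown)
  expect_equal(rec$tree$age[rec$tree$root], 2)
  # weighted mean birth rate over the kept lineages (2, 3, 4)
  expect_equal(rec$mean_birth_rate,
               (0.20 * 1 + 0.25 * 2 + 0.15 * 2) / 5)
})

test_that("sampled tip counts are binomially thinned extant counts", {
  set.seed(14)
  p <- clads_params(lambda0 = 0.25, alpha_lambda = 1, sigma_lambda = 0.2,
                    death_mode = "turnover", epsilon = 0.2, rho = 0.6)
  diffs <- replicate(2000, {
    comp <- simulate_complete_tree(p, 6)
    extant <- sum(comp$status == "extant")
    sum(comp$sampled) - 0.6 * extant
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("valid subtrees under pure birth at rho = 1 have no hidden part", {
  set.seed(15)
  p <- clads_params(lambda0 = 0.3, alpha_lambda = 1.05, sigma_lambda = 0.3,
                    death_mode = "none", rho = 1)
  for (i in 1:200) {
    s <- simulate_subtree(3, FALSE, 2, c(birth = 0.3, death = 0), p)
    if (is.null(s)) next
    expect_equal(s$n_hidden, 0L)
    expect_length(s$b_p_lam, 0L)
    expect_equal(s$k, 1L)
  }
})

test_that("deterministic inheritance yields the bare ancestral spine", {
  set.seed(16)
  p <- clads_params(lambda0 = 0.3, alpha_lambda = 1, sigma_lambda = 0,
                    death_mode = "none", rho = 1)
  s <- NULL
  while (is.null(s))
    s <- simulate_subtree(5, TRUE, 0, c(birth = 0.3, death = 0), p)
  expect_equal(s$seed[["birth"]], 0.3)
  expect_equal(s$spine[["birth"]], 0.3)
  expect_length(s$b_p_lam, 0L)
  expect_equal(s$log_q, -0.3 * 5, tolerance = 1e-12)
})

test_that("record and replay agree on the proposal log-density", {
  set.seed(17)
  configs <- list(
    list(p = fixture_params_turnover(rho = 0.85),
         anc = c(birth = 0.35, death = 0.105)),
    list(p = fixture_params_lognormal(rho = 0.85),
         anc = c(birth = 0.35, death = 0.06)),
    list(p = fixture_params_yule(0.25), anc = c(birth = 0.25, death = 0)))
  for (cf in configs) {
    checked <- 0L
    while (checked < 400L) {
      ends <- runif(1) < 0.5
      s <- simulate_subtree(3, ends, if (ends) 0 else 2, cf$anc, cf$p)
      if (is.null(s)) next
      checked <- checked + 1L
      expect_equal(subtree_proposal_log_density(s, cf$anc, cf$p), s$log_q,
                   tolerance = 1e-9)
      expect_true(is.finite(s$log_q))
    }
  }
})

test_that("proposal and target densities match the term-audit oracles", {
  set.seed(18)
  for (p in list(fixture_params_turnover(rho = 0.85),
                 fixture_params_lognormal(rho = 0.85))) {
    anc <- c(birth = 0.4, death = if (p$death_mode == "turnover")
      0.12 else 0.05)
    checked <- 0L
    while (checked < 300L) {
      ends <- runif(1) < 0.5
      s <- simulate_subtree(2.5, ends, if (ends) 0 else 1.5, anc, p)
      if (is.null(s)) next
      checked <- checked + 1L
      expect_equal(subtree_proposal_log_density(s, anc, p),
                   oracle_subtree_q(s, anc, p), tolerance = 1e-9)
      expect_equal(cladsmc:::subtree_target_contrib(s, anc, p),
                   oracle_edge_contrib(s, anc, p), tolerance = 1e-9)
    }
  }
})

test_that("the complete-tree density matches the oracle on augmented trees", {
  set.seed(19)
  for (i in 1:30) {
    p <- if (i %% 2) fixture_params_turnover(rho = 0.9)
         else fixture_params_lognormal(rho = 0.9)
    tr <- random_ultrametric_tree(sample(4:12, 1L), runif(1, 3, 8))
    aug <- initial_augmentation(tr, p)
    expect_equal(complete_tree_log_density(aug, p),
                 oracle_complete_density(aug, p), tolerance = 1e-9)
  }
})

test_that("default subtrees give a finite posterior on a 50-tip tree", {
  set.seed(20)
  p <- fixture_params_turnover(rho = 0.9)
  tr <- random_ultrametric_tree(50, 12)
  aug <- augmented_tree(tr, local({
    subs <- vector("list", cladsmc:::n_nodes(tr))
    for (e in cladsmc:::edge_ids(tr)) {
      pa <- tr$parent[e]
      dur <- tr$age[pa] - tr$age[e]
      subs[[e]] <- default_subtree(dur, c(birth = 0.2, death = 0.06),
                                   ends_at_present = e <= tr$n_tip)
    }
    subs
  }))
  expect_true(is.finite(complete_tree_log_density(aug, p)))
  expect_equal(mean_birth_rate(aug), 0.2, tolerance = 1e-12)
})

test_that("subtree simulation treats degenerate edges as invalid", {
  p <- fixture_params_turnover()
  expect_null(simulate_subtree(0, FALSE, 2, c(birth = 0.3, death = 0.09), p))
  expect_null(simulate_subtree(-1, TRUE, 0, c(birth = 0.3, death = 0.09), p))
})
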