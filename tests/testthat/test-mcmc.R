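# Metropolis-Hastings machinery: moves, Hastings ratios, the chain driver,
# and operator structural contracts.

make_test_state <- function(n_tip = 8, root_age = 6, rho = 0.9, seed = 21) {
  set.seed(seed)
  p <- fixture_params_turnover(rho = rho)
  tr <- random_ultrametric_tree(n_tip, root_age)
  clads_state(tr, p)
}

test_that("mh_step accepts identity proposals and rejects invalid ones", {
  st <- make_test_state()
  identity_op <- function(s) list(state = s, log_hastings = 0,
                                  touched = "aug")
  res <- mh_step(st, identity_op)
  expect_true(res$accepted)
  expect_equal(state_posterior <- cladsmc:::state_posterior(res$state),
               cladsmc:::state_posterior(st), tolerance = 1e-12)
  invalid_op <- function(s) list(state = NULL, log_hastings = -Inf,
                                 touched = character(0))
  res2 <- mh_step(st, invalid_op)
  expect_false(res2$accepted)
  expect_identical(res2$state, st)
})

test_that("scale moves with the MH correction sample an Exponential prior", {
  set.seed(22)
  x <- 1
  keep <- numeric(10000)
  for (i in seq_len(20000 * 10)) {
    mv <- scale_move(x, 4)
    if (log(runif(1)) < dexp(mv$value, log = TRUE) -
        dexp(x, log = TRUE) + mv$log_hastings)
      x <- mv$value
    if (i %% 20 == 0) keep[i / 20] <- x
  }
  kt <- suppressWarnings(ks.test(keep, rexp(10000)))
  expect_gt(kt$p.value, 0.01)
  expect_true(all(keep > 0))
  mv <- scale_move(5, 2)
  expect_gt(mv$value, 0)
})

test_that("chains are deterministic given a seed and honour zero iterations", {
  set.seed(23)
  p <- fixture_params_turnover(rho = 0.9)
  tr <- random_ultrametric_tree(6, 5)
  c1 <- run_chain(tr, p, n_iter = 600, sample_every = 50, seed = 99)
  c2 <- run_chain(tr, p, n_iter = 600, sample_every = 50, seed = 99)
  expect_identical(c1$trace, c2$trace)
  c0 <- run_chain(tr, p, n_iter = 0, sample_every = 50, seed = 1)
  expect_equal(nrow(c0$trace), 0L)
  expect_true("Sample" %in% names(c0$trace))
})

test_that("run_chain refuses unidentifiable or operator-free setups", {
  p <- fixture_params_turnover(rho = 0.9)
  tr <- random_ultrametric_tree(5, 4)
  p_bad <- p
  p_bad$estimate <- c("rho", "lambda0", "epsilon", "alpha_lambda",
                      "sigma_lambda")
  expect_error(run_chain(tr, p_bad, n_iter = 10), "identifiability")
  expect_error(run_chain(tr, p, n_iter = 10,
                         weights = list(subtree_resim = 0, node_shift = 0,
                                        wilson_balding = 0,
                                        subtree_exchange = 0, scalar = 0,
                                        clock = 0)),
               "weights")
})

test_that("subtree resimulation leaves the reconstructed tree untouched", {
  st <- make_test_state(seed = 24)
  set.seed(31)
  done <- 0L
  while (done < 50L) {
    prop <- augmented_subtree_resim(st)
    if (cladsmc:::is_rejection(prop)) next
    done <- done + 1L
    expect_identical(prop$state$aug$tree, st$aug$tree)
    changed <- which(!vapply(seq_along(st$aug$sub), function(e)
      identical(prop$state$aug$sub[[e]], st$aug$sub[[e]]), TRUE))
    expect_length(changed, 1L)
  }
})

test_that("node shift only resimulates the incident subtrees", {
  st <- make_test_state(n_tip = 10, seed = 25)
  set.seed(32)
  done <- 0L
  while (done < 50L) {
    prop <- augmented_node_shift(st)
    if (cladsmc:::is_rejection(prop)) next
    done <- done + 1L
    tr1 <- st$aug$tree
    tr2 <- prop$state$aug$tree
    moved <- which(abs(tr1$age - tr2$age) > 0)
    expect_length(moved, 1L)
    incident <- c(moved, tr1$children[moved, ])
    for (e in cladsmc:::edge_ids(tr1))
      if (!(e %in% incident))
        expect_identical(prop$state$aug$sub[[e]], st$aug$sub[[e]])
    validate_clads_tree(tr2)
  }
})

test_that("Wilson-Balding and subtree exchange preserve tips and ultrametry", {
  st <- make_test_state(n_tip = 12, seed = 26)
  set.seed(33)
  n_wb <- n_ex <- 0L
  while (n_wb < 100L || n_ex < 100L) {
    if (n_wb < 100L) {
      prop <- augmented_wilson_balding(st)
      if (!cladsmc:::is_rejection(prop)) {
        n_wb <- n_wb + 1L
        tr2 <- prop$state$aug$tree
        validate_clads_tree(tr2)
        expect_setequal(tr2$label, st$aug$tree$label)
        expect_equal(tr2$age[tr2$root], st$aug$tree$age[st$aug$tree$root])
      }
    }
    if (n_ex < 100L) {
      prop <- augmented_subtree_exchange(st)
      if (!cladsmc:::is_rejection(prop)) {
        n_ex <- n_ex + 1L
        tr2 <- prop$state$aug$tree
        validate_clads_tree(tr2)
        expect_setequal(tr2$label, st$aug$tree$label)
        expect_equal(sort(tr2$age), sort(st$aug$tree$age))
      }
    }
  }
})

test_that("2-tip trees admit no topology moves", {
  st <- make_test_state(n_tip = 2, seed = 27)
  expect_true(cladsmc:::is_rejection(augmented_wilson_balding(st)))
  expect_true(cladsmc:::is_rejection(augmented_subtree_exchange(st)))
  # fixed root: the only internal node is the root, so no node shift either
  expect_true(cladsmc:::is_rejection(augmented_node_shift(st)))
})

test_that("cached contributions stay coherent with full recomputation", {
  set.seed(28)
  p <- fixture_params_turnover(rho = 0.9)
  tr <- random_ultrametric_tree(8, 6)
  ch <- run_chain(tr, p, n_iter = 2000, sample_every = 200, seed = 5)
  st <- ch$final_state
  expect_equal(st$log_aug, complete_tree_log_density(st$aug, st$params),
               tolerance = 1e-8)
  expect_equal(st$log_prior,
               cladsmc:::log_prior(st$params, st$priors), tolerance = 1e-12)
})

test_that("full inference co-estimates tree and parameters on fixtures", {
  set.seed(29)
  truth <- clads_params(lambda0 = 0.35, alpha_lambda = 1,
                        sigma_lambda = 0.2, death_mode = "none", rho = 1,
                        estimate = c("lambda0", "sigma_lambda",
                                     "alpha_lambda"))
  rec <- simulate_reconstructed_tree(truth, 6, 7, 10)
  clock <- 0.5 / 6  # expected root-to-tip path ~0.5 substitutions
  aln <- simulate_alignment(rec$tree, 500, clock)
  start <- random_ultrametric_tree(rec$tree$n_tip, 6,
                                   labels = rec$tree$label)
  ch <- run_chain(start, truth, n_iter = 4000, aln = aln,
                  clock_rate = clock, sample_every = 50, seed = 30)
  tr <- ch$trace
  expect_true(all(is.finite(tr$posterior)))
  expect_true(all(is.finite(tr$likelihood)))
  # the chain should improve on the random starting tree's likelihood
  expect_gt(max(tr$likelihood), tr$likelihood[1])
  # root age is fixed; tips fixed
  expect_equal(unique(tr$root_age), 6)
})
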