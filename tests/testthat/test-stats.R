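# Tree-shape statistics and the validation harness plumbing.

test_that("the gamma statistic matches its hand evaluation and ape", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(gamma_statistic(tr), (2 - 5 / 2) / (5 * sqrt(1 / 12)),
               tolerance = 1e-12)
  expect_equal(gamma_statistic(tr), -0.34641, tolerance = 1e-5)
  set.seed(51)
  for (i in 1:25) {
    t2 <- random_ultrametric_tree(sample(4:40, 1L), runif(1, 1, 10))
    expect_equal(gamma_statistic(t2), ape::gammaStat(as_phylo(t2)),
                 tolerance = 1e-8)
    # scale invariance
    t3 <- t2
    t3$age <- t2$age * 7.3
    expect_equal(gamma_statistic(t3), gamma_statistic(t2),
                 tolerance = 1e-9)
  }
  expect_error(gamma_statistic(parse_newick("(A:1,B:1);")), "3 tips")
})

test_that("gamma is approximately standard normal under the Yule model", {
  set.seed(52)
  g <- replicate(1500, gamma_statistic(from_phylo(ape::rphylo(50, 1, 0))))
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g)), 3 * se)
  expect_gt(var(g), 0.8)
  expect_lt(var(g), 1.25)
})

test_that("the Colless index counts subtree imbalance", {
  expect_equal(colless_index(fixture_balanced4()), 0L)
  expect_equal(colless_index(fixture_caterpillar(c(3, 2, 1))), 3L)
  for (n in 4:12) {
    cat_tree <- fixture_caterpillar(seq(n - 1, 1))
    expect_equal(colless_index(cat_tree), (n - 1) * (n - 2) / 2)
  }
  # against ape::balance on random trees
  set.seed(53)
  for (i in 1:25) {
    tr <- random_ultrametric_tree(sample(4:40, 1L), 5)
    b <- ape::balance(as_phylo(tr))
    expect_equal(colless_index(tr), sum(abs(b[, 1] - b[, 2])))
  }
})

test_that("mean birth rate is the branch-length-weighted spine average", {
  tr <- parse_newick("(A:4,B:4);")
  s1 <- default_subtree(4, c(birth = 0.1, death = 0), TRUE)
  s1$spine_seg_lam <- c(0.1, 0.3)
  s1$spine_seg_dt <- c(1, 3)
  s2 <- default_subtree(4, c(birth = 0.2, death = 0), TRUE)
  aug <- augmented_tree(tr, list(s1, s2, NULL))
  expect_equal(mean_birth_rate(aug), (0.1 + 0.9 + 0.8) / 8)
  # invariant to subdividing a constant-rate segment
  s2b <- s2
  s2b$spine_seg_lam <- c(0.2, 0.2)
  s2b$spine_seg_dt <- c(1.5, 2.5)
  aug2 <- augmented_tree(tr, list(s1, s2b, NULL))
  expect_equal(mean_birth_rate(aug2), mean_birth_rate(aug))
})

test_that("two forward samples from the same prior are indistinguishable", {
  p <- clads_params(death_mode = "turnover", rho = 1,
                    estimate = c("lambda0", "alpha_lambda",
                                 "sigma_lambda", "epsilon"))
  pri <- default_priors()
  set.seed(54)
  a <- cladsmc:::forward_prior_sample(p, pri, 6, 8, 600)
  set.seed(99)
  b <- cladsmc:::forward_prior_sample(p, pri, 6, 8, 600)
  ks <- cladsmc:::compare_statistic_samples(a$stats, b$stats)
  expect_true(all(ks$p_bonferroni > 0.01))
})

test_that("degenerate statistics are flagged, not tested", {
  a <- data.frame(gamma = rnorm(50), sigma_lambda = rep(0.5, 50))
  b <- data.frame(gamma = rnorm(50), sigma_lambda = rep(0.5, 50))
  ks <- cladsmc:::compare_statistic_samples(a, b)
  expect_true(ks$degenerate[ks$statistic == "sigma_lambda"])
  expect_false(ks$degenerate[ks$statistic == "gamma"])
})
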