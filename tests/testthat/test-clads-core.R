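# The ClaDS parameter model: inheritance kernel, rate variation summary,
# identifiability, and the complete-tree log-density.

test_that("sample_child_rates degenerates correctly when sigma = 0", {
  p <- clads_params(sigma_lambda = 0, alpha_lambda = 0.9,
                    death_mode = "none")
  kids <- sample_child_rates(c(birth = 0.1, death = 0), p)
  expect_equal(kids[[1]][["birth"]], 0.09)
  expect_equal(kids[[2]][["birth"]], 0.09)
  # alpha = 1, sigma = 0: constant-rate degeneration
  p1 <- clads_params(sigma_lambda = 0, alpha_lambda = 1,
                     death_mode = "none")
  kids <- sample_child_rates(c(birth = 0.14, death = 0), p1)
  expect_equal(kids[[1]][["birth"]], 0.14)
  expect_error(sample_child_rates(c(birth = -1, death = 0), p1),
               "positive")
})

test_that("inheritance kernel matches its stated lognormal moments", {
  set.seed(101)
  p <- clads_params(lambda0 = 0.2, alpha_lambda = 0.8, sigma_lambda = 0.5,
                    death_mode = "none")
  n <- 1e5
  draws <- replicate(n / 500, {
    ks <- vapply(1:250, function(i)
      unlist(sample_child_rates(c(birth = 0.2, death = 0), p))[c(1, 3)],
      numeric(2))
    as.vector(ks)
  })
  lx <- log(as.vector(draws))
  se_mean <- sd(lx) / sqrt(length(lx))
  expect_lt(abs(mean(lx) - log(0.16)), 3 * se_mean)
  se_sd <- 0.5 / sqrt(2 * length(lx))
  expect_lt(abs(sd(lx) - 0.5), 3 * se_sd)
})

test_that("inheritance log-density is a proper lognormal density", {
  # mode of the kernel: child = alpha * parent
  val <- inheritance_log_density(0.09, 0.1, 0.9, 0.5)
  expect_equal(val, -log(0.09) - log(0.5) - 0.5 * log(2 * pi),
               tolerance = 1e-12)
  # against an independent evaluation through dnorm on the log scale
  expect_equal(inheritance_log_density(0.09, 0.1, 0.9, 0.5),
               oracle_lnorm(0.09, 0.9 * 0.1, 0.5), tolerance = 1e-12)
  # integrates to 1
  f <- function(x) exp(inheritance_log_density(x, 0.1, 0.9, 0.5))
  expect_equal(stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  expect_error(inheritance_log_density(0.1, 0.1, 1, 0), "point mass")
  expect_error(inheritance_log_density(-0.1, 0.1, 1, 0.5), "positive")
})

test_that("mean rate variation evaluates alpha * exp(sigma^2/2)", {
  expect_equal(round(mean_rate_variation(0.69, 0.90), 2), 1.03)
  expect_equal(mean_rate_variation(1, 0), 1)
  expect_equal(mean_rate_variation(0.5, 1.0), 0.5 * exp(0.5),
               tolerance = 1e-6)
})

test_that("the identifiability rule is enforced", {
  expect_error(
    clads_params(death_mode = "turnover", epsilon = 0.5,
                 estimate = c("rho", "lambda0", "epsilon")),
    "identifiability")
  # fixing any one of the three anchors is enough
  expect_s3_class(
    clads_params(death_mode = "turnover", epsilon = 0.5,
                 estimate = c("lambda0", "epsilon")), "clads_params")
  expect_error(
    clads_params(death_mode = "lognormal", mu0 = 0.1,
                 estimate = c("rho", "lambda0", "mu0")),
    "identifiability")
  p <- clads_params(death_mode = "turnover", estimate = "lambda0")
  p$estimate <- c("rho", "lambda0", "epsilon")
  expect_error(cladsmc:::check_identifiability(p), "identifiability")
})

test_that("a bare spine contributes only its survival term", {
  # lambda = 0.1, mu = 0.05 over duration 2, rho = 1: -(0.15) * 2
  p <- clads_params(lambda0 = 0.1, alpha_lambda = 1, sigma_lambda = 0,
                    death_mode = "turnover", epsilon = 0.5, rho = 1)
  sub <- default_subtree(2, c(birth = 0.1, death = 0.05),
                         ends_at_present = TRUE)
  anc <- c(birth = 0.1, death = 0.05)
  expect_equal(cladsmc:::subtree_target_contrib(sub, anc, p), -0.3,
               tolerance = 1e-12)
  # a 2-tip tree made of two such edges
  tr <- parse_newick("(A:2,B:2);")
  aug <- augmented_tree(tr, list(sub, sub, NULL))
  expect_equal(complete_tree_log_density(aug, p), -0.6, tolerance = 1e-12)
})

test_that("rho = 1 with hidden survivors and sigma = 0 violations give -Inf", {
  p <- clads_params(lambda0 = 0.1, alpha_lambda = 1, sigma_lambda = 0,
                    death_mode = "turnover", epsilon = 0.5, rho = 1)
  sub <- default_subtree(2, c(birth = 0.1, death = 0.05), TRUE)
  sub$n_hidden <- 1L
  expect_identical(
    cladsmc:::subtree_target_contrib(sub, c(birth = 0.1, death = 0.05), p),
    -Inf)
  # deterministic inheritance constraint: seed must equal alpha * parent
  sub2 <- default_subtree(2, c(birth = 0.12, death = 0.06), TRUE)
  expect_identical(
    cladsmc:::subtree_target_contrib(sub2, c(birth = 0.1, death = 0.05), p),
    -Inf)
})

test_that("turnover mode keeps mu = epsilon * lambda on every lineage", {
  set.seed(3)
  p <- fixture_params_turnover(rho = 0.8)
  for (i in 1:200) {
    s <- simulate_subtree(4, FALSE, 3, c(birth = 0.3, death = 0.09), p)
    if (is.null(s)) next
    expect_identical(s$seed[["death"]], p$epsilon * s$seed[["birth"]])
    expect_identical(s$spine[["death"]], p$epsilon * s$spine[["birth"]])
  }
})

test_that("the density reduces to the Yule closed form for constant rates", {
  set.seed(4)
  p <- fixture_params_yule(lambda0 = 0.17)
  for (i in 1:10) {
    tr <- random_ultrametric_tree(sample(4:15, 1L), runif(1, 2, 8))
    aug <- initial_augmentation(tr, p)
    lam <- p$lambda0
    closed <- -lam * tree_length(tr) + (tr$n_tip - 2L) * log(lam)
    expect_equal(complete_tree_log_density(aug, p), closed,
                 tolerance = 1e-9)
  }
})

test_that("the density is invariant to daughter ordering at births", {
  set.seed(5)
  p <- fixture_params_turnover(rho = 0.8)
  found <- 0L
  anc <- c(birth = 0.4, death = 0.12)
  while (found < 20L) {
    s <- simulate_subtree(4, FALSE, 3, anc, p)
    if (is.null(s) || length(s$b_p_lam) == 0L) next
    found <- found + 1L
    s2 <- s
    s2$b_c1_lam <- s$b_c2_lam
    s2$b_c2_lam <- s$b_c1_lam
    expect_equal(cladsmc:::subtree_target_contrib(s2, anc, p),
                 cladsmc:::subtree_target_contrib(s, anc, p),
                 tolerance = 1e-12)
  }
})
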