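# Shared fixtures: small parameter sets and trees built in code.

fixture_params_turnover <- function(rho = 1, ...) {
  clads_params(lambda0 = 0.2, alpha_lambda = 0.95, sigma_lambda = 0.4,
               death_mode = "turnover", epsilon = 0.3, rho = rho,
               estimate = c("lambda0", "alpha_lambda", "sigma_lambda",
                            "epsilon"), ...)
}

fixture_params_lognormal <- function(rho = 0.9) {
  clads_params(lambda0 = 0.2, alpha_lambda = 0.95, sigma_lambda = 0.4,
               death_mode = "lognormal", mu0 = 0.05, alpha_mu = 0.9,
               sigma_mu = 0.3, rho = rho,
               estimate = c("lambda0", "sigma_lambda"))
}

fixture_params_yule <- function(lambda0 = 0.1) {
  clads_params(lambda0 = lambda0, alpha_lambda = 1, sigma_lambda = 0,
               death_mode = "none", rho = 1, estimate = character())
}

# balanced 4-tip tree ((A,B),(C,D)) with cherry ages a1, a2 and root age r
fixture_balanced4 <- function(a1 = 1, a2 = 1, r = 2) {
  parse_newick(sprintf("((A:%g,B:%g):%g,(C:%g,D:%g):%g);",
                       a1, a1, r - a1, a2, a2, r - a2))
}

# caterpillar with internal node ages given oldest-first (root first)
fixture_caterpillar <- function(ages = c(3, 2, 1)) {
  n <- length(ages) + 1L
  txt <- sprintf("(t1:%g,t2:%g)", ages[n - 1L], ages[n - 1L])
  if (n > 2L) for (i in (n - 2L):1L) {
    txt <- sprintf("(%s:%g,t%d:%g)", txt, ages[i] - ages[i + 1L],
                   n - i + 1L, ages[i])
  }
  parse_newick(paste0(txt, ";"))
}
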