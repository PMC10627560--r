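# The data-augmented engine against an independently written fixed-tree
# sampler. Under pure birth with complete sampling the augmentation is
# exactly the per-edge rate set, so a plain MH sampler over (parameters,
# standardized deviations) with its own hand-written density provides the
# true posterior; the engine's marginals must match it.

test_that("the engine reproduces the independent fixed-tree posterior", {
  set.seed(17)
  truth <- clads_params(lambda0 = 0.25, alpha_lambda = 0.9,
                        sigma_lambda = 0.6, death_mode = "none", rho = 1,
                        estimate = c("lambda0", "alpha_lambda",
                                     "sigma_lambda"))
  rec <- simulate_reconstructed_tree(truth, 8, 5, 7, max_tries = 5000)
  tr <- rec$tree

  ## independent non-centered sampler with its own density --------------
  nn <- length(tr$age)
  edges <- setdiff(seq_len(nn), tr$root)
  dur <- tr$age[tr$parent[edges]] - tr$age[edges]
  internal_child <- edges > tr$n_tip
  ord <- order(tr$age[tr$parent[edges]], decreasing = TRUE)
  edges_o <- edges[ord]; dur_o <- dur[ord]; int_o <- internal_child[ord]
  parent_o <- tr$parent[edges_o]
  pos <- integer(nn); pos[edges_o] <- seq_along(edges_o)
  rates_of <- function(l0, al, sl, z) {
    lam <- numeric(length(edges_o))
    for (i in seq_along(edges_o)) {
      p <- parent_o[i]
      anc <- if (p == tr$root) l0 else lam[pos[p]]
      lam[i] <- exp(log(al * anc) + sl * z[i])
    }
    lam
  }
  logdens <- function(l0, al, sl, z) {
    lam <- rates_of(l0, al, sl, z)
    dlnorm(l0, log(0.1), 1, log = TRUE) + dlnorm(al, 0, 0.5, log = TRUE) +
      dexp(sl, 1, log = TRUE) + sum(dnorm(z, log = TRUE)) -
      sum(lam * dur_o) + sum(log(lam[int_o]))
  }
  set.seed(8)
  l0 <- 0.2; al <- 1; sl <- 0.5; z <- rnorm(length(edges_o))
  cur <- logdens(l0, al, sl, z)
  keep <- numeric(3000)
  for (it in 1:300000) {
    k <- sample.int(3 + length(z), 1)
    l0n <- l0; aln <- al; sln <- sl; zn <- z; lhr <- 0
    if (k <= 3) {
      f <- exp(runif(1, -0.7, 0.7)); lhr <- log(f)
      if (k == 1) l0n <- l0 * f else if (k == 2) aln <- al * f
      else sln <- sl * f
    } else zn[k - 3] <- z[k - 3] + rnorm(1, 0, 0.8)
    newd <- logdens(l0n, aln, sln, zn)
    if (is.finite(newd) && log(runif(1)) < newd - cur + lhr) {
      l0 <- l0n; al <- aln; sl <- sln; z <- zn; cur <- newd
    }
    if (it %% 100 == 0) keep[it / 100] <- sl
  }
  oracle <- keep[601:3000]

  ## engine on the same tree --------------------------------------------
  ch <- run_chain(tr, truth, n_iter = 150000, fixed_tree = TRUE,
                  sample_every = 100, seed = 12,
                  windows = list(scalar = 3, root_age = 1.2, clock = 1.3))
  engine <- ch$trace$sigma_lambda[-(1:375)]

  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  expect_equal(unname(quantile(engine, qs)), unname(quantile(oracle, qs)),
               tolerance = 0.25)
  # and a rank test on independence-subsampled draws
  sub_e <- engine[seq(1, length(engine), by = 8)]
  sub_o <- oracle[seq(1, length(oracle), by = 8)]
  kt <- suppressWarnings(ks.test(sub_e, sub_o))
  expect_gt(kt$p.value, 0.005)
})
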