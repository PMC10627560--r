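# JC69 likelihood, sequence simulation, FASTA I/O.

test_that("JC69 transition probabilities hit their landmarks", {
  expect_equal(jc69_transition_probability("A", "A", 0), 1)
  expect_equal(jc69_transition_probability("A", "C", 0), 0)
  expect_equal(jc69_transition_probability("A", "C", 1e6), 0.25,
               tolerance = 1e-9)
  expect_equal(jc69_transition_probability("A", "A", 0.1),
               0.25 + 0.75 * exp(-2 / 15), tolerance = 1e-12)
  expect_equal(jc69_transition_probability("A", "A", 0.1), 0.9063800,
               tolerance = 1e-6)
  expect_error(jc69_transition_probability("A", "A", -0.1), "non-negative")
})

test_that("two identical tips at zero distance give log(1/4) per site", {
  tr <- parse_newick("(A:0,B:0);", require_ultrametric = FALSE)
  aln <- clads_alignment(c("A", "B"), c("G", "G"))
  expect_equal(tree_log_likelihood(tr, aln, 1), log(0.25),
               tolerance = 1e-12)
})

test_that("pruning matches brute-force state enumeration on 4-tip trees", {
  set.seed(41)
  for (i in 1:6) {
    tr <- random_ultrametric_tree(4, runif(1, 0.5, 2))
    aln <- simulate_alignment(tr, 12, clock_rate = runif(1, 0.2, 1))
    cl <- runif(1, 0.2, 1.5)
    expect_equal(tree_log_likelihood(tr, aln, cl),
                 oracle_tree_likelihood(tr, aln, cl), tolerance = 1e-10)
  }
  # including ambiguous characters
  tr <- fixture_balanced4()
  aln <- clads_alignment(c("A", "B", "C", "D"),
                         c("AC-G", "ACNG", "GCTG", "GTT-"))
  expect_equal(tree_log_likelihood(tr, aln, 0.3),
               oracle_tree_likelihood(tr, aln, 0.3), tolerance = 1e-10)
})

test_that("sites are independent and tip order is irrelevant", {
  set.seed(42)
  tr <- random_ultrametric_tree(5, 2)
  aln <- simulate_alignment(tr, 40, 0.5)
  ll <- tree_log_likelihood(tr, aln, 0.5)
  dbl <- clads_alignment(aln$taxa, paste0(aln$sequences, aln$sequences))
  expect_equal(tree_log_likelihood(tr, dbl, 0.5), 2 * ll,
               tolerance = 1e-9)
  shuf <- sample(length(aln$taxa))
  aln2 <- clads_alignment(aln$taxa[shuf], aln$sequences[shuf])
  expect_equal(tree_log_likelihood(tr, aln2, 0.5), ll, tolerance = 1e-12)
})

test_that("the sequence simulator has the right degenerate and limit laws", {
  set.seed(43)
  tr <- random_ultrametric_tree(4, 3)
  frozen <- simulate_alignment(tr, 30, clock_rate = 0)
  expect_length(unique(frozen$sequences), 1L)
  # stationary base frequencies ~ 1/4
  aln <- simulate_alignment(tr, 10000, clock_rate = 1)
  freq <- table(strsplit(paste(aln$sequences, collapse = ""), "")[[1]])
  prop <- freq / sum(freq)
  se <- sqrt(0.25 * 0.75 / sum(freq))
  expect_true(all(abs(prop - 0.25) < 3 * se * 2))
  # JC-corrected distance on a 2-tip tree concentrates at 2 * rate * age
  tr2 <- parse_newick("(A:2,B:2);")
  d_obs <- replicate(30, {
    a <- simulate_alignment(tr2, 2000, clock_rate = 0.1)
    s <- strsplit(a$sequences, "")
    pdiff <- mean(s[[1]] != s[[2]])
    -3 / 4 * log(1 - 4 * pdiff / 3)
  })
  expect_equal(mean(d_obs), 0.4, tolerance = 0.02)
})

test_that("FASTA round-trips, normalises case, and rejects bad input", {
  aln <- clads_alignment(c("tax1", "tax2"), c("ACGTAC", "ACGTTT"))
  path <- tempfile(fileext = ".fasta")
  write_fasta(aln, path, width = 4)
  back <- read_fasta(path)
  expect_identical(back$taxa, aln$taxa)
  expect_identical(back$sequences, aln$sequences)
  writeLines(c(">a", "acg", "t", ">b", "ACGT"), path)
  low <- read_fasta(path)
  expect_identical(low$sequences, c("ACGT", "ACGT"))
  writeLines(c(">a", "ACGT", ">b", "AC"), path)
  expect_error(read_fasta(path), "ragged")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), path)
  expect_error(read_fasta(path), "duplicate")
  expect_error(clads_alignment("a", "ACGX"), "unsupported")
})

test_that("likelihood demands matching taxa and non-empty data", {
  tr <- parse_newick("(A:1,B:1);")
  aln <- clads_alignment(c("A", "X"), c("ACG", "ACG"))
  expect_error(tree_log_likelihood(tr, aln, 1), "mismatch")
})
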