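# Tree structure, Newick parsing/writing, internode intervals, Nexus logs.

test_that("parse_newick reads ages off a simple tree", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(tr$n_tip, 3L)
  expect_equal(tr$age[tr$root], 2)
  cherry <- setdiff((tr$n_tip + 1L):5L, tr$root)
  expect_equal(tr$age[cherry], 1)
  expect_setequal(tr$label, c("A", "B", "C"))
  expect_equal(sort(tr$age), c(0, 0, 0, 1, 2))
})

test_that("parse_newick rejects malformed and inconsistent input", {
  expect_error(parse_newick("((A:1,B:2):1,C:2);"), "non-ultrametric")
  expect_error(parse_newick("((A:1,B:1,C:1):1,D:2);"), "non-binary")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(parse_newick("((A:1,B:1),C:2);"), "branch length")
  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "malformed|expected")
  # non-ultrametric input is fine when the caller does not require it
  tr <- parse_newick("((A:1,B:2):1,C:2);", require_ultrametric = FALSE)
  expect_equal(tr$n_tip, 3L)
})

test_that("metadata comments are preserved and emitted", {
  tr <- parse_newick("((A[&x=1]:1,B:1)[&rate=0.5]:1,C:2);")
  ann <- attr(tr, "annotations")
  expect_false(is.null(ann))
  expect_true(any(grepl("rate=0.5", unlist(ann[!vapply(ann, is.null,
                                                       TRUE)]))))
  # writing annotations produces the [&key=value] dialect
  ann_out <- vector("list", 5L)
  for (i in 1:5) ann_out[[i]] <- c(lambda = 0.1 * i)
  txt <- write_newick(tr, annotations = ann_out)
  expect_equal(lengths(regmatches(txt, gregexpr("\\[&lambda=", txt))), 5L)
  # and round-trips through the parser
  expect_silent(parse_newick(txt))
})

test_that("parse/write round-trip preserves topology and ages", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:25, 1L)
    tr <- random_ultrametric_tree(n, runif(1, 1, 20))
    tr2 <- parse_newick(write_newick(tr))
    expect_equal(sort(tr2$age), sort(tr$age), tolerance = 1e-9)
    # topology equality via ape (independent reader)
    expect_true(ape::all.equal.phylo(as_phylo(tr), as_phylo(tr2),
                                     use.edge.length = FALSE))
    # pairwise distances agree with ape reading the same string
    phy <- ape::read.tree(text = write_newick(tr))
    d1 <- ape::cophenetic.phylo(phy)
    d2 <- ape::cophenetic.phylo(as_phylo(tr2))
    expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-9)
  }
})

test_that("internode intervals enumerate lineage counts root to present", {
  iv <- internode_intervals(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(iv$k, 2:3)
  expect_equal(iv$duration, c(1, 1))
  iv4 <- internode_intervals(fixture_caterpillar(c(3, 2, 1)))
  expect_equal(iv4$k, 2:4)
  expect_equal(iv4$duration, c(1, 1, 1))
  expect_error(internode_intervals(parse_newick("(A:1,B:1);")), "3 tips")
  set.seed(7)
  for (i in 1:20) {
    tr <- random_ultrametric_tree(sample(3:30, 1L), runif(1, 0.5, 10))
    iv <- internode_intervals(tr)
    expect_true(all(iv$duration >= 0))
    expect_equal(sum(iv$duration), tr$age[tr$root], tolerance = 1e-9)
  }
})

test_that("Nexus tree logs are readable by ape", {
  set.seed(1)
  path <- tempfile(fileext = ".nexus")
  tr <- random_ultrametric_tree(6, 5)
  nx <- nexus_log_open(path, tr$label)
  nexus_log_add(nx, tr, "STATE_0")
  tr2 <- random_ultrametric_tree(6, 5, labels = tr$label)
  nexus_log_add(nx, tr2, "STATE_100")
  nexus_log_close(nx)
  trees <- ape::read.nexus(path)
  expect_length(trees, 2L)
  expect_setequal(trees[[1]]$tip.label, tr$label)
  expect_equal(max(ape::node.depth.edgelength(trees[[1]])), 5,
               tolerance = 1e-9)
})

test_that("tree validation catches broken structures", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  bad <- tr
  bad$age[bad$root] <- 0.5  # child older than parent
  expect_error(validate_clads_tree(bad), "older than parent|negative")
  bad2 <- tr
  bad2$label <- c("A", "A", "C")
  expect_error(validate_clads_tree(bad2), "duplicate")
})
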