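# Reconstructed-tree data structure and Newick / Nexus I/O.
#
# A `clads_tree` is a rooted binary ultrametric tree stored in flat arrays.
# Node ids: tips are 1..n_tip, internal nodes n_tip+1..2*n_tip-1 (the root can
# be any internal id; MCMC surgery keeps ids stable).  Ages are measured
# backward from the present (tips sit at age 0).  Every non-root node `i`
# identifies the edge above it, with duration age[parent] - age[i].

#' Construct a reconstructed tree from flat arrays
#'
#' Low-level constructor used by the parser, the simulators and the tree
#' operators. Most users will obtain trees from [parse_newick()] or
#' [simulate_reconstructed_tree()].
#'
#' @param parent integer vector of parent ids (0 for the root).
#' @param children integer matrix with one row per node and two columns;
#'   `NA` entries for tips.
#' @param age numeric vector of node ages (time before present).
#' @param label character vector of tip labels (tips are nodes `1..n_tip`).
#' @param root id of the root node.
#' @param validate check structural invariants (binary, positive branch
#'   lengths, ultrametric tips).
#' @return an object of class `clads_tree`.
#' @export
clads_tree <- function(parent, children, age, label, root, validate = TRUE) {
  tr <- structure(
    list(n_tip = length(label), label = as.character(label),
         parent = as.integer(parent), children = children,
         age = as.numeric(age), root = as.integer(root)),
    class = "clads_tree")
  if (validate) validate_clads_tree(tr)
  tr
}

n_nodes <- function(tree) length(tree$age)

is_tip <- function(tree, i) i <= tree$n_tip

#' @export
print.clads_tree <- function(x, ...) {
  cat(sprintf("clads_tree: %d tips, root age %.6g\n", x$n_tip,
              x$age[x$root]))
  invisible(x)
}

#' Validate a reconstructed tree
#'
#' Checks the structural invariants: binary topology, consistent parent/child
#' pointers, non-negative branch lengths, and (optionally) ultrametric tips.
#' Tip ages are required to agree within a relative tolerance of the root age;
#' larger deviations are an error, never silently corrected.
#'
#' @param tree a `clads_tree`.
#' @param ultrametric require all tips at age 0.
#' @param tol relative tolerance for tip-age agreement.
#' @return the tree, invisibly.
#' @export
validate_clads_tree <- function(tree, ultrametric = TRUE, tol = 1e-6) {
  n <- tree$n_tip
  nn <- n_nodes(tree)
  if (n < 2L) stop("a reconstructed tree needs at least 2 tips")
  if (nn != 2L * n - 1L) stop("binary tree must have 2*n_tip - 1 nodes")
  if (anyDuplicated(tree$label)) stop("duplicate tip labels")
  if (tree$parent[tree$root] != 0L) stop("root must have no parent")
  if (sum(tree$parent == 0L) != 1L) stop("exactly one root required")
  for (i in seq_len(nn)) {
    kids <- tree$children[i, ]
    if (i <= n) {
      if (!all(is.na(kids))) stop("tips must have no children")
    } else {
      if (any(is.na(kids))) stop("non-binary node: internal nodes need 2 children")
      if (!all(tree$parent[kids] == i)) stop("inconsistent parent/child pointers")
      if (any(tree$age[kids] > tree$age[i] + 1e-12))
        stop("negative branch length: child older than parent")
    }
  }
  if (ultrametric) {
    ra <- tree$age[tree$root]
    if (any(abs(tree$age[seq_len(n)]) > tol * max(ra, 1e-12)))
      stop("non-ultrametric tree: tip ages differ from the present")
  }
  invisible(tree)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------- parsing --

#' Parse a Newick string
#'
#' Reads a rooted binary tree with branch lengths on all non-root edges.
#' Node ages are computed from branch lengths with the deepest leaf placed at
#' age 0. BEAST-style metadata comments of the form `[&...]` attached to
#' nodes are preserved as opaque strings in `attr(tree, "annotations")`
#' (a list indexed by node id).
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @param require_ultrametric error if tip depths disagree by more than
#'   `tol` relative to the tree height.
#' @param tol relative tolerance for the ultrametry check.
#' @return a `clads_tree`.
#' @export
parse_newick <- function(text, require_ultrametric = TRUE, tol = 1e-6) {
  s <- trimws(text)
  nch <- nchar(s)
  pos <- 1L
  peek <- function() if (pos > nch) "" else substr(s, pos, pos)
  adv <- function() pos <<- pos + 1L
  skip_ws <- function() {
    while (pos <= nch && substr(s, pos, pos) %in% c(" ", "\t", "\n", "\r"))
      pos <<- pos + 1L
  }
  specials <- c("(", ")", ",", ":", ";", "[", "]")
  read_comment <- function() {
    start <- pos
    depth <- 0L
    repeat {
      ch <- peek()
      if (ch == "") stop("malformed Newick: unterminated [ comment")
      if (ch == "[") depth <- depth + 1L
      adv()
      if (ch == "]") {
        depth <- depth - 1L
        if (depth == 0L) break
      }
    }
    substr(s, start, pos - 1L)
  }
  read_label <- function() {
    if (peek() == "'") {
      adv()
      start <- pos
      while (peek() != "'") {
        if (peek() == "") stop("malformed Newick: unterminated quoted label")
        adv()
      }
      lab <- substr(s, start, pos - 1L)
      adv()
      return(lab)
    }
    start <- pos
    while (pos <= nch) {
      ch <- substr(s, pos, pos)
      if (ch %in% specials || ch %in% c(" ", "\t", "\n", "\r")) break
      adv()
    }
    substr(s, start, pos - 1L)
  }
  read_number <- function() {
    start <- pos
    while (pos <= nch &&
           grepl("[-+0-9.eE]", substr(s, pos, pos))) adv()
    if (pos == start) stop("malformed Newick: expected a branch length")
    val <- suppressWarnings(as.numeric(substr(s, start, pos - 1L)))
    if (is.na(val)) stop("malformed Newick: unreadable branch length")
    val
  }
  parse_clade <- function() {
    skip_ws()
    node <- list(children = list(), label = "", blen = NA_real_, annot = NULL)
    if (peek() == "(") {
      adv()
      repeat {
        node$children[[length(node$children) + 1L]] <- parse_clade()
        skip_ws()
        ch <- peek()
        if (ch == ",") { adv(); next }
        if (ch == ")") { adv(); break }
        stop("malformed Newick: expected ',' or ')'")
      }
    }
    skip_ws()
    if (!(peek() %in% c(specials, "")))
      node$label <- read_label()
    skip_ws()
    if (peek() == "[") node$annot <- read_comment()
    skip_ws()
    if (peek() == ":") {
      adv()
      skip_ws()
      if (peek() == "[") node$annot <- paste0(node$annot %||% "", read_comment())
      node$blen <- read_number()
      skip_ws()
      if (peek() == "[") node$annot <- paste0(node$annot %||% "", read_comment())
    }
    node
  }
  top <- parse_clade()
  skip_ws()
  if (peek() != ";") stop("malformed Newick: missing terminating ';'")

  count_tips <- function(nd) {
    k <- length(nd$children)
    if (k == 0L) return(1L)
    if (k != 2L) stop("non-binary node: ", k, " children")
    count_tips(nd$children[[1L]]) + count_tips(nd$children[[2L]])
  }
  n <- count_tips(top)
  if (n < 2L) stop("a tree needs at least 2 tips")
  nn <- 2L * n - 1L
  parent <- integer(nn)
  children <- matrix(NA_integer_, nn, 2L)
  depth <- numeric(nn)
  label <- character(n)
  annot <- vector("list", nn)
  next_tip <- 0L
  next_int <- n
  assign_ids <- function(nd, par, d) {
    if (length(nd$children) == 0L) {
      next_tip <<- next_tip + 1L
      id <- next_tip
      if (!nzchar(nd$label)) stop("malformed Newick: unlabelled tip")
      label[id] <<- nd$label
    } else {
      next_int <<- next_int + 1L
      id <- next_int
    }
    parent[id] <<- par
    depth[id] <<- d
    annot[[id]] <<- nd$annot
    if (par > 0L && is.na(nd$blen))
      stop("missing branch length on a non-root edge")
    if (length(nd$children) == 2L) {
      ids <- vapply(nd$children, function(ch) {
        if (is.na(ch$blen)) stop("missing branch length on a non-root edge")
        assign_ids(ch, id, d + ch$blen)
      }, integer(1L))
      children[id, ] <<- ids
    }
    id
  }
  root <- assign_ids(top, 0L, 0)
  if (anyDuplicated(label)) stop("duplicate tip labels")
  height <- max(depth[seq_len(n)])
  age <- height - depth
  if (require_ultrametric &&
      any(abs(age[seq_len(n)]) > tol * max(height, 1e-12)))
    stop("non-ultrametric tree: tip depths differ by more than the tolerance")
  age[seq_len(n)] <- 0
  tr <- clads_tree(parent, children, age, label, root,
                   validate = require_ultrametric)
  if (any(!vapply(annot, is.null, logical(1L))))
    attr(tr, "annotations") <- annot
  tr
}

## ---------------------------------------------------------------- writing --

format_bl <- function(x) sprintf("%.15g", x)

annotation_string <- function(annotations, i) {
  if (is.null(annotations)) return("")
  a <- annotations[[i]]
  if (is.null(a) || length(a) == 0L) return("")
  if (is.character(a) && is.null(names(a)) && length(a) == 1L &&
      startsWith(a, "[")) return(a)  # opaque preserved comment
  vals <- vapply(seq_along(a), function(j) {
    v <- a[[j]]
    if (is.numeric(v)) sprintf("%s=%.15g", names(a)[j], v)
    else sprintf("%s=%s", names(a)[j], as.character(v))
  }, character(1L))
  paste0("[&", paste(vals, collapse = ","), "]")
}

#' Write a tree as a Newick string
#'
#' Branch lengths are emitted with 15 significant digits so that
#' `parse_newick(write_newick(t))` reproduces ages to well below 1e-9.
#' Optional per-node annotations are emitted as `[&key=value,...]` metadata
#' comments after the node label, the dialect understood by common tree
#' annotation and visualisation tools.
#'
#' @param tree a `clads_tree`.
#' @param annotations optional list indexed by node id; each element a named
#'   vector (emitted as `[&k=v,...]`) or an opaque `"[...]"` string.
#' @param labels optional replacement tip labels (used by the Nexus writer's
#'   translate table).
#' @return a single Newick string, terminated by `;`.
#' @export
write_newick <- function(tree, annotations = NULL, labels = tree$label) {
  build <- function(i) {
    kids <- tree$children[i, ]
    core <- if (is.na(kids[1L])) labels[i]
            else paste0("(", build(kids[1L]), ",", build(kids[2L]), ")")
    ann <- annotation_string(annotations, i)
    if (i == tree$root) paste0(core, ann)
    else paste0(core, ann, ":",
                format_bl(tree$age[tree$parent[i]] - tree$age[i]))
  }
  paste0(build(tree$root), ";")
}

#' Convert to / from ape's phylo format
#'
#' @param tree a `clads_tree`.
#' @return `as_phylo()` returns an `ape::phylo`; `from_phylo()` a
#'   `clads_tree`.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' @rdname as_phylo
#' @param phy an ultrametric binary `phylo` object.
#' @export
from_phylo <- function(phy) {
  parse_newick(ape::write.tree(phy, digits = 15))
}

## --------------------------------------------------- internode intervals --

#' Internode intervals of an ultrametric tree
#'
#' Returns the durations g_k during which exactly k lineages exist in the
#' reconstructed tree, ordered from the root (k = 2) to the present (k = n).
#' These are the inputs of the gamma statistic.
#'
#' @param tree an ultrametric `clads_tree` with at least 3 tips.
#' @return a data frame with columns `k` (lineage count) and `duration`;
#'   durations sum to the root age.
#' @export
internode_intervals <- function(tree) {
  n <- tree$n_tip
  if (n < 3L) stop("internode intervals need at least 3 tips")
  ages <- sort(tree$age[(n + 1L):n_nodes(tree)], decreasing = TRUE)
  dur <- c(ages[-length(ages)] - ages[-1L], ages[length(ages)])
  data.frame(k = 2L:n, duration = dur)
}

## -------------------------------------------------------------- file I/O --

#' Read / write Newick tree files
#'
#' @param path file path.
#' @param ... passed to [parse_newick()].
#' @return `read_newick()` returns a `clads_tree`.
#' @export
read_newick <- function(path, ...) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""), ...)
}

#' @rdname read_newick
#' @param tree a `clads_tree`.
#' @param annotations see [write_newick()].
#' @export
write_newick_file <- function(tree, path, annotations = NULL) {
  writeLines(write_newick(tree, annotations), path)
  invisible(path)
}

## ------------------------------------------------------- Nexus tree logs --

#' Streaming Nexus tree-log writer
#'
#' Writes a `#NEXUS` Trees block with a translate table, one tree per logged
#' MCMC sample, readable by TreeAnnotator-style post-processors and by
#' `ape::read.nexus`. Open the log once, append trees as the chain runs,
#' close it at the end.
#'
#' @param path output path.
#' @param labels taxon labels (fixed across the run).
#' @return a log handle (environment) for [nexus_log_add()] /
#'   [nexus_log_close()].
#' @export
nexus_log_open <- function(path, labels) {
  con <- file(path, open = "wt")
  writeLines(c(
    "#NEXUS",
    "Begin taxa;",
    sprintf("\tDimensions ntax=%d;", length(labels)),
    "\tTaxlabels",
    paste0("\t\t", labels),
    "\t\t;",
    "End;",
    "Begin trees;",
    "\tTranslate",
    paste0("\t\t", seq_along(labels), " ", labels,
           ifelse(seq_along(labels) < length(labels), ",", "")),
    ";"), con)
  env <- new.env(parent = emptyenv())
  env$con <- con
  env$labels <- labels
  env
}

#' @rdname nexus_log_open
#' @param log a handle from [nexus_log_open()].
#' @param tree a `clads_tree` whose labels match the log's taxa.
#' @param name tree name (e.g. `"STATE_1000"`).
#' @param annotations see [write_newick()].
#' @export
nexus_log_add <- function(log, tree, name, annotations = NULL) {
  idx <- match(tree$label, log$labels)
  if (anyNA(idx)) stop("tree labels do not match the Nexus taxa")
  num_labels <- tree$label
  num_labels[] <- as.character(idx)
  writeLines(sprintf("tree %s = [&R] %s", name,
                     write_newick(tree, annotations, labels = num_labels)),
             log$con)
  invisible(log)
}

#' @rdname nexus_log_open
#' @export
nexus_log_close <- function(log) {
  writeLines("End;", log$con)
  close(log$con)
  invisible(NULL)
}

## ------------------------------------------------------- small utilities --

#' Total branch length of a tree
#' @param tree a `clads_tree`.
#' @return sum of all edge durations.
#' @export
tree_length <- function(tree) {
  nonroot <- setdiff(seq_len(n_nodes(tree)), tree$root)
  sum(tree$age[tree$parent[nonroot]] - tree$age[nonroot])
}

edge_ids <- function(tree) setdiff(seq_len(n_nodes(tree)), tree$root)

descendant_of <- function(tree, j, i) {
  # is j inside the clade rooted at i?
  while (j != 0L) {
    if (j == i) return(TRUE)
    j <- tree$parent[j]
  }
  FALSE
}

#' Build a random ultrametric starting tree
#'
#' Coalescent-style random topology with node ages placed as sorted uniform
#' draws below the root age. Used only to initialise MCMC chains; the
#' stationary distribution does not depend on the start.
#'
#' @param n_tip number of tips.
#' @param root_age crown age.
#' @param labels optional tip labels (default `t1..tn`).
#' @return a `clads_tree`.
#' @export
random_ultrametric_tree <- function(n_tip, root_age,
                                    labels = paste0("t", seq_len(n_tip))) {
  stopifnot(n_tip >= 2L, root_age > 0)
  nn <- 2L * n_tip - 1L
  parent <- integer(nn)
  children <- matrix(NA_integer_, nn, 2L)
  age <- numeric(nn)
  # internal ages: root age plus sorted uniforms
  if (n_tip > 2L) {
    inner <- sort(stats::runif(n_tip - 2L, 0, root_age), decreasing = TRUE)
  } else inner <- numeric(0)
  int_ages <- c(root_age, inner)  # oldest first
  active <- 1L:n_tip              # start from tips, coalesce upward
  age[active] <- 0
  next_int <- n_tip
  # merge pairs from youngest internal age upward
  for (a in rev(int_ages)) {
    next_int <- next_int + 1L
    pick <- sample(length(active), 2L)
    kids <- active[pick]
    parent[kids] <- next_int
    children[next_int, ] <- kids
    age[next_int] <- a
    active <- c(active[-pick], next_int)
  }
  clads_tree(parent, children, age, labels, root = nn)
}
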