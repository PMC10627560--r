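# Minimal alignment likelihood for full inference: JC69 substitution model,
# strict molecular clock, Felsenstein pruning with per-node scaling, FASTA
# I/O, and a sequence simulator for synthetic fixtures. The smallest model
# sufficient to co-estimate the phylogeny and the diversification parameters
# from molecular data; richer substitution and clock models are out of
# scope.

BASES <- c("A", "C", "G", "T")

#' DNA alignment container
#'
#' Sequences are upper-case strings over `A C G T - N`; gap and `N` are
#' treated as fully ambiguous in the likelihood.
#'
#' @param taxa character vector of unique taxon names.
#' @param sequences character vector of equal-length DNA strings.
#' @return an object of class `clads_alignment` with a cached integer code
#'   matrix (1..4 for ACGT, 0 for ambiguous).
#' @export
clads_alignment <- function(taxa, sequences) {
  taxa <- trimws(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon names")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequences differ in length")
  if (length(taxa) != length(sequences))
    stop("taxa and sequences differ in length")
  chars <- unique(unlist(strsplit(sequences, "")))
  bad <- setdiff(chars, c(BASES, "-", "N"))
  if (length(bad)) stop("unsupported characters: ",
                        paste(bad, collapse = " "))
  codes <- do.call(rbind, lapply(strsplit(sequences, ""), function(s) {
    m <- match(s, BASES)
    m[is.na(m)] <- 0L
    m
  }))
  rownames(codes) <- taxa
  structure(list(taxa = taxa, sequences = sequences,
                 n_sites = lens[1L], codes = codes),
            class = "clads_alignment")
}

#' @export
print.clads_alignment <- function(x, ...) {
  cat(sprintf("clads_alignment: %d taxa x %d sites\n",
              length(x$taxa), x$n_sites))
  invisible(x)
}

#' JC69 transition probability
#'
#' `p = 1/4 + 3/4 exp(-4d/3)` for identical bases and
#' `1/4 - 1/4 exp(-4d/3)` otherwise, with `d` the expected number of
#' substitutions per site.
#'
#' @param from,to bases (`"A"`, `"C"`, `"G"`, `"T"`).
#' @param distance expected substitutions (>= 0).
#' @return the transition probability.
#' @export
jc69_transition_probability <- function(from, to, distance) {
  if (any(distance < 0)) stop("distance must be non-negative")
  e <- exp(-4 * distance / 3)
  ifelse(from == to, 0.25 + 0.75 * e, 0.25 - 0.25 * e)
}

jc69_matrix <- function(distance) {
  e <- exp(-4 * distance / 3)
  p_same <- 0.25 + 0.75 * e
  p_diff <- 0.25 - 0.25 * e
  m <- matrix(p_diff, 4L, 4L)
  diag(m) <- p_same
  m
}

#' Alignment log-likelihood under JC69 and a strict clock
#'
#' Felsenstein pruning over the reconstructed tree with branch distances
#' `clock_rate * branch time`, per-node rescaling for numerical stability,
#' uniform base frequencies at the root, and fully ambiguous partials for
#' gaps and `N`.
#'
#' @param tree a `clads_tree` whose tip labels match the alignment's taxa.
#' @param aln a [clads_alignment()].
#' @param clock_rate substitutions per unit time (> 0).
#' @return the log-likelihood.
#' @export
tree_log_likelihood <- function(tree, aln, clock_rate = 1) {
  stopifnot(clock_rate > 0)
  if (aln$n_sites < 1L) stop("empty alignment")
  idx <- match(tree$label, aln$taxa)
  if (anyNA(idx))
    stop("taxon mismatch between tree and alignment")
  S <- aln$n_sites
  nn <- n_nodes(tree)
  partials <- vector("list", nn)
  for (i in seq_len(tree$n_tip)) {
    code <- aln$codes[idx[i], ]
    L <- matrix(0, 4L, S)
    known <- code > 0L
    L[cbind(code[known], which(known))] <- 1
    L[, !known] <- 1
    partials[[i]] <- L
  }
  log_scale <- 0
  internals <- ((tree$n_tip + 1L):nn)[order(tree$age[(tree$n_tip + 1L):nn])]
  for (i in internals) {
    kids <- tree$children[i, ]
    L <- matrix(1, 4L, S)
    for (k in kids) {
      d <- clock_rate * (tree$age[i] - tree$age[k])
      L <- L * (jc69_matrix(d) %*% partials[[k]])
    }
    cm <- pmax(L[1L, ], L[2L, ], L[3L, ], L[4L, ])
    log_scale <- log_scale + sum(log(cm))
    partials[[i]] <- sweep(L, 2L, cm, "/")
  }
  root <- partials[[tree$root]]
  sum(log(0.25 * (root[1L, ] + root[2L, ] + root[3L, ] + root[4L, ]))) +
    log_scale
}

#' Simulate an alignment down a clocked tree
#'
#' Root states uniform over `A C G T`; states evolve along each edge under
#' JC69 with distance `clock_rate * branch time`.
#'
#' @param tree a `clads_tree`.
#' @param n_sites number of sites (>= 1).
#' @param clock_rate substitutions per unit time (>= 0).
#' @return a [clads_alignment()] over the tree's tip labels.
#' @export
simulate_alignment <- function(tree, n_sites, clock_rate = 1) {
  stopifnot(n_sites >= 1L, clock_rate >= 0)
  nn <- n_nodes(tree)
  states <- vector("list", nn)
  states[[tree$root]] <- sample.int(4L, n_sites, replace = TRUE)
  ord <- ((tree$n_tip + 1L):nn)[order(tree$age[(tree$n_tip + 1L):nn],
                                      decreasing = TRUE)]
  for (i in ord) {
    for (k in tree$children[i, ]) {
      d <- clock_rate * (tree$age[i] - tree$age[k])
      e <- exp(-4 * d / 3)
      p_same <- 0.25 + 0.75 * e
      par <- states[[i]]
      change <- stats::runif(n_sites) >= p_same
      child <- par
      if (any(change)) {
        shift <- sample.int(3L, sum(change), replace = TRUE)
        child[change] <- (par[change] - 1L + shift) %% 4L + 1L
      }
      states[[k]] <- child
    }
  }
  seqs <- vapply(seq_len(tree$n_tip), function(i)
    paste(BASES[states[[i]]], collapse = ""), character(1L))
  clads_alignment(tree$label, seqs)
}

#' Read / write FASTA alignments
#'
#' Reading goes through `ape::read.FASTA` (case-insensitive,
#' wrap-agnostic); sequences are normalised to upper case and must form an
#' alignment (equal lengths, unique headers).
#'
#' @param path file path.
#' @return `read_fasta()` returns a [clads_alignment()].
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  if (anyDuplicated(names(dna))) stop("duplicate headers in FASTA")
  seqs <- vapply(as.character(dna), function(s)
    toupper(paste(s, collapse = "")), character(1L))
  clads_alignment(names(dna), unname(seqs))
}

#' @rdname read_fasta
#' @param aln a [clads_alignment()].
#' @param width line-wrap width.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(aln$taxa)) {
    writeLines(paste0(">", aln$taxa[i]), con)
    s <- aln$sequences[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}
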