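# Tree building and scoring: NJ, UPGMA, Fitch parsimony, exhaustive
# topology enumeration, outgroup rooting and bipartition utilities.

check_dist_input <- function(D, min_taxa) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix must have taxon names")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distances must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero")
  if (nrow(D) < min_taxa) stop("need at least ", min_taxa, " taxa")
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (via \code{ape::nj}). On an additive matrix
#' this recovers the unique generating tree with exact branch lengths.
#' Negative branch-length estimates, which NJ can produce on noisy input,
#' are clamped to zero with the deficit transferred to the sibling branch;
#' the number of clamped branches is recorded in the \code{"clamped"}
#' attribute.
#'
#' @param D symmetric distance matrix (>= 3 taxa) with taxon dimnames.
#' @return an unrooted \code{phylo}.
#' @export
neighbor_joining <- function(D) {
  D <- check_dist_input(D, 3)
  phy <- ape::nj(stats::as.dist(D))
  clamp_negative_branches(phy)
}

# Zero out negative branch lengths, moving the deficit onto a sibling edge
# so path lengths through the node are approximately preserved.
clamp_negative_branches <- function(phy) {
  n_clamped <- 0L
  for (pass in 1:10) {
    neg <- which(phy$edge.length < 0)
    if (!length(neg)) break
    i <- neg[which.min(phy$edge.length[neg])]
    n_clamped <- n_clamped + 1L
    deficit <- phy$edge.length[i]
    phy$edge.length[i] <- 0
    sib <- setdiff(which(phy$edge[, 1] == phy$edge[i, 1]), i)
    if (length(sib)) phy$edge.length[sib[1]] <-
        phy$edge.length[sib[1]] + deficit
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  attr(phy, "clamped") <- n_clamped
  phy
}

#' UPGMA (average-linkage) tree
#'
#' Rooted ultrametric tree from average-linkage agglomeration; node heights
#' are half the merged average distance, so two taxa at distance \code{d}
#' join at height \code{d/2}.
#'
#' @param D symmetric distance matrix (>= 2 taxa) with taxon dimnames.
#' @return a rooted ultrametric \code{phylo}.
#' @export
upgma_tree <- function(D) {
  D <- check_dist_input(D, 2)
  phangorn::upgma(stats::as.dist(D))
}

#' Fitch parsimony score
#'
#' Minimum number of state changes required on the tree, summed over sites
#' (Fitch small parsimony). \code{N} and \code{-} in the alignment are
#' treated as missing data (the leaf may take any base).
#'
#' @param tree a \code{phylo} whose tip labels are a subset of the
#'   alignment's taxa.
#' @param aln a [dna_alignment()].
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  missing <- setdiff(tree$tip.label, aln_taxa(aln))
  if (length(missing))
    stop("tree tips not in alignment: ", paste(missing, collapse = ", "))
  m <- tolower(aln$mat[tree$tip.label, , drop = FALSE])
  pd <- phangorn::phyDat(m, type = "DNA")
  as.integer(phangorn::fitch(tree, pd))
}

#' Enumerate all unrooted binary topologies
#'
#' Every unrooted binary topology on the given taxa exactly once, generated
#' by stepwise leaf insertion. The number of topologies is
#' \eqn{(2n-5)!!}, so \code{n} is capped at 9 (135,135 trees).
#'
#' @param taxa character vector of 3 to 9 taxon names.
#' @return a \code{multiPhylo} of unrooted binary trees.
#' @export
enumerate_topologies <- function(taxa) {
  n <- length(taxa)
  if (n < 3 || n > 9)
    stop("topology enumeration supports 3 to 9 taxa (got ", n, ")")
  phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
}

#' Exhaustive parsimony search against a reference topology
#'
#' Scores every unrooted topology on the alignment's taxa with
#' [fitch_score()] and reports how many are strictly better (fewer steps)
#' than the reference tree, together with the distribution of their
#' step-count margins. This is the mechanism by which a published tree can
#' be shown to be beaten by large numbers of alternatives.
#'
#' @param aln a [dna_alignment()].
#' @param reference a \code{phylo} on the taxa to search over (3-9 taxa).
#' @return a list of class \code{parsimony_search} with elements
#'   \code{best_score}, \code{reference_score}, \code{n_better} (topologies
#'   strictly better than the reference), \code{margin_table} (counts of
#'   better trees by steps saved) and \code{n_topologies}.
#' @export
exhaustive_parsimony_search <- function(aln, reference) {
  taxa <- reference$tip.label
  trees <- enumerate_topologies(taxa)
  m <- tolower(aln_subset(aln, taxa)$mat)
  pd <- phangorn::phyDat(m, type = "DNA")
  scores <- vapply(trees, function(tr) as.numeric(phangorn::fitch(tr, pd)),
                   numeric(1))
  ref_score <- as.numeric(phangorn::fitch(ape::unroot(reference), pd))
  margins <- ref_score - scores
  better <- margins[margins > 0]
  structure(list(best_score = min(scores),
                 reference_score = ref_score,
                 n_better = sum(margins > 0),
                 margin_table = if (length(better)) table(better)
                                else table(numeric(0)),
                 n_topologies = length(trees)),
            class = "parsimony_search")
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat(sprintf("Exhaustive parsimony search over %d topologies\n",
              x$n_topologies))
  cat(sprintf("  best score %d; reference score %d\n",
              as.integer(x$best_score), as.integer(x$reference_score)))
  cat(sprintf("  %d topologies strictly better than the reference\n",
              as.integer(x$n_better)))
  if (x$n_better > 0) {
    cat("  better-by (steps): count\n")
    for (k in names(x$margin_table))
      cat(sprintf("    %s: %d\n", k, x$margin_table[[k]]))
  }
  invisible(x)
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge; all other
#' relationships are preserved.
#'
#' @param tree a \code{phylo}.
#' @param outgroup name of a leaf of \code{tree}.
#' @return a rooted \code{phylo} whose root's two children are the outgroup
#'   and the ingroup clade.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  rt <- ape::root(ape::unroot(tree), outgroup = outgroup,
                  resolve.root = TRUE)
  if (!is.null(rt$edge.length)) {
    root <- length(rt$tip.label) + 1L
    ke <- which(rt$edge[, 1] == root)
    if (length(ke) == 2) {
      total <- sum(rt$edge.length[ke])
      rt$edge.length[ke] <- total / 2
    }
  }
  rt
}

# Tips descending from a node (the node's own label if it is a tip).
tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  ape::extract.clade(phy, node)$tip.label
}

# Canonical key of the split {block, complement} over taxa `all`: the block
# NOT containing the lexicographically smallest taxon, sorted and joined.
split_key <- function(block, all) {
  ref <- min(all)
  if (ref %in% block) block <- setdiff(all, block)
  paste(sort(block), collapse = "|")
}

#' Bipartitions (splits) of a tree
#'
#' The splits of the leaf set induced by removing each edge of the unrooted
#' tree, canonicalized (the block not containing the lexicographically first
#' leaf, sorted, joined with \code{"|"}).
#'
#' @param tree a \code{phylo}.
#' @param include_trivial also return the trivial single-leaf splits.
#' @return character vector of unique canonical split keys.
#' @export
bipartitions <- function(tree, include_trivial = FALSE) {
  phy <- ape::unroot(tree)
  all_tips <- phy$tip.label
  n <- length(all_tips)
  keys <- character(0)
  for (i in seq_len(nrow(phy$edge))) {
    b <- tips_under(phy, phy$edge[i, 2])
    if (!include_trivial && (length(b) < 2 || length(b) > n - 2)) next
    keys <- c(keys, split_key(b, all_tips))
  }
  unique(keys)
}

# TRUE if two trees have identical leaf sets and identical unrooted
# topologies (equal non-trivial split sets).
same_topology <- function(a, b) {
  setequal(a$tip.label, b$tip.label) &&
    setequal(bipartitions(a), bipartitions(b))
}
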