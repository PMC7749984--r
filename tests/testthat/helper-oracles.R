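# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately naive (enumeration, closed forms) so it
# cannot share a failure mode with the package implementation.

# Brute-force small parsimony: minimum changes over all assignments of
# states to internal nodes, leaves with N/- free to take any base.
bf_fitch <- function(tree, aln) {
  m <- aln_matrix(aln)[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  grid <- as.matrix(expand.grid(rep(list(bases), nn),
                                stringsAsFactors = FALSE))
  total <- 0L
  for (site in seq_len(ncol(m))) {
    sets <- lapply(m[, site], function(ch)
      if (ch %in% bases) ch else bases)
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      assign <- grid[g, ]
      cost <- 0L
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        ps <- assign[p - ntip]
        cost <- cost + if (ch <= ntip) !(ps %in% sets[[ch]])
                       else ps != assign[ch - ntip]
      }
      best <- min(best, cost)
    }
    total <- total + best
  }
  as.integer(total)
}

# A dated phylo built straight from a newick string (lengths = years).
dated_tree <- function(text) {
  tr <- ape::read.tree(text = text)
  attr(tr, "dated") <- TRUE
  tr
}

# Random unrooted binary tree with positive branch lengths.
random_additive_tree <- function(n, min_len = 0.05) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- tr$edge.length + min_len
  tr
}

# Move one leaf of a tree onto a random other edge (single-leaf SPR),
# guaranteeing the topology actually changes.
move_one_leaf <- function(tree, leaf) {
  backbone <- ape::drop.tip(tree, leaf)
  tip_tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                             tip.label = leaf, edge.length = 0.1,
                             Nnode = 1L), class = "phylo")
  for (attempt in 1:50) {
    e <- sample(nrow(backbone$edge), 1)
    test <- ape::bind.tree(backbone, tip_tree,
                           where = backbone$edge[e, 2],
                           position = backbone$edge.length[e] / 2)
    if (compare_topologies(tree, test)$rf_distance > 0) return(test)
  }
  stop("could not construct a topology-changing leaf move")
}

# One simulated replicate of the preset mtDNA scenario.
preset_replicate <- function(seed, seq_length = NULL) {
  spec <- build_scenario_preset("fig1_fig3")
  if (!is.null(seq_length)) spec$seq_length <- as.integer(seq_length)
  simulate_alignment(derive_locus_tree(spec, "mtDNA"), spec, seed = seed)
}

# NJ + outgroup rooting + calibration for one replicate alignment.
date_preset_replicate <- function(aln) {
  spec <- build_scenario_preset("fig1_fig3")
  tr <- root_with_outgroup(neighbor_joining(distance_matrix(aln, "K2P")),
                           spec$outgroup)
  calibrate_ages(tr, spec$calibration$tips, spec$calibration$age)
}
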