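test_that("NJ solves the 3-taxon case exactly", {
  # pendant lengths from the three-point formulas
  D <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  pend <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(pend[["a"]], (5 + 7 - 8) / 2)
  expect_equal(pend[["b"]], (5 + 8 - 7) / 2)
  expect_equal(pend[["c"]], (7 + 8 - 5) / 2)
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(101)
  for (i in 1:10) {
    tr <- random_additive_tree(6)
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D)
    expect_equal(compare_topologies(tr, est)$rf_distance, 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("NJ validates its input", {
  D <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(D), "symmetric|at least 3")
  D3 <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  D3[1, 2] <- -0.5
  expect_error(neighbor_joining(D3), "symmetric")
  D3[2, 1] <- -0.5
  expect_error(neighbor_joining(D3), "non-negative")
})

test_that("UPGMA recovers ultrametric trees and keeps heights monotone", {
  tr <- dated_tree("((A:1,B:1):3,(C:2,D:2):2);")
  D <- ape::cophenetic.phylo(tr)
  est <- upgma_tree(D)
  expect_equal(compare_topologies(tr, est)$rf_distance, 0)
  expect_equal(unname(node_depths(est)[ape::getMRCA(est, c("A", "B"))]), 1)
  expect_equal(unname(node_depths(est)[ape::getMRCA(est, c("A", "C"))]), 4)
  # 2 taxa at distance d join at height d/2
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  est2 <- upgma_tree(D2)
  expect_equal(unname(node_depths(est2)[3]), 1.5)
  # heights weakly decrease toward the leaves on noisy input
  set.seed(8)
  aln <- preset_replicate(6, seq_length = 400)
  est3 <- upgma_tree(distance_matrix(aln, "K2P"))
  d <- node_depths(est3)
  for (e in seq_len(nrow(est3$edge)))
    expect_gte(d[est3$edge[e, 1]], d[est3$edge[e, 2]])
})

test_that("Fitch scoring matches brute-force assignment enumeration", {
  # the textbook 4-leaf example
  aln <- dna_alignment(c(a = "A", b = "A", c = "C", d = "C"))
  expect_equal(fitch_score(ape::read.tree(text = "((a,b),(c,d));"), aln), 1)
  expect_equal(fitch_score(ape::read.tree(text = "((a,c),(b,d));"), aln), 2)
  # identical columns cost nothing
  same <- dna_alignment(c(a = "AAA", b = "AAA", c = "AAA", d = "AAA"))
  expect_equal(fitch_score(ape::read.tree(text = "((a,b),(c,d));"), same), 0)
  # randomized cross-check incl. missing data, 5-6 leaves
  set.seed(202)
  for (i in 1:5) {
    n <- sample(5:6, 1)
    tr <- ape::rtree(n, tip.label = letters[1:n])
    m <- matrix(sample(c("A", "C", "G", "T", "N", "-"), n * 6,
                       replace = TRUE, prob = c(rep(0.22, 4), 0.06, 0.06)),
                nrow = n, dimnames = list(letters[1:n], NULL))
    aln <- dna_alignment(m)
    expect_equal(fitch_score(tr, aln), bf_fitch(tr, aln))
  }
  # additivity over concatenated alignments
  a1 <- dna_alignment(m[, 1:3])
  a2 <- dna_alignment(m[, 4:6])
  expect_equal(fitch_score(tr, a1) + fitch_score(tr, a2),
               fitch_score(tr, aln))
  expect_error(fitch_score(ape::rtree(4, tip.label = LETTERS[1:4]), aln),
               "not in alignment")
})

test_that("topology enumeration yields (2n-5)!! distinct trees", {
  dfact <- function(n) prod(seq(n, 1, by = -2))
  for (n in 4:7) {
    trees <- enumerate_topologies(letters[1:n])
    expect_length(trees, dfact(2 * n - 5))
    keys <- vapply(trees, function(tr)
      paste(sort(bipartitions(tr)), collapse = ";"), character(1))
    expect_equal(anyDuplicated(keys), 0)
  }
  expect_length(enumerate_topologies(letters[1:3]), 1)
  expect_error(enumerate_topologies(letters[1:2]), "3 to 9")
  expect_error(enumerate_topologies(letters[1:10]), "3 to 9")
})

test_that("exhaustive search finds no tree beating the true topology on clean data", {
  tr <- dated_tree(paste0("((A:1000000,B:1000000):1000000,",
                          "(C:1000000,D:1000000):1000000,E:2000000);"))
  aln <- simulate_alignment(tr, clock_rate = 1.5e-8, seq_length = 2e4,
                            model = "JC69", seed = 13)
  res <- exhaustive_parsimony_search(aln, tr)
  expect_equal(res$n_better, 0)
  expect_equal(res$best_score, res$reference_score)
  # a wrong reference is beaten by at least the true tree
  wrong <- ape::read.tree(text = "((A,C),(B,D),E);")
  res2 <- exhaustive_parsimony_search(aln, wrong)
  expect_gte(res2$n_better, 1)
  expect_gt(res2$reference_score, res2$best_score)
  # all-identical data: every topology scores zero
  flat <- dna_alignment(matrix("A", 5, 10,
                               dimnames = list(c("A", "B", "C", "D", "E"),
                                               NULL)))
  res3 <- exhaustive_parsimony_search(flat, tr)
  expect_equal(res3$best_score, 0)
  expect_equal(res3$n_better, 0)
})

test_that("outgroup rooting is a midpoint insertion that preserves splits", {
  tr <- ape::read.tree(text = "(A:1,B:2,(C:3,D:4):5);")
  rt <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(rt))
  root <- length(rt$tip.label) + 1L
  kids <- rt$edge[rt$edge[, 1] == root, 2]
  expect_setequal(
    vapply(kids, function(k) paste(sort(ppaphylo:::tips_under(rt, k)),
                                   collapse = "|"), character(1)),
    c("A", "B|C|D"))
  # midpoint of the outgroup pendant edge
  expect_equal(sort(rt$edge.length[rt$edge[, 1] == root]), c(0.5, 0.5))
  # split set preserved; re-rooting then unrooting returns the topology
  expect_setequal(bipartitions(rt, include_trivial = TRUE),
                  bipartitions(tr, include_trivial = TRUE))
  expect_equal(compare_topologies(tr, ape::unroot(rt))$rf_distance, 0)
  expect_error(root_with_outgroup(tr, "Z"), "not a leaf")
})
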