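#' K2P / JC69 transition-probability matrix
#'
#' Closed-form Kimura two-parameter transition probabilities for a branch of
#' expected length \code{d} substitutions/site with transition/transversion
#' rate ratio \code{kappa}; \code{kappa = 1} gives Jukes-Cantor. Row/column
#' order is A, C, G, T.
#'
#' @param d expected substitutions per site on the branch.
#' @param kappa transition/transversion rate ratio.
#' @return a 4x4 stochastic matrix.
#' @keywords internal
k2p_pmatrix <- function(d, kappa = 4) {
  stopifnot(d >= 0, kappa > 0)
  # rate scaling: total rate alpha + 2 beta == 1 per unit branch length
  bt <- d / (kappa + 2)            # beta * t
  at <- kappa * bt                 # alpha * t
  pv <- 0.25 - 0.25 * exp(-4 * bt)                       # each transversion
  ps <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt)) # transition
  p0 <- 1 - ps - 2 * pv
  #        A   C   G   T
  m <- rbind(c(p0, pv, ps, pv),   # A
             c(pv, p0, pv, ps),   # C
             c(ps, pv, p0, pv),   # G
             c(pv, ps, pv, p0))   # T
  dimnames(m) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  m
}

#' Simulate a clock-evolved alignment along a dated tree
#'
#' Evolves sequences site-independently down a dated tree under a strict
#' molecular clock: each branch of duration \eqn{t} years receives expected
#' \eqn{t \times} \code{clock_rate} substitutions per site under the JC69 or
#' K2P model. The random-number stream is consumed branch by branch in a
#' fixed preorder (cladewise) traversal, so a given seed yields an identical
#' alignment on any platform. No rate heterogeneity, indels or ambiguity
#' codes are generated.
#'
#' @param tree a dated rooted \code{phylo} (edge lengths in years, attribute
#'   \code{dated = TRUE}), e.g. from [species_tree()] or
#'   [derive_locus_tree()].
#' @param spec optional [scenario_spec()] supplying defaults for the model
#'   parameters below.
#' @param clock_rate substitutions per site per year.
#' @param seq_length number of sites.
#' @param model \code{"K2P"} or \code{"JC69"}.
#' @param kappa transition/transversion rate ratio (K2P).
#' @param seed integer RNG seed; identical seeds give identical alignments.
#' @return a [dna_alignment()] with one row per tree leaf.
#' @examples
#' spec <- build_scenario_preset("fig1_fig3")
#' aln <- simulate_alignment(derive_locus_tree(spec, "mtDNA"), spec,
#'                           seq_length = 500, seed = 1)
#' @export
simulate_alignment <- function(tree, spec = NULL,
                               clock_rate = NULL, seq_length = NULL,
                               model = NULL, kappa = NULL, seed = NULL) {
  if (!isTRUE(attr(tree, "dated")))
    stop("tree must be dated (edge lengths in years, attribute 'dated'); ",
         "see species_tree() / derive_locus_tree()")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  pick <- function(x, field, default) {
    if (!is.null(x)) x
    else if (!is.null(spec)) spec[[field]]
    else default
  }
  clock_rate <- pick(clock_rate, "clock_rate", 1.5e-8)
  seq_length <- as.integer(pick(seq_length, "seq_length", 16500L))
  model <- match.arg(pick(model, "model", "K2P"), c("K2P", "JC69"))
  kappa <- if (model == "JC69") 1 else pick(kappa, "kappa", 4)
  seed <- as.integer(pick(seed, "seed", 1L))
  stopifnot(clock_rate >= 0, seq_length > 0)

  set.seed(seed)
  phy <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  states <- matrix(NA_integer_, nrow = nnode, ncol = seq_length)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, seq_length, replace = TRUE)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    d <- phy$edge.length[i] * clock_rate
    if (d == 0) {
      states[ch, ] <- states[p, ]
      next
    }
    P <- k2p_pmatrix(d, kappa)
    out <- integer(seq_length)
    for (s in 1:4) {
      idx <- which(states[p, ] == s)
      if (length(idx))
        out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                               prob = P[s, ])
    }
    states[ch, ] <- out
  }
  bases <- c("A", "C", "G", "T")
  m <- matrix(bases[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(m) <- phy$tip.label
  dna_alignment(m)
}
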