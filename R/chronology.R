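# Calibrated molecular-clock dating: relative node depths from branch
# lengths, linearly scaled through a single calibration node.

#' Relative node depths of a rooted tree
#'
#' The depth of a node is the mean, over its descendant leaves, of the path
#' length from the node to the leaf (leaves have depth 0). Because mean
#' path lengths on a non-clocklike tree need not be monotone, depths are
#' then repaired bottom-up: each parent's depth is raised to at least the
#' maximum depth of its children, so depths weakly decrease from root to
#' leaves. On an ultrametric tree the repair is a no-op and depths equal
#' the true node heights.
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @return numeric vector of depths indexed by ape node number (tips
#'   \code{1..n}, internals \code{n+1..}).
#' @export
node_depths <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  psum <- numeric(nn)           # sum of path lengths to descendant leaves
  cnt <- c(rep(1, ntip), rep(0, phy$Nnode))
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    psum[p] <- psum[p] + psum[ch] + phy$edge.length[i] * cnt[ch]
    cnt[p] <- cnt[p] + cnt[ch]
  }
  depth <- psum / cnt
  # monotonicity repair (children are final before their parent edge)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    depth[p] <- max(depth[p], depth[ch])
  }
  depth
}

#' Calibrated node ages from a single calibration point
#'
#' Converts relative node depths (substitutions/site) into absolute ages by
#' linear scaling anchored at one calibrated node:
#' \eqn{age(v) = cal\_age \times depth(v) / depth(cal)}. This is strict-clock
#' dating with a single calibration and no rate smoothing; ages are
#' invariant under uniform rescaling of all branch lengths, and the
#' calibration node's age is exact by construction.
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @param cal_tips a pair of leaf names whose MRCA is the calibration node.
#' @param cal_age the calibration node's age (e.g. in YBP).
#' @return an object of class \code{age_estimates}: list with the tree, the
#'   per-node \code{depths} and \code{ages}, and the calibration used.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):3,C:4);")
#' est <- calibrate_ages(tr, c("A", "C"), 8e6)
#' mrca_age(est, c("A", "B"))   # 2e6: depth 1 vs calibration depth 4
#' @export
calibrate_ages <- function(tree, cal_tips, cal_age) {
  if (length(cal_tips) != 2)
    stop("cal_tips must be a pair of leaf names")
  missing <- setdiff(cal_tips, tree$tip.label)
  if (length(missing))
    stop("calibration tips not in tree: ", paste(missing, collapse = ", "))
  depths <- node_depths(tree)
  cal_node <- ape::getMRCA(tree, cal_tips)
  if (depths[cal_node] <= 0)
    stop("calibration node has zero depth; cannot scale")
  structure(list(tree = tree, depths = depths,
                 ages = cal_age * depths / depths[cal_node],
                 cal_node = cal_node, cal_tips = cal_tips,
                 cal_age = cal_age),
            class = "age_estimates")
}

#' @rdname calibrate_ages
#' @param est an \code{age_estimates} object.
#' @param tips leaf names; the age of their MRCA is returned.
#' @export
mrca_age <- function(est, tips) {
  stopifnot(inherits(est, "age_estimates"))
  if (length(tips) == 1) return(0)
  unname(est$ages[ape::getMRCA(est$tree, tips)])
}

#' Round an age to reporting granularity
#'
#' Stored ages are exact floats; human-readable reports round to the
#' nearest 25,000 years.
#'
#' @param age numeric age(s) in years.
#' @param granularity rounding step in years.
#' @return rounded age(s).
#' @export
round_age <- function(age, granularity = 25000) {
  round(age / granularity) * granularity
}

#' @export
as.data.frame.age_estimates <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  nodes <- ntip + seq_len(x$tree$Nnode)
  data.frame(
    node = nodes,
    clade = vapply(nodes, function(v)
      paste(sort(tips_under(x$tree, v)), collapse = "|"), character(1)),
    depth = unname(x$depths[nodes]),
    age = unname(x$ages[nodes]),
    stringsAsFactors = FALSE)
}

#' @export
print.age_estimates <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Calibrated node ages (MRCA(%s) = %s YBP):\n",
              paste(x$cal_tips, collapse = ", "),
              format(x$cal_age, big.mark = ",", scientific = FALSE)))
  df <- df[order(-df$age), ]
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-11s {%s}\n",
                format(round_age(df$age[i]), big.mark = ",", scientific = FALSE),
                df$clade[i]))
  invisible(x)
}
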