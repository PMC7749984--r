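# Gene-tree / species-tree discordance: bipartition comparison, minimal
# displaced-taxon search, and topological inference of introgression
# direction from sister-group structure.

#' Compare two topologies by their bipartitions
#'
#' Decomposes both trees into non-trivial unrooted bipartitions and reports
#' which are shared and which occur in exactly one tree. The size of the
#' symmetric difference is the Robinson-Foulds distance.
#'
#' @param ref,test \code{phylo} objects on identical leaf sets.
#' @return an object of class \code{topology_comparison}: list with
#'   \code{shared}, \code{conflicting} (list \code{ref}/\code{test}) and
#'   \code{rf_distance}.
#' @export
compare_topologies <- function(ref, test) {
  if (!setequal(ref$tip.label, test$tip.label))
    stop("trees must have identical leaf sets")
  rs <- bipartitions(ref)
  ts <- bipartitions(test)
  structure(list(shared = intersect(rs, ts),
                 conflicting = list(ref = setdiff(rs, ts),
                                    test = setdiff(ts, rs)),
                 rf_distance = length(setdiff(rs, ts)) +
                   length(setdiff(ts, rs))),
            class = "topology_comparison")
}

#' @export
print.topology_comparison <- function(x, ...) {
  cat(sprintf("Topology comparison: RF distance %d (%d shared, %d + %d conflicting)\n",
              x$rf_distance, length(x$shared),
              length(x$conflicting$ref), length(x$conflicting$test)))
  invisible(x)
}

#' Minimal set of displaced taxa between two topologies
#'
#' Exhaustively searches leaf subsets of size 0 to \code{max_k} (in order
#' of increasing size, lexicographically within a size) for the smallest
#' set whose removal from both trees leaves identical unrooted topologies.
#' If no subset within \code{max_k} reconciles the trees the result is
#' flagged irreconcilable rather than raising an error.
#'
#' @param ref,test \code{phylo} objects on identical leaf sets.
#' @param max_k maximum subset size to try (exact search; keep small).
#' @return an object of class \code{displaced_set}: list with \code{taxa}
#'   (character, possibly empty), \code{reconciled} (logical) and \code{k}.
#' @export
displaced_taxa <- function(ref, test, max_k = 3) {
  if (!setequal(ref$tip.label, test$tip.label))
    stop("trees must have identical leaf sets")
  taxa <- sort(ref$tip.label)
  if (same_topology(ref, test))
    return(structure(list(taxa = character(0), reconciled = TRUE, k = 0L),
                     class = "displaced_set"))
  for (k in seq_len(min(max_k, length(taxa) - 3))) {
    subsets <- utils::combn(taxa, k, simplify = FALSE)
    for (ss in subsets) {
      r2 <- ape::drop.tip(ref, ss)
      t2 <- ape::drop.tip(test, ss)
      if (same_topology(r2, t2)) {
        stopifnot(setequal(bipartitions(r2), bipartitions(t2))) # invariant
        return(structure(list(taxa = ss, reconciled = TRUE, k = k),
                         class = "displaced_set"))
      }
    }
  }
  structure(list(taxa = character(0), reconciled = FALSE,
                 k = NA_integer_, max_k = max_k),
            class = "displaced_set")
}

#' @export
print.displaced_set <- function(x, ...) {
  if (!x$reconciled)
    cat(sprintf("irreconcilable within k = %d displaced taxa\n", x$max_k))
  else if (x$k == 0)
    cat("topologies identical; no displaced taxa\n")
  else
    cat(sprintf("displaced taxa (k = %d): %s\n", x$k,
                paste(x$taxa, collapse = ", ")))
  invisible(x)
}

#' Infer the direction of an introgression from sister-group structure
#'
#' Purely topological direction call for a displaced taxon: the donor is
#' the smallest clade of the reference tree that contains the displaced
#' taxon's new sister group in the test tree; the recipient is the
#' displaced taxon itself. The rule trace records the taxon's sister group
#' in both trees, i.e. which of the two competing sister-group
#' configurations (forward vs reverse transfer) the test tree matches. No
#' branch-length or likelihood evidence is used.
#'
#' @param ref rooted reference (species) tree.
#' @param test rooted test (gene) tree on the same leaves.
#' @param taxon a displaced leaf (member of a [displaced_taxa()] result).
#' @return an object of class \code{direction_call}: list with
#'   \code{recipient}, \code{donor_tips} (leaves of the donor clade in
#'   \code{ref}), \code{sister_ref}, \code{sister_test} and \code{trace}.
#' @export
infer_introgression_direction <- function(ref, test, taxon) {
  if (!setequal(ref$tip.label, test$tip.label))
    stop("trees must have identical leaf sets")
  if (!taxon %in% ref$tip.label) stop("unknown taxon '", taxon, "'")
  if (!ape::is.rooted(ref) || !ape::is.rooted(test))
    stop("both trees must be rooted")
  if (compare_topologies(ref, test)$rf_distance == 0)
    stop("trees are concordant; no introgression to infer")
  sister_ref <- sister_leaves(ref, taxon)
  sister_test <- sister_leaves(test, taxon)
  if (setequal(sister_ref, sister_test))
    stop("taxon '", taxon, "' is not displaced: same sister group in both",
         " trees")
  donor_tips <- if (length(sister_test) == 1) sister_test
                else sort(tips_under(ref, ape::getMRCA(ref, sister_test)))
  trace <- c(
    sprintf("reference: %s is sister to {%s}", taxon,
            paste(sister_ref, collapse = ", ")),
    sprintf("test: %s is sister to {%s}", taxon,
            paste(sister_test, collapse = ", ")),
    sprintf("donor = lineage of the smallest reference clade containing the new sister group: {%s}",
            paste(donor_tips, collapse = ", ")),
    sprintf("call: introgression from the {%s} lineage into %s",
            paste(donor_tips, collapse = ", "), taxon))
  structure(list(recipient = taxon, donor_tips = donor_tips,
                 sister_ref = sort(sister_ref),
                 sister_test = sort(sister_test), trace = trace),
            class = "direction_call")
}

# Leaves of the sibling subtree of a leaf in a rooted tree.
sister_leaves <- function(tree, taxon) {
  tip <- match(taxon, tree$tip.label)
  p <- tree$edge[tree$edge[, 2] == tip, 1]
  kids <- setdiff(tree$edge[tree$edge[, 1] == p, 2], tip)
  sort(unlist(lapply(kids, tips_under, phy = tree)))
}

#' @export
print.direction_call <- function(x, ...) {
  cat("Introgression direction call:\n")
  for (line in x$trace) cat(" ", line, "\n")
  invisible(x)
}

#' Full discordance report between a reference and a test tree
#'
#' Combines [compare_topologies()], [displaced_taxa()] and
#' [infer_introgression_direction()] into one report. The direction rule is
#' purely topological; this is stated in the report output.
#'
#' @param ref rooted reference (species) tree.
#' @param test rooted test (gene) tree on the same leaves.
#' @param max_k maximum displaced-set size searched.
#' @return an object of class \code{discordance_report}: list with
#'   \code{comparison}, \code{displaced} and \code{directions} (one
#'   \code{direction_call} or error message per displaced taxon).
#' @export
discordance_report <- function(ref, test, max_k = 3) {
  cmp <- compare_topologies(ref, test)
  disp <- displaced_taxa(ref, test, max_k = max_k)
  directions <- list()
  for (tx in disp$taxa) {
    directions[[tx]] <- tryCatch(
      infer_introgression_direction(ref, test, tx),
      error = function(e) conditionMessage(e))
  }
  structure(list(comparison = cmp, displaced = disp,
                 directions = directions),
            class = "discordance_report")
}

#' @export
print.discordance_report <- function(x, ...) {
  print(x$comparison)
  print(x$displaced)
  for (tx in names(x$directions)) {
    d <- x$directions[[tx]]
    if (is.character(d)) cat(sprintf("  %s: no direction call (%s)\n",
                                     tx, d))
    else print(d)
  }
  cat("note: direction calls are purely topological (sister-group rule);",
      "no branch-length or likelihood test of introgression\n")
  invisible(x)
}
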