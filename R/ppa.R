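# Progressive phylogenetic analysis: ordered taxon addition with full
# re-inference per step, attachment-edge recording and monophyly
# classification of labelled taxon groups.

#' Monophyly / paraphyly / polyphyly of a taxon group
#'
#' A group is monophyletic when the leaves of its MRCA are exactly the
#' group; otherwise it is paraphyletic when its complement (within the
#' classification universe) is monophyletic, i.e. the group is a clade
#' minus a single nested clade; otherwise it is polyphyletic. The verdict
#' is a pure function of the rooted tree and the group.
#'
#' The classification universe defaults to all leaves except the outgroup.
#' Passing \code{within} restricts it further, e.g. to the population-level
#' leaves when archaic lineages in the tree should not count toward the
#' complement.
#'
#' @param tree a rooted \code{phylo}.
#' @param group leaf names; must be a non-empty proper subset of the
#'   universe.
#' @param within optional leaf set defining the classification universe.
#' @param outgroup optional leaf excluded from both group and complement.
#' @return an object of class \code{monophyly_verdict}: list with
#'   \code{status} (\code{"monophyletic"}, \code{"paraphyletic"} or
#'   \code{"polyphyletic"}) and \code{witness} (the MRCA clade's leaf set).
#' @export
monophyly_status <- function(tree, group, within = NULL, outgroup = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  universe <- if (is.null(within)) tree$tip.label else within
  universe <- setdiff(universe, outgroup)
  missing <- setdiff(universe, tree$tip.label)
  if (length(missing))
    stop("universe taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(group) == 0) stop("group must be non-empty")
  if (!all(group %in% universe))
    stop("group must be contained in the classification universe")
  if (setequal(group, universe))
    stop("group must be a proper subset of the classification universe")
  t2 <- if (setequal(universe, tree$tip.label)) tree
        else ape::drop.tip(tree, setdiff(tree$tip.label, universe))
  clade <- function(g) {
    if (length(g) == 1) return(g)
    sort(tips_under(t2, ape::getMRCA(t2, g)))
  }
  w <- clade(group)
  status <-
    if (setequal(w, group)) "monophyletic"
    else if (setequal(clade(setdiff(universe, group)),
                      setdiff(universe, group))) "paraphyletic"
    else "polyphyletic"
  structure(list(status = status, witness = w, group = sort(group)),
            class = "monophyly_verdict")
}

#' @export
print.monophyly_verdict <- function(x, ...) {
  cat(sprintf("{%s} is %s (MRCA clade: {%s})\n",
              paste(x$group, collapse = ", "), x$status,
              paste(x$witness, collapse = ", ")))
  invisible(x)
}

#' Attachment edge of a newly added taxon
#'
#' Given the tree before (\code{prev}) and after (\code{curr}) adding one
#' taxon, finds the edge of \code{prev} onto which the taxon attached:
#' removing the taxon's pendant edge from \code{curr} merges two edges into
#' one, whose bipartition is looked up among the edges of \code{prev}
#' (trivial pendant splits included). When \code{curr} restricted to the
#' old leaves no longer matches \code{prev} (the re-inference rearranged
#' something beyond the insertion), the nearest edge by bipartition
#' similarity is returned and the record is flagged \code{shifted}.
#'
#' @param prev \code{phylo} on the previous leaf set.
#' @param curr \code{phylo} on the previous leaves plus \code{taxon}.
#' @param taxon the added leaf name.
#' @return list of class \code{attachment_edge}: \code{taxon},
#'   \code{edge} (canonical bipartition key of the attachment edge of
#'   \code{prev}), \code{sibling} (the new taxon's sister leaves in
#'   \code{curr}) and \code{shifted} (logical).
#' @export
attachment_edge <- function(prev, curr, taxon) {
  if (!taxon %in% curr$tip.label)
    stop("taxon '", taxon, "' is not a leaf of the current tree")
  if (!setequal(curr$tip.label, c(prev$tip.label, taxon)) ||
      taxon %in% prev$tip.label)
    stop("leaves(curr) must equal leaves(prev) plus the added taxon")
  old <- prev$tip.label
  un <- ape::unroot(curr)
  tip <- match(taxon, un$tip.label)
  p <- un$edge[un$edge[, 2] == tip, 1]
  kids <- setdiff(un$edge[un$edge[, 1] == p, 2], tip)
  sib_block <- tips_under(un, kids[1])
  sibling <- sort(unlist(lapply(kids, tips_under, phy = un)))
  key <- split_key(setdiff(sib_block, taxon), old)
  restricted <- ape::drop.tip(curr, taxon)
  shifted <- !same_topology(prev, restricted)
  prev_keys <- bipartitions(prev, include_trivial = TRUE)
  if (!key %in% prev_keys) {
    # nearest prev edge by symmetric difference of split blocks
    target <- strsplit(key, "|", fixed = TRUE)[[1]]
    dist_to <- function(k) {
      b <- strsplit(k, "|", fixed = TRUE)[[1]]
      min(length(union(b, target)) - length(intersect(b, target)),
          length(union(setdiff(old, b), target)) -
            length(intersect(setdiff(old, b), target)))
    }
    d <- vapply(prev_keys, dist_to, numeric(1))
    key <- sort(prev_keys[d == min(d)])[1]
    shifted <- TRUE
  }
  structure(list(taxon = taxon, edge = key, sibling = sibling,
                 shifted = shifted),
            class = "attachment_edge")
}

#' Progressive phylogenetic analysis (PPA)
#'
#' Runs the ordered taxon-addition procedure: a tree is inferred on the
#' core sampling, then each addition triggers a full re-inference on the
#' enlarged taxon set (not a graft onto the previous tree). For every step
#' the new taxon's attachment edge relative to the previous tree is
#' recorded, the tree is rooted on the outgroup, and each labelled group is
#' classified as mono-, para- or polyphyletic. Group classification is done
#' within the union of the labelled groups, so unlabelled taxa (e.g. the
#' outgroup or archaic lineages) do not count toward a group's complement.
#'
#' @param aln a [dna_alignment()] covering all taxa involved.
#' @param core leaf names of the initial sampling (must include
#'   \code{outgroup}).
#' @param additions ordered leaf names added one per step.
#' @param method \code{"NJ"} (neighbor joining on \code{dist_model}
#'   distances) or \code{"parsimony"} (exhaustive Fitch search; total taxon
#'   count must stay within the 9-taxon enumeration cap).
#' @param outgroup leaf used to root every step's tree.
#' @param groups named list of leaf-name vectors (e.g.
#'   \code{list(african = ..., non_african = ...)}).
#' @param dist_model distance model for \code{method = "NJ"}.
#' @return an object of class \code{ppa_result}: list with \code{initial}
#'   (step-0 tree and verdicts), \code{records} (one
#'   \code{placement_record} per addition: \code{step}, \code{taxon},
#'   \code{attachment}, \code{tree}, \code{status}), \code{final_tree} and
#'   the run settings.
#' @export
ppa_run <- function(aln, core, additions, method = c("NJ", "parsimony"),
                    outgroup, groups, dist_model = "K2P") {
  method <- match.arg(method)
  all_taxa <- c(core, additions)
  if (anyDuplicated(all_taxa)) stop("core and additions must be disjoint")
  missing <- setdiff(all_taxa, aln_taxa(aln))
  if (length(missing))
    stop("taxa not in alignment: ", paste(missing, collapse = ", "))
  if (!outgroup %in% core) stop("outgroup must be part of the core")
  if (method == "parsimony" && length(all_taxa) > 9)
    stop("parsimony PPA is exhaustive and capped at 9 taxa; use method",
         " = \"NJ\" for larger samplings")

  infer <- function(taxa) {
    sub <- aln_subset(aln, taxa)
    tr <- if (method == "NJ") {
      neighbor_joining(distance_matrix(sub, dist_model))
    } else {
      trees <- enumerate_topologies(taxa)
      sc <- vapply(trees, fitch_score, integer(1), aln = sub)
      trees[[which.min(sc)]]
    }
    root_with_outgroup(tr, outgroup)
  }
  classify <- function(tree, taxa) {
    universe <- intersect(unlist(groups, use.names = FALSE), taxa)
    universe <- setdiff(universe, outgroup)
    lapply(groups, function(g) {
      g <- intersect(g, taxa)
      if (length(g) == 0 || setequal(g, universe)) return(NULL)
      monophyly_status(tree, g, within = universe)
    })
  }

  tree <- infer(core)
  initial <- list(tree = tree, status = classify(tree, core))
  records <- vector("list", length(additions))
  for (k in seq_along(additions)) {
    taxa <- c(core, additions[seq_len(k)])
    curr <- infer(taxa)
    att <- attachment_edge(tree, curr, additions[k])
    records[[k]] <- structure(
      list(step = k, taxon = additions[k], attachment = att,
           tree = curr, status = classify(curr, taxa)),
      class = "placement_record")
    tree <- curr
  }
  structure(list(initial = initial, records = records, final_tree = tree,
                 core = core, additions = additions, method = method,
                 outgroup = outgroup, groups = groups,
                 dist_model = if (method == "NJ") dist_model else NA),
            class = "ppa_result")
}

#' @export
print.placement_record <- function(x, ...) {
  cat(sprintf("step %d: + %s -> edge {%s}%s\n", x$step, x$taxon,
              x$attachment$edge,
              if (x$attachment$shifted) " [topology shifted]" else ""))
  for (lab in names(x$status))
    if (!is.null(x$status[[lab]]))
      cat(sprintf("    %s: %s\n", lab, x$status[[lab]]$status))
  invisible(x)
}

#' @export
print.ppa_result <- function(x, ...) {
  cat(sprintf("PPA run: core of %d taxa + %d additions (%s%s)\n",
              length(x$core), length(x$additions), x$method,
              if (!is.na(x$dist_model)) paste0(", ", x$dist_model) else ""))
  cat("  core:", paste(x$core, collapse = ", "), "\n")
  for (rec in x$records) print(rec)
  fin <- x$records[[length(x$records)]]$status
  cat("  final verdicts:",
      paste(sprintf("%s = %s", names(fin),
                    vapply(fin, function(v)
                      if (is.null(v)) "NA" else v$status, character(1))),
            collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.ppa_result <- function(object, ...) {
  recs <- object$records
  data.frame(
    step = vapply(recs, `[[`, integer(1), "step"),
    taxon = vapply(recs, `[[`, character(1), "taxon"),
    edge = vapply(recs, function(r) r$attachment$edge, character(1)),
    shifted = vapply(recs, function(r) r$attachment$shifted, logical(1)),
    do.call(rbind, lapply(recs, function(r)
      as.data.frame(lapply(r$status, function(v)
        if (is.null(v)) NA_character_ else v$status),
        stringsAsFactors = FALSE))),
    stringsAsFactors = FALSE)
}
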